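#' Sweep specification
#'
#' Defines the diameter grid and the field/frequency values a sweep runs
#' over, plus the packing fraction and mobility mode.
#'
#' @param D_min,D_max,D_step Diameter grid (m); the default 0.01 nm step is
#'   fine enough that the sub-grid refinement moves peaks by well under the
#'   0.1 nm reporting precision.
#' @param f_values Frequencies (Hz).
#' @param H_values Field amplitudes (A/m).
#' @param epsilon Packing fraction.
#' @param mode `"dispersed"` or `"immobilized"`.
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(D_min = 1e-9, D_max = 25e-9, D_step = 0.01e-9,
                       f_values = c(100e3, 500e3), H_values = c(10e3, 50e3),
                       epsilon = 0.024,
                       mode = c("dispersed", "immobilized")) {
  mode <- match.arg(mode)
  .check_scalar(D_min, "D_min"); .check_scalar(D_max, "D_max")
  .check_scalar(D_step, "D_step")
  if (D_min >= D_max) {
    stop("invalid parameter: diameter range requires D_min < D_max",
         call. = FALSE)
  }
  if (length(f_values) == 0L || length(H_values) == 0L) {
    stop("invalid parameter: f_values and H_values must be non-empty",
         call. = FALSE)
  }
  if (any(f_values <= 0) || any(H_values < 0)) {
    stop("invalid parameter: frequencies must be positive and field ",
         "amplitudes non-negative", call. = FALSE)
  }
  .check_scalar(epsilon, "epsilon", positive = FALSE, nonneg = TRUE)
  if (epsilon > 1) {
    stop("invalid parameter: `epsilon` must lie in [0, 1]", call. = FALSE)
  }
  structure(list(D_min = D_min, D_max = D_max, D_step = D_step,
                 f_values = f_values, H_values = H_values,
                 epsilon = epsilon, mode = mode),
            class = "sweep_spec")
}

#' Model configuration
#'
#' Bundles material, coating, medium and sweep specification into one
#' validated object consumed by the sweep machinery and the CLI.
#'
#' @param material A [material_params()] object.
#' @param coating A [coating_params()] object.
#' @param medium A [medium_params()] object.
#' @param sweep A [sweep_spec()] object.
#' @return An object of class `slp_config`.
#' @export
slp_config <- function(material, coating, medium, sweep = sweep_spec()) {
  stopifnot(inherits(material, "material_params"),
            inherits(coating, "coating_params"),
            inherits(medium, "medium_params"),
            inherits(sweep, "sweep_spec"))
  structure(list(material = material, coating = coating, medium = medium,
                 sweep = sweep),
            class = "slp_config")
}

#' Packaged parameter presets
#'
#' Two ready-made configurations for gamma-cyclodextrin-coated cobalt
#' ferrite (CoFe2O4) nanoparticles dispersed in saline at 300 K:
#'
#' * `"cofe2o4_gcd"` — the base study conditions: Ms = 425 kA/m,
#'   K = 200 kJ/m^3, rho = 5.29 g/cm^3, packing fraction 0.024,
#'   eta = 7e-4 Pa s, shell thickness 1.6 nm; diameter grid 1-25 nm,
#'   H in 10-50 kA/m, f in 100-500 kHz.
#' * `"cofe2o4_gcd_dense"` — the same particle and medium at high packing
#'   fraction 0.15 with extended ranges: H 5-100 kA/m, f 50-1000 kHz,
#'   D 1-30 nm.
#'
#' @param name Preset name.
#' @return An [slp_config()] object.
#' @examples
#' cfg <- slp_preset("cofe2o4_gcd")
#' @export
slp_preset <- function(name = c("cofe2o4_gcd", "cofe2o4_gcd_dense")) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% c("cofe2o4_gcd", "cofe2o4_gcd_dense")) {
    stop("unknown preset: ", deparse(substitute(name)),
         " (available: \"cofe2o4_gcd\", \"cofe2o4_gcd_dense\")",
         call. = FALSE)
  }
  mat <- material_params(Ms = 425e3, K = 200e3, rho = 5.29e3)
  coat <- coating_params(1.6e-9)
  med <- medium_params(eta = 7e-4, T = 300, mobile = TRUE)
  sw <- if (name == "cofe2o4_gcd") {
    sweep_spec(D_min = 1e-9, D_max = 25e-9, D_step = 0.01e-9,
               f_values = c(100e3, 500e3), H_values = c(10e3, 30e3, 50e3),
               epsilon = 0.024)
  } else {
    sweep_spec(D_min = 1e-9, D_max = 30e-9, D_step = 0.01e-9,
               f_values = c(50e3, 500e3, 1000e3),
               H_values = c(5e3, 50e3, 100e3), epsilon = 0.15)
  }
  slp_config(mat, coat, med, sw)
}

#' @export
print.slp_config <- function(x, ...) {
  print(x$material)
  cat(sprintf("Coating: d = %.3g nm; medium: eta = %.3g Pa s, T = %g K, %s\n",
              x$coating$d * 1e9, x$medium$eta, x$medium$T,
              if (x$medium$mobile) "mobile (dispersed)" else "immobilized"))
  cat(sprintf("Sweep: D %g-%g nm (step %g nm), epsilon = %g, mode = %s\n",
              x$sweep$D_min * 1e9, x$sweep$D_max * 1e9, x$sweep$D_step * 1e9,
              x$sweep$epsilon, x$sweep$mode))
  cat("  H (kA/m):", paste(x$sweep$H_values / 1e3, collapse = ", "),
      "  f (kHz):", paste(x$sweep$f_values / 1e3, collapse = ", "), "\n")
  invisible(x)
}
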