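#' @keywords internal
.check_scalar <- function(x, name, positive = TRUE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop("invalid parameter: `", name, "` must be a single finite number",
         call. = FALSE)
  }
  if (positive && x <= 0) {
    stop("invalid parameter: `", name, "` must be strictly positive, got ",
         format(x), call. = FALSE)
  }
  if (nonneg && x < 0) {
    stop("invalid parameter: `", name, "` must be non-negative, got ",
         format(x), call. = FALSE)
  }
  x
}

#' Intrinsic magnetic material parameters
#'
#' Bundles the material constants of the nanoparticle core. All values are
#' strict SI; user-facing unit conversion happens in the config/CLI layer.
#'
#' @param Ms Spontaneous magnetization (A/m).
#' @param K Effective magnetic anisotropy constant (J/m^3).
#' @param rho Mass density of the magnetic material (kg/m^3). Used to
#'   normalize the volumetric loss power to W per gram of magnetic core;
#'   the coating mass is not counted.
#' @param tau0 Attempt time of the Neel process (s); the customary value
#'   1e-9 s is the default.
#' @param Msat Saturation magnetization (A/m); defaults to `Ms`.
#'
#' @return An object of class `material_params`.
#' @examples
#' cofe2o4 <- material_params(Ms = 425e3, K = 200e3, rho = 5.29e3)
#' @export
material_params <- function(Ms, K, rho, tau0 = 1e-9, Msat = Ms) {
  out <- list(
    Ms   = .check_scalar(Ms, "Ms"),
    K    = .check_scalar(K, "K"),
    rho  = .check_scalar(rho, "rho"),
    tau0 = .check_scalar(tau0, "tau0"),
    Msat = .check_scalar(Msat, "Msat")
  )
  structure(out, class = "material_params")
}

#' Organic coating parameters
#'
#' @param d Thickness of the organic shell (m). `d = 0` recovers an
#'   uncoated particle; the shell enters the model only through the
#'   hydrodynamic diameter used by the Brown relaxation time.
#'
#' @return An object of class `coating_params`.
#' @export
coating_params <- function(d) {
  structure(list(d = .check_scalar(d, "d", positive = FALSE, nonneg = TRUE)),
            class = "coating_params")
}

#' Carrier-medium parameters
#'
#' @param eta Dynamic viscosity of the carrier liquid (Pa s).
#' @param T Absolute temperature (K); 300 K ("room temperature") by default.
#' @param mobile Whether particles are free to rotate physically (dispersed
#'   in a liquid) or are immobilized.
#'
#' @return An object of class `medium_params`.
#' @export
medium_params <- function(eta, T = 300, mobile = TRUE) {
  if (!is.logical(mobile) || length(mobile) != 1L || is.na(mobile)) {
    stop("invalid parameter: `mobile` must be TRUE or FALSE", call. = FALSE)
  }
  if (mobile) .check_scalar(eta, "eta")
  structure(list(eta = eta, T = .check_scalar(T, "T"), mobile = mobile),
            class = "medium_params")
}

#' Alternating-field parameters
#'
#' @param H Field amplitude (A/m); `H = 0` gives zero loss power.
#' @param f Field frequency (Hz).
#'
#' @return An object of class `field_params`.
#' @export
field_params <- function(H, f) {
  structure(list(H = .check_scalar(H, "H", positive = FALSE, nonneg = TRUE),
                 f = .check_scalar(f, "f")),
            class = "field_params")
}

#' Particle ensemble parameters
#'
#' The ensemble is monodisperse: a single spherical core diameter.
#'
#' @param D Magnetic core diameter (m).
#' @param epsilon Packing (volume) fraction of magnetic material in the
#'   suspension, in \[0, 1\]. Enters the model only through the initial
#'   susceptibility, so the loss power is exactly linear in it.
#'
#' @return An object of class `particle_params`.
#' @export
particle_params <- function(D, epsilon) {
  .check_scalar(D, "D")
  .check_scalar(epsilon, "epsilon", positive = FALSE, nonneg = TRUE)
  if (epsilon > 1) {
    stop("invalid parameter: `epsilon` must lie in [0, 1], got ",
         format(epsilon), call. = FALSE)
  }
  structure(list(D = D, epsilon = epsilon), class = "particle_params")
}

#' @export
print.material_params <- function(x, ...) {
  cat("Magnetic material: Ms =", x$Ms / 1e3, "kA/m, K =", x$K / 1e3,
      "kJ/m^3, rho =", x$rho / 1e3, "g/cm^3, tau0 =", format(x$tau0),
      "s\n")
  invisible(x)
}
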