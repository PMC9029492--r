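# Recognized flat config keys (units in the key names; converted to SI
# exactly once, here). Unknown keys are rejected, never ignored.
.config_keys <- c("preset", "Ms_kA_per_m", "K_kJ_per_m3", "rho_g_per_cm3",
                  "epsilon", "eta_Pa_s", "d_nm", "T_K", "tau0_s", "Msat_kA_per_m",
                  "mobile", "H_kA_per_m", "f_kHz", "D_min_nm", "D_max_nm",
                  "D_step_nm", "mode")

#' Load a model configuration from a file or preset
#'
#' Reads a flat key-value configuration (JSON or YAML, chosen by file
#' extension) and resolves it to a fully validated [slp_config()]. Keys
#' carry their units in the name (`Ms_kA_per_m`, `K_kJ_per_m3`,
#' `rho_g_per_cm3`, `epsilon`, `eta_Pa_s`, `d_nm`, `T_K`, `tau0_s`,
#' `H_kA_per_m`, `f_kHz`, `D_min_nm`, `D_max_nm`, `D_step_nm`, `mode`);
#' conversion to SI happens exactly once, at this boundary. A `preset`
#' key supplies defaults that the remaining keys override. Unknown keys
#' are rejected (fail-fast). Passing a preset name instead of a path is
#' equivalent to [slp_preset()].
#'
#' @param path Path to a `.json`/`.yaml`/`.yml` file, or a preset name.
#' @param quiet Suppress the log line with the resolved parameter set.
#' @return An [slp_config()] object.
#' @export
load_config <- function(path, quiet = FALSE) {
  if (is.character(path) && length(path) == 1L &&
      path %in% c("cofe2o4_gcd", "cofe2o4_gcd_dense")) {
    cfg <- slp_preset(path)
    if (!quiet) message("resolved preset \"", path, "\"")
    return(cfg)
  }
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop("missing file: config file not found and not a known preset: ",
         path, call. = FALSE)
  }
  raw <- if (grepl("\\.(yaml|yml)$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  if (!is.list(raw)) {
    stop("invalid config: expected a flat key-value mapping in ", path,
         call. = FALSE)
  }
  unknown <- setdiff(names(raw), .config_keys)
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         " (recognized: ", paste(.config_keys, collapse = ", "), ")",
         call. = FALSE)
  }
  base <- if (!is.null(raw$preset)) slp_preset(raw$preset)
          else slp_preset("cofe2o4_gcd")
  g <- function(key, default) if (!is.null(raw[[key]])) raw[[key]] else default

  mat <- material_params(
    Ms   = g("Ms_kA_per_m", base$material$Ms / 1e3) * 1e3,
    K    = g("K_kJ_per_m3", base$material$K / 1e3) * 1e3,
    rho  = g("rho_g_per_cm3", base$material$rho / 1e3) * 1e3,
    tau0 = g("tau0_s", base$material$tau0),
    Msat = g("Msat_kA_per_m", g("Ms_kA_per_m", base$material$Msat / 1e3)) * 1e3
  )
  coat <- coating_params(g("d_nm", base$coating$d * 1e9) * 1e-9)
  med <- medium_params(eta = g("eta_Pa_s", base$medium$eta),
                       T = g("T_K", base$medium$T),
                       mobile = g("mobile", base$medium$mobile))
  sw <- sweep_spec(
    D_min = g("D_min_nm", base$sweep$D_min * 1e9) * 1e-9,
    D_max = g("D_max_nm", base$sweep$D_max * 1e9) * 1e-9,
    D_step = g("D_step_nm", base$sweep$D_step * 1e9) * 1e-9,
    f_values = g("f_kHz", base$sweep$f_values / 1e3) * 1e3,
    H_values = g("H_kA_per_m", base$sweep$H_values / 1e3) * 1e3,
    epsilon = g("epsilon", base$sweep$epsilon),
    mode = g("mode", base$sweep$mode)
  )
  cfg <- slp_config(mat, coat, med, sw)
  if (!quiet) {
    message(sprintf(
      "resolved config: Ms=%g kA/m K=%g kJ/m^3 rho=%g g/cm^3 eps=%g eta=%g Pa.s d=%g nm T=%g K",
      mat$Ms / 1e3, mat$K / 1e3, mat$rho / 1e3, sw$epsilon, med$eta,
      coat$d * 1e9, med$T))
  }
  cfg
}

#' Write a sweep curve to CSV
#'
#' Full-precision RFC-4180 CSV with the unit-suffixed column set
#' `D_nm, f_kHz, H_kA_per_m, epsilon, chi_i, xi, langevin_factor,
#' tau_N_s, tau_B_s, tau_eff_s, Ps_W_per_g`. Values round-trip
#' bit-identically through [read_sweep_csv()]; rounding is reserved for
#' human-readable tables.
#'
#' @param curve An `slp_curve` from [sweep_curve()].
#' @param path Output file path (or `""` for standard output).
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(curve, path) {
  stopifnot(inherits(curve, "slp_curve"))
  df <- data.frame(
    D_nm = curve$D * 1e9,
    f_kHz = attr(curve, "f") / 1e3,
    H_kA_per_m = attr(curve, "H") / 1e3,
    epsilon = attr(curve, "epsilon"),
    chi_i = curve$chi_i,
    xi = curve$xi,
    langevin_factor = curve$langevin_factor,
    tau_N_s = curve$tau_N,
    tau_B_s = curve$tau_B,
    tau_eff_s = curve$tau_eff,
    Ps_W_per_g = curve$Ps
  )
  # format() with digits=17 preserves doubles exactly across the round trip
  fmt <- vapply(df, function(col) {
    if (is.numeric(col)) format(col, digits = 17, trim = TRUE,
                                scientific = NA) else as.character(col)
  }, FUN.VALUE = character(nrow(df)))
  utils::write.table(fmt, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = colnames(df))
  invisible(path)
}

#' Read a sweep CSV back into a data.frame
#'
#' @param path CSV path written by [write_sweep_csv()].
#' @return A data.frame with the same unit-suffixed columns.
#' @export
read_sweep_csv <- function(path) {
  utils::read.csv(path, colClasses = "numeric")
}

#' Serialize peak and crossover summaries to JSON
#'
#' Writes the peak-table schema used by the CLI: a list of blocks, one
#' per (H, f), each with `H_kA_per_m`, `f_kHz` and a `peaks` array of
#' `{D_M_nm, PsM_W_per_g, regime}` objects, plus an optional top-level
#' `crossover_nm`. Deterministic: no timestamps, fixed key order, full
#' numeric precision.
#'
#' @param peaks A data.frame with columns `H`, `f`, `D_M`, `Ps_M`,
#'   `regime` (SI units), e.g. from [field_response()],
#'   [frequency_response()] or [scenario_table()].
#' @param path Output path, or `NULL` to return the JSON string.
#' @param crossover Optional `crossover_result` to embed.
#' @return The JSON string, invisibly when written to a file.
#' @export
write_peaks_json <- function(peaks, path = NULL, crossover = NULL) {
  blocks <- lapply(split(peaks, interaction(peaks$H, peaks$f, drop = TRUE)),
                   function(b) {
    list(H_kA_per_m = b$H[1] / 1e3,
         f_kHz = b$f[1] / 1e3,
         peaks = lapply(seq_len(nrow(b)), function(i) {
           list(D_M_nm = b$D_M[i] * 1e9,
                PsM_W_per_g = b$Ps_M[i],
                regime = tolower(b$regime[i]))
         }))
  })
  ord <- order(vapply(blocks, function(b) b$f_kHz, numeric(1)),
               vapply(blocks, function(b) b$H_kA_per_m, numeric(1)))
  out <- list(results = unname(blocks[ord]))
  if (!is.null(crossover)) out$crossover_nm <- crossover$D_cross * 1e9
  txt <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
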