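# Continuous Ps(D) closure for a config at fixed (f, H); used by the sweep
# grid, the sub-grid peak refinement and the consistency tests.
.slp_function <- function(config, f, H, mode = config$sweep$mode,
                          epsilon = config$sweep$epsilon) {
  force(config); force(f); force(H); force(mode); force(epsilon)
  function(D) {
    .slp_eval(D, config$material, epsilon, H, f, config$medium$T,
              mode = mode, eta = config$medium$eta, d = config$coating$d)$Ps
  }
}

#' Sweep the loss power over the diameter grid
#'
#' Evaluates the full model at every diameter of the grid in `config$sweep`
#' for one (frequency, amplitude) pair. Deterministic and ordered by `D`.
#'
#' @param config An [slp_config()] object (see [slp_preset()]).
#' @param f Frequency (Hz).
#' @param H Field amplitude (A/m).
#' @param mode Overrides the sweep mode if given.
#' @return A data.frame of class `slp_curve`, one row per grid diameter,
#'   with every intermediate quantity and `Ps` (W/g). The generating
#'   configuration and settings travel along as attributes so downstream
#'   peak finding can refine and classify without re-supplying them.
#' @examples
#' curve <- sweep_curve(slp_preset("cofe2o4_gcd"), f = 500e3, H = 10e3)
#' @export
sweep_curve <- function(config, f, H, mode = config$sweep$mode) {
  stopifnot(inherits(config, "slp_config"))
  .check_scalar(f, "f")
  .check_scalar(H, "H", positive = FALSE, nonneg = TRUE)
  sw <- config$sweep
  D <- seq(sw$D_min, sw$D_max, by = sw$D_step)
  if (length(D) < 1L) {
    stop("invalid parameter: empty diameter grid", call. = FALSE)
  }
  out <- .slp_eval(D, config$material, sw$epsilon, H, f, config$medium$T,
                   mode = mode, eta = config$medium$eta, d = config$coating$d)
  attr(out, "config") <- config
  attr(out, "f") <- f
  attr(out, "H") <- H
  attr(out, "mode") <- mode
  attr(out, "epsilon") <- sw$epsilon
  class(out) <- c("slp_curve", "data.frame")
  out
}

#' Locate and refine the maxima of a loss-power curve
#'
#' Finds every strict interior local maximum of `Ps` on the grid, refines
#' each to sub-grid precision by bracketed one-dimensional optimization of
#' the continuous model within the two neighbouring grid cells, merges
#' maxima closer than `min_separation` (keeping the higher), and labels
#' each peak with its relaxation regime. Maxima sitting on a grid boundary
#' are reported as a warning, never as peaks.
#'
#' @param curve An `slp_curve` from [sweep_curve()], at least 3 points.
#' @param min_separation Merge radius (m); 0.2 nm by default, enough to
#'   suppress float-noise twin maxima.
#' @return A data.frame of class `slp_peaks` sorted by diameter:
#'   `D_M` (m), `Ps_M` (W/g), `regime` ("Brown", "Neel" or "mixed"),
#'   `refined` (logical).
#' @export
find_peaks <- function(curve, min_separation = 0.2e-9) {
  stopifnot(inherits(curve, "slp_curve"))
  if (nrow(curve) < 3L) {
    stop("invalid parameter: peak finding needs at least 3 grid points",
         call. = FALSE)
  }
  D <- curve$D
  y <- curve$Ps
  config <- attr(curve, "config")
  fun <- .slp_function(config, attr(curve, "f"), attr(curve, "H"),
                       mode = attr(curve, "mode"),
                       epsilon = attr(curve, "epsilon"))
  n <- length(y)
  # strict local maxima: y[i] > y[i-1] and y[i] > y[i+1]
  i <- 2:(n - 1L)
  interior <- i[y[i] > y[i - 1L] & y[i] > y[i + 1L]]
  if ((y[1L] > y[2L]) || (y[n] > y[n - 1L])) {
    warning("loss-power curve has a boundary maximum; ",
            "it is not reported as a peak", call. = FALSE)
  }
  if (length(interior) == 0L) {
    return(.peaks_df(numeric(0), numeric(0), character(0), logical(0)))
  }
  D_M <- Ps_M <- numeric(length(interior))
  for (k in seq_along(interior)) {
    idx <- interior[k]
    opt <- stats::optimize(fun, lower = D[idx - 1L], upper = D[idx + 1L],
                           maximum = TRUE, tol = 1e-13)
    D_M[k] <- opt$maximum
    Ps_M[k] <- opt$objective
  }
  ord <- order(D_M)
  D_M <- D_M[ord]; Ps_M <- Ps_M[ord]
  # merge peaks closer than min_separation, keeping the higher
  keep <- rep(TRUE, length(D_M))
  for (k in seq_along(D_M)[-1]) {
    prev <- max(which(keep[seq_len(k - 1L)]))
    if (D_M[k] - D_M[prev] < min_separation) {
      if (Ps_M[k] >= Ps_M[prev]) keep[prev] <- FALSE else keep[k] <- FALSE
    }
  }
  D_M <- D_M[keep]; Ps_M <- Ps_M[keep]
  regime <- if (attr(curve, "mode") == "immobilized") {
    rep("Neel", length(D_M))
  } else {
    vapply(D_M, classify_regime, character(1),
           material = config$material, coating = config$coating,
           medium = config$medium)
  }
  .peaks_df(D_M, Ps_M, regime, rep(TRUE, length(D_M)))
}

.peaks_df <- function(D_M, Ps_M, regime, refined) {
  structure(data.frame(D_M = D_M, Ps_M = Ps_M, regime = regime,
                       refined = refined, stringsAsFactors = FALSE),
            class = c("slp_peaks", "data.frame"))
}

#' Classify the relaxation regime at a diameter
#'
#' Compares the Neel and Brown relaxation times at core diameter `D`:
#' "Neel" when the Neel time is more than tenfold shorter, "Brown" when
#' the Brown time is, and "mixed" in between. The factor-10 threshold
#' reflects the finite diameter band over which both mechanisms contribute
#' comparably.
#'
#' @param D Core diameter (m).
#' @param material,coating,medium Parameter objects.
#' @return `"Brown"`, `"Neel"` or `"mixed"`.
#' @export
classify_regime <- function(D, material, coating, medium) {
  tau_N <- neel_time(material$tau0, material$K, D, medium$T)
  tau_B <- brown_time(medium$eta, hydrodynamic_diameter(D, coating$d),
                      medium$T)
  if (tau_N < tau_B / 10) "Neel"
  else if (tau_B < tau_N / 10) "Brown"
  else "mixed"
}

#' Diameter at which the Neel and Brown times cross
#'
#' Solves \eqn{\tau_N(D) = \tau_B(D_h)} by root finding on
#' \eqn{\log(\tau_N/\tau_B)} over a bracketing interval, to a relative
#' tolerance of 1e-9 in `D`. Below the crossover the moment relaxes
#' internally (Neel); above it the whole particle rotates (Brown).
#'
#' @param material,coating,medium Parameter objects.
#' @param bracket Length-2 diameter interval (m) over which
#'   \eqn{\tau_N - \tau_B} changes sign.
#' @return A list of class `crossover_result`: `D_cross` (m) and
#'   `tau_at_cross` (s), the common relaxation time.
#' @examples
#' cfg <- slp_preset("cofe2o4_gcd")
#' crossover_diameter(cfg$material, cfg$coating, cfg$medium)
#' @export
crossover_diameter <- function(material, coating, medium,
                               bracket = c(1e-9, 15e-9)) {
  ratio <- function(D) {
    expo <- pi * material$K * D^3 / (6 * slp_constants$kB * medium$T)
    log(material$tau0) + expo -
      log(brown_time(medium$eta, hydrodynamic_diameter(D, coating$d),
                     medium$T))
  }
  lo <- ratio(bracket[1]); hi <- ratio(bracket[2])
  if (is.na(lo) || is.na(hi) || lo * hi > 0) {
    stop("bracketing error: tau_N - tau_B does not change sign over ",
         "the given diameter bracket", call. = FALSE)
  }
  root <- stats::uniroot(ratio, bracket, tol = 1e-9 * mean(bracket))
  D_cross <- root$root
  tau <- brown_time(medium$eta, hydrodynamic_diameter(D_cross, coating$d),
                    medium$T)
  structure(list(D_cross = D_cross, tau_at_cross = tau),
            class = "crossover_result")
}

#' @export
print.crossover_result <- function(x, ...) {
  cat(sprintf("Neel-Brown crossover: D = %.4g nm, common tau = %.4g s\n",
              x$D_cross * 1e9, x$tau_at_cross))
  invisible(x)
}

.dominant_peak <- function(config, f, H, mode = config$sweep$mode) {
  curve <- sweep_curve(config, f, H, mode = mode)
  peaks <- find_peaks(curve)
  if (nrow(peaks) == 0L) {
    return(data.frame(D_M = NA_real_, Ps_M = NA_real_,
                      regime = NA_character_))
  }
  peaks[which.max(peaks$Ps_M), c("D_M", "Ps_M", "regime")]
}

#' Dominant-peak response to the field amplitude
#'
#' For each field amplitude, sweeps the diameter grid at fixed frequency
#' and reports the global maximum of the loss power: its location,
#' height and relaxation regime. Over the usual hyperthermia ranges the
#' peak power increases and the optimal diameter decreases with `H`.
#'
#' @param config An [slp_config()] object.
#' @param H_values Field amplitudes (A/m).
#' @param f Frequency (Hz).
#' @return A data.frame with columns `H`, `f`, `D_M`, `Ps_M`, `regime`.
#' @export
field_response <- function(config, H_values = config$sweep$H_values,
                           f = config$sweep$f_values[1]) {
  rows <- lapply(H_values, function(H) {
    cbind(data.frame(H = H, f = f), .dominant_peak(config, f, H))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Peak structure as a function of frequency
#'
#' For each frequency, sweeps the diameter grid at fixed field amplitude
#' and reports every local maximum (one row per peak): above roughly
#' 1500 kHz a second, Neel-branch maximum appears at small diameters next
#' to the dominant Brown-branch one.
#'
#' @param config An [slp_config()] object.
#' @param f_values Frequencies (Hz).
#' @param H Field amplitude (A/m).
#' @return A data.frame with columns `H`, `f`, `D_M`, `Ps_M`, `regime`,
#'   `dominant` (TRUE for the global maximum at that frequency).
#' @export
frequency_response <- function(config, f_values = config$sweep$f_values,
                               H = config$sweep$H_values[1]) {
  rows <- lapply(f_values, function(f) {
    peaks <- find_peaks(sweep_curve(config, f, H))
    if (nrow(peaks) == 0L) return(NULL)
    data.frame(H = H, f = f, D_M = peaks$D_M, Ps_M = peaks$Ps_M,
               regime = peaks$regime,
               dominant = seq_len(nrow(peaks)) == which.max(peaks$Ps_M))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Dominant-peak grid over field amplitude and frequency
#'
#' Crosses `H_values` with `f_values` and reports the global loss-power
#' maximum for every combination — the scenario table used to pick
#' operating conditions at a given packing fraction.
#'
#' @param config An [slp_config()] object (typically the high-packing
#'   preset).
#' @param H_values Field amplitudes (A/m).
#' @param f_values Frequencies (Hz).
#' @return A data.frame with one row per (H, f): `H`, `f`, `D_M`, `Ps_M`,
#'   `regime`.
#' @export
scenario_table <- function(config, H_values = config$sweep$H_values,
                           f_values = config$sweep$f_values) {
  rows <- lapply(H_values, function(H) {
    do.call(rbind, lapply(f_values, function(f) {
      cbind(data.frame(H = H, f = f), .dominant_peak(config, f, H))
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
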