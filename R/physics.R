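#' Hydrodynamic diameter of a core-shell particle
#'
#' The physical diameter that governs viscous (Brown) rotation: the magnetic
#' core plus twice the organic shell thickness. All other quantities in the
#' model (susceptibility, Langevin argument, Neel barrier) use the core
#' diameter alone.
#'
#' @param D Core diameter (m), strictly positive. Vectorized.
#' @param d Shell thickness (m), non-negative.
#' @return Hydrodynamic diameter `D + 2 d` (m).
#' @examples
#' hydrodynamic_diameter(13.6e-9, 1.6e-9)  # 16.8 nm
#' @export
hydrodynamic_diameter <- function(D, d) {
  if (any(!is.finite(D)) || any(D <= 0)) {
    stop("invalid parameter: core diameter `D` must be strictly positive",
         call. = FALSE)
  }
  if (any(!is.finite(d)) || any(d < 0)) {
    stop("invalid parameter: shell thickness `d` must be non-negative",
         call. = FALSE)
  }
  D + 2 * d
}

#' Langevin function argument
#'
#' Ratio of the magnetic (Zeeman) energy of one particle moment to the
#' thermal energy: \eqn{\xi = \pi \mu_0 M_s D^3 H / (6 k_B T)}.
#'
#' @param Ms Spontaneous magnetization (A/m).
#' @param D Core diameter (m). Vectorized.
#' @param H Field amplitude (A/m).
#' @param T Temperature (K).
#' @return Dimensionless argument, zero iff `H = 0`.
#' @export
langevin_argument <- function(Ms, D, H, T) {
  if (any(!is.finite(T)) || any(T <= 0)) {
    stop("invalid parameter: temperature `T` must be strictly positive",
         call. = FALSE)
  }
  pi * slp_constants$mu0 * Ms * D^3 * H / (6 * slp_constants$kB * T)
}

#' Langevin function
#'
#' \eqn{L(\xi) = \coth\xi - 1/\xi}, the equilibrium magnetization fraction
#' of a classical moment. Near zero the closed form cancels catastrophically,
#' so for \eqn{\xi < 10^{-4}} the Taylor series
#' \eqn{\xi/3 - \xi^3/45 + 2\xi^5/945} is used; the two branches agree to
#' better than 1e-12 at the switch point.
#'
#' @param xi Non-negative argument. Vectorized.
#' @return Value in \[0, 1), strictly increasing, `L(0) = 0`.
#' @export
langevin <- function(xi) {
  small <- is.finite(xi) & abs(xi) < 1e-4
  out <- xi
  out[small] <- xi[small] / 3 - xi[small]^3 / 45 + 2 * xi[small]^5 / 945
  big <- !small
  out[big] <- 1 / tanh(xi[big]) - 1 / xi[big]
  out[is.finite(xi) & xi == 0] <- 0
  out
}

#' Langevin saturation correction factor
#'
#' The chord factor \eqn{3 L(\xi)/\xi} that scales the initial (zero-field)
#' susceptibility down to its finite-amplitude value. Equal to 1 in the
#' linear-response limit \eqn{\xi \to 0} and strictly decreasing in
#' \eqn{\xi}.
#'
#' @param xi Non-negative argument. Vectorized.
#' @return Factor in (0, 1\].
#' @export
langevin_factor <- function(xi) {
  small <- is.finite(xi) & abs(xi) < 1e-4
  out <- xi
  out[small] <- 1 - xi[small]^2 / 15 + 2 * xi[small]^4 / 315
  big <- !small
  out[big] <- 3 * langevin(xi[big]) / xi[big]
  out
}

#' Initial magnetic susceptibility of the suspension
#'
#' \eqn{\chi_i = \epsilon \pi \mu_0 M_s^2 D^3 / (18 k_B T)}: linear in the
#' packing fraction and cubic in the core diameter.
#'
#' @param epsilon Packing fraction in \[0, 1\].
#' @param Ms Spontaneous magnetization (A/m).
#' @param D Core diameter (m). Vectorized.
#' @param T Temperature (K).
#' @return Dimensionless initial susceptibility.
#' @export
initial_susceptibility <- function(epsilon, Ms, D, T) {
  if (any(!is.finite(epsilon)) || any(epsilon < 0) || any(epsilon > 1)) {
    stop("invalid parameter: packing fraction `epsilon` must lie in [0, 1]",
         call. = FALSE)
  }
  epsilon * pi * slp_constants$mu0 * Ms^2 * D^3 / (18 * slp_constants$kB * T)
}

#' Neel relaxation time
#'
#' Arrhenius escape over the anisotropy barrier \eqn{K V}:
#' \eqn{\tau_N = \tau_0 \exp(\pi K D^3 / (6 k_B T))}. The exponent grows with
#' \eqn{D^3}; above the overflow guard (700) the time is reported as `Inf`,
#' an "effectively infinite" sentinel whose reciprocal is exactly zero in
#' the combined relaxation time.
#'
#' @param tau0 Attempt time (s).
#' @param K Anisotropy constant (J/m^3).
#' @param D Core diameter (m). Vectorized.
#' @param T Temperature (K).
#' @return Neel time (s), possibly `Inf`.
#' @export
neel_time <- function(tau0, K, D, T) {
  expo <- pi * K * D^3 / (6 * slp_constants$kB * T)
  out <- ifelse(expo > .neel_exponent_guard, Inf, tau0 * exp(expo))
  out
}

#' Brown relaxation time
#'
#' Rotational diffusion of the whole particle against viscous drag:
#' \eqn{\tau_B = 3 \eta V_h / (k_B T)} with the hydrodynamic volume
#' \eqn{V_h = \pi D_h^3/6}, i.e. \eqn{\pi \eta D_h^3 / (2 k_B T)}.
#'
#' @param eta Dynamic viscosity (Pa s).
#' @param Dh Hydrodynamic diameter (m). Vectorized.
#' @param T Temperature (K).
#' @return Brown time (s), cubic in `Dh`.
#' @export
brown_time <- function(eta, Dh, T) {
  pi * eta * Dh^3 / (2 * slp_constants$kB * T)
}

#' Combined (effective) relaxation time
#'
#' Harmonic combination \eqn{1/\tau = 1/\tau_N + 1/\tau_B}: the faster
#' mechanism dominates. Evaluated through reciprocals so that an infinite
#' input degrades gracefully to the other time.
#'
#' @param tau_N Neel time (s), possibly `Inf`. Vectorized.
#' @param tau_B Brown time (s), possibly `Inf`.
#' @return Effective time (s), never larger than either input.
#' @export
effective_time <- function(tau_N, tau_B) {
  r <- 1 / tau_N + 1 / tau_B
  if (any(r == 0)) {
    stop("invalid state: both relaxation times are infinite; ",
         "no relaxation channel remains", call. = FALSE)
  }
  1 / r
}

#' Ensemble magnetization
#'
#' \eqn{M = M_{sat} L(\xi)}: the equilibrium magnetization of the
#' superparamagnetic ensemble. Diagnostic; not on the loss-power path.
#'
#' @param Msat Saturation magnetization (A/m).
#' @param xi Langevin argument. Vectorized.
#' @return Magnetization (A/m), saturating at `Msat`.
#' @export
magnetization <- function(Msat, xi) {
  Msat * langevin(xi)
}

# Vectorized evaluation over D of the full model chain; shared by the scalar
# entry points and the sweep machinery. tau_B is NA when immobilized.
.slp_eval <- function(D, material, epsilon, H, f, T,
                      mode = c("dispersed", "immobilized"),
                      eta = NA_real_, d = 0) {
  mode <- match.arg(mode)
  chi_i <- initial_susceptibility(epsilon, material$Ms, D, T)
  xi <- langevin_argument(material$Ms, D, H, T)
  fac <- langevin_factor(xi)
  L <- langevin(xi)
  tau_N <- neel_time(material$tau0, material$K, D, T)
  if (mode == "dispersed") {
    Dh <- hydrodynamic_diameter(D, d)
    tau_B <- brown_time(eta, Dh, T)
    tau_eff <- effective_time(tau_N, tau_B)
  } else {
    Dh <- D
    tau_B <- rep(NA_real_, length(D))
    tau_eff <- tau_N
  }
  # Lorentzian of the out-of-phase Debye susceptibility
  w <- 2 * pi * f * tau_eff
  lorentz <- ifelse(is.finite(w), w / (1 + w^2), 0)
  Ps_W_per_kg <- pi * slp_constants$mu0 * f * H^2 * chi_i * fac * lorentz /
    material$rho
  data.frame(
    D = D, Dh = Dh, chi_i = chi_i, xi = xi, langevin_factor = fac, L = L,
    M = magnetization(material$Msat, xi),
    tau_N = tau_N, tau_B = tau_B, tau_eff = tau_eff,
    Ps = Ps_W_per_kg / 1000
  )
}

.breakdown <- function(row, mode) {
  structure(c(as.list(row), list(mode = mode)), class = "slp_breakdown")
}

#' Specific loss power of immobilized nanoparticles
#'
#' Debye-model loss power with the Neel relaxation time as the only
#' channel (the particle cannot rotate physically):
#' \deqn{P_s = \pi \mu_0 f H^2 \chi_i \frac{3 L(\xi)}{\xi}
#'   \frac{2\pi f \tau_N}{1 + (2\pi f \tau_N)^2} / \rho}
#' reported per gram of magnetic material (W/g). The core diameter is used
#' everywhere; there is no coating or medium in this limit.
#'
#' @param material A [material_params()] object.
#' @param particle A [particle_params()] object (core diameter, packing
#'   fraction).
#' @param field A [field_params()] object.
#' @param T Temperature (K), 300 by default.
#' @return An `slp_breakdown` object: all intermediate quantities
#'   (`chi_i`, `xi`, `langevin_factor`, `L`, `M`, `tau_N`, `tau_eff`) and
#'   the loss power `Ps` in W/g. `tau_B` is `NA`.
#' @examples
#' m <- material_params(Ms = 425e3, K = 200e3, rho = 5.29e3)
#' slp_immobilized(m, particle_params(6.2e-9, 0.024),
#'                 field_params(10e3, 500e3))
#' @export
slp_immobilized <- function(material, particle, field, T = 300) {
  stopifnot(inherits(material, "material_params"),
            inherits(particle, "particle_params"),
            inherits(field, "field_params"))
  row <- .slp_eval(particle$D, material, particle$epsilon, field$H, field$f,
                   T, mode = "immobilized")
  .breakdown(row, "immobilized")
}

#' Specific loss power of coated nanoparticles dispersed in a liquid
#'
#' Same Debye-model loss power as [slp_immobilized()], but the Lorentzian
#' uses the combined Neel-Brown relaxation time, with the Brown time
#' computed from the hydrodynamic diameter `D + 2 d`. Susceptibility,
#' Langevin argument and Neel barrier still use the core diameter.
#'
#' @param material A [material_params()] object.
#' @param coating A [coating_params()] object (shell thickness).
#' @param medium A [medium_params()] object with `mobile = TRUE`.
#' @param particle A [particle_params()] object.
#' @param field A [field_params()] object.
#' @return An `slp_breakdown` object with all intermediate quantities,
#'   including `tau_B` and the hydrodynamic diameter `Dh`, and `Ps` in W/g.
#' @examples
#' m <- material_params(Ms = 425e3, K = 200e3, rho = 5.29e3)
#' slp_dispersed(m, coating_params(1.6e-9), medium_params(7e-4),
#'               particle_params(13.6e-9, 0.024), field_params(10e3, 500e3))
#' @export
slp_dispersed <- function(material, coating, medium, particle, field) {
  stopifnot(inherits(material, "material_params"),
            inherits(coating, "coating_params"),
            inherits(medium, "medium_params"),
            inherits(particle, "particle_params"),
            inherits(field, "field_params"))
  if (!medium$mobile) {
    stop("invalid parameter: dispersed model requires a mobile medium; ",
         "use slp_immobilized() for fixed particles", call. = FALSE)
  }
  row <- .slp_eval(particle$D, material, particle$epsilon, field$H, field$f,
                   medium$T, mode = "dispersed", eta = medium$eta,
                   d = coating$d)
  .breakdown(row, "dispersed")
}

#' @export
print.slp_breakdown <- function(x, ...) {
  cat(sprintf("SLP breakdown (%s particle)\n", x$mode))
  cat(sprintf("  D      = %.4g nm   Dh = %.4g nm\n", x$D * 1e9, x$Dh * 1e9))
  cat(sprintf("  chi_i  = %.6g   xi = %.6g   3L(xi)/xi = %.6g\n",
              x$chi_i, x$xi, x$langevin_factor))
  cat(sprintf("  tau_N  = %s s   tau_B = %s s   tau = %s s\n",
              format(x$tau_N, digits = 4),
              ifelse(is.na(x$tau_B), "-", format(x$tau_B, digits = 4)),
              format(x$tau_eff, digits = 4)))
  cat(sprintf("  Ps     = %.6g W/g\n", x$Ps))
  invisible(x)
}
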