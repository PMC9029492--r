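# Independent one-line oracle for the full model chain, written directly
# from the closed-form expressions and kept free of package internals.
# Used to pin derived expected values and for the random-draw equivalence
# property.
or_mu0 <- 4 * pi * 1e-7
or_kB <- 1.380649e-23

or_chi <- function(eps, Ms, D, T) eps * pi * or_mu0 * Ms^2 * D^3 / (18 * or_kB * T)
or_xi <- function(Ms, D, H, T) pi * or_mu0 * Ms * D^3 * H / (6 * or_kB * T)
or_L <- function(x) ifelse(x == 0, 0, 1 / tanh(x) - 1 / x)
or_tauN <- function(tau0, K, D, T) tau0 * exp(pi * K * D^3 / (6 * or_kB * T))
or_tauB <- function(eta, Dh, T) pi * eta * Dh^3 / (2 * or_kB * T)

# loss power in W/g; tau supplied by the caller (Neel-only or combined)
or_ps <- function(eps, Ms, rho, D, H, f, T, tau) {
  x <- or_xi(Ms, D, H, T)
  fac <- ifelse(x == 0, 1, 3 * or_L(x) / x)
  w <- 2 * pi * f * tau
  pi * or_mu0 * f * H^2 * or_chi(eps, Ms, D, T) * fac *
    (w / (1 + w^2)) / rho / 1000
}

or_ps_dispersed <- function(eps, Ms, K, rho, eta, d, tau0, D, H, f, T) {
  tau <- 1 / (1 / or_tauN(tau0, K, D, T) + 1 / or_tauB(eta, D + 2 * d, T))
  or_ps(eps, Ms, rho, D, H, f, T, tau)
}

# canonical study conditions shared across tests
base_material <- function() material_params(Ms = 425e3, K = 200e3, rho = 5.29e3)
base_coating <- function() coating_params(1.6e-9)
base_medium <- function() medium_params(eta = 7e-4, T = 300)
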