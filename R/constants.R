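#' Physical constants
#'
#' Exact SI values used throughout: the vacuum permeability
#' \eqn{\mu_0 = 4\pi \times 10^{-7}} H/m and the Boltzmann constant
#' \eqn{k_B = 1.380649 \times 10^{-23}} J/K.
#'
#' @format A list with elements `mu0` (H/m) and `kB` (J/K).
#' @export
slp_constants <- list(
  mu0 = 4 * pi * 1e-7,
  kB  = 1.380649e-23
)

# Neel exponent clamp: exp(700) sits just under the double ceiling and a
# relaxation time beyond ~1e294 s is physically indistinguishable from
# infinite, so 1/tau_N is taken as exactly 0 above it.
.neel_exponent_guard <- 700
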