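test_that("hydrodynamic diameter adds twice the shell thickness", {
  expect_equal(hydrodynamic_diameter(13.6e-9, 1.6e-9), 16.8e-9)
  expect_equal(hydrodynamic_diameter(22.8e-9, 1.6e-9), 26.0e-9)
  expect_equal(hydrodynamic_diameter(5e-9, 0), 5e-9)
  expect_error(hydrodynamic_diameter(0, 1e-9), "strictly positive")
  expect_error(hydrodynamic_diameter(5e-9, -1e-9), "non-negative")
})

test_that("Langevin argument matches the hand oracle and vanishes at H = 0", {
  expect_equal(langevin_argument(425e3, 13.6e-9, 10e3, 300), 1.698281208,
               tolerance = 1e-8)
  expect_equal(langevin_argument(425e3, 22.8e-9, 5e3, 300), 4.000989617,
               tolerance = 1e-8)
  expect_identical(langevin_argument(425e3, 13.6e-9, 0, 300), 0)
  expect_error(langevin_argument(425e3, 13.6e-9, 10e3, -5),
               "temperature")
})

test_that("Langevin function is accurate, monotone and bounded", {
  expect_equal(langevin(1.6983), 0.4804702003, tolerance = 1e-9)
  # small-argument behaviour: L ~ xi/3 with a relative deviation of xi^2/15
  xi <- c(1e-6, 1e-5, 1e-3)
  expect_equal(langevin(xi), xi / 3, tolerance = 1e-6)
  expect_identical(langevin(0), 0)
  # branches agree across the series switch point (the closed form loses
  # ~8 digits to cancellation there, the series none)
  expect_equal(langevin(1e-4 * (1 - 1e-9)), langevin(1e-4 * (1 + 1e-9)),
               tolerance = 1e-6)
  grid <- seq(0, 50, by = 0.05)
  L <- langevin(grid)
  expect_true(all(diff(L) > 0))
  expect_true(all(L >= 0 & L < 1))
  expect_equal(langevin(500), 1, tolerance = 1e-2)
})

test_that("saturation correction factor is 1 at zero and decreasing", {
  expect_identical(langevin_factor(0), 1)
  expect_equal(langevin_factor(1.6983), 0.8487373261, tolerance = 1e-9)
  expect_equal(langevin_factor(4.0011), 0.5628990073, tolerance = 1e-9)
  grid <- seq(0, 30, by = 0.05)
  fac <- langevin_factor(grid)
  expect_true(all(diff(fac) < 0))
  expect_true(all(fac > 0 & fac <= 1))
})

test_that("initial susceptibility matches the oracle and is linear in epsilon", {
  expect_equal(initial_susceptibility(0.024, 425e3, 13.6e-9, 300),
               0.5774156108, tolerance = 1e-9)
  expect_equal(initial_susceptibility(0.15, 425e3, 22.8e-9, 300),
               17.0042058716, tolerance = 1e-9)
  expect_identical(initial_susceptibility(0, 425e3, 13.6e-9, 300), 0)
  expect_equal(initial_susceptibility(0.5, 425e3, 10e-9, 300),
               0.5 / 0.024 * initial_susceptibility(0.024, 425e3, 10e-9, 300))
  expect_error(initial_susceptibility(1.5, 425e3, 10e-9, 300), "epsilon")
})

test_that("Neel time follows the Arrhenius law with an overflow sentinel", {
  expect_equal(neel_time(1e-9, 200e3, 6.1e-9, 300), 3.106605516e-07,
               tolerance = 1e-8)
  # zero-barrier limit
  expect_equal(neel_time(1e-9, 200e3, 1e-10, 300), 1e-9, tolerance = 1e-4)
  # at 25 nm the exponent (~395) is still below the guard: astronomically
  # large but finite, and already negligible in any harmonic combination
  t25 <- neel_time(1e-9, 200e3, 25e-9, 300)
  expect_true(is.finite(t25) && t25 > 1e150)
  # beyond the guard (exponent > 700) the sentinel is exact infinity
  expect_identical(neel_time(1e-9, 200e3, 31e-9, 300), Inf)
})

test_that("Brown time matches the oracle and scales with the cube of Dh", {
  expect_equal(brown_time(7e-4, 16.8e-9, 300), 1.258755047e-06,
               tolerance = 1e-8)
  expect_equal(brown_time(7e-4, 26.0e-9, 300), 4.665878479e-06,
               tolerance = 1e-8)
  expect_equal(brown_time(7e-4, 2 * 16.8e-9, 300),
               8 * brown_time(7e-4, 16.8e-9, 300))
})

test_that("effective time is the harmonic combination with graceful infinities", {
  expect_equal(effective_time(2e-7, 2e-7), 1e-7)
  expect_equal(effective_time(3.11e-7, 2.14e-7), 1.267695238e-07,
               tolerance = 1e-8)
  expect_equal(effective_time(Inf, 5e-7), 5e-7)
  expect_equal(effective_time(5e-7, Inf), 5e-7)
  expect_true(effective_time(3e-7, 2e-7) <= 2e-7)
  expect_error(effective_time(Inf, Inf), "both relaxation times")
})

test_that("ensemble magnetization saturates at Msat", {
  expect_identical(magnetization(425e3, 0), 0)
  expect_equal(magnetization(425e3, 1.6983), 204199.8351, tolerance = 1e-8)
  expect_equal(magnetization(425e3, 1e4), 425e3, tolerance = 1e-3)
})

test_that("immobilized loss power reproduces the hand-evaluated chain", {
  m <- base_material()
  bd <- slp_immobilized(m, particle_params(6.2e-9, 0.024),
                        field_params(10e3, 500e3), T = 300)
  expect_equal(bd$Ps, 0.9847861742, tolerance = 1e-8)
  expect_true(is.na(bd$tau_B))
  expect_identical(bd$tau_eff, bd$tau_N)
  zero <- slp_immobilized(m, particle_params(6.2e-9, 0.024),
                          field_params(0, 500e3))
  expect_identical(zero$Ps, 0)
})

test_that("dispersed loss power reproduces printed operating points", {
  m <- base_material(); co <- base_coating(); me <- base_medium()
  # high-packing, low field/frequency cell
  bd1 <- slp_dispersed(m, co, me, particle_params(22.8e-9, 0.15),
                       field_params(5e3, 50e3))
  expect_equal(bd1$Ps, 4.16, tolerance = 0.01)
  # base packing at 30 kA/m, 1000 kHz
  bd2 <- slp_dispersed(m, co, me, particle_params(9.9e-9, 0.024),
                       field_params(30e3, 1000e3))
  expect_equal(bd2$Ps, 30.16, tolerance = 0.01)
  # no drive
  bd0 <- slp_dispersed(m, co, me, particle_params(9.9e-9, 0.024),
                       field_params(0, 1000e3))
  expect_identical(bd0$Ps, 0)
  # breakdown fields all populated
  expect_true(all(is.finite(c(bd1$chi_i, bd1$xi, bd1$langevin_factor,
                              bd1$tau_B, bd1$tau_eff, bd1$Dh))))
  expect_error(
    slp_dispersed(m, co, medium_params(7e-4, mobile = FALSE),
                  particle_params(9.9e-9, 0.024), field_params(30e3, 1e6)),
    "mobile")
})

test_that("parameter constructors reject invalid values", {
  expect_error(material_params(Ms = -1, K = 200e3, rho = 5.29e3), "Ms")
  expect_error(medium_params(eta = 0), "eta")
  expect_error(medium_params(7e-4, T = 0), "T")
  expect_error(field_params(-1, 500e3), "H")
  expect_error(field_params(10e3, 0), "f")
  expect_error(particle_params(10e-9, 1.5), "epsilon")
  expect_error(particle_params(0, 0.024), "D")
  expect_error(coating_params(-1e-9), "d")
})
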