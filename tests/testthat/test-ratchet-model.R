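test_that("sawtooth potential has the right shape, extrema and period", {
  p <- ratchet_params(1, 4, gamma = 15 / 8)
  expect_equal(potential_value(0, p), 0)
  expect_equal(potential_value(1, p), 4)     # V(alpha L) = L, the maximum
  expect_equal(potential_value(5, p), potential_value(1, p))  # period L
  xs <- seq(-10, 10, by = 0.01)
  expect_equal(potential_value(xs + 4, p), potential_value(xs, p))
  expect_true(all(potential_value(xs, p) >= 0))
  expect_true(all(potential_value(xs, p) <= 4))
  # piecewise linear with slopes 1/alpha and -1/(1-alpha)
  expect_equal((potential_value(0.6, p) - potential_value(0.5, p)) / 0.1, 4)
  expect_equal((potential_value(2.6, p) - potential_value(2.5, p)) / 0.1,
               -4 / 3)
})

test_that("drift is -gamma V' with right-continuous convention at kinks", {
  p <- ratchet_params(1, 4, gamma = 15 / 8)
  expect_equal(drift_value(0.5, p), -7.5)    # -gamma/alpha
  expect_equal(drift_value(2, p), 2.5)       # gamma/(1-alpha)
  expect_equal(drift_value(0, p), -7.5)      # kink: right-continuous
  expect_equal(drift_value(1, p), 2.5)
  expect_equal(drift_value(4.5, p), drift_value(0.5, p))
  # zero net drift over one period
  expect_equal((-p$gamma / p$alpha) * (p$alpha * p$L) +
                 (p$gamma / (1 - p$alpha)) * ((1 - p$alpha) * p$L), 0)
})

test_that("gamma and lambda are linked by gamma = lambda (1 - alpha) / 2", {
  p <- ratchet_params(1, 4, lambda = 5)
  expect_equal(p$gamma, 15 / 8)
  expect_equal(ratchet_params(1, 4, gamma = 15 / 8)$lambda, 5)
  expect_error(ratchet_params(1, 4, gamma = 1, lambda = 5), "inconsistent")
  expect_error(ratchet_params(2, 4, lambda = 5), "coprime")
  expect_error(ratchet_params(4, 4, lambda = 5))
  expect_error(ratchet_params(1, 4), "gamma or lambda")
})

test_that("flashing schedule finds the least m making m^2 tau integral", {
  expect_identical(flashing_schedule(2.4, 2.4)$m, 5L)
  expect_identical(flashing_schedule(1, 1)$m, 1L)
  expect_identical(flashing_schedule(0.5, 1)$m, 2L)
  expect_identical(flashing_schedule(1 / 3, 1)$m, 3L)
  s <- flashing_schedule(2.4, 1.5)  # lcm of denominators 5 and 2 is 10
  expect_identical(s$m, 10L)
  expect_equal(s$m2tau1, 240)
  expect_equal(s$m2tau2, 150)
})

test_that("equilibrium density is normalized with the closed-form constant", {
  for (pars in list(c(1, 4, 15 / 8), c(1, 3, 0.6), c(2, 3, 1.2))) {
    p <- ratchet_params(pars[1], pars[2], gamma = pars[3])
    # quadrature oracle for the normalizer
    q <- integrate(function(x) exp(-2 * p$gamma * potential_value(x, p)),
                   0, p$L, rel.tol = 1e-12)
    expect_equal(integrate(function(x) equilibrium_density(x, p),
                           0, p$L, rel.tol = 1e-12)$value, 1,
                 tolerance = 1e-10)
    expect_equal(q$value * equilibrium_density(0, p),
                 exp(-2 * p$gamma * potential_value(0, p)),
                 tolerance = 1e-10)
    # trough-to-crest ratio exp(2 gamma L)
    expect_equal(equilibrium_density(0, p) /
                   equilibrium_density(p$alpha * p$L, p),
                 exp(2 * p$gamma * p$L), tolerance = 1e-10)
  }
  # flat-potential limit: nearly uniform 1/L
  p0 <- ratchet_params(1, 4, gamma = 1e-8)
  expect_equal(equilibrium_density(c(0.3, 1.7, 3.2), p0), rep(1 / 4, 3),
               tolerance = 1e-6)
})

test_that("equilibrium CDF matches quadrature of the density", {
  p <- ratchet_params(1, 4, gamma = 15 / 8)
  for (x in c(0.3, 1, 2.5, 4)) {
    q <- integrate(function(t) equilibrium_density(t, p), 0, x,
                   rel.tol = 1e-12)$value
    expect_equal(equilibrium_cdf(x, p), q, tolerance = 1e-10)
  }
  expect_equal(equilibrium_cdf(p$L, p), 1)
})

test_that("mean drift vanishes at equilibrium for all parameters", {
  grid <- list(c(1, 4, NA, 5), c(1, 3, 0.01, NA), c(2, 3, NA, 2),
               c(3, 5, 1.7, NA), c(1, 2, 0.3, NA))
  for (g in grid) {
    p <- if (is.na(g[3])) ratchet_params(g[1], g[2], lambda = g[4])
         else ratchet_params(g[1], g[2], gamma = g[3])
    expect_lt(abs(equilibrium_mean_drift(p)), 1e-12)
    # quadrature oracle for the drift integral
    num <- integrate(function(x) drift_value(x, p) *
                       exp(-2 * p$gamma * potential_value(x, p)),
                     0, p$alpha * p$L, rel.tol = 1e-12)$value +
      integrate(function(x) drift_value(x, p) *
                  exp(-2 * p$gamma * potential_value(x, p)),
                p$alpha * p$L, p$L, rel.tol = 1e-12)$value
    expect_lt(abs(num), 1e-10)
  }
})
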