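test_that("rho_from_lambda rescales the drift rate", {
  expect_equal(rho_from_lambda(100, 5), 0.95)
  expect_equal(rho_from_lambda(10, 5), 0.5)
  expect_equal(rho_from_lambda(10, 0), 1)
  expect_error(rho_from_lambda(5, 5), "n > lambda")
  expect_error(rho_from_lambda(4, 5), "n > lambda")
})

test_that("single steps move mass with the kernel's site probabilities", {
  d0 <- delta_pmf(0, 1)
  s1 <- walk_step(d0, symmetric_kernel())
  expect_equal(pmf_sites(s1), -1:1)
  expect_equal(s1$probs, c(0.5, 0, 0.5))
  s2 <- walk_step(s1, symmetric_kernel())
  expect_equal(s2$probs, c(0.25, 0, 0.5, 0, 0.25))
  # ratchet kernel at residue 0 uses p0 = 1/10
  k <- ratchet_kernel(1, 1, 3, 1 / 3)
  r1 <- walk_step(d0, k)
  expect_equal(r1$probs, c(9 / 10, 0, 1 / 10))
})

test_that("symmetric evolution reproduces the shifted binomial law", {
  for (k in c(3, 6)) {
    pmf <- walk_evolve(delta_pmf(0, 1), symmetric_kernel(), 2 * k)
    sites <- pmf_sites(pmf)
    even <- sites %% 2 == 0
    expect_equal(pmf$probs[even], dbinom(0:(2 * k), 2 * k, 0.5))
    expect_true(all(pmf$probs[!even] == 0))   # exact parity zeros
  }
})

test_that("evolution equals exhaustive path enumeration on ratchet kernels", {
  n <- 2L; l <- 1L; Lint <- 4L; rho <- 0.5
  kern <- ratchet_kernel(n, l, Lint, rho)
  pp <- probs_from_rho(rho, l, Lint)
  up_fun <- function(pos, k)
    if (pos %% (n * Lint) < n * l) pp[["p0"]] else pp[["p1"]]
  for (start in c(0L, 3L, -5L)) {
    for (steps in c(4L, 12L)) {
      got <- walk_evolve(delta_pmf(start, n), kern, steps)
      want <- oracle_line_pmf(start, steps, up_fun)
      expect_equal(pmf_sites(got), want$sites)
      expect_equal(got$probs, want$prob, tolerance = 1e-14)
    }
  }
})

test_that("mass is conserved and parity is exact after many steps", {
  kern <- ratchet_kernel(5, 1, 4, 0.8)
  pmf <- walk_evolve(delta_pmf(3, 5), kern, 501)
  expect_lt(abs(sum(pmf$probs) - 1), 1e-12)
  expect_true(all(pmf$probs >= 0))
  # after an odd number of steps from an odd start, even sites are empty
  sites <- pmf_sites(pmf)
  expect_true(all(pmf$probs[sites %% 2 == 1] == 0))
  # stepwise conservation
  p <- delta_pmf(0, 5)
  for (i in 1:50) {
    p <- walk_step(p, kern)
    expect_lt(abs(sum(p$probs) - 1), 1e-12)
  }
})

test_that("symmetric phases preserve the mean exactly", {
  kern <- ratchet_kernel(3, 1, 3, 0.7)
  pmf <- walk_evolve(delta_pmf(1, 3), kern, 7)  # an asymmetric pmf
  m0 <- sum(pmf_positions(pmf) * pmf$probs)
  pmf2 <- walk_evolve(pmf, symmetric_kernel(), 40)
  expect_equal(sum(pmf_positions(pmf2) * pmf2$probs), m0, tolerance = 1e-12)
  expect_identical(walk_evolve(pmf, symmetric_kernel(), 0), pmf)
})

test_that("flash_evolve enforces the refinement preconditions", {
  p <- paper_params(5)
  s <- paper_schedule()
  expect_error(flash_evolve(0, 99, p, s), "multiple of m")
  expect_error(flash_evolve(0, 5, p, s), "n > lambda")
  # degenerate rho = 1: the ratchet phase is symmetric, no net motion
  kern <- ratchet_kernel(2, 1, 4, 1)
  pmf <- walk_evolve(delta_pmf(0, 2), kern, 20)
  expect_equal(sum(pmf_positions(pmf) * pmf$probs), 0, tolerance = 1e-14)
})

test_that("flash_evolve equals the phase-aware path oracle on a tiny lattice", {
  p <- ratchet_params(1, 2, lambda = 1)
  s <- flashing_schedule(1, 2)     # m = 1
  n <- 2L
  K1 <- n^2 * 1; K2 <- n^2 * 2     # 4 + 8 = 12 steps
  got <- flash_evolve(0, n, p, s)
  want <- oracle_line_pmf(0L, K1 + K2, flash_up_fun(n, p, K1))
  expect_equal(pmf_sites(got), want$sites)
  expect_equal(got$probs, want$prob, tolerance = 1e-14)
  expect_equal(got$steps_taken, K1 + K2)
})
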