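test_that("fair-pair parametrization reproduces the known cases", {
  pp <- probs_from_rho(1 / 3, 1, 3)
  expect_equal(pp[["p0"]], 1 / 10)   # classical game B
  expect_equal(pp[["p1"]], 3 / 4)
  expect_equal(unname(probs_from_rho(1, 1, 3)), c(0.5, 0.5))
  pp4 <- probs_from_rho(0.95, 1, 4)  # (1-alpha)/alpha = 3
  expect_equal(pp4[["p0"]], 0.95^3 / (1 + 0.95^3), tolerance = 1e-12)
  expect_equal(pp4[["p1"]], 1 / 1.95, tolerance = 1e-12)
  expect_error(probs_from_rho(1.2, 1, 3), "rho")
  expect_error(probs_from_rho(0, 1, 3), "rho")
  expect_error(probs_from_rho(0.5, 2, 4))
})

test_that("fair pair satisfies the detailed-balance identity and ordering", {
  for (lL in list(c(1, 3), c(1, 4), c(2, 3), c(3, 5), c(2, 5))) {
    for (rho in c(0.1, 1 / 3, 0.6, 0.95)) {
      l <- lL[1]; Lint <- lL[2]
      pp <- probs_from_rho(rho, l, Lint)
      p0 <- pp[["p0"]]; p1 <- pp[["p1"]]
      expect_true(p0 < 1 / 2 && p1 > 1 / 2)
      lhs <- (1 - p0)^l * (1 - p1)^(Lint - l)
      rhs <- p0^l * p1^(Lint - l)
      expect_equal(lhs, rhs, tolerance = 1e-12)
    }
  }
})

test_that("game B invariant profile obeys detailed balance and the closed form", {
  spec <- game_b_spec(1, 3, 1 / 3)
  expect_equal(game_b_invariant_profile(spec), c(5, 2, 6) / 13)
  # symbolic profile (1 + rho^2, rho (1 + rho), 1 + rho) / (2 (1 + rho + rho^2))
  for (rho in c(0.2, 0.5, 0.9)) {
    sp <- game_b_spec(1, 3, rho)
    expect_equal(game_b_invariant_profile(sp),
                 c(1 + rho^2, rho * (1 + rho), 1 + rho) /
                   (2 * (1 + rho + rho^2)),
                 tolerance = 1e-12)
  }
  # detailed balance across every edge of the cycle, general alpha
  for (lL in list(c(1, 4), c(2, 5), c(3, 4))) {
    sp <- game_b_spec(lL[1], lL[2], 0.4)
    pi <- game_b_invariant_profile(sp)
    u <- game_b_up_probs(sp)
    Lint <- sp$L_int
    for (j in seq_len(Lint)) {
      jn <- j %% Lint + 1
      expect_equal(pi[j] * u[j], pi[jn] * (1 - u[jn]), tolerance = 1e-12)
    }
    expect_equal(sum(pi), 1, tolerance = 1e-14)
  }
})

test_that("cycle stationary law solves pi P = pi and matches the profile", {
  expect_equal(cycle_stationary(rep(0.5, 5)), rep(1 / 5, 5))
  # two-state cycle: both moves reach the other state, so uniform
  expect_equal(cycle_stationary(c(0.3, 0.8)), c(0.5, 0.5))
  # independent route agrees with the detailed-balance construction
  for (rho in c(0.25, 0.7)) {
    sp <- game_b_spec(2, 5, rho)
    expect_equal(cycle_stationary(game_b_up_probs(sp)),
                 game_b_invariant_profile(sp), tolerance = 1e-12)
  }
  # residual property on arbitrary chains
  set.seed(7)
  for (i in 1:5) {
    u <- runif(sample(3:7, 1), 0.05, 0.95)
    pi <- cycle_stationary(u)
    P <- ratchetwalk:::cycle_transition_matrix(u)
    expect_lt(max(abs(drop(pi %*% P) - pi)), 1e-12)
    expect_true(all(pi >= 0))
    expect_equal(sum(pi), 1)
  }
})

test_that("game B is asymptotically fair across shapes and rho", {
  for (lL in list(c(1, 3), c(1, 4), c(2, 3), c(3, 5), c(1, 5), c(4, 5))) {
    for (rho in c(0.1, 1 / 3, 0.6, 0.95)) {
      sp <- game_b_spec(lL[1], lL[2], rho)
      expect_lt(abs(mean_profit(game_b_up_probs(sp))), 1e-12)
    }
  }
  expect_equal(mean_profit(rep(0.5, 3)), 0)     # game A
  expect_equal(mean_profit(rep(0.6, 4)), 0.2)   # uniformly biased walk
})

test_that("mixtures are winning for alpha < 1/2 and losing for alpha > 1/2", {
  spB <- game_b_spec(1, 3, 1 / 3)
  expect_equal(mixture_mean_profit(0, spB), 0, tolerance = 1e-12)
  expect_equal(mixture_mean_profit(1, spB), 0, tolerance = 1e-12)
  for (c in c(0.2, 0.5, 0.8)) {
    expect_gt(mixture_mean_profit(c, spB), 0)              # Parrondo
    expect_lt(mixture_mean_profit(c, game_b_spec(2, 3, 1 / 3)), 0)  # anti
  }
  # another shape on each side of 1/2
  expect_gt(mixture_mean_profit(0.5, game_b_spec(1, 4, 0.5)), 0)
  expect_lt(mixture_mean_profit(0.5, game_b_spec(3, 4, 0.5)), 0)
})

test_that("periodic patterns: AB is fair, longer patterns are winning", {
  spB <- game_b_spec(1, 3, 1 / 3)
  expect_lt(abs(pattern_mean_profit(1, 1, spB)), 1e-10)
  expect_gt(pattern_mean_profit(2, 2, spB), 0)
  expect_gt(pattern_mean_profit(1, 2, spB), 0)
  expect_gt(pattern_mean_profit(2, 1, spB), 0)
  expect_gt(pattern_mean_profit(3, 2, spB), 0)
  sym <- suppressWarnings(game_b_spec(1, 3, 1))
  expect_equal(pattern_mean_profit(1, 1, sym), 0, tolerance = 1e-12)
})
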