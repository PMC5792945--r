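#' Monte-Carlo configuration for the SDE oracle
#'
#' @param n_paths number of independent sample paths.
#' @param seed integer seed for the (Mersenne-Twister) generator; every
#'   simulation call restores the caller's RNG state afterwards, so the
#'   oracle has no global side effects.
#' @param t_end simulated duration.
#' @param dt Euler-Maruyama time step (default `1e-3`; should satisfy
#'   `dt << (alpha*L/gamma)^2` so that the discontinuous-drift bias stays
#'   below the Monte-Carlo noise).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_paths, seed, t_end, dt = 1e-3) {
  stopifnot(n_paths >= 1, n_paths == as.integer(n_paths),
            seed == as.integer(seed), t_end > 0, dt > 0)
  nsteps <- round(t_end / dt)
  if (abs(nsteps * dt - t_end) > 1e-9)
    stop("dt must divide t_end")
  structure(list(n_paths = as.integer(n_paths), seed = as.integer(seed),
                 t_end = t_end, dt = dt, nsteps = as.integer(nsteps)),
            class = "sim_config")
}

# run expr under a local seed, restoring the caller's RNG state
with_local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister")
  expr
}

#' Euler-Maruyama simulation of the flashing ratchet SDE
#'
#' Simulates \eqn{dY_t = dB_t + \eta(t)\mu(Y_t)\,dt} with the flashing
#' indicator \eqn{\eta(t) = 0} when \eqn{mod(t, \tau_1+\tau_2) < \tau_1}
#' and 1 otherwise, both \eqn{\eta} and \eqn{\mu} evaluated at the left
#' endpoint of each time step (explicit scheme; the drift discontinuities
#' are not smoothed).
#'
#' @param p a [ratchet_params()] object.
#' @param s a [flashing_schedule()] object; `cfg$dt` must divide both
#'   `tau1` and `tau2`.
#' @param cfg a [sim_config()] object.
#' @param start common starting position.
#' @return Numeric vector of `n_paths` endpoint positions at `t_end`.
#' @export
simulate_flashing <- function(p, s, cfg, start = 0) {
  stopifnot(inherits(p, "ratchet_params"), inherits(s, "flashing_schedule"),
            inherits(cfg, "sim_config"))
  if (abs(s$tau1 / cfg$dt - round(s$tau1 / cfg$dt)) > 1e-12 * s$tau1 / cfg$dt ||
      abs(s$tau2 / cfg$dt - round(s$tau2 / cfg$dt)) > 1e-12 * s$tau2 / cfg$dt)
    stop("dt must divide tau1 and tau2")
  period <- s$tau1 + s$tau2
  sq <- sqrt(cfg$dt)
  with_local_seed(cfg$seed, {
    x <- rep(as.numeric(start), cfg$n_paths)
    for (k in seq_len(cfg$nsteps)) {
      t0 <- (k - 1) * cfg$dt
      eta <- (t0 %% period) >= s$tau1 - 1e-12 * period
      if (eta) x <- x + drift_value(x, p) * cfg$dt
      x <- x + sq * rnorm(cfg$n_paths)
    }
    x
  })
}

#' Wrapped endpoint histogram of the always-on Brownian ratchet
#'
#' Simulates the ratchet SDE (potential always on) to time `t_end`, wraps
#' the endpoints mod \eqn{L} and bins them; for `t_end` large relative to
#' \eqn{L^2} the histogram approaches the closed-form equilibrium density
#' \eqn{C e^{-2\gamma V}}.
#'
#' @param p a [ratchet_params()] object.
#' @param cfg a [sim_config()] object.
#' @param nbins number of equal-width bins on \eqn{[0, L)}.
#' @param start common starting position.
#' @return A list with `breaks`, bin probabilities `prob` (summing to 1),
#'   bin `density`, and `expected_prob` (the closed-form equilibrium mass
#'   per bin from [equilibrium_cdf()]).
#' @export
simulate_ratchet_wrapped <- function(p, cfg, nbins = 40L, start = 0) {
  stopifnot(inherits(p, "ratchet_params"), inherits(cfg, "sim_config"))
  sq <- sqrt(cfg$dt)
  x <- with_local_seed(cfg$seed, {
    x <- rep(as.numeric(start), cfg$n_paths)
    for (k in seq_len(cfg$nsteps))
      x <- x + drift_value(x, p) * cfg$dt + sq * rnorm(cfg$n_paths)
    x
  })
  xw <- x %% p$L
  breaks <- seq(0, p$L, length.out = nbins + 1)
  counts <- tabulate(findInterval(xw, breaks, rightmost.closed = TRUE),
                     nbins = nbins)
  prob <- counts / cfg$n_paths
  width <- p$L / nbins
  expected <- diff(equilibrium_cdf(breaks, p))
  list(breaks = breaks, prob = prob, density = prob / width,
       expected_prob = expected)
}
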