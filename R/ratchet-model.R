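#' @useDynLib ratchetwalk, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats pnorm rnorm integrate
#' @importFrom utils read.table write.table
NULL

gcd <- function(a, b) {
  while (b != 0) {
    t <- b
    b <- a %% b
    a <- t
  }
  a
}

# continued-fraction rational approximation; exact for decimal inputs such as 2.4
as_rational <- function(x, tol = 1e-9, max_den = 1000000L) {
  stopifnot(is.numeric(x), length(x) == 1L, is.finite(x), x > 0)
  p0 <- 0; q0 <- 1; p1 <- 1; q1 <- 0
  r <- x
  repeat {
    a <- floor(r)
    p2 <- a * p1 + p0
    q2 <- a * q1 + q0
    if (q2 > max_den) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    if (abs(x - p1 / q1) < tol * max(1, abs(x))) break
    if (r == a) break
    r <- 1 / (r - a)
  }
  if (abs(x - p1 / q1) > tol * max(1, abs(x)))
    stop("cannot represent ", x, " as a rational with denominator <= ", max_den)
  c(num = as.integer(p1), den = as.integer(q1))
}

prime_factors <- function(n) {
  stopifnot(n >= 1)
  f <- integer(0)
  d <- 2
  while (d * d <= n) {
    while (n %% d == 0) {
      f <- c(f, d)
      n <- n %/% d
    }
    d <- d + 1
  }
  if (n > 1) f <- c(f, n)
  f
}

#' Parameters of the sawtooth-potential Brownian ratchet
#'
#' The ratchet is a one-dimensional diffusion with unit diffusion coefficient
#' and drift \eqn{-\gamma V'(x)} for the periodic asymmetric sawtooth
#' potential \eqn{V} with rational shape \eqn{\alpha = l/L_{int}} and period
#' \eqn{L}.  The drift strength can be given either directly as `gamma` or
#' through the lattice scaling rate `lambda`, linked by
#' \eqn{\gamma = \lambda(1-\alpha)/2}; both are stored.
#'
#' @param l,L_int coprime positive integers with \eqn{0 < l < L_{int}};
#'   the shape parameter is \eqn{\alpha = l/L_{int}}.
#' @param L period length of the potential (defaults to `L_int`, the
#'   convention under which the lattice walk and the continuous model share
#'   the same period).
#' @param gamma drift strength \eqn{\gamma > 0}.
#' @param lambda scaling rate \eqn{\lambda > 0} of the walk approximation;
#'   exactly one of `gamma`, `lambda` must be supplied (or both, consistently).
#' @return An object of class `ratchet_params`.
#' @examples
#' p <- ratchet_params(1, 4, lambda = 5)
#' p$gamma  # 15/8
#' @export
ratchet_params <- function(l, L_int, L = L_int, gamma = NULL, lambda = NULL) {
  stopifnot(l == as.integer(l), L_int == as.integer(L_int))
  l <- as.integer(l); L_int <- as.integer(L_int)
  if (!(l > 0 && l < L_int)) stop("need 0 < l < L_int")
  if (gcd(l, L_int) != 1L) stop("l and L_int must be coprime")
  stopifnot(is.numeric(L), length(L) == 1L, L > 0)
  alpha <- l / L_int
  if (is.null(gamma) && is.null(lambda))
    stop("supply gamma or lambda")
  if (is.null(gamma)) gamma <- lambda * (1 - alpha) / 2
  if (is.null(lambda)) lambda <- 2 * gamma / (1 - alpha)
  if (abs(gamma - lambda * (1 - alpha) / 2) > 1e-12 * max(1, gamma))
    stop("inconsistent gamma and lambda: gamma must equal lambda*(1-alpha)/2")
  if (gamma <= 0) stop("gamma must be positive")
  structure(list(l = l, L_int = L_int, alpha = alpha, L = L,
                 gamma = gamma, lambda = lambda),
            class = "ratchet_params")
}

#' @export
print.ratchet_params <- function(x, ...) {
  cat(sprintf("Brownian ratchet: alpha = %d/%d, L = %g, gamma = %g (lambda = %g)\n",
              x$l, x$L_int, x$L, x$gamma, x$lambda))
  invisible(x)
}

#' Flashing schedule of the ratchet
#'
#' The potential is off for `tau1` time units (free Brownian motion) and on
#' for `tau2` (ratchet), repeating.  Both durations must be rational; the
#' returned object records the smallest positive integer `m` such that
#' \eqn{m^2\tau_1} and \eqn{m^2\tau_2} are integers, which is the lattice
#' refinement granularity: the walk approximation is defined for refinements
#' `n` that are multiples of `m`, so that the phase step counts
#' \eqn{n^2\tau_1} and \eqn{n^2\tau_2} are exact integers.
#'
#' @param tau1 off-phase (Brownian) duration, positive rational.
#' @param tau2 on-phase (ratchet) duration, positive rational.
#' @return An object of class `flashing_schedule` with fields `tau1`, `tau2`,
#'   `m`, and the exact integers `m2tau1` \eqn{= m^2\tau_1},
#'   `m2tau2` \eqn{= m^2\tau_2}.
#' @examples
#' flashing_schedule(2.4, 2.4)$m  # 5
#' @export
flashing_schedule <- function(tau1, tau2) {
  stopifnot(tau1 > 0, tau2 > 0)
  r1 <- as_rational(tau1)
  r2 <- as_rational(tau2)
  den <- r1[["den"]] * r2[["den"]] / gcd(r1[["den"]], r2[["den"]])  # lcm
  # smallest m with den | m^2: for each prime p^e in den take p^ceil(e/2)
  f <- prime_factors(den)
  m <- 1
  for (p in unique(f)) {
    e <- sum(f == p)
    m <- m * p^ceiling(e / 2)
  }
  m <- as.integer(m)
  m2tau1 <- round(as.numeric(m)^2 * r1[["num"]] / r1[["den"]])
  m2tau2 <- round(as.numeric(m)^2 * r2[["num"]] / r2[["den"]])
  structure(list(tau1 = tau1, tau2 = tau2,
                 tau1_frac = r1, tau2_frac = r2,
                 m = m, m2tau1 = m2tau1, m2tau2 = m2tau2),
            class = "flashing_schedule")
}

#' @export
print.flashing_schedule <- function(x, ...) {
  cat(sprintf("Flashing schedule: tau1 = %g (off), tau2 = %g (on), m = %d\n",
              x$tau1, x$tau2, x$m))
  invisible(x)
}

#' Sawtooth potential
#'
#' \eqn{V(x) = x/\alpha} on \eqn{[0, \alpha L]} and
#' \eqn{V(x) = (L-x)/(1-\alpha)} on \eqn{[\alpha L, L]}, extended
#' periodically.  The minima (value 0) are at multiples of \eqn{L}; the
#' maxima (value \eqn{L}) at \eqn{x \equiv \alpha L \pmod L}.
#'
#' @param x position(s), any real.
#' @param p a [ratchet_params()] object.
#' @return Potential value(s), vectorized over `x`.
#' @export
potential_value <- function(x, p) {
  stopifnot(inherits(p, "ratchet_params"))
  xm <- x - p$L * floor(x / p$L)
  ifelse(xm <= p$alpha * p$L, xm / p$alpha, (p$L - xm) / (1 - p$alpha))
}

#' Ratchet drift
#'
#' \eqn{\mu(x) = -\gamma V'(x)}: \eqn{-\gamma/\alpha} on
#' \eqn{[nL, (n+\alpha)L)} and \eqn{+\gamma/(1-\alpha)} on
#' \eqn{[(n+\alpha)L, (n+1)L)} (right-continuous at the kinks).
#'
#' @inheritParams potential_value
#' @return Drift value(s), vectorized over `x`.
#' @export
drift_value <- function(x, p) {
  stopifnot(inherits(p, "ratchet_params"))
  xm <- x - p$L * floor(x / p$L)
  ifelse(xm < p$alpha * p$L, -p$gamma / p$alpha, p$gamma / (1 - p$alpha))
}

# closed-form normalizer Z = int_0^L exp(-2 gamma V) dx
# = alpha L/(2 gamma L') + ... both pieces are exponential integrals; with
# V linear of slope 1/alpha the first piece is alpha/(2 gamma) (1 - e^{-2 gamma L})
equilibrium_normalizer <- function(p) {
  E <- exp(-2 * p$gamma * p$L)
  (1 - E) / (2 * p$gamma)
}

#' Equilibrium density of the wrapped Brownian ratchet
#'
#' The reversible invariant density \eqn{C e^{-2\gamma V(x)}} on
#' \eqn{[0, L)}, with the normalizer computed in closed form from the two
#' piecewise-exponential integrals.
#'
#' @param x position(s) in \eqn{[0, L)} (values outside are reduced mod L).
#' @param p a [ratchet_params()] object.
#' @return Density value(s).
#' @examples
#' p <- ratchet_params(1, 4, gamma = 15/8)
#' d <- equilibrium_density(seq(0, 4, by = 0.01), p)
#' @export
equilibrium_density <- function(x, p) {
  stopifnot(inherits(p, "ratchet_params"))
  exp(-2 * p$gamma * potential_value(x, p)) / equilibrium_normalizer(p)
}

#' Equilibrium CDF of the wrapped Brownian ratchet on [0, L)
#'
#' Closed-form integral of [equilibrium_density()] from 0 to `x`.
#'
#' @inheritParams equilibrium_density
#' @return Cumulative probability at `x` (clamped to \eqn{[0, L]}).
#' @export
equilibrium_cdf <- function(x, p) {
  stopifnot(inherits(p, "ratchet_params"))
  a <- p$alpha; g <- p$gamma; L <- p$L
  Z <- equilibrium_normalizer(p)
  x <- pmin(pmax(x, 0), L)
  E <- exp(-2 * g * L)
  FaL <- a / (2 * g) * (1 - E)
  ifelse(x <= a * L,
         a / (2 * g) * (1 - exp(-2 * g * x / a)) / Z,
         (FaL + (1 - a) / (2 * g) *
            (exp(-2 * g * (L - x) / (1 - a)) - E)) / Z)
}

#' Mean drift of the ratchet at equilibrium
#'
#' \eqn{\int_0^L \mu e^{-2\gamma V} dx / \int_0^L e^{-2\gamma V} dx},
#' evaluated by closed-form piecewise integration.  Because
#' \eqn{V(L) = V(0) = 0} the two pieces cancel exactly, so the result is 0
#' to machine precision for every parameter set; the function performs the
#' computation rather than returning the identity.
#'
#' @param p a [ratchet_params()] object.
#' @return The equilibrium mean drift (numerically 0).
#' @export
equilibrium_mean_drift <- function(p) {
  stopifnot(inherits(p, "ratchet_params"))
  a <- p$alpha; g <- p$gamma; L <- p$L
  E <- exp(-2 * g * L)
  I1 <- a / (2 * g) * (1 - E)        # int_0^{aL} e^{-2gV}
  I2 <- (1 - a) / (2 * g) * (1 - E)  # int_{aL}^{L} e^{-2gV}
  num <- (-g / a) * I1 + (g / (1 - a)) * I2
  num / equilibrium_normalizer(p)
}
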