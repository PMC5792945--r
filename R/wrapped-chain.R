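#' Wrap a lattice pmf around the circle of nL sites
#'
#' Mass at circle site `r` is the total mass over all lattice sites congruent
#' to `r` mod `nL` (floor-division residues, so negative sites wrap
#' correctly).
#'
#' @param pmf a [lattice_pmf()].
#' @param nL_int number of circle sites.
#' @return Probability vector of length `nL_int` (index `r + 1` holds site
#'   `r`).
#' @export
wrap_pmf <- function(pmf, nL_int) {
  stopifnot(nL_int == as.integer(nL_int), nL_int >= 1)
  sites <- pmf_sites(pmf)
  r <- sites %% nL_int  # R's %% is floor-division mod
  out <- numeric(nL_int)
  agg <- tapply(pmf$probs, r, sum)
  out[as.integer(names(agg)) + 1] <- agg
  out
}

#' One-flash-period transition matrix of the wrapped walk
#'
#' Row `i` is the law of the wrapped walk after one full flash period
#' (\eqn{n^2\tau_1} symmetric steps then \eqn{n^2\tau_2} ratchet steps)
#' started at circle site `i`; all rows are propagated simultaneously by
#' circular shift-add updates.  When `nL` and the period step count are both
#' even the sampled chain would split into two parity classes, so one extra
#' symmetric step is appended (the first step of the next flash period),
#' making the chain irreducible.  The per-start expected unwrapped
#' displacement over the period (`disp`, in lattice units, excluding the
#' extra step) is accumulated during the ratchet phase.
#'
#' @param n lattice refinement, a multiple of `s$m`, with `n > p$lambda`.
#' @param p a [ratchet_params()] object.
#' @param s a [flashing_schedule()] object.
#' @return An object of class `period_matrix` with fields `matrix`
#'   (row-stochastic `nL x nL`), `disp` (length `nL`), `size`, `extra_step`,
#'   `steps` (number propagated, including any extra step), `n`, `params`,
#'   `schedule`.
#' @export
period_matrix <- function(n, p, s) {
  stopifnot(inherits(p, "ratchet_params"), inherits(s, "flashing_schedule"))
  if (n %% s$m != 0)
    stop("n = ", n, " must be a positive multiple of m = ", s$m)
  q <- n %/% s$m
  K1 <- q^2 * s$m2tau1
  K2 <- q^2 * s$m2tau2
  rho <- rho_from_lambda(n, p$lambda)
  S <- as.integer(n * p$L_int)
  pp <- probs_from_rho(rho, p$l, p$L_int)
  up_sym <- rep(0.5, S)
  up_rat <- ifelse(seq_len(S) - 1 < n * p$l, pp[["p0"]], pp[["p1"]])

  M <- diag(S)
  res1 <- cpp_evolve_wrapped(M, up_sym, as.integer(K1), FALSE)
  res2 <- cpp_evolve_wrapped(res1$matrix, up_rat, as.integer(K2), TRUE)
  M <- res2$matrix
  disp <- res2$disp  # symmetric phase contributes exactly 0 drift

  extra <- (S %% 2 == 0) && ((K1 + K2) %% 2 == 0)
  if (extra)
    M <- cpp_evolve_wrapped(M, up_sym, 1L, FALSE)$matrix

  structure(list(matrix = M, disp = disp, size = S, extra_step = extra,
                 steps = K1 + K2 + as.integer(extra), n = as.integer(n),
                 params = p, schedule = s),
            class = "period_matrix")
}

#' @export
print.period_matrix <- function(x, ...) {
  cat(sprintf(
    "period matrix: %d circle sites, %g propagated steps%s\n",
    x$size, x$steps,
    if (x$extra_step) " (incl. 1 extra symmetric step for irreducibility)" else ""))
  invisible(x)
}

#' Stationary law of the period chain
#'
#' Solves \eqn{\bar\pi P = \bar\pi}, \eqn{\sum \bar\pi = 1} by a direct
#' linear solve; tiny negative entries from rounding (\eqn{\ge -10^{-14}})
#' are clipped to 0 and the vector renormalized.
#'
#' @param pm a [period_matrix()] object (or any row-stochastic matrix).
#' @return An object of class `stationary_law` with fields `pi_bar` and
#'   `residual` \eqn{= \|\bar\pi P - \bar\pi\|_\infty < 10^{-12}}.
#' @export
stationary <- function(pm) {
  P <- if (inherits(pm, "period_matrix")) pm$matrix else pm
  stopifnot(is.matrix(P), nrow(P) == ncol(P))
  pi <- stationary_solve(P)
  residual <- max(abs(drop(pi %*% P) - pi))
  if (residual > 1e-12)
    stop("stationary residual ", format(residual), " exceeds 1e-12")
  structure(list(pi_bar = pi, residual = residual),
            class = "stationary_law")
}

#' @export
print.stationary_law <- function(x, ...) {
  cat(sprintf("stationary law over %d sites, residual %.3g\n",
              length(x$pi_bar), x$residual))
  invisible(x)
}

#' Remap the wrapped stationary law to a unimodal support
#'
#' The stationary density on \eqn{[0, L)} is U-shaped (peaked at both ends,
#' which are the same potential well).  Shifting the sites with
#' \eqn{x \ge \alpha L} down by \eqn{L} moves the support to
#' \eqn{[-(1-\alpha)L, \alpha L)} and makes the measure unimodal around 0.
#'
#' @param law a [stationary()] result (or a bare probability vector).
#' @param p a [ratchet_params()] object.
#' @param n lattice refinement used to build the chain.
#' @return A data frame with columns `site`, `x`, `remapped_x`, `prob`,
#'   sorted by `remapped_x`; total mass is preserved.
#' @export
remap_to_unimodal <- function(law, p, n) {
  stopifnot(inherits(p, "ratchet_params"))
  pi <- if (inherits(law, "stationary_law")) law$pi_bar else law
  site <- seq_along(pi) - 1
  x <- site / n
  rx <- ifelse(x >= p$alpha * p$L, x - p$L, x)
  out <- data.frame(site = site, x = x, remapped_x = rx, prob = pi)
  out[order(out$remapped_x), ]
}

#' Stationary mean displacement over one flash period
#'
#' \eqn{\bar\mu = \sum_i \bar\pi(i)\, d(i)/n}, where \eqn{d(i)} is the
#' expected unwrapped displacement (in lattice units) of one full flash
#' period started at circle site `i` — the displacement excludes the extra
#' irreducibility step, which exists only to make \eqn{\bar\pi}
#' well-defined.  By the periodicity of the kernels, \eqn{d} depends on the
#' start only through its residue mod `nL`.
#'
#' @param pm a [period_matrix()] object.
#' @param law optionally a precomputed [stationary()] law for `pm`.
#' @return The stationary mean displacement \eqn{\bar\mu}.
#' @examples
#' \donttest{
#' p <- ratchet_params(1, 4, lambda = 5)
#' s <- flashing_schedule(2.4, 2.4)
#' pm <- period_matrix(100, p, s)
#' stationary_mean_displacement(pm)  # 0.684827
#' }
#' @export
stationary_mean_displacement <- function(pm, law = NULL) {
  stopifnot(inherits(pm, "period_matrix"))
  if (is.null(law)) law <- stationary(pm)
  stopifnot(inherits(law, "stationary_law"),
            length(law$pi_bar) == pm$size)
  sum(law$pi_bar * pm$disp) / pm$n
}
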