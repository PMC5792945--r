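#' Lattice probability mass function
#'
#' Exact pmf of a nearest-neighbour walk on the integer lattice, stored as a
#' contiguous probability vector with an explicit offset.  Scaled positions
#' are `x = site / n` where `n` is the lattice refinement.  No pruning of
#' small probabilities is ever applied: propagation is exact to
#' double-precision rounding.
#'
#' @param probs probability vector over contiguous sites (sums to 1).
#' @param offset integer site of `probs[1]`.
#' @param n lattice refinement (positive integer).
#' @param steps_taken number of steps already taken (used for parity checks).
#' @return An object of class `lattice_pmf`.
#' @export
lattice_pmf <- function(probs, offset, n, steps_taken = 0L) {
  stopifnot(is.numeric(probs), length(probs) >= 1L, all(probs >= 0),
            n == as.integer(n), n >= 1, steps_taken >= 0)
  if (abs(sum(probs) - 1) > 1e-12)
    stop("probabilities must sum to 1 (got ", format(sum(probs)), ")")
  structure(list(probs = probs, offset = as.numeric(offset),
                 n = as.integer(n), steps_taken = as.numeric(steps_taken)),
            class = "lattice_pmf")
}

#' Point mass at a single lattice site
#'
#' @param site integer site carrying all mass.
#' @param n lattice refinement.
#' @return A `lattice_pmf`.
#' @export
delta_pmf <- function(site, n) lattice_pmf(1, site, n)

#' @export
print.lattice_pmf <- function(x, ...) {
  nz <- which(x$probs > 0)
  cat(sprintf(
    "lattice pmf: n = %d, %d sites on [%g, %g], %g steps taken, mass %.15g\n",
    x$n, length(x$probs), x$offset / x$n,
    (x$offset + length(x$probs) - 1) / x$n, x$steps_taken, sum(x$probs)))
  invisible(x)
}

#' Sites and scaled positions of a pmf
#' @param pmf a [lattice_pmf()].
#' @return Integer sites (for `pmf_sites`) or positions `site/n`
#'   (for `pmf_positions`), parallel to `pmf$probs`.
#' @export
pmf_sites <- function(pmf) pmf$offset + seq_along(pmf$probs) - 1

#' @rdname pmf_sites
#' @export
pmf_positions <- function(pmf) pmf_sites(pmf) / pmf$n

#' Step kernels for the walk phases
#'
#' `symmetric_kernel()` is the simple symmetric walk (game A).
#' `ratchet_kernel()` is the periodic-environment walk approximating the
#' Brownian ratchet at refinement `n`: the up-probability at site `j` is
#' `p0` when `mod(j, n*L_int) < n*l` and `p1` otherwise, with `(p0, p1)`
#' the fair pair of [probs_from_rho()].
#'
#' @param n lattice refinement.
#' @param l,L_int coprime integers defining the shape \eqn{\alpha = l/L_{int}}.
#' @param rho fairness parameter in \eqn{(0, 1]}; use
#'   [rho_from_lambda()] to target a drift rate \eqn{\lambda}.
#' @return An object of class `step_kernel` with fields `up` (per-residue
#'   up-probabilities), `period`, and `kind`.
#' @export
symmetric_kernel <- function() {
  structure(list(up = 0.5, period = 1L, kind = "symmetric"),
            class = "step_kernel")
}

#' @rdname symmetric_kernel
#' @export
ratchet_kernel <- function(n, l, L_int, rho) {
  stopifnot(n == as.integer(n), n >= 1)
  pp <- probs_from_rho(rho, l, L_int)
  period <- as.integer(n * L_int)
  up <- ifelse(seq_len(period) - 1 < n * l, pp[["p0"]], pp[["p1"]])
  structure(list(up = up, period = period, kind = "ratchet",
                 n = as.integer(n), l = as.integer(l),
                 L_int = as.integer(L_int), rho = rho,
                 p0 = pp[["p0"]], p1 = pp[["p1"]]),
            class = "step_kernel")
}

#' Fairness parameter from the drift rate
#'
#' The walk approximation at refinement `n` targets drift rate
#' \eqn{\lambda} through \eqn{\rho = 1 - \lambda/n}; requires
#' \eqn{n > \lambda}.  \eqn{\lambda = 0} gives the degenerate symmetric
#' case \eqn{\rho = 1}.
#'
#' @param n lattice refinement.
#' @param lambda drift rate \eqn{\ge 0}.
#' @return `rho` in \eqn{(0, 1]}.
#' @export
rho_from_lambda <- function(n, lambda) {
  stopifnot(lambda >= 0)
  if (n <= lambda) stop("need n > lambda (got n = ", n,
                        ", lambda = ", lambda, ")")
  1 - lambda / n
}

#' Advance a pmf by one or more exact steps
#'
#' Each step moves the mass at site `j` up with the kernel's up-probability
#' at residue `mod(j, period)` and down otherwise; the support widens by one
#' site on each end and total mass is conserved exactly (two shifted adds in
#' a fixed order).
#'
#' @param pmf a [lattice_pmf()].
#' @param kernel a [symmetric_kernel()] or [ratchet_kernel()].
#' @param steps nonnegative integer number of steps.
#' @return The evolved `lattice_pmf`.
#' @export
walk_evolve <- function(pmf, kernel, steps) {
  stopifnot(inherits(pmf, "lattice_pmf"), inherits(kernel, "step_kernel"),
            steps == as.integer(steps), steps >= 0)
  if (steps == 0) return(pmf)
  out <- cpp_evolve_line(pmf$probs, as.integer(pmf$offset),
                         as.integer(steps), kernel$up, kernel$period)
  lattice_pmf(out$probs, out$offset, pmf$n, pmf$steps_taken + steps)
}

#' @rdname walk_evolve
#' @export
walk_step <- function(pmf, kernel) walk_evolve(pmf, kernel, 1L)

#' Exact pmf of the flashing walk after whole flash periods
#'
#' Starting from a point mass at `start_site`, alternates \eqn{n^2\tau_1}
#' simple-symmetric steps (potential off) with \eqn{n^2\tau_2} ratchet steps
#' (potential on, kernel from \eqn{\rho = 1 - \lambda/n}), repeated
#' `periods` times.  `n` must be a positive multiple of the schedule's `m`
#' so that the step counts are exact integers, and `n` must exceed
#' \eqn{\lambda}.
#'
#' @param start_site integer start site (position `start_site / n`).
#' @param n lattice refinement, a multiple of `s$m`, with `n > p$lambda`.
#' @param p a [ratchet_params()] object.
#' @param s a [flashing_schedule()] object.
#' @param periods number of full off/on periods (default 1).
#' @return The final `lattice_pmf`.
#' @examples
#' \donttest{
#' p <- ratchet_params(1, 4, lambda = 5)
#' s <- flashing_schedule(2.4, 2.4)
#' pmf <- flash_evolve(0, 100, p, s)  # 48 000 exact steps
#' mean_displacement(pmf)             # 0.678364
#' }
#' @export
flash_evolve <- function(start_site, n, p, s, periods = 1L) {
  stopifnot(inherits(p, "ratchet_params"), inherits(s, "flashing_schedule"),
            periods == as.integer(periods), periods >= 1)
  if (n %% s$m != 0)
    stop("n = ", n, " must be a positive multiple of m = ", s$m,
         " so that n^2 tau1 and n^2 tau2 are integers")
  q <- n %/% s$m
  K1 <- q^2 * s$m2tau1
  K2 <- q^2 * s$m2tau2
  rho <- rho_from_lambda(n, p$lambda)  # errors if n <= lambda
  ksym <- symmetric_kernel()
  krat <- ratchet_kernel(n, p$l, p$L_int, rho)
  pmf <- delta_pmf(start_site, n)
  for (i in seq_len(periods)) {
    pmf <- walk_evolve(pmf, ksym, K1)
    pmf <- walk_evolve(pmf, krat, K2)
  }
  pmf
}
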