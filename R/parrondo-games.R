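#' Up-probabilities of the fair ratchet game from rho
#'
#' The capital-dependent game moves capital up with probability `p0` when the
#' capital's residue mod `L_int` is below `l`, and with probability `p1`
#' otherwise.  Fairness (detailed balance of the periodic walk) constrains
#' the pair to a one-parameter family:
#' \deqn{p_0 = \frac{\rho^{(1-\alpha)/\alpha}}{1+\rho^{(1-\alpha)/\alpha}},
#'       \qquad p_1 = \frac{1}{1+\rho},}
#' with \eqn{\alpha = l/L_{int}} and \eqn{0 < \rho \le 1} (\eqn{\rho = 1} is
#' the degenerate symmetric case \eqn{p_0 = p_1 = 1/2}).
#'
#' @param rho fairness parameter in \eqn{(0, 1]}.
#' @param l,L_int coprime integers, \eqn{0 < l < L_{int}}.
#' @return Named numeric vector `c(p0 = , p1 = )`.
#' @examples
#' probs_from_rho(1/3, 1, 3)  # (1/10, 3/4), the classical Parrondo game B
#' @export
probs_from_rho <- function(rho, l, L_int) {
  stopifnot(l == as.integer(l), L_int == as.integer(L_int),
            l > 0, l < L_int, gcd(l, L_int) == 1L)
  if (!(is.numeric(rho) && length(rho) == 1L && rho > 0 && rho <= 1))
    stop("rho must lie in (0, 1]")
  e <- (L_int - l) / l  # (1 - alpha)/alpha
  re <- rho^e
  c(p0 = re / (1 + re), p1 = 1 / (1 + rho))
}

#' Specification of the generalized fair game B
#'
#' Bundles `(l, L_int, rho)` with the derived up-probabilities `p0`, `p1`.
#' The detailed-balance identity
#' \eqn{(1-p_0)^l (1-p_1)^{L-l} = p_0^l p_1^{L-l}} holds by construction.
#'
#' @inheritParams probs_from_rho
#' @return An object of class `game_b_spec`.
#' @export
game_b_spec <- function(l, L_int, rho) {
  pp <- probs_from_rho(rho, l, L_int)
  if (rho == 1)
    warning("rho = 1 is the degenerate symmetric case (p0 = p1 = 1/2)")
  structure(list(l = as.integer(l), L_int = as.integer(L_int), rho = rho,
                 alpha = l / L_int, p0 = pp[["p0"]], p1 = pp[["p1"]]),
            class = "game_b_spec")
}

#' @export
print.game_b_spec <- function(x, ...) {
  cat(sprintf("Game B: alpha = %d/%d, rho = %g, p0 = %.10g, p1 = %.10g\n",
              x$l, x$L_int, x$rho, x$p0, x$p1))
  invisible(x)
}

#' Per-residue up-probabilities of a game/walk
#'
#' @param spec a [game_b_spec()] object.
#' @return Numeric vector of length `L_int`: entry `j+1` is the probability
#'   of moving up from a state with residue `j` mod `L_int`.
#' @export
game_b_up_probs <- function(spec) {
  stopifnot(inherits(spec, "game_b_spec"))
  ifelse(seq_len(spec$L_int) - 1 < spec$l, spec$p0, spec$p1)
}

#' Invariant profile of game B on one period
#'
#' The reversible invariant measure of the periodic walk, restricted to the
#' residues \eqn{\{0, \dots, L_{int}-1\}} and normalized to sum to 1.  Built
#' by the detailed-balance recursion
#' \eqn{\pi(j+1) = \pi(j)\, u_j / (1 - u_{j+1})} around the cycle, which has
#' a consistent solution exactly because `(p0, p1)` satisfy the
#' detailed-balance identity.
#'
#' @param spec a [game_b_spec()] object with `rho < 1`.
#' @return Probability vector of length `L_int`.
#' @examples
#' game_b_invariant_profile(game_b_spec(1, 3, 1/3))  # (5/13, 2/13, 6/13)
#' @export
game_b_invariant_profile <- function(spec) {
  stopifnot(inherits(spec, "game_b_spec"))
  u <- game_b_up_probs(spec)
  Lp <- spec$L_int
  pi <- numeric(Lp)
  pi[1] <- 1
  for (j in seq_len(Lp - 1))
    pi[j + 1] <- pi[j] * u[j] / (1 - u[j + 1])
  # wrap-around consistency of the cycle
  resid <- abs(pi[Lp] * u[Lp] - pi[1] * (1 - u[1])) / pi[Lp]
  if (resid > 1e-10)
    stop("detailed balance does not close around the cycle (residual ",
         format(resid), ")")
  pi / sum(pi)
}

#' Stationary law of a birth-death walk on a cycle
#'
#' For a walk on \eqn{Z_{L}} that moves up (mod \eqn{L}) with site-dependent
#' probability `up_probs[j+1]` and down otherwise, solves
#' \eqn{\pi P = \pi,\ \sum\pi = 1} by a direct linear solve (the state space
#' is tiny, so a dense solve is exact to rounding).
#'
#' @param up_probs numeric vector of up-probabilities, all in \eqn{(0, 1)}.
#' @return Probability vector `pi` with residual
#'   \eqn{\|\pi P - \pi\|_\infty < 10^{-12}}.
#' @export
cycle_stationary <- function(up_probs) {
  stopifnot(all(up_probs > 0), all(up_probs < 1))
  Lp <- length(up_probs)
  P <- cycle_transition_matrix(up_probs)
  pi <- stationary_solve(P)
  resid <- max(abs(drop(pi %*% P) - pi))
  if (resid > 1e-12)
    stop("stationary solve residual ", format(resid), " exceeds 1e-12")
  pi
}

# transition matrix of the up/down walk on Z_L (rows sum to 1; on a 2-cycle
# both moves reach the same neighbour, hence the += accumulation)
cycle_transition_matrix <- function(up_probs) {
  Lp <- length(up_probs)
  P <- matrix(0, Lp, Lp)
  for (j in seq_len(Lp)) {
    ju <- j %% Lp + 1
    jd <- (j - 2) %% Lp + 1
    P[j, ju] <- P[j, ju] + up_probs[j]
    P[j, jd] <- P[j, jd] + 1 - up_probs[j]
  }
  P
}

# pi P = pi with sum(pi) = 1, by least squares on the stacked system
stationary_solve <- function(P) {
  S <- nrow(P)
  A <- rbind(t(P) - diag(S), rep(1, S))
  b <- c(rep(0, S), 1)
  pi <- tryCatch(qr.solve(A, b),
                 error = function(e) stop("stationary solve failed: ",
                                          conditionMessage(e)))
  pi <- pmax(pi, 0)
  pi / sum(pi)
}

#' Asymptotic mean profit per play of a periodic walk
#'
#' \eqn{\sum_j \pi(j) (2 u_j - 1)} with \eqn{\pi} the stationary law of the
#' residue cycle: the long-run expected capital gain per play.
#'
#' @inheritParams cycle_stationary
#' @return Expected profit per play (0 for any fair game B).
#' @export
mean_profit <- function(up_probs) {
  pi <- cycle_stationary(up_probs)
  sum(pi * (2 * up_probs - 1))
}

#' Mean profit of the random mixture c*A + (1-c)*B
#'
#' Game A is the fair coin.  At each play, A is chosen with probability `c`,
#' otherwise B; the mixed walk has up-probabilities
#' \eqn{c/2 + (1-c) p_j}.  For \eqn{0 < c < 1} the mixture is winning when
#' \eqn{\alpha < 1/2} (Parrondo effect) and losing when \eqn{\alpha > 1/2}
#' (anti-Parrondo effect).
#'
#' @param c mixing probability in \eqn{[0, 1]}.
#' @param spec a [game_b_spec()] object.
#' @return Expected profit per play.
#' @export
mixture_mean_profit <- function(c, spec) {
  stopifnot(inherits(spec, "game_b_spec"), c >= 0, c <= 1)
  mean_profit(c / 2 + (1 - c) * game_b_up_probs(spec))
}

#' Mean profit of the periodic pattern A^r B^s
#'
#' Plays game A for `r` rounds then game B for `s` rounds, repeating.  The
#' long-run profit per play is the expected drift under the stationary law
#' of the chain on (capital residue, phase), advanced one play at a time
#' with the phase cycling deterministically through \eqn{0, \dots, r+s-1}
#' (phases below `r` play A).
#'
#' @param r,s positive integers.
#' @param spec a [game_b_spec()] object.
#' @return Expected profit per play (0 when `r == s == 1`; positive for all
#'   other patterns at \eqn{\alpha < 1/2}).
#' @export
pattern_mean_profit <- function(r, s, spec) {
  stopifnot(inherits(spec, "game_b_spec"),
            r == as.integer(r), s == as.integer(s), r >= 1, s >= 1)
  Lp <- spec$L_int
  K <- r + s
  ub <- game_b_up_probs(spec)
  # state index: 1 + j + Lp * k for residue j, phase k
  S <- Lp * K
  u <- numeric(S)
  P <- matrix(0, S, S)
  for (k in 0:(K - 1)) {
    for (j in 0:(Lp - 1)) {
      i <- 1 + j + Lp * k
      u[i] <- if (k < r) 0.5 else ub[j + 1]
      k2 <- (k + 1) %% K
      iu <- 1 + (j + 1) %% Lp + Lp * k2
      id <- 1 + (j - 1) %% Lp + Lp * k2
      P[i, iu] <- P[i, iu] + u[i]
      P[i, id] <- P[i, id] + 1 - u[i]
    }
  }
  pi <- stationary_solve(P)
  resid <- max(abs(drop(pi %*% P) - pi))
  if (resid > 1e-10)
    stop("pattern stationary solve residual ", format(resid))
  sum(pi * (2 * u - 1))
}
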