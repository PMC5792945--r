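# parity of the occupied sites; errors on mixed parity
pmf_parity <- function(pmf) {
  sites <- pmf_sites(pmf)[pmf$probs > 0]
  par <- unique(sites %% 2)
  if (length(par) != 1L)
    stop("pmf has mixed parity; density interpolation requires a fixed parity")
  par
}

#' Interpolation nodes of the walk density
#'
#' After an even number of steps from a point start the pmf lives on sites of
#' one parity, so the histogram bin width is `2/n` and the density node at an
#' occupied site is `prob * n/2`.  Nodes are returned for every site of the
#' support's parity (zeros included) plus one zero node beyond each end, so
#' that the piecewise-linear interpolant integrates to exactly 1 by the
#' trapezoid rule.
#'
#' @param pmf a [lattice_pmf()] with fixed-parity support.
#' @return A data frame with columns `site`, `x` (= site/n) and `height`.
#' @export
density_nodes <- function(pmf) {
  par <- pmf_parity(pmf)
  sites <- pmf_sites(pmf)
  keep <- sites %% 2 == par
  s <- sites[keep]
  h <- pmf$probs[keep] * pmf$n / 2
  s <- c(s[1] - 2, s, s[length(s)] + 2)
  h <- c(0, h, 0)
  data.frame(site = s, x = s / pmf$n, height = h)
}

# linearly-interpolated density at arbitrary positions (0 outside support)
density_at <- function(pmf, xq) {
  nd <- density_nodes(pmf)
  stats::approx(nd$x, nd$height, xout = xq, yleft = 0, yright = 0)$y
}

#' Maximum interpolated density height over a position window
#'
#' @param pmf a [lattice_pmf()].
#' @param x_lo,x_hi closed interval of scaled positions.
#' @return The maximum node height with `x_lo <= x <= x_hi`.
#' @export
max_density_height <- function(pmf, x_lo = -Inf, x_hi = Inf) {
  nd <- density_nodes(pmf)
  keep <- nd$x >= x_lo & nd$x <= x_hi
  if (!any(keep)) stop("no density nodes in [", x_lo, ", ", x_hi, "]")
  max(nd$height[keep])
}

#' Positions of the potential maxima in a window
#'
#' The sawtooth maxima at \eqn{x \equiv \alpha L \pmod L} are the natural
#' separators between the peaks of the walk density (the peaks themselves
#' sit at the potential minima, multiples of \eqn{L}).
#'
#' @param p a [ratchet_params()] object.
#' @param x_lo,x_hi open interval bounds, `x_lo < x_hi`.
#' @return Sorted positions of all maxima strictly inside `(x_lo, x_hi)`.
#' @examples
#' peak_boundaries(ratchet_params(1, 4, lambda = 5), -6, 6)  # -3 1 5
#' @export
peak_boundaries <- function(p, x_lo, x_hi) {
  stopifnot(inherits(p, "ratchet_params"), x_lo < x_hi)
  x0 <- p$alpha * p$L
  k_lo <- ceiling((x_lo - x0) / p$L + 1e-12)
  k_hi <- floor((x_hi - x0) / p$L - 1e-12)
  if (k_lo > k_hi) return(numeric(0))
  x0 + (k_lo:k_hi) * p$L
}

#' Areas of the density peaks between separators
#'
#' Total probability in each of the regions delimited by `boundaries`.
#' Regions are half-open `[b, b')`: the mass at a site that falls exactly on
#' a separator is assigned to the region on its right
#' (`boundary_mass = "right"`, the convention under which the reference
#' tables are reproduced to all printed digits).  With
#' `boundary_mass = "split"` a separator site's mass is divided equally
#' between the two adjacent regions.
#'
#' @param pmf a [lattice_pmf()].
#' @param boundaries sorted separator positions.
#' @param boundary_mass `"right"` (default) or `"split"`.
#' @return Numeric vector of `length(boundaries) + 1` areas summing to 1.
#' @export
peak_areas <- function(pmf, boundaries,
                       boundary_mass = c("right", "split")) {
  boundary_mass <- match.arg(boundary_mass)
  stopifnot(length(boundaries) >= 1, !is.unsorted(boundaries))
  x <- pmf_positions(pmf)
  tol <- 1e-9 / pmf$n
  reg <- findInterval(x, boundaries - tol) + 1
  areas <- numeric(length(boundaries) + 1)
  agg <- tapply(pmf$probs, reg, sum)
  areas[as.integer(names(agg))] <- agg
  if (boundary_mass == "split") {
    for (i in seq_along(boundaries)) {
      onb <- abs(x - boundaries[i]) < tol
      if (any(onb)) {
        half <- sum(pmf$probs[onb]) / 2
        areas[i + 1] <- areas[i + 1] - half
        areas[i] <- areas[i] + half
      }
    }
  }
  areas
}

#' Heights of the density peaks
#'
#' A peak sits at a minimum of the sawtooth potential (a multiple of
#' \eqn{L}); its height is the linearly-interpolated density there.  For
#' each region delimited by `boundaries` the potential minima inside the
#' region (and inside the pmf support) are evaluated and the largest value
#' is reported, together with the position at which it is attained.
#'
#' @inheritParams peak_areas
#' @param p a [ratchet_params()] object (for the period \eqn{L}).
#' @return A list with numeric vectors `heights` and `centers`, one entry
#'   per region.
#' @export
peak_heights <- function(pmf, p, boundaries) {
  stopifnot(inherits(p, "ratchet_params"))
  nd <- density_nodes(pmf)
  bnds <- c(-Inf, boundaries, Inf)
  nreg <- length(boundaries) + 1
  heights <- numeric(nreg)
  centers <- numeric(nreg)
  for (r in seq_len(nreg)) {
    lo <- max(bnds[r], min(nd$x))
    hi <- min(bnds[r + 1], max(nd$x))
    k_lo <- ceiling(lo / p$L - 1e-12)
    k_hi <- floor(hi / p$L + 1e-12)
    ks <- if (k_lo <= k_hi) k_lo:k_hi else integer(0)
    if (length(ks) > 0) {
      cand <- ks * p$L
      hv <- density_at(pmf, cand)
      i <- which.max(hv)
      heights[r] <- hv[i]
      centers[r] <- cand[i]
    } else {
      keep <- nd$x >= lo & nd$x <= hi
      i <- which.max(nd$height[keep])
      heights[r] <- nd$height[keep][i]
      centers[r] <- nd$x[keep][i]
    }
  }
  list(heights = heights, centers = centers)
}

#' Mean displacement of a walk distribution
#'
#' \eqn{\sum_j (j/n)\,P(j) - x_0}: the expected scaled position minus the
#' start.
#'
#' @param pmf a [lattice_pmf()].
#' @param start starting position on the `x` scale (default 0).
#' @return The mean displacement.
#' @export
mean_displacement <- function(pmf, start = 0) {
  sum(pmf_positions(pmf) * pmf$probs) - start
}

#' Mean displacement implied by symmetric peaks
#'
#' \eqn{\sum_i c_i a_i}: the mean the distribution would have if all mass of
#' each peak sat at its centre; the gap to the true mean measures the
#' asymmetry of the peaks.
#'
#' @param areas peak areas.
#' @param centers peak centres (same length).
#' @return The implied mean displacement.
#' @export
symmetric_peak_displacement <- function(areas, centers) {
  stopifnot(length(areas) == length(centers))
  sum(areas * centers)
}

#' Gaussian reference areas between separators
#'
#' Areas of the normal distribution centred at `start` with variance `tau1`
#' (the law of the free Brownian phase) over the regions delimited by
#' `boundaries` — the values the peak areas approach as the ratchet drift
#' becomes strong.
#'
#' @param tau1 variance (the off-phase duration).
#' @param boundaries sorted separator positions.
#' @param start centre of the reference normal.
#' @return Numeric vector of `length(boundaries) + 1` areas summing to 1.
#' @examples
#' gaussian_reference_areas(2.4, c(-3, 1))
#' # 0.0264038 0.7142940 0.2593030
#' @export
gaussian_reference_areas <- function(tau1, boundaries, start = 0) {
  stopifnot(tau1 > 0, !is.unsorted(boundaries))
  cdf <- pnorm(boundaries, mean = start, sd = sqrt(tau1))
  diff(c(0, cdf, 1))
}

#' Peak statistics of a flashing-walk density
#'
#' Bundles the separator positions (by default the two potential maxima
#' flanking the start's well), the peak areas and heights, the peak centres
#' and the mean displacement into one object.
#'
#' @param pmf a [lattice_pmf()].
#' @param p a [ratchet_params()] object.
#' @param boundaries separator positions; default
#'   `peak_boundaries(p, start - L, start + L)`.
#' @param start starting position (default 0).
#' @param boundary_mass see [peak_areas()].
#' @return An object of class `peak_stats` with fields `boundaries`,
#'   `areas`, `heights`, `centers`, `mean_displacement`.
#' @export
peak_stats <- function(pmf, p, boundaries = NULL, start = 0,
                       boundary_mass = c("right", "split")) {
  stopifnot(inherits(p, "ratchet_params"))
  if (is.null(boundaries))
    boundaries <- peak_boundaries(p, start - p$L, start + p$L)
  ph <- peak_heights(pmf, p, boundaries)
  structure(list(boundaries = boundaries,
                 areas = peak_areas(pmf, boundaries,
                                    boundary_mass = match.arg(boundary_mass)),
                 heights = ph$heights,
                 centers = ph$centers,
                 mean_displacement = mean_displacement(pmf, start)),
            class = "peak_stats")
}

#' @export
print.peak_stats <- function(x, ...) {
  cat("peak statistics\n")
  cat("  separators:        ", paste(format(x$boundaries), collapse = ", "), "\n")
  cat("  areas:             ", paste(sprintf("%.6g", x$areas), collapse = ", "), "\n")
  cat("  heights:           ", paste(sprintf("%.6g", x$heights), collapse = ", "), "\n")
  cat("  centres:           ", paste(format(x$centers), collapse = ", "), "\n")
  cat("  mean displacement: ", sprintf("%.6g", x$mean_displacement), "\n")
  invisible(x)
}
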