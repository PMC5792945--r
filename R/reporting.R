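#' Write a lattice pmf to a TSV file
#'
#' Columns `site`, `x`, `prob`; probabilities are written with 17
#' significant digits so the file round-trips losslessly.  Two comment
#' lines record `n` and `steps_taken` so the pmf can be reconstructed.
#'
#' @param pmf a [lattice_pmf()] with non-empty support.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pmf_table <- function(pmf, path) {
  stopifnot(inherits(pmf, "lattice_pmf"))
  if (!any(pmf$probs > 0)) stop("refusing to write a pmf with empty support")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# n=%d", pmf$n),
               sprintf("# steps=%.17g", pmf$steps_taken),
               "site\tx\tprob"), con)
  sites <- pmf_sites(pmf)
  lines <- sprintf("%.17g\t%.17g\t%.17g", sites, sites / pmf$n, pmf$probs)
  writeLines(lines, con)
  invisible(path)
}

#' Read a lattice pmf written by [write_pmf_table()]
#'
#' @param path file path.
#' @return The reconstructed [lattice_pmf()], bit-identical to the one
#'   written.
#' @export
read_pmf_table <- function(path) {
  hdr <- readLines(path, n = 2)
  n <- as.integer(sub("# n=", "", hdr[1], fixed = TRUE))
  steps <- as.numeric(sub("# steps=", "", hdr[2], fixed = TRUE))
  tab <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  stopifnot(all(diff(tab$site) == 1))
  lattice_pmf(tab$prob, tab$site[1], n, steps)
}

#' Reference-table experiments
#'
#' Recomputes rows of the two benchmark tables for the flashing walk with
#' \eqn{\alpha = 1/4}, \eqn{L = 4}, \eqn{\tau_1 = \tau_2 = 2.4}, start 0:
#' `"table1"` varies the drift rate \eqn{\lambda} at refinement `n = 100`;
#' `"table2"` varies the refinement `n` at \eqn{\lambda = 5}.  Each row
#' reports the three peak areas and heights (separators at the potential
#' maxima \eqn{-3} and 1) and the mean displacement at time
#' \eqn{\tau_1 + \tau_2}.
#'
#' @param which `"table1"` or `"table2"`.
#' @param rows for `"table1"`, a subset of \eqn{\lambda \in}
#'   `c(1:5, 10, 15, 20, 25, 50)`; for `"table2"`, a subset of
#'   `seq(10, 200, by = 10)`.
#' @return A data frame with one row per requested grid value and columns
#'   `lambda`/`n`, `area1..3`, `height1..3`, `mean_displacement`.
#' @export
run_table_experiment <- function(which = c("table1", "table2"), rows) {
  which <- match.arg(which)
  grid <- if (which == "table1") c(1:5, 10, 15, 20, 25, 50)
          else seq(10L, 200L, by = 10L)
  if (!all(rows %in% grid))
    stop("rows must be a subset of the ", which, " grid: ",
         paste(grid, collapse = ", "))
  s <- flashing_schedule(2.4, 2.4)
  out <- lapply(rows, function(v) {
    if (which == "table1") {
      lambda <- v; n <- 100L
    } else {
      lambda <- 5; n <- as.integer(v)
    }
    p <- ratchet_params(1, 4, lambda = lambda)
    pmf <- flash_evolve(0, n, p, s)
    st <- peak_stats(pmf, p)
    data.frame(row = v, area1 = st$areas[1], area2 = st$areas[2],
               area3 = st$areas[3], height1 = st$heights[1],
               height2 = st$heights[2], height3 = st$heights[3],
               mean_displacement = st$mean_displacement)
  })
  out <- do.call(rbind, out)
  names(out)[1] <- if (which == "table1") "lambda" else "n"
  rownames(out) <- NULL
  out
}

#' Parse a flat key-value run configuration
#'
#' Accepts a character scalar with `key=value` pairs separated by commas
#' and/or newlines.  Recognized keys: `alpha` (as a fraction string
#' `"l/L"`), `L`, `lambda` or `gamma`, `tau1`, `tau2`, `n`, `periods`,
#' `start`.  Unknown keys are rejected by name; `alpha` is reduced to
#' lowest terms with a warning; all walk preconditions (`n` a multiple of
#' the schedule's `m`, `n > lambda`) are validated at parse time.
#'
#' @param text configuration text, e.g.
#'   `"alpha=1/4, L=4, lambda=5, tau1=2.4, tau2=2.4, n=100"`.
#' @return A list with validated components `params`
#'   ([ratchet_params()]), `schedule` ([flashing_schedule()]), `n`,
#'   `periods`, `start`.
#' @export
parse_config <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  parts <- strsplit(text, "[,\n]")[[1]]
  parts <- trimws(parts)
  parts <- parts[nzchar(parts)]
  kv <- strsplit(parts, "=", fixed = TRUE)
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad)) stop("malformed entry: ", parts[bad][1])
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, `[`, "", 2))
  known <- c("alpha", "L", "lambda", "gamma", "tau1", "tau2", "n",
             "periods", "start")
  if (any(!keys %in% known))
    stop("unknown configuration key: ", keys[!keys %in% known][1])
  if (anyDuplicated(keys)) stop("duplicate key: ", keys[duplicated(keys)][1])
  cfg <- as.list(vals)
  names(cfg) <- keys
  need <- c("alpha", "tau1", "tau2", "n")
  if (any(!need %in% keys))
    stop("missing required key: ", setdiff(need, keys)[1])

  frac <- strsplit(cfg$alpha, "/", fixed = TRUE)[[1]]
  if (length(frac) != 2L) stop("alpha must be a fraction string like 1/4")
  l <- as.integer(frac[1]); L_int <- as.integer(frac[2])
  g <- gcd(l, L_int)
  if (g != 1L) {
    warning("alpha = ", cfg$alpha, " reduced to ", l %/% g, "/", L_int %/% g)
    l <- l %/% g; L_int <- L_int %/% g
  }
  L <- if (!is.null(cfg$L)) as.numeric(cfg$L) else L_int
  p <- ratchet_params(l, L_int, L = L,
                      gamma = if (!is.null(cfg$gamma)) as.numeric(cfg$gamma),
                      lambda = if (!is.null(cfg$lambda)) as.numeric(cfg$lambda))
  s <- flashing_schedule(as.numeric(cfg$tau1), as.numeric(cfg$tau2))
  n <- as.integer(cfg$n)
  if (n %% s$m != 0)
    stop("n = ", n, " is not a multiple of m = ", s$m)
  if (n <= p$lambda) stop("need n > lambda")
  list(params = p, schedule = s, n = n,
       periods = if (!is.null(cfg$periods)) as.integer(cfg$periods) else 1L,
       start = if (!is.null(cfg$start)) as.numeric(cfg$start) else 0)
}
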