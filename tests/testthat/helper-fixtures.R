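# shared fixtures and independent oracles

paper_params <- function(lambda = 5) ratchet_params(1, 4, lambda = lambda)
paper_schedule <- function() flashing_schedule(2.4, 2.4)

# heavy flashing runs are reused across test files
.run_cache <- new.env(parent = emptyenv())
cached_flash_run <- function(lambda, n) {
  key <- sprintf("lambda%g_n%d", lambda, n)
  if (is.null(.run_cache[[key]]))
    .run_cache[[key]] <- flash_evolve(0, n, paper_params(lambda),
                                      paper_schedule())
  .run_cache[[key]]
}

# agreement with a printed reference value to one unit in its last decimal
expect_printed <- function(value, printed) {
  dec <- nchar(sub("^-?[0-9]*\\.", "", printed))
  expect_lt(abs(value - as.numeric(printed)), 10^(-dec) * 1.0000001)
}

# independent path-enumeration oracle: exact law of a nearest-neighbour walk
# whose up-probability is up_fun(site, step_index), start included
oracle_line_pmf <- function(start, steps, up_fun) {
  signs <- as.matrix(expand.grid(rep(list(c(-1L, 1L)), steps)))
  sites <- (start - steps):(start + steps)
  prob <- numeric(length(sites))
  for (i in seq_len(nrow(signs))) {
    pos <- start
    w <- 1
    for (k in seq_len(steps)) {
      u <- up_fun(pos, k)
      w <- w * if (signs[i, k] > 0L) u else 1 - u
      pos <- pos + signs[i, k]
    }
    idx <- pos - start + steps + 1L
    prob[idx] <- prob[idx] + w
  }
  list(sites = sites, prob = prob)
}

# same oracle on the circle of S sites
oracle_wrapped_row <- function(start, S, steps, up_fun) {
  line <- oracle_line_pmf(start, steps, function(pos, k) up_fun(pos %% S, k))
  prob <- numeric(S)
  for (i in seq_along(line$sites)) {
    r <- line$sites[i] %% S
    prob[r + 1] <- prob[r + 1] + line$prob[i]
  }
  prob
}

# up-probability function of the flashing walk used by the oracles
flash_up_fun <- function(n, p, K1) {
  rho <- rho_from_lambda(n, p$lambda)
  pp <- probs_from_rho(rho, p$l, p$L_int)
  period <- n * p$L_int
  function(pos, k) {
    if (k <= K1) return(0.5)
    if (pos %% period < n * p$l) pp[["p0"]] else pp[["p1"]]
  }
}
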