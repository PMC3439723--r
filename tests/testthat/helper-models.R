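# Shared fixtures and independent oracles, built in code at test time.

simple_model <- function(...) assemble_system(simple_pathway_config(...))

simple_ts <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- explore_state_space(simple_model())
    cache
  }
})

# Closed-form CDF of a sum of independent exponentials with distinct rates.
hypoexp_cdf <- function(t, rates) {
  cf <- vapply(seq_along(rates), function(i)
    prod(rates[-i] / (rates[-i] - rates[i])), 0)
  vapply(t, function(tt) 1 - sum(cf * exp(-rates * tt)), 0)
}

# Independent oracle: expected net drift of every (group, local) count at a
# given CTMC state, by direct enumeration of the outgoing transitions.
ctmc_expected_drift <- function(ts, odes, state = 1L) {
  e0 <- ts$edges[ts$edges$src == state, ]
  d <- numeric(nrow(odes$vars))
  vid <- function(g, l) which(odes$vars$group == g & odes$vars$local == l)
  for (k in seq_len(nrow(e0))) {
    dif <- which(ts$states[e0$tgt[k], ] != ts$states[e0$src[k], ])
    for (i in dif) {
      g <- ts$instances$group[i]
      from <- ts$local_names[[g]][ts$states[e0$src[k], i]]
      to <- ts$local_names[[g]][ts$states[e0$tgt[k], i]]
      d[vid(g, from)] <- d[vid(g, from)] - e0$rate[k]
      d[vid(g, to)] <- d[vid(g, to)] + e0$rate[k]
    }
  }
  d
}

# Plain-R Gillespie sampler recording a per-state statistic at checkpoint
# times, used as a Monte-Carlo oracle for the fluid trajectories.
gillespie_at <- function(ts, stat, checkpoints, nrep) {
  e <- ts$edges
  esrc <- split(seq_len(nrow(e)), e$src)
  out <- matrix(0, nrep, length(checkpoints))
  for (r in seq_len(nrep)) {
    s <- 1L; t <- 0
    repeat {
      rows <- esrc[[as.character(s)]]
      t2 <- t + stats::rexp(1, sum(e$rate[rows]))
      for (ci in seq_along(checkpoints))
        if (t <= checkpoints[ci] && t2 > checkpoints[ci]) out[r, ci] <- stat[s]
      if (t2 > max(checkpoints)) break
      s <- e$tgt[rows][sample.int(length(rows), 1, prob = e$rate[rows])]
      t <- t2
    }
  }
  out
}

# Brute-force generator assembly from the edge list, independent of
# build_generator's sparse path.
dense_generator <- function(ts) {
  n <- ts$n_states
  Q <- matrix(0, n, n)
  e <- ts$edges
  for (k in seq_len(nrow(e)))
    if (e$src[k] != e$tgt[k]) Q[e$src[k], e$tgt[k]] <- Q[e$src[k], e$tgt[k]] + e$rate[k]
  diag(Q) <- -rowSums(Q)
  Q
}
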