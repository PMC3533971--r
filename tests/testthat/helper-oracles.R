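# Brute-force oracles: enumerate every window satisfying a rule, then tile
# greedily (smallest start first; among windows sharing a start, the
# longest). These deliberately share no code with the package's scanning
# detectors.

# All half-open [i, j) windows (0-based) of >= `window` minutes containing
# at most `allowance` non-zero minutes and bounded by zero minutes.
oracle_non_wear <- function(counts, window = 60L, allowance = 2L) {
  n <- length(counts)
  nz <- counts > 0
  cum <- c(0L, cumsum(nz))
  zero_idx <- which(!nz)
  wins <- list()
  for (i in zero_idx) {
    ends <- zero_idx[zero_idx >= i + window - 1L]
    if (!length(ends)) next
    interruptions <- cum[ends + 1L] - cum[i]
    ends <- ends[interruptions <= allowance]
    for (j in ends) wins[[length(wins) + 1L]] <- c(i, j)
  }
  .oracle_tile(wins)
}

# All windows bounded by MVPA minutes, >= `min_duration` long, with at
# most `max_drop` non-MVPA minutes.
oracle_bouts <- function(mvpa, min_duration = 10L, max_drop = 2L) {
  n <- length(mvpa)
  cum <- c(0L, cumsum(!mvpa))
  m_idx <- which(mvpa)
  wins <- list()
  for (i in m_idx) {
    ends <- m_idx[m_idx >= i + min_duration - 1L]
    if (!length(ends)) next
    drops <- cum[ends + 1L] - cum[i]
    ends <- ends[drops <= max_drop]
    for (j in ends) wins[[length(wins) + 1L]] <- c(i, j)
  }
  .oracle_tile(wins)
}

# Greedy tiling over the enumerated windows: repeatedly emit the window
# with the smallest start (ties: largest end), discard overlaps, repeat.
.oracle_tile <- function(wins) {
  out <- data.frame(start = integer(0), end = integer(0), minutes = integer(0))
  if (!length(wins)) return(out)
  mat <- do.call(rbind, wins)
  pos <- 1L
  repeat {
    ok <- mat[, 1] >= pos
    if (!any(ok)) break
    cand <- mat[ok, , drop = FALSE]
    s <- min(cand[, 1])
    e <- max(cand[cand[, 1] == s, 2])
    out <- rbind(out, data.frame(start = s - 1L, end = e, minutes = e - s + 1L))
    pos <- e + 1L
  }
  out
}

# Random day streams with genuine zero runs: a two-state Markov chain over
# wear/non-wear whose wear minutes are mostly non-zero.
random_count_stream <- function(n = 300L) {
  p_switch <- stats::runif(1, 0.01, 0.2)
  state <- stats::runif(1) < 0.5
  counts <- integer(n)
  for (t in seq_len(n)) {
    if (stats::runif(1) < p_switch) state <- !state
    counts[t] <- if (state) {
      if (stats::runif(1) < 0.9) sample(1:2500, 1) else 0L
    } else {
      if (stats::runif(1) < 0.05) sample(1:2500, 1) else 0L
    }
  }
  counts
}

random_mvpa_mask <- function(n = 300L) {
  p <- stats::runif(1, 0.2, 0.9)
  stats::runif(n) < p
}

# Exact two-sided signed-rank p-value by enumerating all sign patterns.
enumerate_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- drop(signs %*% r)
  lower <- mean(v_all <= v_obs)
  upper <- mean(v_all >= v_obs)
  min(1, 2 * min(lower, upper))
}

# Convenience builders ------------------------------------------------------

# A noiseless session on a known MET line over given counts.
line_session <- function(id = "S01", intercept = 2.5276, slope = 0.000690,
                         counts = c(200, 600, 1000, 1400, 1800),
                         resting_vo2 = 3.0, speeds = seq(2, length.out = length(counts))) {
  compute_mets(calibration_session(id, resting_vo2,
    data.frame(speed = speeds, vo2 = resting_vo2 * (intercept + slope * counts),
               counts_per_min = counts)))
}
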