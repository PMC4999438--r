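# Independent oracles and small shared fixtures for the test suite.
# The oracles deliberately use plain loops / direct summation, independent
# of the implementation paths they check.

# brute-force Shannon entropy of a probability array, nested loops
oracle_entropy <- function(p) {
  h <- 0
  for (v in as.numeric(p)) if (v > 0) h <- h - v * log2(v)
  h
}

# brute-force MI from a 2-D joint probability matrix (rows X, cols Y)
oracle_mi <- function(joint) {
  px <- rowSums(joint)
  py <- colSums(joint)
  mi <- 0
  for (i in seq_along(px)) for (j in seq_along(py)) {
    p <- joint[i, j]
    if (p > 0) mi <- mi + p * log2(p / (px[i] * py[j]))
  }
  unname(mi)
}

# expand a joint count matrix into a two-column data.frame of observations
joint_to_data <- function(counts, xname = "x", yname = "label") {
  rows <- list()
  for (i in seq_len(nrow(counts))) for (j in seq_len(ncol(counts))) {
    n <- counts[i, j]
    if (n > 0) rows[[length(rows) + 1]] <-
        data.frame(rep(i, n), rep(j, n)) |> setNames(c(xname, yname))
  }
  do.call(rbind, rows)
}

# brute-force two-cycle segment average (explicit loop, no vapply tricks)
oracle_segment_mean <- function(trace, starts_ms, seg_len, fs = 1000) {
  acc <- numeric(seg_len)
  n <- 0
  for (s in starts_ms) {
    i0 <- floor(s * fs / 1000) + 1
    if (i0 + seg_len - 1 > length(trace)) next
    acc <- acc + trace[i0:(i0 + seg_len - 1)]
    n <- n + 1
  }
  acc / n
}

# a very small network for fast simulation tests (45 cells)
micro_network_config <- function(seed = 1, background_rate_hz = 10, ...) {
  network_config(e_grid = c(6, 6), i_grid = c(3, 3), seed = seed,
                 background_rate_hz = background_rate_hz, ...)
}

micro_sim_config <- function(duration_ms = 1500, transient_ms = 250, ...) {
  simulation_config(duration_ms = duration_ms, transient_ms = transient_ms,
                    ...)
}

# band powers helper from constant values
bp_const <- function(p40, p20, p30) band_powers(p40, p20, p30)

# control stats directly from vectors (bypassing list-of-band_powers)
ctrl_from <- function(p40, p20, p30) {
  control_stats(lapply(seq_along(p40), function(i)
    band_powers(p40[i], p20[i], p30[i])))
}
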