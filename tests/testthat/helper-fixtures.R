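# Fixtures are built in code: cosine count series, event sets, and an
# independent Kendall-S enumeration oracle (Heap's algorithm, a different
# permutation generator than the implementation uses).

cosine_series <- function(n, period, bin_width = 24, start_index = 0,
                          amplitude = 10, baseline = 10, phase = 0,
                          regime = NULL, label = "cosine") {
  t <- start_index + seq_len(n) - 1
  counts <- round(baseline + amplitude * cos(2 * pi * (t - phase) / period))
  emergence_series(counts, bin_width = bin_width, start_index = start_index,
                   regime = regime, label = label)
}

mask_bins <- function(series, at) {
  series$counts[at] <- NA
  series
}

# Lexicographic next-permutation enumeration; independent of the
# recursive-insertion generator in the package.
lex_perms <- function(n) {
  p <- seq_len(n)
  res <- list(p)
  repeat {
    i <- n - 1L
    while (i >= 1L && p[i] >= p[i + 1L]) i <- i - 1L
    if (i < 1L) break
    j <- n
    while (p[j] <= p[i]) j <- j - 1L
    tmp <- p[i]; p[i] <- p[j]; p[j] <- tmp
    p[(i + 1L):n] <- rev(p[(i + 1L):n])
    res[[length(res) + 1L]] <- p
  }
  do.call(rbind, res)
}

# Brute-force Kendall S via an explicit double loop over pairs.
brute_kendall_S <- function(x, y) {
  s <- 0
  n <- length(x)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- s + sign(x[j] - x[i]) * sign(y[j] - y[i])
    }
  }
  s
}

# Exhaustive two-sided permutation tail of |S|.
brute_kendall_tail <- function(x, y) {
  s_obs <- brute_kendall_S(x, y)
  perms <- lex_perms(length(y))
  hits <- 0L
  for (r in seq_len(nrow(perms))) {
    if (abs(brute_kendall_S(x, y[perms[r, ]])) >= abs(s_obs)) hits <- hits + 1L
  }
  hits / nrow(perms)
}

# Pairwise-complete autocorrelation by direct enumeration of index pairs.
brute_autocorr <- function(y, lag) {
  obs <- which(!is.na(y))
  yc <- y - mean(y[obs])
  num <- 0
  for (t in seq_len(length(y) - lag)) {
    if (!is.na(y[t]) && !is.na(y[t + lag])) num <- num + yc[t] * yc[t + lag]
  }
  num / sum(yc[obs]^2)
}
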