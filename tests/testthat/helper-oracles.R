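# Independent oracles and shared fixtures for the test suite.

# Brute-force DTW: enumerate monotone warping paths from (1,1) to (n,m)
# recursively (branch-and-bound pruning of provably worse prefixes), fully
# independent of the package's dynamic-programming core.
dtw_brute_force <- function(x, y) {
  n <- nrow(x); m <- nrow(y)
  d <- matrix(0, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) d[i, j] <- sqrt(sum((x[i, ] - y[j, ])^2))
  }
  best <- Inf
  rec <- function(i, j, acc) {
    acc <- acc + d[i, j]
    if (acc >= best) return(invisible())
    if (i == n && j == m) {
      best <<- acc
      return(invisible())
    }
    if (i < n && j < m) rec(i + 1, j + 1, acc)
    if (i < n) rec(i + 1, j, acc)
    if (j < m) rec(i, j + 1, acc)
  }
  rec(1, 1, 0)
  best / (n + m)
}

rand_features <- function(n, d = 39) matrix(rnorm(n * d), n, d)

# Default synthetic cohort, generated once per test run and reused.
.cohort_cache <- new.env(parent = emptyenv())
default_cohort <- function() {
  if (is.null(.cohort_cache$co)) {
    dir <- file.path(tempdir(), "accdist-default-cohort")
    .cohort_cache$co <- make_cohort(dir, seed = 1)
  }
  .cohort_cache$co
}

# A small cohort for unit tests that only need structure, not statistics.
tiny_cohort <- function() {
  if (is.null(.cohort_cache$tiny)) {
    dir <- file.path(tempdir(), "accdist-tiny-cohort")
    .cohort_cache$tiny <- make_cohort(dir, n_targets = 4, n_references = 3,
                                      accent_magnitudes = c(0, 0.3, 0.6, 1),
                                      seed = 42)
  }
  .cohort_cache$tiny
}

# Minimal stereo 16-bit PCM WAV writer (test-only; the package writes mono).
write_stereo_wav <- function(left, right, rate, path) {
  q <- as.integer(round(pmin(1, pmax(-1, c(rbind(left, right)))) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * length(q)), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(as.integer(rate), con, size = 4, endian = "little")
  writeBin(as.integer(rate * 4), con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * length(q)), con, size = 4, endian = "little")
  writeBin(q, con, size = 2, endian = "little")
  invisible(path)
}
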