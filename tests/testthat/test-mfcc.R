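test_that("pre-emphasis implements y[t] = x[t] - alpha x[t-1]", {
  expect_equal(pre_emphasize(c(1, 1, 1, 1), 0.97), c(1, 0.03, 0.03, 0.03))
  x <- rnorm(50)
  expect_equal(pre_emphasize(x, 0), x)
  # matches direct FIR convolution with kernel [1, -0.97] after sample 1
  conv <- convolve(x, rev(c(1, -0.97)), type = "open")[seq_along(x)]
  expect_equal(pre_emphasize(x, 0.97)[-1], conv[-1], tolerance = 1e-12)
})

test_that("framing geometry follows the 25 ms / 10 ms Hamming recipe", {
  cfg <- mfcc_config()
  f <- frame_signal(rnorm(16000), 16000, cfg)
  expect_equal(dim(f), c(98, 400))  # 1 + floor((16000 - 400) / 160)

  # exactly one window of samples gives exactly one frame
  expect_equal(nrow(frame_signal(rnorm(400), 16000, cfg)), 1)

  # all-ones input: each frame is the Hamming window itself
  f1 <- frame_signal(rep(1, 800), 16000, cfg)
  expect_equal(f1[1, ], as.numeric(signal::hamming(400)))
  expect_equal(f1[nrow(f1), ], as.numeric(signal::hamming(400)))

  set.seed(31)
  for (L in sample(300:30000, 100)) {
    n_expected <- if (L < 400) 1 else 1 + (L - 400) %/% 160
    f <- suppressWarnings(frame_signal(rnorm(L), 16000, cfg))
    expect_equal(nrow(f), n_expected)
  }
  expect_error(frame_signal(numeric(0), 16000, cfg), "empty")
})

test_that("mel filterbank energies localize tones and floor silence", {
  cfg <- mfcc_config()
  rate <- 11025
  W <- round(0.025 * rate)

  # all-zero frame: every energy sits at the floor constant
  e0 <- mel_filterbank_energies(numeric(W), rate, cfg)
  expect_equal(e0, rep(cfg$energy_floor, cfg$n_filters))

  # a tone at filter k's center frequency maximizes energy k
  mel <- function(f) 2595 * log10(1 + f / 700)
  imel <- function(m) 700 * (10^(m / 2595) - 1)
  centers <- imel(seq(mel(0), mel(rate / 2), length.out = cfg$n_filters + 2))
  for (k in c(5, 10, 18)) {
    tone <- sin(2 * pi * centers[k + 1] * (0:(W - 1)) / rate)
    e <- mel_filterbank_energies(tone * signal::hamming(W), rate, cfg)
    expect_equal(which.max(e), k)
  }

  # white noise: strictly positive everywhere
  set.seed(5)
  en <- mel_filterbank_energies(rnorm(W) * signal::hamming(W), rate, cfg)
  expect_true(all(en > 0))
})

test_that("compute_mfcc returns 39 columns with the framing row count", {
  set.seed(11)
  cfg <- mfcc_config()
  for (L in c(300, 1000, 5000, 11025)) {
    w <- waveform(rnorm(L), 11025)
    m <- suppressWarnings(compute_mfcc(w, cfg))
    expect_equal(ncol(m), 39)
    W <- round(0.025 * 11025); H <- round(0.010 * 11025)
    expect_equal(nrow(m), if (L < W) 1 else 1 + (L - W) %/% H)
    expect_true(all(is.finite(m)))
  }
})

test_that("stationary input has all-zero delta and double-delta columns", {
  rate <- 16000
  H <- round(0.010 * rate)
  # signal periodic in the frame step: every frame is identical
  pattern <- sin(2 * pi * (0:(H - 1)) / H) + 0.3 * cos(2 * pi * 3 * (0:(H - 1)) / H)
  x <- rep(pattern, 20)
  m <- compute_mfcc(waveform(x[1:(400 + 10 * H)], rate), mfcc_config(preemphasis = 0))
  expect_gt(nrow(m), 3)
  expect_equal(max(abs(m[, 14:39])), 0)
})

test_that("cepstral columns 1-12 are invariant to global gain", {
  set.seed(12)
  w <- waveform(0.3 * rnorm(4000), 11025)
  m1 <- compute_mfcc(w)
  m2 <- compute_mfcc(waveform(2.5 * w$samples, 11025))
  expect_equal(m1[, 1:12], m2[, 1:12], tolerance = 1e-10)
  # the energy column shifts additively by log(g^2)
  expect_equal(m2[, 13] - m1[, 13], rep(log(2.5^2), nrow(m1)),
               tolerance = 1e-10)
})

test_that("first 12 cepstra match a literal log-mel + DCT-II oracle", {
  set.seed(13)
  rate <- 11025
  cfg <- mfcc_config(preemphasis = 0)
  W <- round(0.025 * rate)
  x <- rnorm(W)  # exactly one frame
  m <- compute_mfcc(waveform(x, rate), cfg)

  # independent step-by-step reimplementation on that frame
  frame <- x * (0.54 - 0.46 * cos(2 * pi * (0:(W - 1)) / (W - 1)))
  padded <- c(frame, numeric(512 - W))
  ps <- Mod(fft(padded))[1:257]^2 / 512
  mel <- function(f) 2595 * log10(1 + f / 700)
  imel <- function(m) 700 * (10^(m / 2595) - 1)
  edges <- imel(seq(mel(0), mel(rate / 2), length.out = 28))
  freqs <- (0:256) * rate / 512
  fbank <- sapply(1:26, function(k) {
    up <- (freqs - edges[k]) / (edges[k + 1] - edges[k])
    dn <- (edges[k + 2] - freqs) / (edges[k + 2] - edges[k + 1])
    sum(pmax(0, pmin(up, dn)) * ps)
  })
  logfb <- log(pmax(fbank, 1e-10))
  cep <- sapply(1:12, function(k) {
    sqrt(2 / 26) * sum(logfb * cos(pi * ((1:26) - 0.5) * k / 26))
  })
  expect_equal(as.numeric(m[1, 1:12]), cep, tolerance = 1e-8)
})

test_that("feature extraction is deterministic", {
  set.seed(14)
  w <- waveform(rnorm(3000), 11025)
  expect_identical(compute_mfcc(w), compute_mfcc(w))
})

test_that("time-reversing a stationary signal leaves static frames unchanged", {
  rate <- 16000
  H <- round(0.010 * rate)
  pattern <- sin(2 * pi * (0:(H - 1)) / H)
  x <- rep(pattern, 15)[1:(400 + 6 * H)]
  cfg <- mfcc_config(preemphasis = 0)
  m_fwd <- compute_mfcc(waveform(x, rate), cfg)[, 1:13]
  m_rev <- compute_mfcc(waveform(rev(x), rate), cfg)[, 1:13]
  # compare as multisets of rows (sorted by first coefficient)
  expect_equal(m_fwd[order(m_fwd[, 1]), ], m_rev[order(m_rev[, 1]), ],
               tolerance = 1e-8)
})
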