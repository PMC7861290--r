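# LPC-based formant estimates: fit an autoregressive model and take the
# angles of its complex poles — independent of the synthesis path.
est_formants <- function(x, rate, order = 12) {
  a <- stats::ar(x, order.max = order, aic = FALSE, method = "burg")$ar
  rts <- polyroot(c(1, -a))
  f <- abs(Arg(rts)) * rate / (2 * pi)
  sort(unique(round(f[f > 120 & f < rate / 2 - 120])))
}

# Cepstral pitch estimate over a sample window: the peak quefrency of the
# real cepstrum in the plausible pitch-period range.
est_f0 <- function(x, rate, lo = 70, hi = 320) {
  n <- length(x)
  spec <- log(Mod(fft(x * signal::hamming(n)))^2 + 1e-12)
  cep <- Re(fft(spec, inverse = TRUE)) / n
  q <- round(rate / hi):round(rate / lo)
  rate / q[which.max(cep[q + 1])]
}

test_that("synthesized vowels have the requested length and are seeded", {
  spec <- talker_spec(jitter = 0, duration = 0.3, seed = 5)
  w <- synth_vowel(spec, "a", rate = 11025)
  expect_equal(length(w$samples), round(0.3 * 11025))
  expect_identical(w$samples, synth_vowel(spec, "a", rate = 11025)$samples)
  # different renditions differ once jitter is present
  spec2 <- talker_spec(jitter = 0.02, seed = 5)
  expect_false(identical(synth_vowel(spec2, "a", rendition = 1)$samples,
                         synth_vowel(spec2, "a", rendition = 2)$samples))
  expect_error(synth_vowel(spec, "xx"), "unknown vowel")
  expect_error(talker_spec(formant_grid = list(bad = c(900, 800, 2500))),
               "F1 < F2 < F3")
})

test_that("spectral envelope peaks sit at the specified formants", {
  spec <- talker_spec(f0 = 110, jitter = 0.02, duration = 0.35, seed = 6)
  for (v in c("a", "i", "O")) {
    w <- synth_vowel(spec, v, rate = 11025)
    planted <- attr(w, "synth_params")$formants
    est <- est_formants(w$samples, 11025)
    for (k in 1:2) {  # F1 and F2
      rel <- min(abs(est - planted[k])) / planted[k]
      expect_lt(rel, 0.05)
    }
  }
})

test_that("rising intonation raises the f0 track by the contour ratio", {
  spec <- talker_spec(f0 = 120, jitter = 0.01, duration = 0.5, seed = 7)
  w <- synth_vowel(spec, "a", rate = 11025)
  expect_identical(apply_intonation(w, "flat"), w)
  r <- apply_intonation(w, "rising")
  # length preserved within one pitch period
  expect_lt(abs(length(r$samples) - length(w$samples)), 11025 / 120 + 1)
  n <- length(r$samples)
  f0_start <- est_f0(r$samples[1:round(n / 4)], 11025)
  f0_end <- est_f0(r$samples[round(3 * n / 4):n], 11025)
  expect_gte(f0_end / f0_start, 1.3)
  expect_error(apply_intonation(waveform(rnorm(100), 11025), "rising"),
               "synthetic")
})

test_that("stretch_segment dilates exactly the requested span", {
  set.seed(71)
  # amplitude-modulated noise, so the energy envelope has visible shape
  tt <- (0:9999) / 10000
  w <- waveform(rnorm(10000) * (0.2 + abs(sin(2 * pi * 3 * tt))), 10000)
  expect_equal(stretch_segment(w, c(0.2, 0.5), 1)$samples, w$samples)
  s2 <- stretch_segment(w, c(0.2, 0.5), 2)
  # a span of 0.3 s doubled grows the signal by 0.3 s
  expect_equal(length(s2$samples), 10000 + 3000, tolerance = 2 / 10000)
  # untouched head and tail are bit-identical
  expect_identical(s2$samples[1:2000], w$samples[1:2000])
  expect_identical(rev(s2$samples)[1:5000], rev(w$samples)[1:5000])

  # energy envelope of the stretched region is a time-dilated copy
  seg <- w$samples[2001:5000]
  seg2 <- s2$samples[2001:8000]
  env <- function(x, k = 30) {
    m <- matrix(x[1:(k * (length(x) %/% k))], ncol = k)
    sqrt(colMeans(m^2))
  }
  expect_gt(cor(env(seg), env(seg2)), 0.9)
  expect_error(stretch_segment(w, c(0.9, 1.5), 2), "invalid span")
})

test_that("the coloured device changes the signal without destroying it", {
  spec <- talker_spec(seed = 8)
  w <- synth_vowel(spec, "e", rate = 11025)
  expect_identical(simulate_device(w, "flat"), w)
  d <- simulate_device(w, "coloured", seed = 3)
  expect_false(identical(d$samples, w$samples))
  expect_gt(cor(w$samples, d$samples), 0.8)
  expect_identical(d$samples,
                   simulate_device(w, "coloured", seed = 3)$samples)
})

test_that("cohorts regenerate bit-identically from the same seed", {
  d1 <- file.path(tempdir(), "cohort-rep1")
  d2 <- file.path(tempdir(), "cohort-rep2")
  make_cohort(d1, n_targets = 2, n_references = 2,
              accent_magnitudes = c(0, 1), seed = 33)
  make_cohort(d2, n_targets = 2, n_references = 2,
              accent_magnitudes = c(0, 1), seed = 33)
  f1 <- list.files(d1, recursive = TRUE, full.names = TRUE)
  f2 <- list.files(d2, recursive = TRUE, full.names = TRUE)
  expect_equal(basename(f1), basename(f2))
  expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  expect_error(make_cohort(tempdir(), n_targets = 2, n_references = 1,
                           accent_magnitudes = c(-1, 0), seed = 1),
               ">= 0")
})

test_that("zero-magnitude targets blend into the reference spread", {
  co <- tiny_cohort()
  res <- run_measure(co$targets_dir, co$references_dir)
  refref <- run_measure(co$references_dir, co$references_dir)
  pm <- attr(refref, "pair_matrix")
  offdiag <- pm[row(pm) != col(pm)]
  d0 <- res$mean_distance[res$target_speaker_id == "tgt01"]  # magnitude 0
  expect_lt(abs(d0 - mean(offdiag)), 3 * sd(offdiag) + 0.05 * mean(offdiag))
})

test_that("perturbed renditions are farther from normals than normals are", {
  d <- perturbation_experiment(seed = 2, n_renditions = 4)
  expect_gt(d["device"], d["normal"])
  expect_gt(d["intonation"], d["normal"])
  expect_gt(d["duration"], d["normal"])
})
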