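#' Default synthetic vowel formant grid
#'
#' Twelve monophthongs with (F1, F2, F3) targets in Hz, roughly spanning
#' an adult vowel space from close front /i/ to open /a/ to close back /u/
#' (ASCII labels; capitals mark the lax counterparts).
#'
#' @return Named list of 3-vectors `c(F1, F2, F3)`.
#' @export
default_formant_grid <- function() {
  list(
    i  = c(290, 2250, 2900),
    I  = c(400, 1950, 2600),
    e  = c(420, 2100, 2750),
    E  = c(580, 1800, 2500),
    a  = c(750, 1300, 2400),
    A  = c(700, 1100, 2450),
    O  = c(550,  900, 2400),
    o  = c(450,  850, 2350),
    u  = c(320,  800, 2250),
    y  = c(300, 1750, 2200),
    Y  = c(440, 1650, 2450),
    eu = c(430, 1500, 2400)
  )
}

#' Specify a synthetic talker
#'
#' Bundles the parameters of the deterministic source-filter synthesizer:
#' base pitch, per-vowel formant targets, rendition-to-rendition relative
#' jitter (applied to pitch, formants and duration so repeated renditions
#' of the same word differ slightly, as human repetitions do), syllable
#' duration, and the seed all randomness flows from.
#'
#' @param f0 Base fundamental frequency in Hz.
#' @param formant_grid Named list of `c(F1, F2, F3)` targets in Hz.
#' @param jitter Relative rendition-to-rendition variability (fraction).
#' @param duration Seconds per syllable nucleus.
#' @param seed Integer seed.
#' @return A `TalkerSpec` list.
#' @export
talker_spec <- function(f0 = 120, formant_grid = default_formant_grid(),
                        jitter = 0.02, duration = 0.25, seed = 1L) {
  if (f0 <= 0) stop("f0 must be positive")
  if (jitter < 0) stop("jitter must be >= 0")
  for (v in names(formant_grid)) {
    fr <- formant_grid[[v]]
    if (length(fr) != 3L || !all(diff(fr) > 0)) {
      stop("formant targets for vowel '", v, "' must satisfy F1 < F2 < F3")
    }
  }
  structure(list(f0 = f0, formant_grid = formant_grid, jitter = jitter,
                 duration = duration, seed = as.integer(seed)),
            class = "TalkerSpec")
}

# One cascaded second-order resonator per formant, excited by a jittered
# impulse train; the classic source-filter vowel model.
synth_engine <- function(spec, vowel, rate, rendition, f0_mult, duration) {
  fr_target <- spec$formant_grid[[vowel]]
  if (is.null(fr_target)) stop("unknown vowel '", vowel, "'")
  v_idx <- match(vowel, names(spec$formant_grid))
  rng <- init_rng(as.numeric(spec$seed) + 7919 * v_idx +
                    104729 * as.numeric(rendition))
  # rendition-level parameter jitter
  fr <- fr_target * (1 + spec$jitter * rnorm_rng(rng, 3))
  f0 <- spec$f0 * (1 + spec$jitter * rnorm_rng(rng, 1))
  dur <- duration * (1 + spec$jitter * rnorm_rng(rng, 1))
  n <- max(16L, round(dur * rate))

  # glottal source: impulse train with per-period jitter, linear f0 ramp
  src <- numeric(n)
  pos <- 1
  while (pos <= n) {
    src[ceiling(pos)] <- 1
    frac <- pos / n
    f0_here <- f0 * (f0_mult[1] + (f0_mult[2] - f0_mult[1]) * frac)
    period <- rate / f0_here
    pos <- pos + period * (1 + 0.25 * spec$jitter * rnorm_rng(rng, 1))
  }
  # vocal tract: cascade of two-pole resonators
  bw <- c(80, 90, 120)
  y <- src
  for (k in seq_along(fr)) {
    r <- exp(-pi * bw[k] / rate)
    theta <- 2 * pi * fr[k] / rate
    y <- as.numeric(stats::filter(y, c(2 * r * cos(theta), -r^2),
                                  method = "recursive"))
  }
  # 5 ms raised-cosine on/offset ramps, amplitude normalization
  ramp <- min(round(0.005 * rate), n %/% 2)
  if (ramp > 0) {
    env <- c(0.5 - 0.5 * cos(pi * seq_len(ramp) / ramp),
             rep(1, n - 2 * ramp),
             0.5 + 0.5 * cos(pi * seq_len(ramp) / ramp))
    y <- y * env
  }
  y <- 0.5 * y / max(abs(y))
  list(samples = y, formants = fr, f0 = f0)
}

#' Synthesize one vowel rendition
#'
#' Source-filter synthesis: an impulse train at the talker's (jittered)
#' pitch filtered through cascaded second-order resonators at the vowel's
#' formant targets, with onset/offset ramps and amplitude normalization.
#' Renditions are deterministic given `(seed, vowel, rendition)`; different
#' `rendition` indices give slightly different parameter draws.
#'
#' @param spec A [talker_spec()].
#' @param vowel Vowel label present in the talker's formant grid.
#' @param rate Sampling rate in Hz.
#' @param rendition Rendition index (changes the jitter draws).
#' @param f0_mult Length-2 multiplier `c(start, end)` for a linear pitch
#'   ramp over the vowel (default flat).
#' @return A [waveform()] of length `~ duration * rate`, carrying a
#'   `synth_params` attribute (including the realized formants).
#' @export
synth_vowel <- function(spec, vowel, rate = 11025, rendition = 1L,
                        f0_mult = c(1, 1)) {
  stopifnot(inherits(spec, "TalkerSpec"))
  res <- synth_engine(spec, vowel, rate, rendition, f0_mult, spec$duration)
  w <- waveform(res$samples, rate)
  attr(w, "synth_params") <- list(type = "vowel", spec = spec, vowel = vowel,
                                  rate = rate, rendition = rendition,
                                  f0_mult = f0_mult, formants = res$formants)
  w
}

#' Synthesize a multi-syllable word
#'
#' Concatenates vowel nuclei separated by short closure gaps, with one
#' pitch ramp spanning the whole word. Used for the two-syllable word of
#' the perturbation experiments.
#'
#' @param spec A [talker_spec()].
#' @param vowels Character vector of vowel labels, one per syllable.
#' @param rate Sampling rate in Hz.
#' @param rendition Rendition index.
#' @param f0_mult Length-2 pitch ramp multiplier over the whole word.
#' @param durations Per-syllable durations in seconds (default: the
#'   talker's `duration` for each).
#' @param gap Closure gap between syllables in seconds.
#' @return A [waveform()] with a `synth_params` attribute and a
#'   `syllable_spans` attribute of per-syllable `(start, end)` times.
#' @export
synth_word <- function(spec, vowels, rate = 11025, rendition = 1L,
                       f0_mult = c(1, 1), durations = NULL, gap = 0.03) {
  stopifnot(inherits(spec, "TalkerSpec"))
  if (is.null(durations)) durations <- rep(spec$duration, length(vowels))
  n_syl <- length(vowels)
  total <- sum(durations)
  parts <- vector("list", n_syl)
  spans <- matrix(0, n_syl, 2)
  t_done <- 0
  for (s in seq_len(n_syl)) {
    # pitch ramp section for this syllable
    m0 <- f0_mult[1] + (f0_mult[2] - f0_mult[1]) * t_done / total
    m1 <- f0_mult[1] + (f0_mult[2] - f0_mult[1]) * (t_done + durations[s]) / total
    res <- synth_engine(spec, vowels[s], rate, rendition + 131L * (s - 1L),
                        c(m0, m1), durations[s])
    parts[[s]] <- res$samples
    t_done <- t_done + durations[s]
  }
  gap_n <- round(gap * rate)
  samples <- numeric(0)
  for (s in seq_len(n_syl)) {
    spans[s, 1] <- length(samples) / rate
    samples <- c(samples, parts[[s]])
    spans[s, 2] <- length(samples) / rate
    if (s < n_syl) samples <- c(samples, numeric(gap_n))
  }
  w <- waveform(samples, rate)
  attr(w, "synth_params") <- list(type = "word", spec = spec, vowels = vowels,
                                  rate = rate, rendition = rendition,
                                  f0_mult = f0_mult, durations = durations,
                                  gap = gap)
  attr(w, "syllable_spans") <- spans
  w
}

#' Re-synthesize with a different intonation contour
#'
#' `"flat"` returns the input unchanged; `"rising"` re-runs the synthesizer
#' with the same seed and jitter draws but the fundamental frequency
#' ramped from 1.0x to 1.5x over the duration, preserving length up to a
#' pitch period. Only works on waveforms produced by [synth_vowel()] or
#' [synth_word()] (which carry their generating parameters).
#'
#' @param w A synthetic [waveform()].
#' @param contour `"flat"` or `"rising"`.
#' @return A [waveform()].
#' @export
apply_intonation <- function(w, contour = c("flat", "rising")) {
  contour <- match.arg(contour)
  if (contour == "flat") return(w)
  p <- attr(w, "synth_params")
  if (is.null(p)) {
    stop("apply_intonation requires a synthetic waveform from synth_vowel()/synth_word()")
  }
  if (p$type == "vowel") {
    synth_vowel(p$spec, p$vowel, p$rate, p$rendition, f0_mult = c(1, 1.5))
  } else {
    synth_word(p$spec, p$vowels, p$rate, p$rendition, f0_mult = c(1, 1.5),
               durations = p$durations, gap = p$gap)
  }
}

#' Stretch a time span of a waveform
#'
#' Linearly time-dilates the samples inside `span` by `factor` (simple
#' interpolation; pitch is not preserved), leaving the rest untouched.
#' Emulates a lengthened syllable.
#'
#' @param w A [waveform()].
#' @param span `c(start, end)` in seconds, within the waveform.
#' @param factor Positive stretch ratio (2 doubles the span).
#' @return A [waveform()] whose duration grew by `(factor - 1)` times the
#'   span length.
#' @export
stretch_segment <- function(w, span, factor) {
  stopifnot(inherits(w, "Waveform"))
  if (factor <= 0) stop("factor must be positive")
  dur <- wave_duration(w)
  if (span[1] < 0 || span[2] <= span[1] || span[2] > dur + 1e-9) {
    stop("invalid span [", span[1], ", ", span[2], "] for a ",
         round(dur, 3), " s waveform")
  }
  i0 <- floor(span[1] * w$rate) + 1L
  i1 <- min(floor(span[2] * w$rate), length(w$samples))
  seg <- w$samples[i0:i1]
  n_new <- max(2L, round(length(seg) * factor))
  seg2 <- stats::approx(seq_along(seg), seg, n = n_new)$y
  waveform(c(if (i0 > 1L) w$samples[1:(i0 - 1L)], seg2,
             if (i1 < length(w$samples)) w$samples[(i1 + 1L):length(w$samples)]),
           w$rate)
}

#' Simulate a recording-channel difference
#'
#' `"flat"` is the identity. `"coloured"` applies a mild fixed spectral
#' tilt (first-order FIR high-boost) and adds low-level seeded noise,
#' emulating the same pronunciation captured by a different microphone.
#'
#' @param w A [waveform()].
#' @param device `"flat"` or `"coloured"`.
#' @param seed Seed for the noise draw.
#' @return A [waveform()].
#' @export
simulate_device <- function(w, device = c("flat", "coloured"), seed = 1L) {
  device <- match.arg(device)
  if (device == "flat") return(w)
  x <- w$samples
  y <- x - 0.3 * c(0, x[-length(x)])
  rng <- init_rng(seed)
  y <- y + rnorm_rng(rng, length(y), 0, 0.1 * stats::sd(x))
  waveform(y, w$rate)
}

# hVd-style word labels for the cohort recordings, one per grid vowel.
.cohort_words <- c(i = "heed", I = "hid", e = "hayed", E = "head",
                   a = "haad", A = "hod", O = "hawed", o = "hoed")

#' Generate a synthetic speaker cohort on disk
#'
#' Writes the exact on-disk layout [run_measure()] consumes: a references/
#' directory of native-like talkers drawn around one formant grid, and a
#' targets/ directory of talkers whose formants and durations are shifted
#' in proportion to a planted accent magnitude. Each speaker gets
#' `<id>.wav` (words concatenated with silent gaps) and `<id>.csv` word
#' alignments; `ratings.csv` holds planted native-likeness ratings (an
#' affine decreasing function of magnitude plus seeded noise, clipped to
#' the 1-7 scale) and `magnitudes.csv` the planted magnitudes.
#'
#' Two nuisance features of field recordings are emulated, uncorrelated
#' with the planted accent: each speaker records through their own channel
#' (random gain, mild spectral tilt, low-level noise), and the pauses
#' between words vary in length and sometimes contain a filled-pause
#' ("uh"-like) disfluency that lies outside the word boundaries. Speaker
#' normalization targets the former, word segmentation the latter.
#'
#' @param out_dir Output directory (created if needed).
#' @param n_targets,n_references Cohort sizes.
#' @param accent_magnitudes Non-negative planted accent magnitudes, one
#'   per target (default an even grid on \[0, 1\]).
#' @param seed Integer seed; the same seed reproduces identical files.
#' @param rate Sampling rate of the written WAV files.
#' @return Invisibly, a list with `targets_dir`, `references_dir`,
#'   `ratings` (data.frame), `magnitudes` (data.frame), `words`.
#' @export
make_cohort <- function(out_dir, n_targets = 20, n_references = 10,
                        accent_magnitudes = NULL, seed = 1L, rate = 11025) {
  if (is.null(accent_magnitudes)) {
    accent_magnitudes <- seq(0, 1, length.out = n_targets)
  }
  if (length(accent_magnitudes) != n_targets) {
    stop("need one accent magnitude per target")
  }
  if (any(accent_magnitudes < 0)) stop("accent magnitudes must be >= 0")
  t_dir <- file.path(out_dir, "targets")
  r_dir <- file.path(out_dir, "references")
  dir.create(t_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(r_dir, recursive = TRUE, showWarnings = FALSE)
  rng <- init_rng(seed)
  base_grid <- default_formant_grid()[names(.cohort_words)]

  write_speaker <- function(dir, id, magnitude, spk_seed) {
    spk_rng <- init_rng(spk_seed)
    f0 <- runif_rng(spk_rng, 1, 100, 200)
    # speaker-specific vowel-space scatter plus the planted accent shift
    grid <- base_grid
    for (v in names(grid)) {
      scatter <- 1 + 0.02 * rnorm_rng(spk_rng, 3)
      shift <- c(1 + 0.25 * magnitude, 1 - 0.15 * magnitude, 1)
      grid[[v]] <- sort(grid[[v]] * scatter * shift)
    }
    dur <- 0.25 * (1 + 0.3 * magnitude)
    spec <- talker_spec(f0 = f0, formant_grid = grid, jitter = 0.02,
                        duration = dur, seed = spk_seed)
    # speaker-specific recording channel, uncorrelated with accent
    chan_gain <- runif_rng(spk_rng, 1, 0.3, 1.0)
    chan_tilt <- runif_rng(spk_rng, 1, -0.3, 0.3)
    chan_noise <- runif_rng(spk_rng, 1, 0.01, 0.05)
    disfl_spec <- talker_spec(f0 = f0,
                              formant_grid = list(uh = c(500, 1500, 2500)),
                              jitter = 0.05, duration = 0.1,
                              seed = spk_seed + 17L)
    pause <- function() {
      # variable silence, sometimes holding a filled-pause disfluency
      g1 <- numeric(round(runif_rng(spk_rng, 1, 0.08, 0.25) * rate))
      if (runif_rng(spk_rng, 1) < 0.5) {
        uh <- synth_engine(disfl_spec, "uh", rate,
                           rendition = round(runif_rng(spk_rng, 1, 1, 1e4)),
                           f0_mult = c(1, 1),
                           duration = runif_rng(spk_rng, 1, 0.05, 0.15))
        g2 <- numeric(round(runif_rng(spk_rng, 1, 0.05, 0.15) * rate))
        c(g1, 0.4 * uh$samples, g2)
      } else {
        g1
      }
    }
    samples <- pause()
    starts <- ends <- numeric(length(.cohort_words))
    for (k in seq_along(.cohort_words)) {
      wv <- synth_vowel(spec, names(.cohort_words)[k], rate, rendition = k)
      starts[k] <- length(samples) / rate
      samples <- c(samples, wv$samples)
      ends[k] <- length(samples) / rate
      samples <- c(samples, pause())
    }
    samples <- samples + chan_tilt * c(0, samples[-length(samples)])
    samples <- samples + chan_noise * stats::sd(samples) *
      rnorm_rng(spk_rng, length(samples))
    samples <- chan_gain * samples
    write_wav(waveform(samples, rate), file.path(dir, paste0(id, ".wav")))
    a <- word_alignment(unname(.cohort_words), starts, ends)
    write_alignment(a, file.path(dir, paste0(id, ".csv")))
  }

  for (j in seq_len(n_references)) {
    write_speaker(r_dir, sprintf("ref%02d", j), 0, seed + 500L + j)
  }
  target_ids <- sprintf("tgt%02d", seq_len(n_targets))
  for (j in seq_len(n_targets)) {
    write_speaker(t_dir, target_ids[j], accent_magnitudes[j],
                  seed + 9000L + j)
  }
  ratings <- data.frame(
    speaker_id = target_ids,
    mean_rating = pmin(7, pmax(1, 7 - 5.5 * accent_magnitudes +
                                 rnorm_rng(rng, n_targets, 0, 0.3))))
  magnitudes <- data.frame(speaker_id = target_ids,
                           magnitude = accent_magnitudes)
  utils::write.csv(ratings, file.path(out_dir, "ratings.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(magnitudes, file.path(out_dir, "magnitudes.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(list(targets_dir = t_dir, references_dir = r_dir,
                 ratings = ratings, magnitudes = magnitudes,
                 words = unname(.cohort_words)))
}

#' Perturbation experiment on synthetic renditions of one word
#'
#' Synthesizes repeated renditions of a two-syllable word by one talker
#' and compares, after speaker CMVN, (a) normal renditions among
#' themselves, (b) the same renditions re-recorded through a coloured
#' channel, (c) renditions with rising intonation, and (d) renditions with
#' the first syllable lengthened. Mean DTW distances per condition answer
#' whether the measure picks up channel, intonation and timing differences
#' beyond natural rendition-to-rendition variation.
#'
#' @param seed Integer seed.
#' @param n_renditions Renditions per condition.
#' @param rate Sampling rate in Hz.
#' @param cfg An [mfcc_config()].
#' @param stretch_factor First-syllable lengthening factor.
#' @return Named numeric vector of mean distances:
#'   `normal`, `device`, `intonation`, `duration`.
#' @export
perturbation_experiment <- function(seed = 1L, n_renditions = 5L,
                                    rate = 11025, cfg = mfcc_config(),
                                    stretch_factor = 1.5) {
  spec <- talker_spec(f0 = 120, jitter = 0.02, duration = 0.12,
                      seed = as.integer(seed))
  syl <- c("I", "i")
  normals <- lapply(seq_len(n_renditions), function(k) {
    synth_word(spec, syl, rate, rendition = k)
  })
  device <- lapply(seq_len(n_renditions), function(k) {
    simulate_device(normals[[k]], "coloured", seed = seed + 100L + k)
  })
  rising <- lapply(seq_len(n_renditions), function(k) {
    synth_word(spec, syl, rate, rendition = n_renditions + k,
               f0_mult = c(1, 1.5))
  })
  lengthened <- lapply(seq_len(n_renditions), function(k) {
    w <- synth_word(spec, syl, rate, rendition = 2L * n_renditions + k)
    span <- attr(w, "syllable_spans")[1, ]
    stretch_segment(w, span, stretch_factor)
  })
  all_w <- c(normals, device, rising, lengthened)
  feats <- lapply(all_w, function(w) compute_mfcc(w, cfg))
  stats <- estimate_cmvn(feats)
  feats <- lapply(feats, apply_cmvn, stats = stats)
  idx <- function(block) (block - 1L) * n_renditions + seq_len(n_renditions)
  nrm <- feats[idx(1)]
  cross_mean <- function(a, b) {
    mean(vapply(a, function(fa) {
      mean(vapply(b, function(fb) dtw_distance(fa, fb)$distance, numeric(1)))
    }, numeric(1)))
  }
  pairs_nn <- utils::combn(n_renditions, 2)
  normal_d <- mean(vapply(seq_len(ncol(pairs_nn)), function(p) {
    dtw_distance(nrm[[pairs_nn[1, p]]], nrm[[pairs_nn[2, p]]])$distance
  }, numeric(1)))
  c(normal = normal_d,
    device = cross_mean(feats[idx(2)], nrm),
    intonation = cross_mean(feats[idx(3)], nrm),
    duration = cross_mean(feats[idx(4)], nrm))
}

#' Synthetic vowel-grid experiment (hVd analog)
#'
#' Synthesizes repetitions of each vowel of the talker's grid, computes the
#' mean CMVN-normalized DTW distance between every vowel pair, and relates
#' it to the Bark-scaled (F1, F2) formant distance between the planted
#' vowel targets. The correlation between the two distance sets indicates
#' how much segmental (vowel-quality) information the acoustic measure
#' captures.
#'
#' @param seed Integer seed.
#' @param n_repetitions Renditions per vowel.
#' @param rate Sampling rate in Hz.
#' @param cfg An [mfcc_config()].
#' @return List: `r` and `p` (Pearson over vowel pairs), `dtw_dist` and
#'   `formant_dist` (12 x 12 matrices), `vowels`.
#' @export
hvd_experiment <- function(seed = 1L, n_repetitions = 10L, rate = 11025,
                           cfg = mfcc_config()) {
  spec <- talker_spec(f0 = 120, jitter = 0.02, duration = 0.2,
                      seed = as.integer(seed))
  vowels <- names(spec$formant_grid)
  nv <- length(vowels)
  feats <- list()
  realized <- list()
  for (v in vowels) {
    for (k in seq_len(n_repetitions)) {
      w <- synth_vowel(spec, v, rate, rendition = k)
      feats[[paste(v, k)]] <- compute_mfcc(w, cfg)
      realized[[paste(v, k)]] <- attr(w, "synth_params")$formants
    }
  }
  stats <- estimate_cmvn(feats)
  feats <- lapply(feats, apply_cmvn, stats = stats)
  dtw_d <- matrix(0, nv, nv, dimnames = list(vowels, vowels))
  fmt_d <- matrix(0, nv, nv, dimnames = list(vowels, vowels))
  mean_fmt <- lapply(vowels, function(v) {
    rowMeans(sapply(seq_len(n_repetitions), function(k) {
      realized[[paste(v, k)]]
    }))
  })
  names(mean_fmt) <- vowels
  for (i in seq_len(nv - 1)) {
    for (j in (i + 1):nv) {
      ds <- numeric(0)
      for (ki in seq_len(n_repetitions)) {
        for (kj in seq_len(n_repetitions)) {
          ds <- c(ds, dtw_distance(feats[[paste(vowels[i], ki)]],
                                   feats[[paste(vowels[j], kj)]])$distance)
        }
      }
      dtw_d[i, j] <- dtw_d[j, i] <- mean(ds)
      fmt_d[i, j] <- fmt_d[j, i] <- formant_distance(
        formant_point(mean_fmt[[i]][1], mean_fmt[[i]][2]),
        formant_point(mean_fmt[[j]][1], mean_fmt[[j]][2]))
    }
  }
  ut <- upper.tri(dtw_d)
  ct <- pearson_cor(dtw_d[ut], fmt_d[ut])
  list(r = ct$r, p = ct$p_value, dtw_dist = dtw_d, formant_dist = fmt_d,
       vowels = vowels)
}
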