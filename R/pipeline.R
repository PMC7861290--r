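#' Per-word normalized features for one speaker
#'
#' Computes the MFCC feature matrix of every word of a segmented utterance
#' and (optionally) applies the speaker's own CMVN statistics, pooled over
#' all of the speaker's words.
#'
#' @param utt A `SegmentedUtterance` from [segment_words()].
#' @param cfg An [mfcc_config()].
#' @param normalize Apply speaker CMVN (`TRUE` for the full measure,
#'   `FALSE` for the segmentation-only baseline).
#' @return Named list of feature matrices, one per word.
#' @export
speaker_word_features <- function(utt, cfg = mfcc_config(), normalize = TRUE) {
  stopifnot(inherits(utt, "SegmentedUtterance"))
  feats <- lapply(utt$words, compute_mfcc, cfg = cfg)
  if (normalize) feats <- cmvn_speaker(feats)$features
  feats
}

#' Mean acoustic distance between two speakers
#'
#' Computes the word-level DTW distance for every word the two speakers
#' share and returns the arithmetic mean. Words are matched by their
#' (positionally disambiguated) labels; the intersection of available
#' words is used.
#'
#' @param target,reference Named lists of per-word feature matrices, e.g.
#'   from [speaker_word_features()].
#' @param word_list Optional character vector restricting the comparison to
#'   these word labels.
#' @param squared Use squared Euclidean frame costs.
#' @return Scalar mean distance with attribute `n_words` (words compared).
#' @export
speaker_pair_distance <- function(target, reference, word_list = NULL,
                                  squared = FALSE) {
  shared <- intersect(names(target), names(reference))
  if (!is.null(word_list)) shared <- intersect(shared, word_list)
  if (!length(shared)) stop("speakers share no words to compare")
  d <- vapply(shared, function(wd) {
    dtw_distance(target[[wd]], reference[[wd]], squared = squared)$distance
  }, numeric(1))
  structure(mean(d), n_words = length(shared))
}

#' Mean acoustic distance of a target speaker to a reference set
#'
#' Unweighted mean of [speaker_pair_distance()] over all reference
#' speakers: the accent-strength score of the target.
#'
#' @param target Named list of per-word feature matrices.
#' @param references List of such lists, one per reference speaker.
#' @inheritParams speaker_pair_distance
#' @return Scalar mean distance with attributes `n_words` (average words
#'   per comparison) and `n_references`.
#' @export
distance_to_reference_set <- function(target, references, word_list = NULL,
                                      squared = FALSE) {
  if (!length(references)) stop("empty reference list")
  d <- vapply(references, function(ref) {
    speaker_pair_distance(target, ref, word_list = word_list,
                          squared = squared)
  }, numeric(1))
  nw <- vapply(references, function(ref) {
    attr(speaker_pair_distance(target, ref, word_list = word_list,
                               squared = squared), "n_words")
  }, integer(1))
  structure(mean(d), n_words = as.integer(round(mean(nw))),
            n_references = length(references))
}

# ---- on-disk speaker collections -------------------------------------------

# Enumerate <id>.wav recordings in a directory with their alignment files.
list_speaker_files <- function(dir, dialect) {
  wavs <- sort(list.files(dir, pattern = "\\.wav$", ignore.case = TRUE,
                          full.names = TRUE))
  if (!length(wavs)) stop("no .wav files found in ", dir)
  ids <- sub("\\.wav$", "", basename(wavs), ignore.case = TRUE)
  ext <- if (dialect == "csv") ".csv" else ".TextGrid"
  aligns <- file.path(dir, paste0(ids, ext))
  data.frame(id = ids, wav = wavs, align = aligns, stringsAsFactors = FALSE)
}

# Load one speaker into per-word features; NULL (with a warning) on failure.
load_speaker_features <- function(id, wav_path, align_path, mode, rate,
                                  dialect, cfg, word_list, validate) {
  tryCatch({
    w <- resample_wave(read_wav(wav_path), rate)
    if (mode == "normalization_only") {
      feats <- list(`_recording_` = compute_mfcc(w, cfg))
      cmvn_speaker(feats)$features
    } else {
      a <- read_alignment(align_path, dialect = dialect,
                          word_list = if (validate) word_list else NULL)
      utt <- segment_words(w, a, speaker_id = id)
      speaker_word_features(utt, cfg, normalize = (mode == "full"))
    }
  }, error = function(e) {
    warning("skipping speaker '", id, "': ", conditionMessage(e),
            call. = FALSE)
    NULL
  })
}

load_speaker_set <- function(dir, mode, rate, dialect, cfg, word_list,
                             validate) {
  files <- list_speaker_files(dir, dialect)
  feats <- lapply(seq_len(nrow(files)), function(k) {
    load_speaker_features(files$id[k], files$wav[k], files$align[k], mode,
                          rate, dialect, cfg, word_list, validate)
  })
  names(feats) <- files$id
  feats
}

#' Run the acoustic pronunciation distance measure over speaker directories
#'
#' End-to-end computation: for every target speaker, read the recording,
#' resample to the working rate, segment into words, extract MFCC features,
#' apply speaker CMVN, compute length-normalized DTW distances to every
#' reference speaker word by word, and average — first over words, then
#' over references. Two baseline modes drop one ingredient each:
#' `"segmentation_only"` skips CMVN, and `"normalization_only"` skips
#' segmentation (one DTW comparison over the whole CMVN-normalized
#' recording per speaker pair; no alignments needed).
#'
#' Speakers whose audio or alignment cannot be read are skipped with a
#' warning and listed in the `failures` attribute of the result.
#'
#' @param target_dir,reference_dir Directories of `<id>.wav` recordings
#'   plus `<id>.csv` / `<id>.TextGrid` alignments.
#' @param mode `"full"`, `"segmentation_only"`, or `"normalization_only"`.
#' @param rate Working sampling rate in Hz (default 11025).
#' @param dialect Alignment file dialect, `"csv"` or `"textgrid"`.
#' @param cfg An [mfcc_config()].
#' @param word_list Optional expected word list; with `validate = TRUE`
#'   alignments must match it exactly (e.g. [stella_words()] for full
#'   paragraph recordings).
#' @param validate Validate alignments against `word_list`.
#' @return A `SpeakerDistanceTable` data.frame with columns
#'   `target_speaker_id`, `mean_distance`, `n_words_used`,
#'   `n_references_used`, plus attributes `pair_matrix` (targets x
#'   references distance matrix) and `failures` (skipped speaker ids).
#' @export
run_measure <- function(target_dir, reference_dir,
                        mode = c("full", "segmentation_only",
                                 "normalization_only"),
                        rate = 11025, dialect = c("csv", "textgrid"),
                        cfg = mfcc_config(), word_list = NULL,
                        validate = FALSE) {
  mode <- match.arg(mode)
  dialect <- match.arg(dialect)
  targets <- load_speaker_set(target_dir, mode, rate, dialect, cfg,
                              word_list, validate)
  refs <- load_speaker_set(reference_dir, mode, rate, dialect, cfg,
                           word_list, validate)
  failures <- c(names(targets)[vapply(targets, is.null, logical(1))],
                names(refs)[vapply(refs, is.null, logical(1))])
  targets <- Filter(Negate(is.null), targets)
  refs <- Filter(Negate(is.null), refs)
  if (!length(targets)) stop("no readable target speakers")
  if (!length(refs)) stop("no readable reference speakers")

  squared <- isTRUE(cfg$squared_cost)
  pair <- pair_distance_matrix(targets, refs, word_list = word_list,
                               squared = squared)
  n_words <- vapply(names(targets), function(tid) {
    as.integer(round(mean(vapply(refs, function(ref) {
      length(intersect(names(targets[[tid]]), names(ref)))
    }, integer(1)))))
  }, integer(1))
  out <- data.frame(target_speaker_id = names(targets),
                    mean_distance = rowMeans(pair),
                    n_words_used = n_words,
                    n_references_used = length(refs),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("SpeakerDistanceTable", "data.frame")
  attr(out, "pair_matrix") <- pair
  attr(out, "failures") <- failures
  attr(out, "mode") <- mode
  out
}

#' Run a baseline variant of the measure
#'
#' Convenience wrapper around [run_measure()] for the two single-ingredient
#' baselines: `"segmentation_only"` (word-level DTW on raw, un-normalized
#' MFCCs) and `"normalization_only"` (one whole-recording DTW on
#' CMVN-normalized MFCCs).
#'
#' @param mode `"segmentation_only"` or `"normalization_only"`.
#' @param ... Passed to [run_measure()].
#' @return A `SpeakerDistanceTable`.
#' @export
run_baseline <- function(mode = c("segmentation_only", "normalization_only"),
                         ...) {
  mode <- match.arg(mode)
  run_measure(..., mode = mode)
}

#' Target-by-reference pair distance matrix
#'
#' @param targets,references Named lists of per-word feature lists.
#' @inheritParams speaker_pair_distance
#' @return Numeric matrix (targets in rows, references in columns) of mean
#'   per-word DTW distances.
#' @export
pair_distance_matrix <- function(targets, references, word_list = NULL,
                                 squared = FALSE) {
  m <- matrix(NA_real_, length(targets), length(references),
              dimnames = list(names(targets), names(references)))
  for (i in seq_along(targets)) {
    for (j in seq_along(references)) {
      m[i, j] <- speaker_pair_distance(targets[[i]], references[[j]],
                                       word_list = word_list,
                                       squared = squared)
    }
  }
  m
}

#' Effect of reference-set size on the rating correlation
#'
#' For each requested subset size, draws seeded random subsets of the
#' reference speakers (uniformly, without replacement), recomputes each
#' target's mean distance over the subset, correlates the distances with
#' the human native-likeness ratings, and reports the mean (and spread)
#' of the Pearson correlation over draws.
#'
#' @param pair_matrix Targets x references distance matrix, e.g. the
#'   `pair_matrix` attribute of [run_measure()]'s result.
#' @param ratings Data frame with columns `speaker_id`, `mean_rating`;
#'   joined to the matrix rows by speaker id.
#' @param sizes Integer vector of reference-subset sizes.
#' @param n_draws Random subsets per size (default 10).
#' @param seed RNG seed; the experiment is reproducible given the seed.
#' @return Data frame with columns `size`, `mean_r`, `sd_r`, `n_draws`.
#' @export
reference_subset_experiment <- function(pair_matrix, ratings, sizes,
                                        n_draws = 10, seed = 1) {
  stopifnot(is.matrix(pair_matrix))
  ids <- rownames(pair_matrix)
  ratings <- ratings[match(ids, ratings$speaker_id), , drop = FALSE]
  if (anyNA(ratings$mean_rating)) stop("ratings missing for some speakers")
  n_refs <- ncol(pair_matrix)
  if (any(sizes > n_refs)) {
    stop("subset size exceeds the reference pool (", n_refs, ")")
  }
  rng <- init_rng(seed)
  rows <- lapply(sizes, function(sz) {
    rs <- vapply(seq_len(n_draws), function(k) {
      pick <- sample_rng(rng, n_refs, sz)
      d <- rowMeans(pair_matrix[, pick, drop = FALSE])
      stats::cor(d, ratings$mean_rating)
    }, numeric(1))
    data.frame(size = sz, mean_r = mean(rs),
               sd_r = if (n_draws > 1) stats::sd(rs) else NA_real_,
               n_draws = n_draws)
  })
  do.call(rbind, rows)
}

#' Write a SpeakerDistanceTable to CSV
#'
#' @param x A `SpeakerDistanceTable`.
#' @param path Output path (header
#'   `target_speaker_id,mean_distance,n_words_used,n_references_used`).
#' @return `path`, invisibly.
#' @export
write_distance_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
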