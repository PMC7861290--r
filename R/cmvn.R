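#' Estimate speaker CMVN statistics
#'
#' Pools all frames of all the speaker's word feature matrices and computes
#' the per-coefficient mean and population (1/N) standard deviation used
#' for cepstral mean and variance normalization.
#'
#' @param features A single feature matrix or a list of feature matrices
#'   (all with the same column count), e.g. from [compute_mfcc()].
#' @return A `CmvnStats` list with `mean`, `std` (per-column vectors) and
#'   `n_frames`.
#' @export
estimate_cmvn <- function(features) {
  if (is.matrix(features)) features <- list(features)
  if (!length(features)) stop("no feature matrices supplied")
  pooled <- do.call(rbind, features)
  n <- nrow(pooled)
  if (n < 1L) stop("zero pooled frames")
  mu <- colMeans(pooled)
  sdev <- sqrt(colMeans(sweep(pooled, 2L, mu, `-`)^2))
  structure(list(mean = mu, std = sdev, n_frames = n), class = "CmvnStats")
}

#' Apply cepstral mean and variance normalization
#'
#' Standardizes each feature dimension with the speaker's statistics:
#' `(c(i,t) - mean_i) / std_i`. Degenerate columns (std below `eps`) are
#' only mean-subtracted, so silent-channel columns do not blow up.
#'
#' @param features A feature matrix (frames x coefficients).
#' @param stats A `CmvnStats` from [estimate_cmvn()].
#' @param eps Degenerate-standard-deviation guard.
#' @return The normalized feature matrix, same shape.
#' @export
apply_cmvn <- function(features, stats, eps = 1e-10) {
  stopifnot(inherits(stats, "CmvnStats"))
  if (ncol(features) != length(stats$mean)) {
    stop("feature matrix has ", ncol(features), " columns but stats cover ",
         length(stats$mean))
  }
  if (!all(is.finite(stats$mean)) || !all(is.finite(stats$std))) {
    stop("non-finite CMVN statistics")
  }
  div <- ifelse(stats$std < eps, 1, stats$std)
  out <- sweep(sweep(features, 2L, stats$mean, `-`), 2L, div, `/`)
  attr(out, "frame_step") <- attr(features, "frame_step")
  out
}

#' Normalize all words of a segmented utterance with one set of stats
#'
#' Convenience wrapper: estimates the speaker's CMVN statistics from the
#' supplied word feature matrices pooled together, then applies them to
#' each word.
#'
#' @param word_features Named list of feature matrices (one per word).
#' @return List with `features` (normalized matrices) and `stats`.
#' @export
cmvn_speaker <- function(word_features) {
  stats <- estimate_cmvn(word_features)
  list(features = lapply(word_features, apply_cmvn, stats = stats),
       stats = stats)
}
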