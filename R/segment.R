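#' Slice a recording into per-word waveforms
#'
#' Cuts one word [waveform()] out of the full recording for every interval
#' of the alignment. Sample indexing is 0-based and half-open:
#' word `k` receives samples `[floor(start_k * rate), floor(end_k * rate))`,
#' so for a gap-free alignment the slices concatenate back to the spanned
#' region exactly.
#'
#' Repeated labels (the elicitation paragraph contains e.g. "her" four
#' times) are disambiguated positionally with [make.unique()], so word
#' tokens pair up across speakers in paragraph order.
#'
#' @param w A [waveform()] of the complete recording.
#' @param a A [word_alignment()] whose intervals all end within the
#'   recording.
#' @param speaker_id Identifier attached to the result.
#' @return A `SegmentedUtterance`: list with `speaker_id`, `rate`, and
#'   `words`, a named list of word [waveform()]s in alignment order.
#' @export
segment_words <- function(w, a, speaker_id = "speaker") {
  stopifnot(inherits(w, "Waveform"), inherits(a, "WordAlignment"))
  dur <- wave_duration(w)
  over <- a$end > dur + 1e-9
  if (any(over)) {
    stop("Alignment interval(s) beyond audio end (duration ", round(dur, 3),
         " s): ", paste(a$word[over], collapse = ", "))
  }
  i0 <- floor(a$start * w$rate)
  i1 <- floor(a$end * w$rate)
  i1 <- pmin(i1, length(w$samples))
  words <- vector("list", nrow(a))
  for (k in seq_len(nrow(a))) {
    if (i1[k] <= i0[k]) {
      stop("Interval for word '", a$word[k], "' contains no samples")
    }
    words[[k]] <- waveform(w$samples[(i0[k] + 1):i1[k]], w$rate)
  }
  names(words) <- make.unique(tolower(a$word), sep = ".")
  structure(list(speaker_id = speaker_id, rate = w$rate, words = words),
            class = "SegmentedUtterance")
}

#' @export
print.SegmentedUtterance <- function(x, ...) {
  cat(sprintf("<SegmentedUtterance '%s': %d words @ %g Hz>\n",
              x$speaker_id, length(x$words), x$rate))
  invisible(x)
}
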