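#' Construct a WordAlignment
#'
#' Labeled `(word, start, end)` intervals locating each read word in a
#' recording. Intervals are validated: starts are non-negative, every end
#' exceeds its start, and intervals must not overlap. Entries are sorted
#' by start time.
#'
#' @param word Character vector of word labels.
#' @param start,end Numeric vectors of interval boundaries in seconds.
#' @param word_list Optional character vector of expected words (in order).
#'   When supplied, the alignment labels must match it one-to-one,
#'   case-insensitively.
#' @return A `WordAlignment`: a data.frame with columns `word`, `start`,
#'   `end`, of class `c("WordAlignment", "data.frame")`.
#' @export
word_alignment <- function(word, start, end, word_list = NULL) {
  word <- as.character(word)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (length(word) != length(start) || length(word) != length(end)) {
    stop("word, start and end must have equal length")
  }
  if (length(word) == 0L) stop("Alignment contains no word intervals")
  if (any(start < 0)) stop("Interval start times must be >= 0")
  if (any(end <= start)) {
    bad <- word[end <= start]
    stop("Intervals with end <= start: ", paste(bad, collapse = ", "))
  }
  o <- order(start)
  word <- word[o]; start <- start[o]; end <- end[o]
  if (length(start) > 1L) {
    overlap <- which(start[-1] < end[-length(end)] - 1e-9)
    if (length(overlap)) {
      stop("Overlapping intervals: ",
           paste(sprintf("'%s'/'%s'", word[overlap], word[overlap + 1]),
                 collapse = ", "))
    }
  }
  if (!is.null(word_list)) {
    got <- tolower(word)
    want <- tolower(word_list)
    if (length(got) != length(want) || !all(got == want)) {
      stop("Alignment labels do not match the expected word list (",
           length(got), " vs ", length(want), " words)")
    }
  }
  structure(data.frame(word = word, start = start, end = end,
                       stringsAsFactors = FALSE),
            class = c("WordAlignment", "data.frame"))
}

# Interval labels treated as silence/pause markers by forced aligners.
.silence_labels <- c("", "sp", "sil", "<sil>", "sp1", "pause")

#' Read a word alignment from a TextGrid or CSV file
#'
#' Consumes externally produced word-boundary annotations. Silent or empty
#' intervals (`""`, `"sp"`, `"sil"`, ...) are dropped; remaining entries
#' are sorted and validated (non-overlapping, end > start).
#'
#' @param path Path to the annotation file.
#' @param dialect `"textgrid"` (Praat long or short interval format) or
#'   `"csv"` (header `word,start,end`, times in seconds with dot decimal).
#' @param tier For TextGrids, the name of the interval tier holding words
#'   (default `"words"`); ignored for CSV.
#' @param word_list Optional expected word list passed to [word_alignment()].
#' @return A [word_alignment()].
#' @export
read_alignment <- function(path, dialect = c("csv", "textgrid"),
                           tier = "words", word_list = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("Alignment file does not exist: ", path)
  raw <- if (dialect == "csv") read_alignment_csv(path) else
    read_alignment_textgrid(path, tier)
  keep <- !(tolower(trimws(raw$word)) %in% .silence_labels)
  raw <- raw[keep, , drop = FALSE]
  if (nrow(raw) == 0L) stop("Alignment contains no word intervals: ", path)
  word_alignment(raw$word, raw$start, raw$end, word_list = word_list)
}

read_alignment_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("word", "start", "end")
  if (!all(need %in% names(df))) {
    stop("Alignment CSV must have columns word,start,end: ", path)
  }
  df[, need]
}

# Praat TextGrid interval-tier parser (long and short text formats).
read_alignment_textgrid <- function(path, tier) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- trimws(lines)
  if (!any(grepl("ooTextFile", lines[seq_len(min(3, length(lines)))]))) {
    stop("Not a Praat TextGrid file: ", path)
  }
  long <- any(grepl("^item\\s*\\[", lines))
  qstr <- function(s) gsub('^"|"$', "", gsub('""', '"', s))
  if (long) {
    # Locate IntervalTiers and their names
    cls_idx <- grep('class\\s*=\\s*"IntervalTier"', lines)
    tier_start <- NA_integer_
    for (i in cls_idx) {
      nm <- qstr(sub('.*name\\s*=\\s*', "", lines[i + 1]))
      if (identical(tolower(nm), tolower(tier))) { tier_start <- i; break }
    }
    if (is.na(tier_start)) {
      stop("TextGrid has no interval tier named '", tier, "': ", path)
    }
    item_idx <- grep("^item\\s*\\[", lines)
    tier_end <- item_idx[item_idx > tier_start]
    tier_end <- if (length(tier_end)) tier_end[1] - 1L else length(lines)
    block <- lines[tier_start:tier_end]
    xmin <- as.numeric(sub(".*xmin\\s*=\\s*", "", grep("xmin\\s*=", block, value = TRUE)))
    xmax <- as.numeric(sub(".*xmax\\s*=\\s*", "", grep("xmax\\s*=", block, value = TRUE)))
    text <- vapply(grep("text\\s*=", block, value = TRUE),
                   function(s) qstr(sub('.*text\\s*=\\s*', "", s)), "",
                   USE.NAMES = FALSE)
    # first xmin/xmax pair is the tier's own range
    if (length(xmin) == length(text) + 1L) { xmin <- xmin[-1]; xmax <- xmax[-1] }
    data.frame(word = text, start = xmin, end = xmax, stringsAsFactors = FALSE)
  } else {
    # Short format: "IntervalTier", "name", xmin, xmax, n, then triples
    idx <- which(lines == '"IntervalTier"')
    if (!length(idx)) stop("TextGrid has no interval tier: ", path)
    tier_start <- NA_integer_
    for (i in idx) {
      if (identical(tolower(qstr(lines[i + 1])), tolower(tier))) {
        tier_start <- i; break
      }
    }
    if (is.na(tier_start)) {
      stop("TextGrid has no interval tier named '", tier, "': ", path)
    }
    n <- as.integer(lines[tier_start + 4L])
    base <- tier_start + 4L
    starts <- as.numeric(lines[base + (seq_len(n) - 1) * 3 + 1])
    ends <- as.numeric(lines[base + (seq_len(n) - 1) * 3 + 2])
    texts <- qstr(lines[base + (seq_len(n) - 1) * 3 + 3])
    data.frame(word = texts, start = starts, end = ends,
               stringsAsFactors = FALSE)
  }
}

#' Write a word alignment to CSV or TextGrid
#'
#' CSV output has header `word,start,end`; TextGrid output is a long-format
#' Praat file with a single interval tier named `tier`, with silent
#' intervals filling any gaps between words.
#'
#' @param a A [word_alignment()].
#' @param path Output path.
#' @param dialect `"csv"` or `"textgrid"`.
#' @param tier Tier name for TextGrid output.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(a, path, dialect = c("csv", "textgrid"),
                            tier = "words") {
  stopifnot(inherits(a, "WordAlignment"))
  dialect <- match.arg(dialect)
  if (dialect == "csv") {
    utils::write.csv(as.data.frame(a)[, c("word", "start", "end")], path,
                     row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  # fill gaps with empty (silent) intervals so the tier is contiguous
  starts <- numeric(0); ends <- numeric(0); labels <- character(0)
  cursor <- 0
  for (k in seq_len(nrow(a))) {
    if (a$start[k] > cursor + 1e-9) {
      starts <- c(starts, cursor); ends <- c(ends, a$start[k])
      labels <- c(labels, "")
    }
    starts <- c(starts, a$start[k]); ends <- c(ends, a$end[k])
    labels <- c(labels, a$word[k])
    cursor <- a$end[k]
  }
  xmax <- max(ends)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    'File type = "ooTextFile"', 'Object class = "TextGrid"', "",
    "xmin = 0", sprintf("xmax = %.6f", xmax),
    "tiers? <exists>", "size = 1", "item []:", "    item [1]:",
    '        class = "IntervalTier"', sprintf('        name = "%s"', tier),
    "        xmin = 0", sprintf("        xmax = %.6f", xmax),
    sprintf("        intervals: size = %d", length(starts))), con)
  for (k in seq_along(starts)) {
    writeLines(c(sprintf("        intervals [%d]:", k),
                 sprintf("            xmin = %.6f", starts[k]),
                 sprintf("            xmax = %.6f", ends[k]),
                 sprintf('            text = "%s"', labels[k])), con)
  }
  invisible(path)
}

#' The 69-word elicitation paragraph word list
#'
#' The words of the standard reading paragraph ("Please call Stella, ..."),
#' in order, lower-cased. Alignments of full paragraph recordings can be
#' validated against it.
#'
#' @return Character vector of 69 words.
#' @export
stella_words <- function() {
  readLines(system.file("extdata", "stella_words.txt", package = "accdist"),
            warn = FALSE)
}
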