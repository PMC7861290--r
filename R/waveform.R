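#' Construct a Waveform
#'
#' A `Waveform` is the unit every acoustic operation consumes: a mono,
#' real-valued sample sequence (nominal amplitude range \[-1, 1\]) together
#' with its sampling rate in Hz.
#'
#' @param samples Numeric vector of amplitudes, length >= 1.
#' @param rate Sampling rate in samples per second (positive).
#' @return An object of class `Waveform` with elements `samples` and `rate`.
#' @examples
#' w <- waveform(sin(2 * pi * 440 * seq(0, 1, by = 1 / 8000)), 8000)
#' wave_duration(w)
#' @export
waveform <- function(samples, rate) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("Waveform must contain at least one sample")
  if (!all(is.finite(samples))) stop("Waveform samples must be finite")
  rate <- as.numeric(rate)
  if (length(rate) != 1L || !is.finite(rate) || rate <= 0) {
    stop("Sampling rate must be a single positive number")
  }
  structure(list(samples = samples, rate = rate), class = "Waveform")
}

#' @export
print.Waveform <- function(x, ...) {
  cat(sprintf("<Waveform: %d samples @ %g Hz (%.3f s)>\n",
              length(x$samples), x$rate, wave_duration(x)))
  invisible(x)
}

#' Duration of a Waveform in seconds
#' @param w A `Waveform`.
#' @return Duration in seconds.
#' @export
wave_duration <- function(w) length(w$samples) / w$rate

#' Read a PCM WAV file
#'
#' Reads a RIFF/WAVE file containing uncompressed PCM (8/16/24/32-bit
#' integer) or IEEE float samples. Samples are scaled to \[-1, 1\] and
#' multi-channel audio is averaged to mono; the sampling rate is taken
#' from the file header.
#'
#' @param path Path to a `.wav` file.
#' @return A [waveform()].
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("Audio file does not exist: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("Not a RIFF/WAVE file: ", path)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("Not a RIFF/WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        audio_format = readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE),
        n_channels   = readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE),
        sample_rate  = readBin(con, "integer", 1, size = 4, endian = "little"),
        byte_rate    = readBin(con, "integer", 1, size = 4, endian = "little"),
        block_align  = readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE),
        bits         = readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE)
      )
      extra <- size - 16L
      if (extra > 0L) invisible(readBin(con, "raw", extra))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
      if (size %% 2L == 1L) invisible(readBin(con, "raw", 1))
    } else {
      invisible(readBin(con, "raw", size + size %% 2L))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop("Malformed WAV file (missing fmt or data chunk): ", path)
  }
  if (!fmt$audio_format %in% c(1L, 3L)) {
    stop("Unsupported (compressed) WAV encoding in ", path,
         "; only PCM and IEEE float are readable")
  }
  bits <- fmt$bits
  if (fmt$audio_format == 3L) {
    if (!bits %in% c(32L, 64L)) stop("Unsupported float bit depth: ", bits)
    x <- readBin(data_raw, "numeric", n = length(data_raw) %/% (bits / 8),
                 size = bits / 8, endian = "little")
  } else if (bits == 8L) {
    # 8-bit PCM is unsigned
    x <- (readBin(data_raw, "integer", n = length(data_raw), size = 1,
                  signed = FALSE) - 128) / 128
  } else if (bits == 16L) {
    x <- readBin(data_raw, "integer", n = length(data_raw) %/% 2, size = 2,
                 endian = "little") / 32768
  } else if (bits == 24L) {
    n <- length(data_raw) %/% 3
    m <- matrix(as.integer(data_raw[seq_len(n * 3)]), nrow = 3)
    v <- m[1, ] + m[2, ] * 256L + m[3, ] * 65536L
    v <- ifelse(v >= 8388608, v - 16777216, v)
    x <- v / 8388608
  } else if (bits == 32L) {
    x <- readBin(data_raw, "integer", n = length(data_raw) %/% 4, size = 4,
                 endian = "little") / 2147483648
  } else {
    stop("Unsupported PCM bit depth: ", bits)
  }
  nc <- fmt$n_channels
  if (nc > 1L) {
    usable <- (length(x) %/% nc) * nc
    x <- rowMeans(matrix(x[seq_len(usable)], ncol = nc, byrow = TRUE))
  }
  waveform(x, fmt$sample_rate)
}

#' Write a Waveform to a 16-bit PCM WAV file
#'
#' Samples outside \[-1, 1\] are clipped before quantization.
#'
#' @param w A [waveform()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(w, path) {
  stopifnot(inherits(w, "Waveform"))
  x <- pmin(1, pmax(-1, w$samples))
  q <- pmin(32767L, as.integer(round(x * 32768)))
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- length(q) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")        # PCM
  writeBin(1L, con, size = 2, endian = "little")        # mono
  writeBin(as.integer(w$rate), con, size = 4, endian = "little")
  writeBin(as.integer(w$rate * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  writeBin(q, con, size = 2, endian = "little")
  invisible(path)
}

#' Resample a Waveform
#'
#' Band-limited polyphase resampling to a new rate. The output length is
#' `round(length(samples) * target_rate / rate)`, so duration is conserved
#' to within one output sample. A waveform already at the target rate is
#' returned unchanged.
#'
#' @param w A [waveform()].
#' @param target_rate Target sampling rate in Hz (default 11025, the
#'   working rate used throughout the measure).
#' @return A [waveform()] at `target_rate`.
#' @export
resample_wave <- function(w, target_rate = 11025) {
  stopifnot(inherits(w, "Waveform"))
  if (target_rate <= 0) stop("target_rate must be positive")
  if (w$rate == target_rate) return(w)
  frac <- rational_approx(target_rate / w$rate)
  y <- signal::resample(w$samples, frac[1], frac[2])
  n_out <- round(length(w$samples) * target_rate / w$rate)
  if (length(y) >= n_out) {
    y <- y[seq_len(n_out)]
  } else {
    y <- c(y, numeric(n_out - length(y)))
  }
  waveform(y, target_rate)
}

# Small continued-fraction rational approximation p/q of a positive ratio.
rational_approx <- function(x, max_den = 10000L) {
  a <- floor(x)
  p0 <- 1; q0 <- 0; p1 <- a; q1 <- 1
  frac <- x - a
  while (frac > 1e-12 && q1 < max_den) {
    x <- 1 / frac
    a <- floor(x)
    frac <- x - a
    p2 <- a * p1 + p0; q2 <- a * q1 + q0
    if (q2 > max_den) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
  }
  c(as.integer(p1), as.integer(q1))
}
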