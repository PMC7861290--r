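#' MFCC extraction configuration
#'
#' Defaults follow the common automatic-speech-recognition recipe: 25 ms
#' Hamming-windowed frames with a 10 ms step, pre-emphasis 0.97, a 26-filter
#' mel filterbank, 12 cepstral coefficients plus log frame energy, and
#' delta/double-delta regression over a +/-2 frame window, giving 39
#' features per frame.
#'
#' @param preemphasis Pre-emphasis coefficient in \[0, 1).
#' @param frame_length Analysis window length in seconds.
#' @param frame_step Window step in seconds (must not exceed `frame_length`).
#' @param n_cepstra Number of cepstral coefficients kept (the 0th is
#'   dropped in favor of the explicit log-energy feature).
#' @param n_filters Number of triangular mel filters.
#' @param fft_size FFT length in samples; must cover one frame at the
#'   working sampling rate.
#' @param delta_window Half-width (in frames) of the delta regression.
#' @param low_freq,high_freq Filterbank edge frequencies in Hz; `NULL`
#'   `high_freq` means the Nyquist frequency of the input.
#' @param energy_floor Floor applied to filterbank outputs and frame energy
#'   before taking logs.
#' @param squared_cost If `TRUE`, downstream DTW uses squared instead of
#'   rooted Euclidean frame costs (see [dtw_distance()]).
#' @return An `MfccConfig` list.
#' @export
mfcc_config <- function(preemphasis = 0.97, frame_length = 0.025,
                        frame_step = 0.010, n_cepstra = 12L,
                        n_filters = 26L, fft_size = 512L,
                        delta_window = 2L, low_freq = 0, high_freq = NULL,
                        energy_floor = 1e-10, squared_cost = FALSE) {
  if (preemphasis < 0 || preemphasis >= 1) stop("preemphasis must be in [0, 1)")
  if (frame_step > frame_length) stop("frame_step must not exceed frame_length")
  if (n_cepstra >= n_filters) stop("n_cepstra must be < n_filters")
  structure(list(preemphasis = preemphasis, frame_length = frame_length,
                 frame_step = frame_step, n_cepstra = as.integer(n_cepstra),
                 n_filters = as.integer(n_filters),
                 fft_size = as.integer(fft_size),
                 delta_window = as.integer(delta_window),
                 low_freq = low_freq, high_freq = high_freq,
                 energy_floor = energy_floor,
                 squared_cost = isTRUE(squared_cost)),
            class = "MfccConfig")
}

#' First-order pre-emphasis filter
#'
#' Applies `y[t] = x[t] - alpha * x[t-1]` (with `y[1] = x[1]`), the
#' high-pass filter `H(z) = 1 - alpha z^-1` that compensates the downward
#' spectral tilt of voiced speech.
#'
#' @param x Numeric sample vector.
#' @param alpha Filter coefficient (default 0.97).
#' @return Filtered vector of the same length.
#' @export
pre_emphasize <- function(x, alpha = 0.97) {
  if (length(x) < 1L) stop("empty signal")
  if (length(x) == 1L) return(x)
  c(x[1], x[-1] - alpha * x[-length(x)])
}

frame_geometry <- function(L, rate, cfg) {
  W <- round(cfg$frame_length * rate)
  H <- round(cfg$frame_step * rate)
  if (W > cfg$fft_size) {
    stop("fft_size (", cfg$fft_size, ") smaller than the ", W,
         "-sample analysis window; increase fft_size or lower the rate")
  }
  list(W = as.integer(W), H = as.integer(H),
       n = if (L < W) 0L else as.integer(1 + (L - W) %/% H))
}

#' Slice a signal into overlapping Hamming-windowed frames
#'
#' Frame `t` (0-based) covers samples `[t*H, t*H + W)` with
#' `W = round(frame_length * rate)` and `H = round(frame_step * rate)`;
#' there are `1 + floor((L - W) / H)` frames. Each frame is multiplied by
#' the Hamming window. A signal shorter than one window is symmetrically
#' zero-padded to `W` (with a warning), so even very short words yield one
#' frame.
#'
#' @param x Numeric sample vector.
#' @param rate Sampling rate in Hz.
#' @param cfg An [mfcc_config()].
#' @param window Apply the Hamming window (`TRUE`) or return raw frames.
#' @return Matrix with one frame per row (`n x W`).
#' @export
frame_signal <- function(x, rate, cfg = mfcc_config(), window = TRUE) {
  if (length(x) < 1L) stop("empty signal")
  g <- frame_geometry(length(x), rate, cfg)
  if (g$n == 0L) {
    pad <- g$W - length(x)
    x <- c(numeric(pad %/% 2), x, numeric(pad - pad %/% 2))
    warning("signal shorter than one analysis window; zero-padded to ",
            g$W, " samples")
    g$n <- 1L
  }
  idx <- outer(seq_len(g$W), (seq_len(g$n) - 1L) * g$H, `+`)
  frames <- t(matrix(x[idx], nrow = g$W))
  if (window) {
    frames <- sweep(frames, 2L, signal::hamming(g$W), `*`)
  }
  frames
}

mel_of_hz <- function(f) 2595 * log10(1 + f / 700)
hz_of_mel <- function(m) 700 * (10^(m / 2595) - 1)

# Triangular mel filterbank evaluated at the FFT bin frequencies:
# rows = filters, columns = bins 0..fft_size/2.
mel_filterbank <- function(rate, cfg) {
  high <- if (is.null(cfg$high_freq)) rate / 2 else cfg$high_freq
  mels <- seq(mel_of_hz(cfg$low_freq), mel_of_hz(high),
              length.out = cfg$n_filters + 2L)
  edges <- hz_of_mel(mels)
  f <- (0:(cfg$fft_size %/% 2)) * rate / cfg$fft_size
  fb <- matrix(0, cfg$n_filters, length(f))
  for (m in seq_len(cfg$n_filters)) {
    lo <- edges[m]; ce <- edges[m + 1]; hi <- edges[m + 2]
    up <- (f - lo) / (ce - lo)
    down <- (hi - f) / (hi - ce)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  fb
}

# Periodogram power spectrum of zero-padded frames: rows = frames.
power_spectrum <- function(frames, fft_size) {
  n <- ncol(frames)
  padded <- cbind(frames, matrix(0, nrow(frames), fft_size - n))
  spec <- stats::mvfft(t(padded))[seq_len(fft_size %/% 2 + 1L), , drop = FALSE]
  t(Mod(spec)^2 / fft_size)
}

#' Mel filterbank energies of one windowed frame
#'
#' Computes the periodogram power spectrum of the zero-padded frame and
#' integrates it through the triangular mel filterbank. Outputs are floored
#' at `cfg$energy_floor` so the subsequent log is finite.
#'
#' @param frame A windowed frame (numeric vector).
#' @param rate Sampling rate in Hz.
#' @param cfg An [mfcc_config()].
#' @return Numeric vector of `n_filters` non-negative energies.
#' @export
mel_filterbank_energies <- function(frame, rate, cfg = mfcc_config()) {
  if (length(frame) > cfg$fft_size) stop("frame longer than fft_size")
  ps <- power_spectrum(matrix(frame, 1L), cfg$fft_size)
  pmax(as.numeric(mel_filterbank(rate, cfg) %*% ps[1, ]), cfg$energy_floor)
}

# Orthonormal DCT-II basis rows k (0-based) over N points.
dct_matrix <- function(k_rows, N) {
  n <- seq_len(N) - 1L
  m <- outer(k_rows, n, function(k, n) cos(pi * (n + 0.5) * k / N))
  scale <- ifelse(k_rows == 0, sqrt(1 / N), sqrt(2 / N))
  m * scale
}

delta_features <- function(x, N) {
  # x: T x d statics; regression deltas with edge frames replicated
  T_ <- nrow(x)
  denom <- 2 * sum((1:N)^2)
  out <- matrix(0, T_, ncol(x))
  for (n in seq_len(N)) {
    fwd <- pmin(seq_len(T_) + n, T_)
    bwd <- pmax(seq_len(T_) - n, 1L)
    out <- out + n * (x[fwd, , drop = FALSE] - x[bwd, , drop = FALSE])
  }
  out / denom
}

#' Compute the 39-dimensional MFCC feature matrix of a word
#'
#' The full per-word feature pipeline: pre-emphasis of the whole word
#' signal, Hamming-windowed framing, periodogram power spectrum, mel
#' filterbank, log, orthonormal DCT-II keeping cepstra 1..12 (the 0th is
#' replaced by explicit log frame energy, computed on the pre-emphasized
#' un-windowed frame), then delta and double-delta regression coefficients
#' of all 13 static features. Rows are frames in time order; the 39
#' columns are cepstra 1-12, log-energy, 13 deltas, 13 double-deltas.
#'
#' @param w A [waveform()].
#' @param cfg An [mfcc_config()].
#' @return A `T x 39` numeric matrix with attribute `frame_step` (seconds).
#' @export
compute_mfcc <- function(w, cfg = mfcc_config()) {
  stopifnot(inherits(w, "Waveform"))
  x <- pre_emphasize(w$samples, cfg$preemphasis)
  raw <- frame_signal(x, w$rate, cfg, window = FALSE)
  frames <- sweep(raw, 2L, signal::hamming(ncol(raw)), `*`)
  ps <- power_spectrum(frames, cfg$fft_size)
  fb <- mel_filterbank(w$rate, cfg)
  energies <- pmax(ps %*% t(fb), cfg$energy_floor)
  cep <- log(energies) %*% t(dct_matrix(seq_len(cfg$n_cepstra), cfg$n_filters))
  log_e <- log(pmax(rowSums(raw^2), cfg$energy_floor))
  statics <- cbind(cep, log_e)
  d1 <- delta_features(statics, cfg$delta_window)
  d2 <- delta_features(d1, cfg$delta_window)
  out <- cbind(statics, d1, d2)
  dimnames(out) <- NULL
  attr(out, "frame_step") <- cfg$frame_step
  out
}
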