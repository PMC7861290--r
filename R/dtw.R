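#' Euclidean cost between two feature frames
#'
#' @param x,y Numeric vectors of equal length.
#' @param squared Return the squared distance instead of its root.
#' @return Non-negative scalar cost.
#' @export
frame_cost <- function(x, y, squared = FALSE) {
  if (length(x) != length(y)) stop("frame dimension mismatch")
  s <- sum((x - y)^2)
  if (squared) s else sqrt(s)
}

#' Length-normalized dynamic time warping distance
#'
#' Aligns a target feature sequence `x_1..x_n` with a reference sequence
#' `y_1..y_m` by dynamic programming over the cumulative cost
#' `gamma(i,j) = d(i,j) + min(gamma(i-1,j-1), gamma(i-1,j), gamma(i,j-1))`
#' with `gamma(1,1) = d(1,1)`, where `d` is the (rooted) Euclidean distance
#' between frames. The minimum cumulative cost `gamma(n,m)` is divided by
#' `n + m` so that recordings of different lengths are comparable. No
#' warping-window constraint or slope weighting is applied.
#'
#' @param target,reference Numeric matrices with frames in rows and equal
#'   column counts (vectors are treated as 1-column matrices).
#' @param squared Use squared instead of rooted Euclidean frame costs.
#' @return A `DtwResult` list: `distance` (normalized), `raw_cost`
#'   (`gamma(n,m)`), `n_frames_target`, `m_frames_reference`.
#' @examples
#' a <- matrix(c(1, 2), ncol = 1)
#' b <- matrix(c(1, 2, 2), ncol = 1)
#' dtw_distance(a, b)$distance   # 0: warping absorbs the repeat
#' @export
dtw_distance <- function(target, reference, squared = FALSE) {
  if (!is.matrix(target)) target <- matrix(target, ncol = 1L)
  if (!is.matrix(reference)) reference <- matrix(reference, ncol = 1L)
  if (nrow(target) < 1L || nrow(reference) < 1L) stop("empty feature matrix")
  if (ncol(target) != ncol(reference)) stop("frame dimension mismatch")
  res <- .dtw_core(target, reference, isTRUE(squared))
  structure(list(distance = res$distance, raw_cost = res$raw_cost,
                 n_frames_target = res$n, m_frames_reference = res$m),
            class = "DtwResult")
}
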