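#' Pearson correlation with a two-sided p-value
#'
#' Sample Pearson correlation; the p-value comes from the t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` with `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length (>= 3), non-constant.
#' @return List with `r`, `p_value`, `n`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for constant input")
  }
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Multiple regression of ratings on pronunciation measures
#'
#' Ordinary least squares with intercept, predicting the response (human
#' native-likeness ratings) from the supplied predictor columns. Standard
#' errors use the unbiased residual variance; p-values are two-sided t
#' tests.
#'
#' @param data Data frame containing `response` and `predictors`.
#' @param response Name of the response column.
#' @param predictors Character vector of predictor column names.
#' @return A `RegressionResult` list: `coefficients` (data.frame with
#'   `term`, `estimate`, `std_error`, `t_value`, `p_value`; intercept
#'   first), `r_squared`, `n`, and the underlying `model`.
#' @export
fit_regression <- function(data, response, predictors) {
  cols <- c(response, predictors)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  df <- data[stats::complete.cases(data[, cols]), cols, drop = FALSE]
  if (nrow(df) <= length(predictors) + 1) {
    stop("need more complete cases than parameters")
  }
  fml <- stats::reformulate(predictors, response)
  fit <- stats::lm(fml, data = df)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  sm <- summary(fit)
  co <- sm$coefficients
  res <- data.frame(term = rownames(co), estimate = co[, 1],
                    std_error = co[, 2], t_value = co[, 3],
                    p_value = co[, 4], row.names = NULL,
                    stringsAsFactors = FALSE)
  structure(list(coefficients = res, r_squared = sm$r.squared,
                 n = nrow(df), model = fit),
            class = "RegressionResult")
}

#' Steiger's modified z test for dependent correlations
#'
#' Compares two correlations `r12` and `r13` that share variable 1 (e.g.
#' ratings correlated with two different distance measures on the same
#' speakers), accounting for the correlation `r23` between the two
#' measures. Uses Fisher z transforms of `r12` and `r13` and Steiger's
#' (1980) modified statistic with the pooled correlation in the covariance
#' term:
#' `Z = sqrt(n - 3) * (z12 - z13) / sqrt(2 - 2 * s)`, where
#' `s = psi / (1 - rbar^2)^2`,
#' `psi = r23 * (1 - 2 * rbar^2) - rbar^2 * (1 - 2 * rbar^2 - r23^2) / 2`,
#' and `rbar = (r12 + r13) / 2`.
#'
#' @param r12,r13 Correlations being compared (each shares variable 1).
#' @param r23 Correlation between variables 2 and 3.
#' @param n Sample size (> 3).
#' @return List with `z` and two-sided `p_value`.
#' @export
steiger_test <- function(r12, r13, r23, n) {
  for (r in c(r12, r13, r23)) {
    if (abs(r) >= 1) stop("correlations must lie strictly inside (-1, 1)")
  }
  if (n <= 3) stop("n must exceed 3")
  z12 <- atanh(r12)
  z13 <- atanh(r13)
  rbar <- (r12 + r13) / 2
  psi <- r23 * (1 - 2 * rbar^2) - rbar^2 * (1 - 2 * rbar^2 - r23^2) / 2
  s <- psi / (1 - rbar^2)^2
  z <- sqrt(n - 3) * (z12 - z13) / sqrt(2 - 2 * s)
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Convert frequency to the Bark scale
#'
#' Default is Traunmueller's (1990) formula
#' `z = 26.81 * f / (1960 + f) - 0.53`; Zwicker's arctangent formula is
#' available as an alternative.
#'
#' @param f Frequency in Hz (>= 0), vectorized.
#' @param method `"traunmuller"` or `"zwicker"`.
#' @return Bark value(s).
#' @export
bark <- function(f, method = c("traunmuller", "zwicker")) {
  method <- match.arg(method)
  if (any(f < 0)) stop("frequency must be >= 0")
  if (method == "traunmuller") {
    26.81 * f / (1960 + f) - 0.53
  } else {
    13 * atan(0.00076 * f) + 3.5 * atan((f / 7500)^2)
  }
}

#' A vowel-midpoint formant measurement
#'
#' @param F1,F2 First and second formant in Hz, `0 < F1 < F2`.
#' @return A `FormantPoint` list.
#' @export
formant_point <- function(F1, F2) {
  if (F1 <= 0 || F2 <= F1) stop("formants must satisfy 0 < F1 < F2")
  structure(list(F1 = F1, F2 = F2), class = "FormantPoint")
}

#' Bark-scaled distance between two formant points
#'
#' Euclidean distance in `(bark(F1), bark(F2))` space.
#'
#' @param a,b [formant_point()]s.
#' @param method Bark formula, see [bark()].
#' @return Non-negative distance in Bark units.
#' @export
formant_distance <- function(a, b, method = "traunmuller") {
  stopifnot(inherits(a, "FormantPoint"), inherits(b, "FormantPoint"))
  sqrt((bark(a$F1, method) - bark(b$F1, method))^2 +
         (bark(a$F2, method) - bark(b$F2, method))^2)
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers the squared distance matrix and embeds the objects in
#' `k` dimensions via the top eigenpairs. Axes are oriented so that the
#' largest-magnitude loading on each axis is positive, making plots
#' reproducible. Variance explained is the kept eigenvalue sum over the
#' positive eigenvalue sum.
#'
#' @param D Symmetric, non-negative distance matrix with zero diagonal.
#' @param k Number of embedding dimensions.
#' @return List with `points` (n x k configuration), `eig` (all
#'   eigenvalues), `variance_explained` (per kept axis), and
#'   `total_variance_explained`.
#' @export
classical_mds <- function(D, k = 2) {
  D <- as.matrix(D)
  if (!isSymmetric(unname(D), tol = 1e-8)) stop("distance matrix must be symmetric")
  if (any(D < 0)) stop("distances must be non-negative")
  fit <- stats::cmdscale(D, k = k, eig = TRUE)
  pts <- fit$points
  if (is.null(pts) || ncol(pts) < k) {
    # degenerate geometry: pad missing axes with zeros
    pad <- matrix(0, nrow(D), k - if (is.null(pts)) 0 else ncol(pts))
    pts <- cbind(pts, pad)
  }
  for (a in seq_len(ncol(pts))) {
    if (any(pts[, a] != 0) && pts[which.max(abs(pts[, a])), a] < 0) {
      pts[, a] <- -pts[, a]
    }
  }
  pos <- fit$eig[fit$eig > 1e-12]
  ve <- if (length(pos)) pmax(fit$eig[seq_len(k)], 0) / sum(pos) else rep(0, k)
  list(points = pts, eig = fit$eig, variance_explained = ve,
       total_variance_explained = sum(ve))
}

#' Evaluate the acoustic measure against human judgments
#'
#' Joins a speaker distance table with native-likeness ratings by speaker
#' id and reports the Pearson correlation. If transcription-based
#' distances (and optionally mispronunciation counts) are supplied, a
#' multiple regression of ratings on all measures and a Steiger comparison
#' of the two measures' correlations (ratings being the shared variable)
#' are added.
#'
#' @param distances A `SpeakerDistanceTable` (or data.frame with
#'   `target_speaker_id`, `mean_distance`).
#' @param ratings Data frame `speaker_id`, `mean_rating` (1-7 scale).
#' @param transcription Optional data frame `speaker_id`, `distance`.
#' @param mispronunciations Optional data frame `speaker_id`, `count`.
#' @param report_path Optional path; the report is written there as JSON.
#' @return List: `r`, `p_value`, `n`, and when inputs allow, `regression`
#'   (a `RegressionResult`) and `steiger` (z and p comparing the
#'   transcription measure's correlation against the acoustic one).
#' @export
evaluate_measure <- function(distances, ratings, transcription = NULL,
                             mispronunciations = NULL, report_path = NULL) {
  d <- as.data.frame(distances)[, c("target_speaker_id", "mean_distance")]
  if (anyDuplicated(d$target_speaker_id)) {
    stop("duplicated speaker rows in the distance table")
  }
  if (anyDuplicated(ratings$speaker_id)) {
    stop("duplicated speaker rows in the ratings table")
  }
  joined <- merge(d, ratings, by.x = "target_speaker_id",
                  by.y = "speaker_id")
  if (!nrow(joined)) stop("no speakers shared between distances and ratings")
  ct <- pearson_cor(joined$mean_distance, joined$mean_rating)
  out <- list(r = ct$r, p_value = ct$p_value, n = ct$n)
  if (!is.null(transcription)) {
    joined <- merge(joined, stats::setNames(
      transcription, c("target_speaker_id", "transcription_dist")),
      by = "target_speaker_id")
    preds <- c("transcription_dist", "mean_distance")
    if (!is.null(mispronunciations)) {
      joined <- merge(joined, stats::setNames(
        mispronunciations, c("target_speaker_id", "mispronunciations")),
        by = "target_speaker_id")
      preds <- c(preds, "mispronunciations")
    }
    out$regression <- fit_regression(joined, "mean_rating", preds)
    out$steiger <- steiger_test(
      r12 = stats::cor(joined$mean_rating, joined$transcription_dist),
      r13 = stats::cor(joined$mean_rating, joined$mean_distance),
      r23 = stats::cor(joined$transcription_dist, joined$mean_distance),
      n = nrow(joined))
  }
  if (!is.null(report_path)) {
    rep <- out
    rep$regression <- if (!is.null(out$regression)) {
      list(coefficients = out$regression$coefficients,
           r_squared = out$regression$r_squared, n = out$regression$n)
    }
    jsonlite::write_json(rep, report_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  out
}
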