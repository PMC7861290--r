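test_that("pearson_cor matches the covariance formula and flags degenerate input", {
  x <- 1:10
  expect_equal(pearson_cor(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_cor(x, -x)$r, -1)
  set.seed(61)
  a <- rnorm(50); b <- 0.4 * a + rnorm(50)
  r_oracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  ct <- pearson_cor(a, b)
  expect_equal(ct$r, r_oracle, tolerance = 1e-12)
  t_stat <- r_oracle * sqrt(48 / (1 - r_oracle^2))
  expect_equal(ct$p_value, 2 * pt(-abs(t_stat), 48), tolerance = 1e-12)
  expect_error(pearson_cor(rep(1, 10), rnorm(10)), "constant")
})

test_that("regression recovers planted coefficients and matches normal equations", {
  set.seed(62)
  n <- 100
  df <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  df$y <- 2 - 3 * df$x1 + 0.5 * df$x2
  fit0 <- suppressWarnings(fit_regression(df, "y", c("x1", "x2")))
  expect_equal(fit0$coefficients$estimate, c(2, -3, 0.5), tolerance = 1e-10)

  df$y <- df$y + rnorm(n)
  fit <- fit_regression(df, "y", c("x1", "x2", "x3"))
  X <- cbind(1, df$x1, df$x2, df$x3)
  beta <- solve(t(X) %*% X, t(X) %*% df$y)
  resid <- df$y - X %*% beta
  s2 <- sum(resid^2) / (n - 4)
  se <- sqrt(diag(s2 * solve(t(X) %*% X)))
  expect_equal(fit$coefficients$estimate, as.numeric(beta), tolerance = 1e-8)
  expect_equal(fit$coefficients$std_error, se, tolerance = 1e-8)
  expect_equal(fit$coefficients$t_value,
               fit$coefficients$estimate / fit$coefficients$std_error,
               tolerance = 1e-6)
  expect_true(fit$r_squared >= 0 && fit$r_squared <= 1)

  # single predictor: r_squared equals the squared Pearson correlation
  f1 <- fit_regression(df, "y", "x1")
  expect_equal(f1$r_squared, cor(df$y, df$x1)^2, tolerance = 1e-12)

  # collinear columns are named
  df$x4 <- df$x1
  expect_error(fit_regression(df, "y", c("x1", "x4")), "x4")
})

test_that("Steiger's modified z behaves as the dependent-correlation test", {
  expect_equal(steiger_test(0.5, 0.5, 0.3, 50)$z, 0)
  z1 <- steiger_test(0.7, 0.5, 0.6, 100)$z
  z2 <- steiger_test(0.5, 0.7, 0.6, 100)$z
  expect_equal(z1, -z2)
  expect_gt(z1, 0)
  expect_error(steiger_test(1, 0.5, 0.3, 50), "strictly inside")
  expect_error(steiger_test(0.5, 0.4, 0.3, 3), "exceed")
})

test_that("Steiger null p-values are approximately uniform", {
  set.seed(63)
  n <- 60
  rho <- 0.4; r23 <- 0.5
  S <- matrix(c(1, rho, rho, rho, 1, r23, rho, r23, 1), 3, 3)
  L <- chol(S)
  p <- vapply(1:2000, function(k) {
    X <- matrix(rnorm(n * 3), n, 3) %*% L
    r <- cor(X)
    steiger_test(r[1, 2], r[1, 3], r[2, 3], n)$p_value
  }, numeric(1))
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("bark scale follows the Traunmueller formula", {
  expect_equal(bark(0), -0.53)
  expect_equal(bark(1960), 26.81 / 2 - 0.53)
  f <- seq(50, 8000, by = 50)
  expect_true(all(diff(bark(f)) > 0))
  expect_true(all(diff(bark(f, "zwicker")) > 0))
  expect_error(bark(-1), ">= 0")
})

test_that("formant distances are Bark-space Euclidean and symmetric", {
  a <- formant_point(500, 1500)
  b <- formant_point(700, 1200)
  expect_equal(formant_distance(a, a), 0)
  expect_equal(formant_distance(a, b), formant_distance(b, a))
  # F1-only offset reduces to the 1-D Bark difference
  c_ <- formant_point(700, 1500)
  expect_equal(formant_distance(a, c_), abs(bark(500) - bark(700)))
  expect_error(formant_point(1500, 500), "F1 < F2")
})

test_that("classical MDS recovers planted configurations", {
  set.seed(64)
  pts <- matrix(rnorm(8), 4, 2)
  D <- as.matrix(dist(pts))
  fit <- classical_mds(D, k = 2)
  expect_equal(as.matrix(dist(fit$points)), D, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(fit$total_variance_explained, 1, tolerance = 1e-8)

  # collinear points: first axis explains (essentially) everything
  line <- cbind(seq(0, 3, length.out = 5), 0)
  fitl <- classical_mds(as.matrix(dist(line)), k = 2)
  expect_gt(fitl$variance_explained[1], 0.999)

  expect_equal(suppressWarnings(classical_mds(matrix(0, 3, 3), k = 2)$points),
               matrix(0, 3, 2), ignore_attr = TRUE)
  D2 <- D; D2[1, 2] <- D2[1, 2] + 1
  expect_error(classical_mds(D2, 2), "symmetric")
})

test_that("evaluate_measure joins tables and reports the correlation", {
  dist_tab <- data.frame(target_speaker_id = sprintf("s%02d", 1:15),
                         mean_distance = seq(1, 8, length.out = 15))
  ratings <- data.frame(speaker_id = sprintf("s%02d", 1:15),
                        mean_rating = seq(7, 1, length.out = 15))
  out <- evaluate_measure(dist_tab, ratings)
  expect_equal(out$r, -1)
  expect_equal(out$n, 15)

  # with a second measure: regression plus Steiger comparison
  set.seed(65)
  tr <- data.frame(speaker_id = ratings$speaker_id,
                   distance = seq(0.1, 0.9, length.out = 15) + rnorm(15, 0, 0.05))
  out2 <- evaluate_measure(dist_tab,
                           transform(ratings,
                                     mean_rating = mean_rating + rnorm(15, 0, 0.2)),
                           transcription = tr)
  expect_s3_class(out2$regression$coefficients, "data.frame")
  expect_true(is.finite(out2$steiger$z))

  # machine-readable report
  p <- tempfile(fileext = ".json")
  evaluate_measure(dist_tab, ratings, report_path = p)
  rep <- jsonlite::read_json(p)
  expect_equal(rep$r, -1, tolerance = 1e-12)

  dup <- rbind(dist_tab, dist_tab[1, ])
  expect_error(evaluate_measure(dup, ratings), "duplicated")
  expect_error(evaluate_measure(dist_tab,
                                data.frame(speaker_id = "zz",
                                           mean_rating = 3)),
               "no speakers")
})
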