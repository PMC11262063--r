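# NIPALS PLS: fitting, prediction, cross-validation, bootstrap, LoD

test_that("PLS at full rank equals the least-squares pseudo-inverse", {
  set.seed(10)
  for (i in 1:50) {
    X <- matrix(rnorm(20 * 8), 20, 8)
    Y <- X %*% rnorm(8) + rnorm(20, sd = 0.2)
    fit <- fit_pls(X, Y, n_lv = 8)
    ols <- qr.solve(cbind(1, X), Y)
    expect_lt(max(abs(fit$coefficients - ols[-1, ])), 1e-8)
  }
})

test_that("exact linear responses are fitted exactly with one LV", {
  set.seed(11)
  t_score <- rnorm(30)
  X <- outer(t_score, rnorm(12))       # rank 1
  Y <- matrix(2 * t_score)
  fit <- fit_pls(X, Y, n_lv = 1)
  rmsec <- sqrt(mean((predict(fit, X) - Y)^2))
  expect_lt(rmsec, 1e-8 * diff(range(Y)))
  expect_error(fit_pls(X, Y, n_lv = 40), "exceeds")
})

test_that("PLS-2 on a single-column Y reproduces PLS-1", {
  set.seed(12)
  X <- matrix(rnorm(25 * 10), 25, 10)
  y <- X %*% rnorm(10) + rnorm(25, sd = 0.1)
  f1 <- fit_pls(X, y, n_lv = 4)
  f2 <- fit_pls(X, matrix(y, ncol = 1), n_lv = 4)
  expect_lt(max(abs(f1$coefficients - f2$coefficients)), 1e-10)
})

test_that("prediction is the stored affine map", {
  set.seed(13)
  X <- matrix(rnorm(20 * 6), 20, 6)
  Y <- cbind(X %*% rnorm(6), X %*% rnorm(6))
  fit <- fit_pls(X, Y, n_lv = 6)
  expect_equal(predict(fit, X), Y, tolerance = 1e-8, ignore_attr = TRUE)
  # the all-mean spectrum predicts the response centre
  expect_equal(drop(predict(fit, matrix(colMeans(X), 1))),
               colMeans(Y), tolerance = 1e-10, ignore_attr = TRUE)
  # affine in the input
  x1 <- X[1, , drop = FALSE]; x2 <- X[2, , drop = FALSE]; a <- 0.3
  expect_equal(predict(fit, a * x1 + (1 - a) * x2),
               a * predict(fit, x1) + (1 - a) * predict(fit, x2),
               tolerance = 1e-10)
  expect_error(predict(fit, X[, 1:3]), "channels")
})

test_that("metrics follow their definitions exactly", {
  known <- c(0.1, 0.2, 0.3, 0.4)
  m <- compute_metrics(known, c(0.1, 0.2, 0.3, 0.5), "test")
  expect_equal(m$rmse_ppm, 0.05)
  expect_equal(compute_metrics(known, known, "test")$r2, 1)
  expect_equal(compute_metrics(known, known, "cv")$rmse_ppm, 0)
  expect_equal(compute_metrics(known, rep(mean(known), 4), "test")$r2, 0)
  # Q2 and RMSE are consistent: Q2 = 1 - RMSE^2 * n / TSS
  set.seed(14)
  y <- rnorm(15); p <- y + rnorm(15, sd = 0.3)
  m2 <- compute_metrics(y, p, "cv")
  tss <- sum((y - mean(y))^2)
  expect_equal(m2$r2, 1 - m2$rmse_ppm^2 * 15 / tss, tolerance = 1e-12)
  expect_error(compute_metrics(rep(1, 4), rnorm(4), "test"), "variance")
})

test_that("leave-one-concentration-out double CV separates signal from noise", {
  lib <- small_library()
  levels <- c(0.1, 0.2, 0.4, 0.8, 1.6)
  s <- simulate_dilution_series(lib, "A", levels, noise = noiseless(),
                                replicates = 3, include_blank = FALSE)
  y <- s$concentrations$A
  cv <- double_cv_loco(s$spectra, matrix(y), factor(y),
                       candidate_lvs = 1:3)
  expect_gt(cv$metrics$r2, 0.999)
  expect_length(cv$per_fold_lv, 5L)    # one outer fold per level
  # permuted responses carry no information
  nm <- noise_model(0.002, 0, 0.001, seed = 5)
  s2 <- simulate_dilution_series(lib, "A", levels, noise = nm,
                                 replicates = 3, include_blank = FALSE)
  set.seed(21)
  q2_perm <- replicate(20, {
    yp <- sample(s2$concentrations$A)
    double_cv_loco(s2$spectra, matrix(yp), factor(yp),
                   candidate_lvs = 1:3)$metrics$r2
  })
  expect_lte(mean(q2_perm), 0.2)
  expect_error(double_cv_loco(s$spectra, matrix(y), factor(rep(1, 15)),
                              1:2), "levels")
})

test_that("bootstrap validation pools out-of-bag predictions deterministically", {
  set.seed(15)
  n <- 360
  X <- matrix(rnorm(n * 6), n, 6)
  Y <- matrix(X %*% rnorm(6))
  b1 <- bootstrap_validate(X, Y, n_lv = 3, n_resamples = 60, seed = 99)
  b2 <- bootstrap_validate(X, Y, n_lv = 3, n_resamples = 60, seed = 99)
  expect_identical(b1$metrics, b2$metrics)
  expect_identical(b1$per_sample, b2$per_sample)
  # noiseless: pooled Q2 ~ 1
  expect_gt(b1$metrics$r2, 0.999)
  # per-iteration out-of-bag fraction is (1 - 1/n)^n, so the in-bag
  # (unique-sample) fraction is the classic 0.632 within 2%
  expect_equal(b1$oob_fraction, (1 - 1 / n)^n, tolerance = 0.02)
  expect_equal(1 - b1$oob_fraction, 0.632, tolerance = 0.02)
})

test_that("capability-of-detection LoD follows the closed form", {
  # zero residuals: LoD 0
  known <- rep(c(0.1, 0.2, 0.4, 0.8, 1.6), each = 3)
  expect_equal(pls_lod(known, known)$value, 0, tolerance = 1e-10)
  # Monte-Carlo agreement with delta * (s/b) * sqrt(1 + 1/n + xbar^2/Sxx)
  sigma <- 0.05
  xbar <- mean(known); sxx <- sum((known - xbar)^2); n <- length(known)
  oracle <- 3.29 * sigma * sqrt(1 + 1 / n + xbar^2 / sxx)
  set.seed(16)
  lods <- replicate(200, pls_lod(known, known + rnorm(n, sd = sigma))$value)
  expect_equal(mean(lods), oracle, tolerance = 0.2)
  # halving the noise halves the LoD
  lods_half <- replicate(200,
    pls_lod(known, known + rnorm(n, sd = sigma / 2))$value)
  expect_equal(mean(lods_half) / mean(lods), 0.5, tolerance = 0.1)
  expect_error(pls_lod(known, -known + 0.01 * rnorm(n)), "slope")
  expect_error(pls_lod(rep(1:2, 3), rnorm(6)), "levels")
})

test_that("models survive a JSON round trip", {
  set.seed(17)
  X <- matrix(rnorm(30 * 8), 30, 8)
  Y <- cbind(a = X %*% rnorm(8), b = X %*% rnorm(8)) + rnorm(30, sd = 0.05)
  colnames(Y) <- c("a", "b")
  fit <- fit_pls(X, Y, n_lv = 4)
  path <- tempfile(fileext = ".json")
  save_pls_model(fit, path)
  back <- load_pls_model(path)
  expect_equal(predict(back, X), predict(fit, X), tolerance = 1e-12)
  expect_identical(back$analytes, fit$analytes)
  unlink(path)
})
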