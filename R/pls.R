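#' Fit a PLS regression model (NIPALS)
#'
#' Mean-centred NIPALS partial least squares with deflation. A single-column
#' `Y` gives PLS-1 (the inner loop converges in one pass); a multi-column
#' `Y` gives PLS-2 — both share the same core, and PLS-2 on a one-column
#' matrix reproduces PLS-1 exactly. With `n_lv` equal to the rank of a
#' full-rank `X`, the coefficients coincide with the ordinary least-squares
#' pseudo-inverse solution.
#'
#' @param X predictor matrix (`n x p`, preprocessed spectra).
#' @param Y response matrix or vector (`n x m` concentrations, ppm).
#' @param n_lv number of latent variables (1 <= n_lv <= min(n-1, p)).
#' @param tol inner-loop convergence tolerance on the score vector.
#' @param max_inner maximum inner iterations per latent variable.
#' @param keep_path keep the coefficient matrix after each latent variable
#'   (`coef_path`), used by the cross-validation routines.
#' @param strict_rank if FALSE, stop extracting latent variables quietly
#'   when the deflated `X` runs out of rank (the coefficient path is padded
#'   with the last valid solution) instead of raising an error; used by the
#'   cross-validation routines, where candidate LV counts can exceed the
#'   rank of a training fold.
#' @return A `pls_model`: `x_center`, `y_center`, `weights` (W), `loadings`
#'   (P), `y_loadings` (Q), `scores` (T), `coefficients` (`p x m`), `n_lv`,
#'   `analytes`, and optionally `coef_path`.
#' @export
fit_pls <- function(X, Y, n_lv, tol = 1e-10, max_inner = 200,
                    keep_path = FALSE, strict_rank = TRUE) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  n <- nrow(X); p <- ncol(X); m <- ncol(Y)
  if (nrow(Y) != n) stop_sq("X and Y row counts differ")
  if (n_lv < 1) stop_sq("n_lv must be >= 1")
  if (n_lv > min(n - 1L, p))
    stop_sq("n_lv = ", n_lv, " exceeds min(n_samples - 1, n_channels) = ",
            min(n - 1L, p))
  x_center <- colMeans(X)
  y_center <- colMeans(Y)
  Xc <- sweep(X, 2L, x_center)
  Yc <- sweep(Y, 2L, y_center)
  W <- matrix(0, p, n_lv); P <- matrix(0, p, n_lv)
  Q <- matrix(0, m, n_lv); TT <- matrix(0, n, n_lv)
  path <- if (keep_path) vector("list", n_lv)
  n_extracted <- 0L
  for (a in seq_len(n_lv)) {
    u <- Yc[, which.max(apply(Yc, 2L, stats::var)), drop = TRUE]
    t_old <- rep(Inf, n)
    exhausted <- FALSE
    for (it in seq_len(max_inner)) {
      w <- drop(crossprod(Xc, u))
      wn <- sqrt(sum(w^2))
      if (wn < 1e-14) {
        if (strict_rank) stop_sq("X is rank-deficient at latent variable ",
                                 a)
        exhausted <- TRUE; break
      }
      w <- w / wn
      t_sc <- drop(Xc %*% w)
      tt <- sum(t_sc^2)
      if (tt < 1e-14) {
        if (strict_rank) stop_sq("degenerate score at latent variable ", a)
        exhausted <- TRUE; break
      }
      q <- drop(crossprod(Yc, t_sc)) / tt
      if (m == 1L) break
      u <- drop(Yc %*% q) / sum(q^2)
      if (sqrt(sum((t_sc - t_old)^2)) < tol * sqrt(tt)) break
      t_old <- t_sc
    }
    if (exhausted) break
    p_load <- drop(crossprod(Xc, t_sc)) / tt
    Xc <- Xc - tcrossprod(t_sc, p_load)
    Yc <- Yc - tcrossprod(t_sc, q)
    W[, a] <- w; P[, a] <- p_load; Q[, a] <- q; TT[, a] <- t_sc
    n_extracted <- a
    if (keep_path) {
      Wa <- W[, seq_len(a), drop = FALSE]
      path[[a]] <- Wa %*% solve(crossprod(P[, seq_len(a), drop = FALSE],
                                          Wa),
                                t(Q[, seq_len(a), drop = FALSE]))
    }
  }
  if (n_extracted == 0L) stop_sq("no latent variable could be extracted")
  if (n_extracted < n_lv) {
    keep <- seq_len(n_extracted)
    W <- W[, keep, drop = FALSE]; P <- P[, keep, drop = FALSE]
    Q <- Q[, keep, drop = FALSE]; TT <- TT[, keep, drop = FALSE]
    if (keep_path)
      for (a in (n_extracted + 1L):n_lv) path[[a]] <- path[[n_extracted]]
  }
  B <- if (keep_path) path[[n_lv]] else
    W %*% solve(crossprod(P, W), t(Q))
  structure(list(x_center = x_center, y_center = y_center, weights = W,
                 loadings = P, y_loadings = Q, scores = TT,
                 coefficients = B, n_lv = n_lv,
                 analytes = colnames(Y) %||% paste0("Y", seq_len(m)),
                 coef_path = if (keep_path) path),
            class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat("pls_model:", length(x$x_center), "channels ->",
      length(x$analytes), "response(s) [",
      paste(x$analytes, collapse = ", "), "],", x$n_lv, "LVs\n")
  invisible(x)
}

#' Predict concentrations from a PLS model
#'
#' Linear map through the stored centres and coefficients. Predictions are
#' never clipped: negative concentrations are reported as such.
#'
#' @param object a `pls_model`.
#' @param newdata matrix of spectra (`n x p`) or a [spectra_set()].
#' @param n_lv predict with a reduced number of latent variables (requires
#'   `keep_path = TRUE` at fit time).
#' @param ... ignored.
#' @return Matrix of predicted concentrations (ppm), one column per
#'   response.
#' @export
predict.pls_model <- function(object, newdata, n_lv = NULL, ...) {
  if (inherits(newdata, "spectra_set")) newdata <- newdata$spectra
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$x_center))
    stop_sq("newdata has ", ncol(newdata), " channels; model was trained ",
            "on ", length(object$x_center))
  B <- object$coefficients
  if (!is.null(n_lv)) {
    if (is.null(object$coef_path))
      stop_sq("model was fitted without keep_path; cannot truncate LVs")
    B <- object$coef_path[[n_lv]]
  }
  out <- sweep(newdata, 2L, object$x_center) %*% B
  out <- sweep(out, 2L, object$y_center, `+`)
  colnames(out) <- object$analytes
  out
}

#' Goodness-of-prediction metrics
#'
#' `RMSE = sqrt(mean((known - predicted)^2))` in ppm and
#' `R2/Q2 = 1 - RSS/TSS` with TSS centred on the known values of the given
#' context; per-analyte columns for multi-response data. The identity
#' `Q2 = 1 - RMSE^2 * n / TSS` holds exactly.
#'
#' @param known,predicted matrices or vectors of equal shape (ppm).
#' @param context `"train"`, `"cv"` or `"test"` (label only; determines
#'   which metric name the value reports as).
#' @return Data frame with columns `analyte`, `context`, `n`, `r2`
#'   (R2 for train, Q2 otherwise), `rmse_ppm`.
#' @export
compute_metrics <- function(known, predicted,
                            context = c("train", "cv", "test")) {
  context <- match.arg(context)
  known <- as.matrix(known); predicted <- as.matrix(predicted)
  if (!all(dim(known) == dim(predicted))) stop_sq("shape mismatch")
  if (nrow(known) < 2) stop_sq("need at least 2 observations")
  out <- lapply(seq_len(ncol(known)), function(j) {
    y <- known[, j]; yhat <- predicted[, j]
    tss <- sum((y - mean(y))^2)
    if (tss == 0) stop_sq("zero variance in known values (analyte ",
                          colnames(known)[j] %||% j, ")")
    rss <- sum((y - yhat)^2)
    data.frame(analyte = colnames(known)[j] %||% paste0("Y", j),
               context = context, n = length(y), r2 = 1 - rss / tss,
               rmse_ppm = sqrt(rss / length(y)))
  })
  do.call(rbind, out)
}

#' Leave-one-concentration-out double cross-validation
#'
#' Nested CV for PLS complexity selection: the outer loop holds out all
#' replicates of one concentration level at a time; the inner loop repeats
#' leave-one-level-out on the remaining levels to pick the number of latent
#' variables (minimum pooled RMSECV, with a one-standard-error parsimony
#' tie-break toward fewer LVs). Outer held-out predictions are pooled into
#' Q2_cv and RMSECV. The reported `n_lv` is the inner selection run on all
#' levels.
#'
#' @param X,Y as [fit_pls()].
#' @param groups factor of concentration levels (replicates of a level share
#'   a group and always travel together); >= 3 distinct levels.
#' @param candidate_lvs integer vector of LV counts to consider.
#' @param fixed_lv skip selection and use this LV count everywhere.
#' @param one_se use the one-standard-error parsimony rule (default TRUE).
#' @return List: `n_lv` (selected), `metrics` (Q2_cv / RMSECV per analyte),
#'   `predictions` (pooled outer CV predictions, sample order), `per_fold_lv`.
#' @export
double_cv_loco <- function(X, Y, groups, candidate_lvs = 1:10,
                           fixed_lv = NULL, one_se = TRUE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  groups <- as.factor(groups)
  lev <- levels(droplevels(groups))
  if (length(lev) < 3L) stop_sq("need at least 3 distinct concentration ",
                                "levels for double cross-validation")
  if (any(table(groups) == length(groups)))
    stop_sq("a single level contains all samples")
  candidate_lvs <- sort(unique(as.integer(candidate_lvs)))
  select_lv <- function(idx) {
    # inner leave-one-level-out over the rows in idx
    g <- droplevels(groups[idx])
    kmax_global <- Inf
    fold_rmse <- matrix(NA_real_, nrow = nlevels(g),
                        ncol = length(candidate_lvs))
    for (fi in seq_len(nlevels(g))) {
      hold <- g == levels(g)[fi]
      tr <- idx[!hold]; te <- idx[hold]
      kmax <- min(length(tr) - 1L, ncol(X))
      lvs <- candidate_lvs[candidate_lvs <= kmax]
      fit <- fit_pls(X[tr, , drop = FALSE], Y[tr, , drop = FALSE],
                     n_lv = max(lvs), keep_path = TRUE,
                     strict_rank = FALSE)
      for (li in seq_along(candidate_lvs)) {
        if (candidate_lvs[li] > kmax) next
        pred <- predict(fit, X[te, , drop = FALSE],
                        n_lv = candidate_lvs[li])
        fold_rmse[fi, li] <- sqrt(mean((Y[te, , drop = FALSE] - pred)^2))
      }
    }
    rmsecv <- colMeans(fold_rmse)
    best <- which.min(rmsecv)
    if (one_se) {
      se <- stats::sd(fold_rmse[, best]) / sqrt(nrow(fold_rmse))
      best <- min(which(rmsecv <= rmsecv[best] + se))
    }
    candidate_lvs[best]
  }
  n <- nrow(X)
  preds <- matrix(NA_real_, n, ncol(Y))
  per_fold_lv <- integer(length(lev))
  for (oi in seq_along(lev)) {
    test <- which(groups == lev[oi])
    train <- which(groups != lev[oi])
    lv_sel <- if (!is.null(fixed_lv)) fixed_lv else select_lv(train)
    lv_sel <- min(lv_sel, length(train) - 1L, ncol(X))
    per_fold_lv[oi] <- lv_sel
    fit <- fit_pls(X[train, , drop = FALSE], Y[train, , drop = FALSE],
                   n_lv = lv_sel, strict_rank = FALSE)
    preds[test, ] <- predict(fit, X[test, , drop = FALSE])
  }
  colnames(preds) <- colnames(Y) %||% paste0("Y", seq_len(ncol(Y)))
  n_lv_final <- if (!is.null(fixed_lv)) fixed_lv else
    select_lv(seq_len(n))
  list(n_lv = n_lv_final, per_fold_lv = per_fold_lv,
       metrics = compute_metrics(Y, preds, "cv"), predictions = preds)
}

#' Bootstrap out-of-bag validation of a PLS model
#'
#' Each resample draws `n` rows with replacement as the training set, fits
#' at the fixed LV count and predicts the out-of-bag rows. Q2_test and
#' RMSEP are pooled over every (sample, iteration) out-of-bag prediction;
#' per-sample OOB means and SDs drive prediction plots. Deterministic under
#' the seed; iterations with an empty OOB set are skipped and counted.
#'
#' @param X,Y as [fit_pls()].
#' @param n_lv latent variables (fixed).
#' @param n_resamples bootstrap iterations (default 1000).
#' @param seed RNG seed.
#' @return A `bootstrap_result`: `metrics` (pooled Q2_test / RMSEP per
#'   analyte), `per_sample` (known, OOB mean/SD, count), `n_resamples`,
#'   `n_skipped`, `oob_fraction`, `seed`.
#' @export
bootstrap_validate <- function(X, Y, n_lv, n_resamples = 1000,
                               seed = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (n_resamples < 1) stop_sq("n_resamples must be >= 1")
  n <- nrow(X); m <- ncol(Y)
  s_pred <- matrix(0, n, m); s_pred2 <- matrix(0, n, m)
  count <- integer(n)
  rss <- numeric(m); n_oob_total <- 0L; n_skipped <- 0L
  with_seed(seed, {
    for (b in seq_len(n_resamples)) {
      idx <- sample.int(n, n, replace = TRUE)
      oob <- setdiff(seq_len(n), idx)
      if (!length(oob)) { n_skipped <- n_skipped + 1L; next }
      fit <- fit_pls(X[idx, , drop = FALSE], Y[idx, , drop = FALSE],
                     n_lv = n_lv)
      pred <- predict(fit, X[oob, , drop = FALSE])
      err <- Y[oob, , drop = FALSE] - pred
      rss <- rss + colSums(err^2)
      s_pred[oob, ] <- s_pred[oob, ] + pred
      s_pred2[oob, ] <- s_pred2[oob, ] + pred^2
      count[oob] <- count[oob] + 1L
      n_oob_total <- n_oob_total + length(oob)
    }
  })
  if (any(count == 0))
    warning(sum(count == 0), " sample(s) never out-of-bag; increase ",
            "n_resamples")
  ybar <- colSums(Y * count) / sum(count)
  tss <- colSums(sweep(Y, 2L, ybar)^2 * count)
  q2 <- 1 - rss / tss
  rmsep <- sqrt(rss / n_oob_total)
  analytes <- colnames(Y) %||% paste0("Y", seq_len(m))
  metrics <- data.frame(analyte = analytes, context = "test",
                        n = n_oob_total, r2 = q2, rmse_ppm = rmsep)
  mean_pred <- s_pred / pmax(count, 1L)
  sd_pred <- sqrt(pmax(s_pred2 / pmax(count, 1L) - mean_pred^2, 0) *
                    ifelse(count > 1L, count / (count - 1L), NA_real_))
  per_sample <- data.frame(sample = seq_len(n), n_oob = count)
  for (j in seq_len(m)) {
    per_sample[[paste0("known_", analytes[j])]] <- Y[, j]
    per_sample[[paste0("pred_mean_", analytes[j])]] <- mean_pred[, j]
    per_sample[[paste0("pred_sd_", analytes[j])]] <- sd_pred[, j]
  }
  structure(list(metrics = metrics, per_sample = per_sample,
                 n_resamples = n_resamples, n_skipped = n_skipped,
                 oob_fraction = n_oob_total /
                   (n * (n_resamples - n_skipped)),
                 seed = seed),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat("bootstrap_result:", x$n_resamples, "resamples (",
      x$n_skipped, "skipped ), mean OOB fraction",
      sprintf("%.3f", x$oob_fraction), "\n")
  print(x$metrics)
  invisible(x)
}

#' Multivariate (pseudo-univariate) limit of detection
#'
#' Capability-of-detection estimate from the regression of PLS-predicted on
#' known concentrations: with `predicted = a + b * known`, residual SD `s`,
#' `n` calibration points, mean `xbar` and spread `Sxx`,
#' `LoD = delta * (s/b) * sqrt(1 + 1/n + xbar^2/Sxx)`. `delta` at
#' `alpha = beta = 0.05` is 3.29 under the normal approximation (default);
#' `method = "noncentral_t"` uses `qt` quantiles at `n - 2` degrees of
#' freedom instead.
#'
#' @param known known concentrations (ppm).
#' @param predicted model-predicted concentrations (ppm), typically
#'   cross-validated.
#' @param alpha,beta false-positive and false-negative rates.
#' @param method `"normal"` or `"noncentral_t"` for delta.
#' @param analyte optional label.
#' @return An `lod_estimate` with method `"pls_ortiz"`.
#' @export
pls_lod <- function(known, predicted, alpha = 0.05, beta = 0.05,
                    method = c("normal", "noncentral_t"),
                    analyte = NA_character_) {
  method <- match.arg(method)
  if (length(unique(known)) < 5L)
    stop_sq("need at least 5 calibration levels")
  fit <- stats::lm(predicted ~ known)
  b <- unname(stats::coef(fit)[2])
  if (!is.finite(b) || b <= 0)
    stop_sq("non-positive predicted-vs-known slope")
  n <- length(known)
  s <- sqrt(sum(stats::residuals(fit)^2) / (n - 2L))
  xbar <- mean(known)
  sxx <- sum((known - xbar)^2)
  delta <- switch(method,
    normal = stats::qnorm(1 - alpha) + stats::qnorm(1 - beta),
    noncentral_t = stats::qt(1 - alpha, df = n - 2L) +
      stats::qt(1 - beta, df = n - 2L))
  lod <- delta * (s / b) * sqrt(1 + 1 / n + xbar^2 / sxx)
  new_lod(lod, "pls_ortiz", analyte,
          details = list(slope = b, resid_sd = s, n = n, delta = delta,
                         method = method))
}

#' Save / load a PLS model as JSON
#'
#' Documented plain-text container holding centres, coefficients, loadings
#' and metadata; round-trips through [jsonlite].
#'
#' @param model a `pls_model`.
#' @param path file path.
#' @return `save_pls_model` returns `path` invisibly; `load_pls_model`
#'   returns the `pls_model`.
#' @export
save_pls_model <- function(model, path) {
  stopifnot(inherits(model, "pls_model"))
  obj <- list(format = "sersquant_pls_model", version = 1L,
              n_lv = model$n_lv, analytes = model$analytes,
              x_center = model$x_center, y_center = model$y_center,
              coefficients = model$coefficients,
              weights = model$weights, loadings = model$loadings,
              y_loadings = model$y_loadings)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_pls_model
#' @export
load_pls_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "sersquant_pls_model"))
    stop_sq("not a sersquant PLS model file")
  structure(list(x_center = as.numeric(obj$x_center),
                 y_center = as.numeric(obj$y_center),
                 weights = as.matrix(obj$weights),
                 loadings = as.matrix(obj$loadings),
                 y_loadings = matrix(as.matrix(obj$y_loadings),
                                     ncol = obj$n_lv),
                 scores = NULL,
                 coefficients = matrix(as.matrix(obj$coefficients),
                                       nrow = length(obj$x_center)),
                 n_lv = obj$n_lv, analytes = obj$analytes,
                 coef_path = NULL),
            class = "pls_model")
}
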