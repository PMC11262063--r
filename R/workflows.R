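#' Pipeline run configuration
#'
#' Collects every tunable of the four workflows in one serialisable list; a
#' run is reproducible from the config alone (all randomness flows from the
#' single root `seed`, split deterministically per stage). The defaults are
#' the study conditions: four thiols on a 200-2000 cm^-1 axis, 120 LHS
#' mixtures in 0.05-1 ppm with 3 replicates, a two-fold dilution series
#' 2 -> 0.016 ppm for the LoD study, fixed PLS-1 LVs 6/7/8/6 and PLS-2
#' LV 11, 1000 bootstrap resamples, and a 15-sample blind test with a 5%
#' batch gain.
#'
#' @param seed root RNG seed (integer).
#' @param noise a [noise_model()] for the multiplex, blind-test and MCR
#'   sets (its seed field is ignored; stage seeds are derived from `seed`).
#' @param lod_noise a [noise_model()] for the dilution-series LoD study,
#'   which emulates the longer, optimised acquisition of a detection-limit
#'   measurement (lower channel noise and drift than routine multiplex
#'   acquisition).
#' @param replicates replicate spectra per design row.
#' @param n_mixtures LHS training mixtures.
#' @param mixture_range (min, max) ppm per thiol in the multiplex design.
#' @param pls1_lvs named integer vector of PLS-1 latent variables per
#'   analyte; `NULL` selects automatically by grouped cross-validation.
#' @param pls2_lv PLS-2 latent variables; `NULL` for automatic selection.
#' @param candidate_lvs LV counts considered by automatic selection.
#' @param n_bootstrap bootstrap resamples for validation.
#' @param cv_folds folds of the grouped CV used for multiplex Q2_cv.
#' @param lod_levels dilution-series concentrations, ppm.
#' @param lod_k SD multiplier of the univariate LoD.
#' @param peak_half_width peak-height window half-width, cm^-1.
#' @param n_blind blind-test samples.
#' @param batch_gain blind-test batch gain fraction.
#' @param mcr_tol,mcr_max_iter MCR-ALS convergence settings.
#' @return A `sersquant_config` list.
#' @export
sersquant_config <- function(seed = 1L,
                             noise = noise_model(),
                             lod_noise = noise_model(
                               additive_sd = 0.002,
                               multiplicative_sd = 0.02,
                               baseline_amplitude = 0.001),
                             replicates = 3L,
                             n_mixtures = 120L,
                             mixture_range = c(0.05, 1),
                             pls1_lvs = c(`3M3MH` = 6L, `2M3MB` = 7L,
                                          `3MH` = 8L, `2M3MP` = 6L),
                             pls2_lv = 11L,
                             candidate_lvs = 1:12,
                             n_bootstrap = 1000L,
                             cv_folds = 10L,
                             lod_levels = dilution_levels(),
                             lod_k = 3,
                             peak_half_width = 10,
                             n_blind = 15L,
                             batch_gain = 0.05,
                             mcr_tol = 1e-6,
                             mcr_max_iter = 100L) {
  structure(list(seed = as.integer(seed), noise = noise,
                 lod_noise = lod_noise,
                 replicates = replicates, n_mixtures = n_mixtures,
                 mixture_range = mixture_range, pls1_lvs = pls1_lvs,
                 pls2_lv = pls2_lv, candidate_lvs = candidate_lvs,
                 n_bootstrap = n_bootstrap, cv_folds = cv_folds,
                 lod_levels = lod_levels, lod_k = lod_k,
                 peak_half_width = peak_half_width, n_blind = n_blind,
                 batch_gain = batch_gain, mcr_tol = mcr_tol,
                 mcr_max_iter = mcr_max_iter),
            class = "sersquant_config")
}

config_noise <- function(config, stage, which = c("noise", "lod_noise")) {
  nm <- config[[match.arg(which)]]
  noise_model(nm$additive_sd, nm$multiplicative_sd, nm$baseline_amplitude,
              nm$baseline_smoothness, nm$background_amplitude,
              seed = stage_seed(config$seed, stage))
}

write_report_tables <- function(report, outdir) {
  if (is.null(outdir)) return(invisible(report))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report$config, file.path(outdir, "config.json"),
                       digits = NA, auto_unbox = TRUE, force = TRUE)
  for (nm in names(report$tables))
    utils::write.csv(report$tables[[nm]],
                     file.path(outdir, paste0(nm, ".csv")),
                     row.names = FALSE)
  invisible(report)
}

# grouped k-fold CV of PLS at fixed or candidate LVs; groups travel together
group_kfold_cv <- function(X, Y, groups, candidate_lvs, n_folds, seed,
                           fixed_lv = NULL) {
  groups <- as.factor(groups)
  lev <- levels(groups)
  fold_of <- with_seed(seed, sample(rep_len(seq_len(n_folds),
                                            length(lev))))
  names(fold_of) <- lev
  kmax <- max(candidate_lvs)
  preds <- array(NA_real_, c(nrow(as.matrix(Y)), ncol(as.matrix(Y)),
                             length(candidate_lvs)))
  Y <- as.matrix(Y)
  for (f in seq_len(n_folds)) {
    test <- which(fold_of[as.character(groups)] == f)
    if (!length(test)) next
    train <- setdiff(seq_len(nrow(X)), test)
    fit <- fit_pls(X[train, , drop = FALSE], Y[train, , drop = FALSE],
                   n_lv = min(kmax, length(train) - 1L), keep_path = TRUE,
                   strict_rank = FALSE)
    for (li in seq_along(candidate_lvs)) {
      lv <- candidate_lvs[li]
      if (lv > fit$n_lv) next
      preds[test, , li] <- predict(fit, X[test, , drop = FALSE],
                                   n_lv = lv)
    }
  }
  rmsecv <- vapply(seq_along(candidate_lvs), function(li)
    sqrt(mean((Y - preds[, , li])^2)), numeric(1))
  sel <- if (!is.null(fixed_lv)) match(fixed_lv, candidate_lvs) else
    which.min(rmsecv)
  if (is.na(sel)) stop_sq("fixed LV not among candidate_lvs")
  pred_sel <- matrix(preds[, , sel], ncol = ncol(Y),
                     dimnames = list(NULL, colnames(Y)))
  list(n_lv = candidate_lvs[sel], rmsecv_by_lv = rmsecv,
       predictions = pred_sel,
       metrics = compute_metrics(Y, pred_sel, "cv"))
}

#' Multiplex training study: PLS-1 and PLS-2 on the 120-mixture set
#'
#' Simulates the LHS multiplex set (or uses `set`), applies the PLS chain,
#' fits four PLS-1 models and one PLS-2 model at the configured (or
#' CV-selected) latent variables, estimates Q2_cv/RMSECV by grouped k-fold
#' cross-validation over mixtures, and validates by bootstrap out-of-bag
#' resampling. The metrics table mirrors the standard calibration report:
#' one row per analyte and model family with R2, Q2_cv, Q2_test, RMSEC,
#' RMSECV and RMSEP (ppm).
#'
#' @param config a [sersquant_config()].
#' @param library a [component_library()] (default four-thiol library).
#' @param set optional pre-simulated training [spectra_set()].
#' @param outdir optional directory for CSV/JSON artifacts.
#' @return A run report: `tables$metrics`, `tables$design`,
#'   `tables$oob_predictions`, fitted `models`, the processed `set`, and
#'   the config echo.
#' @export
run_multiplex_study <- function(config = sersquant_config(),
                                library = default_thiol_library(),
                                set = NULL, outdir = NULL) {
  analytes <- library$components
  if (is.null(set)) {
    design <- lhs_design(config$n_mixtures, analytes,
                         config$mixture_range,
                         seed = stage_seed(config$seed, "multiplex_design"))
    set <- simulate_mixture_set(library, design,
                                config_noise(config, "multiplex_spectra"),
                                replicates = config$replicates)
  }
  proc <- apply_chain(set, "pls_chain")
  X <- proc$spectra
  Y <- as.matrix(proc$concentrations)
  mixture_id <- sub("_r\\d+$", "", proc$metadata$sample_id)
  cv_seed <- stage_seed(config$seed, "multiplex_cv")
  boot_seed <- stage_seed(config$seed, "multiplex_boot")

  fit_family <- function(Ysub, fixed_lv, label) {
    cv <- group_kfold_cv(X, Ysub, mixture_id, config$candidate_lvs,
                         config$cv_folds, cv_seed, fixed_lv = fixed_lv)
    model <- fit_pls(X, Ysub, n_lv = cv$n_lv)
    train <- compute_metrics(Ysub, predict(model, X), "train")
    boot <- bootstrap_validate(X, Ysub, n_lv = cv$n_lv,
                               n_resamples = config$n_bootstrap,
                               seed = boot_seed)
    metrics <- data.frame(model = label, analyte = train$analyte,
                          n_lv = cv$n_lv, R2 = train$r2,
                          Q2_cv = cv$metrics$r2, Q2_test = boot$metrics$r2,
                          RMSEC_ppm = train$rmse_ppm,
                          RMSECV_ppm = cv$metrics$rmse_ppm,
                          RMSEP_ppm = boot$metrics$rmse_ppm)
    list(model = model, metrics = metrics, boot = boot)
  }

  pls1 <- lapply(analytes, function(an)
    fit_family(Y[, an, drop = FALSE],
               if (!is.null(config$pls1_lvs)) config$pls1_lvs[[an]],
               "PLS-1"))
  names(pls1) <- analytes
  pls2 <- fit_family(Y, config$pls2_lv, "PLS-2")

  metrics <- rbind(do.call(rbind, lapply(pls1, `[[`, "metrics")),
                   pls2$metrics)
  rownames(metrics) <- NULL
  oob <- cbind(data.frame(model = "PLS-2"), pls2$boot$per_sample)
  report <- list(workflow = "multiplex_study", seed = config$seed,
                 config = unclass(config),
                 models = list(pls1 = lapply(pls1, `[[`, "model"),
                               pls2 = pls2$model),
                 bootstrap = c(lapply(pls1, `[[`, "boot"),
                               list(pls2 = pls2$boot)),
                 set = proc,
                 tables = list(metrics = metrics,
                               design = as.data.frame(Y),
                               oob_predictions = oob))
  write_report_tables(report, outdir)
}

#' Blind-test study: frozen models on a new batch
#'
#' Generates a fresh random-design set (default 15 samples) measured as a
#' second batch with a smooth multiplicative batch gain, preprocesses it
#' with the PLS chain and predicts with the *frozen* training models at the
#' training latent variables. Reports RMSEP per analyte and model family
#' next to the same-batch (training bootstrap) RMSEP.
#'
#' @param config a [sersquant_config()].
#' @param training a [run_multiplex_study()] report; run if omitted.
#' @param library the [component_library()] used for training.
#' @param outdir optional artifact directory.
#' @return A run report with `tables$blind_metrics` and
#'   `tables$blind_predictions`.
#' @export
run_blind_test <- function(config = sersquant_config(), training = NULL,
                           library = default_thiol_library(),
                           outdir = NULL) {
  if (is.null(training))
    training <- run_multiplex_study(config, library)
  analytes <- library$components
  design <- random_design(config$n_blind, analytes, config$mixture_range,
                          seed = stage_seed(config$seed, "blind_design"))
  blind <- simulate_mixture_set(library, design,
                                config_noise(config, "blind_spectra"),
                                replicates = config$replicates,
                                batch = "batch2")
  blind <- apply_batch_effect(blind, config$batch_gain,
                              seed = stage_seed(config$seed, "blind_batch"))
  proc <- apply_chain(blind, "pls_chain")
  Y <- as.matrix(proc$concentrations)
  same_batch <- training$tables$metrics

  rows <- list(); preds_out <- list()
  for (an in analytes) {
    pred <- predict(training$models$pls1[[an]], proc)
    met <- compute_metrics(Y[, an, drop = FALSE], pred, "test")
    rows[[paste0("pls1_", an)]] <-
      data.frame(model = "PLS-1", analyte = an, RMSEP_ppm = met$rmse_ppm,
                 Q2_test = met$r2,
                 RMSEP_train_era_ppm = same_batch$RMSEP_ppm[
                   same_batch$model == "PLS-1" & same_batch$analyte == an])
    preds_out[[paste0("pls1_", an)]] <-
      data.frame(model = "PLS-1", analyte = an,
                 sample_id = proc$metadata$sample_id,
                 known_ppm = Y[, an], predicted_ppm = drop(pred))
  }
  pred2 <- predict(training$models$pls2, proc)
  met2 <- compute_metrics(Y, pred2, "test")
  for (an in analytes) {
    rows[[paste0("pls2_", an)]] <-
      data.frame(model = "PLS-2", analyte = an,
                 RMSEP_ppm = met2$rmse_ppm[met2$analyte == an],
                 Q2_test = met2$r2[met2$analyte == an],
                 RMSEP_train_era_ppm = same_batch$RMSEP_ppm[
                   same_batch$model == "PLS-2" & same_batch$analyte == an])
    preds_out[[paste0("pls2_", an)]] <-
      data.frame(model = "PLS-2", analyte = an,
                 sample_id = proc$metadata$sample_id,
                 known_ppm = Y[, an], predicted_ppm = pred2[, an])
  }
  metrics <- do.call(rbind, rows); rownames(metrics) <- NULL
  report <- list(workflow = "blind_test", seed = config$seed,
                 config = unclass(config), set = proc,
                 tables = list(blind_metrics = metrics,
                               blind_predictions = do.call(rbind,
                                                           preds_out)))
  write_report_tables(report, outdir)
}

#' Limit-of-detection study per analyte
#'
#' For each analyte: simulate a dilution series (blanks included), run the
#' PCA chain and select candidate peaks from the PC-1 loading, build
#' peak-height calibrations over the lowest five levels and estimate the
#' univariate LoD (`k*SD/m`) plus the blank-3SD criterion for each peak;
#' then, on the five lowest levels, fit PLS with leave-one-concentration-out
#' double cross-validation and estimate the multivariate
#' (capability-of-detection) LoD from the CV predictions.
#'
#' @param config a [sersquant_config()].
#' @param library a [component_library()].
#' @param analytes analytes to study (default: all in library).
#' @param outdir optional artifact directory.
#' @return A run report: `tables$univariate` (one row per selected peak:
#'   analyte, wavenumber, R2, LoD ppm, blank-criterion LoD) and
#'   `tables$pls` (one row per analyte: LoD ppm, Q2_cv, RMSECV ppm, n_lv).
#' @export
run_lod_study <- function(config = sersquant_config(),
                          library = default_thiol_library(),
                          analytes = library$components, outdir = NULL) {
  uni_rows <- list(); pls_rows <- list()
  for (an in analytes) {
    noise <- config_noise(config, paste0("lod_", an), "lod_noise")
    series <- simulate_dilution_series(library, an,
                                       concentrations = config$lod_levels,
                                       noise = noise,
                                       replicates = config$replicates)
    conc <- series$concentrations[[an]]
    nonblank <- series[which(conc > 0)]
    cnb <- nonblank$concentrations[[an]]

    pca <- fit_pca(apply_chain(nonblank, "pca_chain"),
                   n_components = min(5L, nrow(nonblank$spectra) - 1L))
    peaks <- select_peaks_from_loadings(pca, component = 1L,
                                        max_peaks = 3L)
    for (i in seq_len(nrow(peaks))) {
      wn <- peaks$wavenumber[i]
      h <- peak_heights(nonblank, wn, config$peak_half_width)
      curve <- fit_calibration(cnb, h)
      if (!is.finite(curve$m) || curve$m <= 0) {
        # a loading extremum with no concentration sensitivity at low
        # levels; reported but not usable for a k*SD/m LoD
        uni_rows[[paste(an, wn)]] <-
          data.frame(analyte = an, wavenumber_cm1 = wn, R2 = curve$r2,
                     LoD_ppm = NA_real_, LoD_blank_ppm = NA_real_)
        next
      }
      lod <- lod_from_calibration(curve, k = config$lod_k, analyte = an)
      blank <- lod_blank_criterion(series, wn, config$peak_half_width,
                                   k = config$lod_k)
      uni_rows[[paste(an, wn)]] <-
        data.frame(analyte = an, wavenumber_cm1 = wn, R2 = curve$r2,
                   LoD_ppm = lod$value, LoD_blank_ppm = blank$value)
    }

    # PLS on the five lowest levels, as the univariate calibration uses
    lv5 <- sort(unique(cnb))[1:5]
    sub <- nonblank[which(cnb %in% lv5)]
    proc <- apply_chain(sub, "pls_chain")
    ysub <- proc$concentrations[[an]]
    cv <- double_cv_loco(proc$spectra, matrix(ysub, ncol = 1L),
                         groups = factor(ysub),
                         candidate_lvs = 1:6)
    lod_pls <- pls_lod(ysub, drop(cv$predictions), analyte = an)
    pls_rows[[an]] <- data.frame(analyte = an, LoD_ppm = lod_pls$value,
                                 Q2_cv = cv$metrics$r2,
                                 RMSECV_ppm = cv$metrics$rmse_ppm,
                                 n_lv = cv$n_lv)
  }
  univariate <- do.call(rbind, uni_rows); rownames(univariate) <- NULL
  pls_tab <- do.call(rbind, pls_rows); rownames(pls_tab) <- NULL
  report <- list(workflow = "lod_study", seed = config$seed,
                 config = unclass(config),
                 tables = list(univariate = univariate, pls = pls_tab))
  write_report_tables(report, outdir)
}

#' MCR-ALS study: raw versus derivative domain
#'
#' Runs MCR-ALS on the multiplex set in the two preprocessing modes — raw
#' (SNV only) and derivative (SNV + Savitzky-Golay first derivative) —
#' initialised from the identically processed pure spectra, assigns
#' components to analytes by permutation-matched spectral correlation, and
#' regresses each concentration profile against the known concentrations.
#'
#' @param config a [sersquant_config()].
#' @param library a [component_library()].
#' @param set optional pre-simulated multiplex [spectra_set()].
#' @param outdir optional artifact directory.
#' @return A run report: `tables$mcr_comparison` (mode x component:
#'   matched analyte, spectral correlation, profile-vs-known R2),
#'   `tables$lof_trace`, and the `mcr_result` objects per mode.
#' @export
run_mcr_study <- function(config = sersquant_config(),
                          library = default_thiol_library(), set = NULL,
                          outdir = NULL) {
  if (is.null(set)) {
    design <- lhs_design(config$n_mixtures, library$components,
                         config$mixture_range,
                         seed = stage_seed(config$seed, "mcr_design"))
    set <- simulate_mixture_set(library, design,
                                config_noise(config, "mcr_spectra"),
                                replicates = config$replicates)
  }
  known <- as.matrix(set$concentrations)
  chains <- list(
    derivative = preprocessing_chain("mcr_chain"),
    raw = preprocessing_chain("custom", list(list(op = "snv"))))
  rows <- list(); traces <- list(); fits <- list()
  for (mode in names(chains)) {
    chain <- chains[[mode]]
    proc <- apply_chain(set, chain)
    S_init <- initialize_from_pure(library, chain,
                                   wavenumber = set$wavenumber)
    fit <- fit_mcr_als(proc$spectra, S_init, nonneg_C = TRUE,
                       nonneg_S = FALSE, tol = config$mcr_tol,
                       max_iter = config$mcr_max_iter)
    assignment <- assign_components(fit$S, S_init)
    # undo the per-spectrum SNV scaling before regressing on known
    # concentrations: SNV divides row i by its sd, so the recovered
    # C[i, ] carries a 1/sd_i distortion that is not concentration
    snv_scale <- apply(set$spectra, 1L, stats::sd)
    C_descaled <- fit$C * snv_scale
    reg <- regress_profiles(C_descaled, known, assignment)
    rows[[mode]] <- data.frame(mode = mode,
                               component = assignment$component,
                               analyte = assignment$analyte,
                               spectral_correlation =
                                 assignment$correlation,
                               profile_r2 = reg$r2)
    traces[[mode]] <- data.frame(mode = mode,
                                 iteration = seq_along(fit$lof) - 1L,
                                 lof_percent = fit$lof)
    fits[[mode]] <- fit
  }
  comparison <- do.call(rbind, rows); rownames(comparison) <- NULL
  report <- list(workflow = "mcr_study", seed = config$seed,
                 config = unclass(config), fits = fits,
                 tables = list(mcr_comparison = comparison,
                               lof_trace = do.call(rbind, traces)))
  write_report_tables(report, outdir)
}
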