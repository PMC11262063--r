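# CSV I/O, configuration and the four end-to-end workflows (reduced scale)

test_that("spectra CSV round-trips losslessly with its companion table", {
  lib <- small_library()
  d <- lhs_design(4, c("A", "B"), c(0.1, 1), seed = 2)
  s <- simulate_mixture_set(lib, d, noise_model(seed = 3), replicates = 2)
  path <- tempfile(fileext = ".csv")
  write_spectra_csv(s, path)
  back <- read_spectra_csv(path)
  expect_equal(back$spectra, s$spectra, tolerance = 1e-12)
  expect_equal(back$wavenumber, s$wavenumber)
  expect_equal(as.matrix(back$concentrations),
               as.matrix(s$concentrations), tolerance = 1e-12)
  expect_equal(back$metadata$replicate, s$metadata$replicate)
  unlink(c(path, sub("\\.csv$", "_conc.csv", path)))
})

test_that("descending axes are re-sorted and missing cells rejected", {
  wn <- seq(400, 420, by = 2)
  df <- data.frame(wavenumber_cm1 = rev(wn),
                   S1 = rev(sin(wn)), S2 = rev(cos(wn)))
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  expect_warning(back <- read_spectra_csv(path), "descending")
  expect_equal(back$wavenumber, wn)
  expect_equal(back$spectra["S1", ], sin(wn), ignore_attr = TRUE)
  df$S2[3] <- NA
  write.csv(df, path, row.names = FALSE)
  expect_error(suppressWarnings(read_spectra_csv(path)), "S2")
  unlink(path)
})

test_that("the multiplex study emits the full metrics frame and models", {
  cfg <- sersquant_config(seed = 5, n_mixtures = 16, replicates = 2,
                          n_bootstrap = 8, cv_folds = 4,
                          pls1_lvs = c(`3M3MH` = 4L, `2M3MB` = 4L,
                                       `3MH` = 4L, `2M3MP` = 4L),
                          pls2_lv = 6L, candidate_lvs = 1:6)
  rep <- suppressWarnings(run_multiplex_study(cfg))  # tiny bootstrap: OOB-coverage flag expected
  m <- rep$tables$metrics
  expect_equal(nrow(m), 8L)                       # 4 analytes x 2 families
  expect_setequal(unique(m$model), c("PLS-1", "PLS-2"))
  expect_true(all(c("R2", "Q2_cv", "Q2_test", "RMSEC_ppm", "RMSECV_ppm",
                    "RMSEP_ppm") %in% names(m)))
  expect_all_finite(m$RMSEP_ppm)
  expect_length(rep$models$pls1, 4L)
  expect_s3_class(rep$models$pls2, "pls_model")
})

test_that("workflows write their artifact tables and config echo", {
  outdir <- tempfile("run")
  cfg <- sersquant_config(seed = 5, n_mixtures = 12, replicates = 1,
                          n_bootstrap = 5, cv_folds = 3,
                          pls1_lvs = c(`3M3MH` = 3L, `2M3MB` = 3L,
                                       `3MH` = 3L, `2M3MP` = 3L),
                          pls2_lv = 4L, candidate_lvs = 1:4)
  suppressWarnings(run_multiplex_study(cfg, outdir = outdir))
  expect_true(file.exists(file.path(outdir, "metrics.csv")))
  expect_true(file.exists(file.path(outdir, "oob_predictions.csv")))
  expect_true(file.exists(file.path(outdir, "config.json")))
  cfg_back <- jsonlite::read_json(file.path(outdir, "config.json"))
  expect_equal(cfg_back$seed, 5L)
  unlink(outdir, recursive = TRUE)
})

test_that("the LoD study reports one PLS row per analyte and peaks per band", {
  cfg <- sersquant_config(seed = 8)
  rep <- run_lod_study(cfg, analytes = c("3M3MH", "3MH"))
  uni <- rep$tables$univariate
  pls <- rep$tables$pls
  expect_equal(nrow(pls), 2L)                     # exactly one row per analyte
  expect_true(all(table(uni$analyte) >= 1))
  expect_true(all(uni$LoD_ppm > 0, na.rm = TRUE))
  expect_all_finite(pls$LoD_ppm)
  expect_true(all(pls$Q2_cv <= 1))
})

test_that("the blind test reports both model families for every analyte", {
  cfg <- sersquant_config(seed = 5, n_mixtures = 16, replicates = 2,
                          n_bootstrap = 8, cv_folds = 4,
                          pls1_lvs = c(`3M3MH` = 4L, `2M3MB` = 4L,
                                       `3MH` = 4L, `2M3MP` = 4L),
                          pls2_lv = 6L, n_blind = 6L)
  tr <- suppressWarnings(run_multiplex_study(cfg))
  bl <- run_blind_test(cfg, training = tr)
  m <- bl$tables$blind_metrics
  expect_equal(nrow(m), 8L)
  expect_all_finite(m$RMSEP_ppm)
  expect_equal(nrow(bl$tables$blind_predictions), 8L * 6L * 2L)
})

test_that("the MCR study compares modes and records the LOF trace", {
  cfg <- sersquant_config(seed = 5, n_mixtures = 20, replicates = 1)
  rep <- run_mcr_study(cfg)
  comp <- rep$tables$mcr_comparison
  expect_setequal(unique(comp$mode), c("derivative", "raw"))
  expect_equal(nrow(comp), 8L)
  trace <- rep$tables$lof_trace
  expect_true(all(c("derivative", "raw") %in% trace$mode))
  for (mode in c("derivative", "raw")) {
    lof <- trace$lof_percent[trace$mode == mode]
    expect_true(all(diff(lof) <= 1e-12))
  }
})

test_that("identical config and seed give byte-identical metric tables", {
  cfg <- sersquant_config(seed = 31, n_mixtures = 12, replicates = 1,
                          n_bootstrap = 5, cv_folds = 3,
                          pls1_lvs = c(`3M3MH` = 3L, `2M3MB` = 3L,
                                       `3MH` = 3L, `2M3MP` = 3L),
                          pls2_lv = 4L, candidate_lvs = 1:4)
  out1 <- tempfile("a"); out2 <- tempfile("b")
  suppressWarnings(run_multiplex_study(cfg, outdir = out1))
  suppressWarnings(run_multiplex_study(cfg, outdir = out2))
  f1 <- readBin(file.path(out1, "metrics.csv"), "raw", 1e6)
  f2 <- readBin(file.path(out2, "metrics.csv"), "raw", 1e6)
  expect_identical(f1, f2)
  unlink(c(out1, out2), recursive = TRUE)
})
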