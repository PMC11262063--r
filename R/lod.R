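#' Baseline-corrected peak height
#'
#' Draws a local linear baseline between the two window endpoints (each
#' averaged over `edge_points` channels just inside the window, which keeps
#' endpoint noise from dominating the height variance) and returns the
#' maximum of signal minus baseline inside the window. May be negative for
#' pure noise.
#'
#' @param y intensity vector (one spectrum).
#' @param wavenumber axis, cm^-1.
#' @param peak peak position, cm^-1.
#' @param half_width window half-width, cm^-1 (default 10).
#' @param edge_points channels averaged at each endpoint (default 3).
#' @return Peak height (intensity units).
#' @export
measure_peak_height <- function(y, wavenumber, peak, half_width = 10,
                                edge_points = 3L) {
  check_axis(wavenumber)
  lo <- peak - half_width; hi <- peak + half_width
  if (lo < min(wavenumber) || hi > max(wavenumber))
    stop_sq("window [", lo, ", ", hi, "] cm-1 extends off-axis")
  idx <- which(wavenumber >= lo & wavenumber <= hi)
  if (length(idx) < 2L * edge_points + 1L)
    stop_sq("window too narrow for edge_points = ", edge_points)
  left <- idx[seq_len(edge_points)]
  right <- idx[seq.int(length(idx) - edge_points + 1L, length(idx))]
  x1 <- mean(wavenumber[left]); y1 <- mean(y[left])
  x2 <- mean(wavenumber[right]); y2 <- mean(y[right])
  base <- y1 + (y2 - y1) * (wavenumber[idx] - x1) / (x2 - x1)
  max(y[idx] - base)
}

#' Peak heights for every spectrum of a set
#'
#' @param set a [spectra_set()].
#' @inheritParams measure_peak_height
#' @return Numeric vector of heights, one per spectrum.
#' @export
peak_heights <- function(set, peak, half_width = 10, edge_points = 3L)
  apply(set$spectra, 1L, measure_peak_height, wavenumber = set$wavenumber,
        peak = peak, half_width = half_width, edge_points = edge_points)

#' Fit a univariate calibration curve
#'
#' Ordinary least squares of peak height on concentration over the linear
#' region, by default the lowest `n_lowest = 5` distinct concentration
#' levels (all replicates included); the five-point rule is enforced.
#'
#' @param concentrations ppm vector (>= 0, not all equal within the region).
#' @param heights peak heights, same length.
#' @param n_lowest number of lowest distinct levels forming the linear
#'   region (>= 5).
#' @param auto_region if TRUE, grow the region upward from `n_lowest`
#'   levels, keeping the region with maximal R^2.
#' @return A `calibration_curve`: slope `m` (intensity/ppm), intercept `c`,
#'   residual `sd` = sqrt(RSS/(n-2)), `r2`, `region` (ppm bounds),
#'   `n_points`, plus the regression data.
#' @export
fit_calibration <- function(concentrations, heights, n_lowest = 5L,
                            auto_region = FALSE) {
  if (length(concentrations) != length(heights))
    stop_sq("concentrations and heights differ in length")
  if (any(concentrations < 0)) stop_sq("concentrations must be >= 0")
  levels_all <- sort(unique(concentrations))
  if (n_lowest < 5L) stop_sq("the linear region needs at least five levels")
  if (length(levels_all) < n_lowest)
    stop_sq("only ", length(levels_all), " distinct levels; the linear ",
            "region needs a minimum of five datapoints")
  fit_region <- function(k) {
    lv <- levels_all[seq_len(k)]
    keep <- concentrations %in% lv
    x <- concentrations[keep]; y <- heights[keep]
    if (stats::var(x) == 0) stop_sq("zero concentration variance in region")
    fit <- stats::lm(y ~ x)
    rss <- sum(stats::residuals(fit)^2)
    tss <- sum((y - mean(y))^2)
    list(k = k, m = unname(stats::coef(fit)[2]),
         c = unname(stats::coef(fit)[1]),
         sd = sqrt(rss / (length(x) - 2L)),
         r2 = 1 - rss / tss, region = range(lv),
         n_points = length(x), concentrations = x, heights = y)
  }
  best <- fit_region(n_lowest)
  if (auto_region && length(levels_all) > n_lowest) {
    for (k in (n_lowest + 1L):length(levels_all)) {
      cand <- fit_region(k)
      if (cand$r2 > best$r2) best <- cand
    }
  }
  structure(best, class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("calibration_curve: m = %.4g, c = %.4g, SD = %.4g, R2 = %.4f (%d points, %g-%g ppm)\n",
              x$m, x$c, x$sd, x$r2, x$n_points, x$region[1], x$region[2]))
  invisible(x)
}

new_lod <- function(value, method, analyte = NA_character_,
                    wavenumber = NA_real_, details = list()) {
  structure(list(value = value, method = method, analyte = analyte,
                 wavenumber = wavenumber, details = details),
            class = "lod_estimate")
}

#' @export
print.lod_estimate <- function(x, ...) {
  val <- if (is.na(x$value)) "above tested range" else
    sprintf("%.4g ppm", x$value)
  cat("LoD (", x$method, "): ", val,
      if (!is.na(x$wavenumber)) sprintf(" at %g cm-1", x$wavenumber),
      "\n", sep = "")
  invisible(x)
}

#' Limit of detection from a calibration curve
#'
#' `LoD = k * SD / m`: the critical response `c + k*SD` back-transformed
#' through the calibration line (the intercept cancels). `SD` is the
#' residual standard deviation of the calibration fit and `k = 3` by
#' default (3.3 supported).
#'
#' @param curve a [fit_calibration()] result with positive slope.
#' @param k SD multiplier.
#' @param analyte optional analyte label.
#' @return An `lod_estimate` with method `"univariate_ksd"`.
#' @export
lod_from_calibration <- function(curve, k = 3, analyte = NA_character_) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (!is.finite(curve$m) || curve$m <= 0)
    stop_sq("non-positive calibration slope: no sensitivity at this peak")
  new_lod(k * curve$sd / curve$m, "univariate_ksd", analyte,
          details = list(k = k, sd = curve$sd, m = curve$m, r2 = curve$r2))
}

#' Limit of detection by the 3-SD-of-blank criterion
#'
#' Returns the lowest concentration level whose mean peak height exceeds
#' `k` times the standard deviation of the blank heights measured in the
#' same window. When no level qualifies the estimate's value is `NA` and
#' `details$outcome` is `"above_tested_range"`.
#'
#' @param set a single-analyte dilution [spectra_set()] including blank
#'   (0 ppm) rows, at least 3 blank replicates.
#' @param peak peak position, cm^-1.
#' @param half_width window half-width, cm^-1.
#' @param k multiplier (default 3).
#' @return An `lod_estimate` with method `"blank_3sd"`.
#' @export
lod_blank_criterion <- function(set, peak, half_width = 10, k = 3) {
  stopifnot(inherits(set, "spectra_set"))
  conc <- rowSums(as.matrix(set$concentrations))
  blanks <- which(conc == 0)
  if (length(blanks) < 3L) stop_sq("need at least 3 blank replicates")
  h <- peak_heights(set, peak, half_width)
  threshold <- k * stats::sd(h[blanks])
  levels_nz <- sort(unique(conc[conc > 0]))
  for (lv in levels_nz) {
    if (mean(h[conc == lv]) > threshold)
      return(new_lod(lv, "blank_3sd", wavenumber = peak,
                     details = list(threshold = threshold, k = k)))
  }
  new_lod(NA_real_, "blank_3sd", wavenumber = peak,
          details = list(threshold = threshold, k = k,
                         outcome = "above_tested_range"))
}
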