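#' Default wavenumber axis
#'
#' Uniform grid of 901 channels over 200-2000 cm^-1 (2 cm^-1 spacing), the
#' working range of a dispersive Raman instrument.
#'
#' @param from,to,by axis limits and spacing in cm^-1.
#' @return Numeric wavenumber vector.
#' @export
default_axis <- function(from = 200, to = 2000, by = 2) seq(from, to, by = by)

#' Define a spectral band
#'
#' @param center band position, cm^-1.
#' @param fwhm full width at half maximum, cm^-1 (> 0).
#' @param amplitude peak intensity per ppm of analyte (>= 0).
#' @param shape `"lorentzian"` (Raman default) or `"gaussian"`.
#' @return A `peak_def` object.
#' @export
peak_def <- function(center, fwhm = 12, amplitude = 1,
                     shape = c("lorentzian", "gaussian")) {
  shape <- match.arg(shape)
  if (fwhm <= 0) stop_sq("fwhm must be > 0 (peak at ", center, " cm-1)")
  if (amplitude < 0) stop_sq("amplitude must be >= 0 (peak at ", center,
                             " cm-1)")
  structure(list(center = center, fwhm = fwhm, amplitude = amplitude,
                 shape = shape), class = "peak_def")
}

peak_profile <- function(peak, wavenumber) {
  x <- wavenumber - peak$center
  if (peak$shape == "gaussian") {
    peak$amplitude * exp(-4 * log(2) * x^2 / peak$fwhm^2)
  } else {
    peak$amplitude / (1 + (2 * x / peak$fwhm)^2)
  }
}

#' Pure-component spectral library
#'
#' Holds one peak list per analyte on a shared axis. At zero noise the pure
#' spectra must be linearly independent (library rank equals the number of
#' components).
#'
#' @param peaks named list; each element a list of [peak_def()] objects.
#' @param wavenumber shared axis (cm^-1).
#' @return A `component_library` with the pure spectra matrix precomputed
#'   (`n_components x n_channels`, unit-concentration response).
#' @export
component_library <- function(peaks, wavenumber = default_axis()) {
  if (is.null(names(peaks)) || anyDuplicated(names(peaks)))
    stop_sq("component names must be unique and non-empty")
  check_axis(wavenumber)
  pure <- t(vapply(names(peaks), function(nm) {
    build_pure_spectrum(peaks[[nm]], wavenumber)$spectra[1, ]
  }, numeric(length(wavenumber))))
  if (qr(pure)$rank < length(peaks))
    stop_sq("pure spectra are linearly dependent; check peak definitions")
  structure(list(components = names(peaks), peaks = peaks,
                 wavenumber = wavenumber, pure = pure),
            class = "component_library")
}

#' @export
print.component_library <- function(x, ...) {
  cat("component_library:", length(x$components), "components on",
      length(x$wavenumber), "channels\n")
  for (nm in x$components) {
    ctr <- vapply(x$peaks[[nm]], `[[`, numeric(1), "center")
    cat("  ", nm, ": bands at", paste(ctr, collapse = ", "), "cm-1\n")
  }
  invisible(x)
}

#' Build a noise-free pure-component spectrum
#'
#' Sums the band profiles at unit (1 ppm) concentration; zero baseline.
#'
#' @param peaks list of [peak_def()] objects (possibly empty).
#' @param wavenumber axis on which to evaluate.
#' @return A single-spectrum [spectra_set()].
#' @export
build_pure_spectrum <- function(peaks, wavenumber = default_axis()) {
  check_axis(wavenumber)
  y <- numeric(length(wavenumber))
  for (pk in peaks) {
    if (!inherits(pk, "peak_def")) stop_sq("peaks must be peak_def objects")
    if (pk$center < min(wavenumber) || pk$center > max(wavenumber))
      stop_sq("peak center ", pk$center, " cm-1 is outside the axis (",
              min(wavenumber), "-", max(wavenumber), " cm-1)")
    y <- y + peak_profile(pk, wavenumber)
  }
  spectra_set(wavenumber, matrix(y, nrow = 1L),
              metadata = data.frame(sample_id = "pure", replicate = 1L,
                                    batch = "pure"))
}

#' Default four-thiol SERS library
#'
#' Pure-component band models for the four malodorous thiols. Each thiol
#' carries its dominant nu(C-S) stretching band (591, 639, 634 and 642 cm^-1
#' for 3M3MH, 2M3MB, 3MH and 2M3MP; the strongest band of a thiol
#' chemisorbed to silver) plus its secondary fingerprint bands at one third
#' the dominant amplitude. Lorentzian profiles, FWHM 12 cm^-1. 2M3MB and
#' 2M3MP share nearly coincident nu(C-S) positions (639 vs 642 cm^-1), which
#' makes them the most spectrally overlapped pair.
#'
#' @param dominant_amplitude intensity per ppm of the nu(C-S) band.
#' @param secondary_ratio dominant:secondary amplitude ratio (default 3).
#' @param fwhm band width, cm^-1.
#' @param wavenumber axis.
#' @return A [component_library()].
#' @export
default_thiol_library <- function(dominant_amplitude = 1,
                                  secondary_ratio = 3, fwhm = 12,
                                  wavenumber = default_axis()) {
  a1 <- dominant_amplitude
  a2 <- dominant_amplitude / secondary_ratio
  band <- function(center, amp) peak_def(center, fwhm = fwhm,
                                         amplitude = amp)
  peaks <- list(
    `3M3MH` = list(band(591, a1), band(926, a2), band(1137, a2)),
    `2M3MB` = list(band(639, a1), band(910, a2), band(1089, a2)),
    `3MH`   = list(band(634, a1), band(673, a2), band(887, a2),
                   band(1107, a2)),
    `2M3MP` = list(band(642, a1), band(706, a2), band(963, a2),
                   band(1053, a2), band(1234, a2))
  )
  component_library(peaks, wavenumber)
}
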