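#' Noise model for simulated SERS spectra
#'
#' Additive homoscedastic channel noise, one multiplicative intensity factor
#' per replicate (replicate-to-replicate enhancement variation, applied to
#' the chemical signal), a smooth random baseline drift, and a fixed smooth
#' background continuum shared by all spectra (the solvent/substrate
#' contribution every SERS measurement carries). The stable background is
#' what lets vector-normalised spectra carry absolute concentration
#' information: the analyte-band to background ratio. Identical seed and
#' parameters reproduce identical spectra bit-for-bit.
#'
#' @param additive_sd additive channel noise SD, intensity units.
#' @param multiplicative_sd SD of the per-replicate intensity factor
#'   (dimensionless fraction).
#' @param baseline_amplitude scale of the random baseline drift, intensity
#'   units.
#' @param baseline_smoothness characteristic width of the drift, cm^-1.
#' @param background_amplitude amplitude of the fixed background continuum
#'   (see [background_shape()]), intensity units.
#' @param seed RNG seed.
#' @return A `noise_model` object.
#' @export
noise_model <- function(additive_sd = 0.01, multiplicative_sd = 0.02,
                        baseline_amplitude = 0.015,
                        baseline_smoothness = 300,
                        background_amplitude = 0.5, seed = NULL) {
  if (additive_sd < 0 || multiplicative_sd < 0 || baseline_amplitude < 0 ||
      background_amplitude < 0)
    stop_sq("noise standard deviations and amplitudes must be >= 0")
  if (baseline_smoothness <= 0) stop_sq("baseline_smoothness must be > 0")
  structure(list(additive_sd = additive_sd,
                 multiplicative_sd = multiplicative_sd,
                 baseline_amplitude = baseline_amplitude,
                 baseline_smoothness = baseline_smoothness,
                 background_amplitude = background_amplitude, seed = seed),
            class = "noise_model")
}

#' Zero-noise model (optionally keeping baseline drift and background)
#' @param baseline_amplitude baseline drift amplitude; 0 for fully noiseless.
#' @param background_amplitude fixed background amplitude.
#' @param seed RNG seed (needed when baseline drift is kept).
#' @return A `noise_model`.
#' @export
zero_noise <- function(baseline_amplitude = 0, background_amplitude = 0,
                       seed = NULL)
  noise_model(0, 0, baseline_amplitude,
              background_amplitude = background_amplitude, seed = seed)

#' Fixed background continuum
#'
#' Broad exponentially decaying continuum,
#' `exp(-(nu - min(nu)) / 600)`, emulating the smooth fluorescence-like
#' background of a SERS measurement; identical for every spectrum.
#'
#' @param wavenumber axis, cm^-1.
#' @param decay decay constant, cm^-1.
#' @return Unit-amplitude background vector.
#' @export
background_shape <- function(wavenumber, decay = 600)
  exp(-(wavenumber - min(wavenumber)) / decay)

# free-form smooth random curve (spline through random knots); used for the
# batch-effect gain curve
random_smooth_curve <- function(wavenumber, smoothness) {
  rng <- range(wavenumber)
  knots <- seq(rng[1] - smoothness, rng[2] + smoothness, by = smoothness)
  vals <- stats::rnorm(length(knots))
  stats::spline(knots, vals, xout = wavenumber)$y
}

# fixed smooth drift basis: low-order polynomials plus two broad
# long-wavelength shapes, each unit-RMS. Baseline drift lives in the span of
# these shapes with random per-spectrum coefficients — backgrounds vary in
# intensity and tilt far more than in shape, so the drift subspace is
# low-dimensional across a data set (this is also what makes whole-spectrum
# calibration able to separate drift from analyte signal).
drift_basis <- function(wavenumber, smoothness = 300) {
  t <- 2 * (wavenumber - min(wavenumber)) / diff(range(wavenumber)) - 1
  rng <- diff(range(wavenumber))
  c1 <- min(wavenumber) + 0.35 * rng
  c2 <- min(wavenumber) + 0.80 * rng
  B <- cbind(rep(1, length(t)), t, 0.5 * (3 * t^2 - 1),
             exp(-(wavenumber - c1)^2 / (2 * smoothness^2)),
             exp(-(wavenumber - c2)^2 / (2 * smoothness^2)))
  sweep(B, 2L, sqrt(colMeans(B^2)), `/`)
}

# one random drift realisation, unit amplitude scale
random_baseline <- function(wavenumber, smoothness) {
  B <- drift_basis(wavenumber, smoothness)
  drop(B %*% stats::rnorm(ncol(B)))
}

#' Simulate a multiplex SERS data set
#'
#' Bilinear concentration-response model: each spectrum is the
#' concentration-weighted sum of the library's pure spectra, times a
#' per-replicate multiplicative factor, plus smooth baseline drift and
#' additive channel noise. Deterministic under the noise model's seed.
#'
#' @param library a [component_library()].
#' @param design a `mixture_design`; its analytes must all be in the library.
#' @param noise a [noise_model()].
#' @param replicates replicate spectra per design row (>= 1).
#' @param competition optional `list(affinities =, capacity =)` applying
#'   [apply_monolayer_competition()] to each row before spectrum synthesis
#'   (the recorded concentration table keeps the nominal values).
#' @param batch batch label stored in the metadata.
#' @return A [spectra_set()] with `replicates * n_samples` rows.
#' @export
simulate_mixture_set <- function(library, design, noise = noise_model(),
                                 replicates = 3, competition = NULL,
                                 batch = "batch1") {
  stopifnot(inherits(library, "component_library"),
            inherits(design, "mixture_design"))
  if (replicates < 1) stop_sq("replicates must be >= 1")
  missing <- setdiff(design$analytes, library$components)
  if (length(missing))
    stop_sq("design analytes not in library: ",
            paste(missing, collapse = ", "))
  conc <- design$concentrations[, library$components[
    library$components %in% design$analytes], drop = FALSE]
  # reorder pure spectra to the design's analyte order
  pure <- library$pure[match(colnames(conc), library$components), ,
                       drop = FALSE]
  eff <- conc
  if (!is.null(competition)) {
    eff <- t(apply(conc, 1L, apply_monolayer_competition,
                   affinities = competition$affinities,
                   capacity = competition$capacity))
  }
  n <- nrow(conc); p <- ncol(pure); total <- n * replicates
  bg <- noise$background_amplitude * background_shape(library$wavenumber)
  with_seed(noise$seed, {
    spectra <- matrix(0, nrow = total, ncol = p)
    ids <- character(total); reps <- integer(total)
    row <- 0L
    for (i in seq_len(n)) {
      base_signal <- drop(eff[i, , drop = FALSE] %*% pure)
      for (r in seq_len(replicates)) {
        row <- row + 1L
        fac <- 1 + stats::rnorm(1) * noise$multiplicative_sd
        y <- base_signal * fac + bg
        if (noise$baseline_amplitude > 0)
          y <- y + noise$baseline_amplitude *
            random_baseline(library$wavenumber, noise$baseline_smoothness)
        if (noise$additive_sd > 0)
          y <- y + stats::rnorm(p, sd = noise$additive_sd)
        spectra[row, ] <- y
        ids[row] <- sprintf("S%03d_r%d", i, r)
        reps[row] <- r
      }
    }
    meta <- data.frame(sample_id = ids, replicate = reps, batch = batch,
                       stringsAsFactors = FALSE)
    conc_tab <- as.data.frame(conc[rep(seq_len(n), each = replicates), ,
                                   drop = FALSE])
    spectra_set(library$wavenumber, spectra, conc_tab, meta)
  })
}

#' Simulate a single-analyte dilution series
#'
#' Convenience wrapper used by the limit-of-detection workflows; includes
#' blanks when `include_blank` is TRUE.
#'
#' @inheritParams simulate_mixture_set
#' @param analyte analyte name (must be in the library).
#' @param concentrations ppm levels (may include 0).
#' @param include_blank prepend blank (0 ppm) rows.
#' @return A [spectra_set()].
#' @export
simulate_dilution_series <- function(library, analyte,
                                     concentrations = dilution_levels(),
                                     noise = noise_model(), replicates = 3,
                                     include_blank = TRUE) {
  if (!analyte %in% library$components)
    stop_sq("unknown analyte '", analyte, "'; library has: ",
            paste(library$components, collapse = ", "))
  if (any(concentrations < 0)) stop_sq("concentrations must be >= 0")
  design <- dilution_design(analyte, concentrations,
                            include_blank = include_blank)
  simulate_mixture_set(library, design, noise, replicates)
}

#' Monolayer competition for the nanoparticle surface
#'
#' Below the capacity (one adsorbed monolayer, ~20 ppm total) response is
#' linear and concentrations pass through unchanged; above it, analytes
#' compete for the surface and the effective concentrations are reallocated
#' in proportion to affinity-weighted abundance, summing to the capacity.
#'
#' @param concentrations ppm vector (>= 0).
#' @param affinities positive adsorption weights, recycled to length.
#' @param capacity total ppm of one monolayer (> 0), default 20.
#' @return Effective ppm vector; its sum never exceeds `capacity`, with
#'   equality exactly when the input total is at or above it.
#' @export
apply_monolayer_competition <- function(concentrations, affinities = 1,
                                        capacity = 20) {
  if (any(concentrations < 0)) stop_sq("concentrations must be >= 0")
  if (capacity <= 0) stop_sq("capacity must be > 0")
  affinities <- rep_len(affinities, length(concentrations))
  if (any(affinities <= 0)) stop_sq("affinities must be > 0")
  total <- sum(concentrations)
  if (total <= capacity) return(concentrations)
  w <- affinities * concentrations
  capacity * w / sum(w)
}

#' Apply a batch-level intensity effect
#'
#' Emulates day-to-day variation between measurement sessions: every
#' spectrum of a batch is multiplied by one shared gain curve
#' `1 + gain * (z/2 + f(nu))`, where `z` is a batch-level standard normal
#' scalar and `f` a smooth unit-scale random function of wavenumber. The
#' wavelength dependence makes the effect survive per-spectrum
#' normalisation, as real instrument/enhancement drift does. Concentrations
#' are unchanged; `gain = 0` is the identity.
#'
#' @param set a [spectra_set()].
#' @param gain fractional gain scale (>= 0), e.g. 0.05 for 5%.
#' @param seed RNG seed (one draw per batch, in batch order).
#' @return The modified `spectra_set`.
#' @export
apply_batch_effect <- function(set, gain, seed = NULL) {
  stopifnot(inherits(set, "spectra_set"))
  if (gain < 0) stop_sq("gain must be >= 0")
  if (gain == 0) return(set)
  batches <- unique(set$metadata$batch)
  with_seed(seed, {
    for (b in batches) {
      z <- stats::rnorm(1)
      f <- random_smooth_curve(set$wavenumber, smoothness = 150)
      f <- f / max(stats::sd(f), 1e-12)
      # random shape, fixed magnitude: the spectral distortion has RMS
      # exactly `gain`; the scalar part shifts overall intensity
      curve <- 1 + gain * f + gain * z / 2
      rows <- which(set$metadata$batch == b)
      set$spectra[rows, ] <- sweep(set$spectra[rows, , drop = FALSE], 2L,
                                   curve, `*`)
    }
    set
  })
}
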