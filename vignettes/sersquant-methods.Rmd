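---
title: "Quantifying thiol mixtures from SERS spectra: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying thiol mixtures from SERS spectra: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sersquant)
```

## The problem

Four malodorous thiols — 3-mercaptohexan-1-ol (3MH),
3-methyl-3-mercaptohexan-1-ol (3M3MH), 2-methyl-3-mercaptobutan-1-ol
(2M3MB) and 2-methyl-3-mercaptopentan-1-ol (2M3MP) — chemisorb to silver
nanoparticles through their sulfur atom, which makes them strong
surface-enhanced Raman (SERS) scatterers. Their spectra are dominated by
the carbon–sulfur stretching band, nu(C–S), between 590 and 645 cm^-1, and
the four nu(C–S) positions lie within 50 cm^-1 of one another; 2M3MB
(639 cm^-1) and 2M3MP (642 cm^-1) are nearly coincident. Quantifying all
four simultaneously in a mixture is therefore a genuinely multivariate
problem: no single band is specific enough, and the overlapped pair cannot
be resolved by eye at all.

`sersquant` implements the complete chemometric workflow for this problem:
spectral pre-treatment, PCA-guided band selection, univariate and
multivariate limit-of-detection (LoD) estimation, PLS-1/PLS-2 calibration
with nested cross-validation and bootstrap validation, MCR-ALS curve
resolution, and a blind-test protocol — together with a synthetic spectrum
generator that reproduces the statistical structure these methods assume,
so that every stage can be validated end-to-end with known ground truth.

## The synthetic spectrum generator

Measured SERS spectra of these thiols are not publicly deposited, so the
package ships a generator whose defaults define the standard study
conditions used throughout the test suite.

A simulated spectrum on the default axis (200–2000 cm^-1, 2 cm^-1 spacing,
901 channels — a typical dispersive-instrument grid) is

```
x_i(nu) = f_i * sum_k c_ik * p_k(nu)   (chemical signal)
        + B * b(nu)                    (stable background continuum)
        + d * sum_m z_im * D_m(nu)     (smooth baseline drift)
        + e_i(nu)                      (white channel noise)
```

* `p_k` — pure-component response of thiol `k` at 1 ppm: Lorentzian bands
  (FWHM 12 cm^-1) at the literature positions, the dominant nu(C–S) band
  (591/639/634/642 cm^-1 for 3M3MH/2M3MB/3MH/2M3MP, amplitude 1 intensity
  unit per ppm) plus the secondary fingerprint bands at one third of that
  amplitude. Absolute SERS cross-sections are not reported anywhere, so
  the dominant amplitude is the package's intensity unit.
* `f_i = 1 + N(0, 0.02^2)` — one multiplicative factor per replicate,
  the enhancement variability of a colloidal SERS measurement. It scales
  the chemical signal, not the background: enhancement lives in the
  analyte–metal interaction, detector noise and solvent continuum do not
  share it.
* `b(nu) = exp(-(nu - 200)/600)` with amplitude `B = 0.5` — a fixed,
  smooth solvent/substrate continuum shared by every spectrum. This term
  matters more than it looks: the PLS chain is vector normalisation only,
  and normalisation discards the absolute intensity scale. What keeps the
  normalised spectra quantitative is the *ratio* of analyte bands to the
  stable continuum. Without it, no amount of modelling recovers absolute
  concentrations from normalised spectra.
* drift — random per-spectrum coefficients `z_im ~ N(0,1)` on a fixed
  five-member smooth basis `D_m` (constant, tilt, curvature, two broad
  Gaussians; unit RMS each), amplitude `d = 0.015`. Real backgrounds vary
  mostly in intensity and tilt, far less in shape, so the drift subspace
  across a data set is low-dimensional — which is also precisely why
  whole-spectrum calibration can separate drift from analyte signal.
* `e_i` — i.i.d. Gaussian channel noise, SD 0.01 = 1% of the maximum pure
  intensity for the multiplex conditions.

Two additional mechanisms complete the measurement model:

* **Monolayer competition** (`apply_monolayer_competition`): below a total
  concentration of one adsorbed monolayer (20 ppm) the response is linear;
  above it, analytes compete for the nanoparticle surface and effective
  concentrations are reallocated in proportion to affinity-weighted
  abundance, summing to the capacity. The multiplex design (4 × ≤1 ppm)
  stays far below this threshold by construction.
* **Batch effect** (`apply_batch_effect`): all spectra of a measurement
  session share one smooth multiplicative gain curve
  `1 + g*f(nu) + g*z/2`, with `f` a random smooth shape of unit RMS and
  `z` a batch-level scalar. A purely scalar day-to-day gain would be
  removed exactly by vector normalisation and could not produce the
  prediction-error degradation that blind tests on real instruments show;
  a wavelength-dependent gain survives normalisation, as real
  enhancement/instrument drift does. Because the shape is random, the
  *direction* of its effect on a particular analyte varies between batch
  realisations; its magnitude is fixed at `g` RMS.

### Two acquisition regimes

The generator carries two noise defaults, reflecting that a detection-limit
study and a routine multiplex screen are different measurements:

| parameter | multiplex / blind / MCR | LoD study |
|---|---|---|
| additive channel noise (intensity) | 0.01 | 0.002 |
| replicate factor SD | 0.02 | 0.02 |
| drift amplitude (intensity) | 0.015 | 0.001 |
| background amplitude | 0.5 | 0.5 |

A dilution series probes concentrations 30–500 times lower than the
multiplex range; at routine noise the five lowest levels would sit entirely
below the detection limit and the single-analyte PLS models (15 spectra)
would be unlearnable, whereas the published workflow plainly succeeded
there. Detection studies use longer, optimised acquisition; the LoD-study
defaults are calibrated so the univariate dominant-band LoDs land in the
low-0.01-ppm range such studies report. Both regimes are ordinary
`noise_model()` objects and can be overridden per run.

### What the generator does not emulate

No electromagnetic or chemical enhancement physics, no aggregation or pH
kinetics, no band-shape changes with surface coverage (conformer
redistribution), no wavenumber calibration drift, no cosmic-ray spikes, and
no literature band model of the acetonitrile/NaCl background (the continuum
is a generic smooth decay). Passing the test suite therefore demonstrates
that the *chemometric machinery* is correct and behaves as the field
expects on data with the assumed structure — not that any particular
laboratory instrument will achieve these numbers.

## Preprocessing chains

Three named chains, applied row-wise by `apply_chain()`:

* `pca_chain` — AsLS baseline correction, Savitzky–Golay smoothing
  (window 11, order 2), vector normalisation.
* `pls_chain` — vector normalisation only. Heavier pre-treatment before
  PLS invites overfitting; normalisation alone removes the scalar
  intensity fluctuations that dominate colloidal SERS.
* `mcr_chain` — SNV normalisation followed by the Savitzky–Golay first
  derivative.

**AsLS** estimates the baseline `z` minimising
`sum w_j (y_j - z_j)^2 + lambda * sum (delta^2 z_j)^2` with
`w_j = p` above the baseline and `1 - p` below, iterated to weight
convergence. Defaults `lambda = 1e5` (on the 2 cm^-1 grid), `p = 0.001`,
10 iterations — standard settings for Raman fluorescence backgrounds. The
sparse-matrix solve is verified against a dense direct solve of the same
penalised system in the test suite.

**Savitzky–Golay** uses the projection-matrix edge policy: edge points take
the polynomial fitted to the full first/last window, evaluated at the edge
positions, so polynomials up to the filter order are reproduced exactly at
every point and no signal is fabricated beyond the record. The derivative
uses the same window and order, scaled by the channel spacing to give
intensity per cm^-1.

**SNV** uses the sample-SD convention (n − 1), the chemometrics standard.

## PCA and band selection

PCA is column-mean-centred with no per-channel scaling (standard for
spectra). Component signs are fixed deterministically — the
largest-magnitude loading element is made positive — because the sign of a
principal component is otherwise arbitrary and score-plot orientation
would differ between runs. Candidate bands for univariate work are local
extrema of the PC-1 loading magnitude, ranked by magnitude, with a
prominence floor of 10% of the largest loading element; exact-magnitude
ties break to the lower wavenumber. On a dilution series the PC-1 loading
is, to a very good approximation, the analyte's own spectrum, so the
selected extrema are its strongest bands.

## Univariate limit of detection

Peak heights are measured after a local two-point linear baseline across a
±10 cm^-1 window; each baseline endpoint is the average of 3 channels just
inside the window. Endpoint averaging matters quantitatively: with raw
single-channel endpoints the baseline noise inflates the height SD by
~22%, which propagates directly into the LoD.

The calibration is ordinary least squares of height on concentration over
the linear region — by default the five lowest levels, never fewer than
five — and

```
LoD = k * SD / m,        k = 3 (3.3 supported)
```

with `SD` the residual SD of the calibration, `sqrt(RSS/(n-2))`, and `m`
the slope: the critical response `c + k*SD` back-transformed through the
line, the intercept cancelling. The companion blank criterion returns the
lowest level whose mean height exceeds `k` times the SD of the blank
heights in the same window; both estimators are labelled by method, and on
well-behaved series they agree within about one two-fold dilution step.

## PLS calibration

`fit_pls()` is NIPALS with deflation and mean centring; a one-column
response gives PLS-1, a four-column response PLS-2, through the same core.
Its correctness anchor is exact: at the full rank of a small full-rank
problem, the PLS coefficients equal the least-squares pseudo-inverse
solution to better than 1e-8 (an acceptance requirement). Predictions are
never clipped — negative concentration estimates are information about the
error structure and clipping would bias RMSEP.

**Complexity selection** uses leave-one-concentration-out double
cross-validation: the outer loop holds out every replicate of one level;
the inner loop repeats leave-one-level-out on the remaining levels and
picks the LV count with minimum pooled RMSECV, with a one-standard-error
tie-break toward fewer LVs. Outer predictions pool into Q2_cv and RMSECV.
A fixed-LV override mimics the published choices (6/7/8/6 for the four
PLS-1 models, 11 for PLS-2), and those are the package defaults for the
multiplex study. For the multiplex set (120 levels) full nested LOCO is
disproportionate; Q2_cv/RMSECV are there estimated by 10-fold grouped CV
over mixtures (replicates travel together) at the fixed LV counts.

**Bootstrap validation** draws `n` rows with replacement (1000 resamples
by default), fits at the fixed LV count, and predicts the out-of-bag rows.
Q2_test and RMSEP are pooled over every (sample, iteration) out-of-bag
pair; per-sample OOB means and SDs drive prediction plots. Replicates
enter as independent rows, so the expected out-of-bag fraction per
iteration is `(1 - 1/n)^n ≈ 0.368` and the unique in-bag fraction the
classic 0.632.

**Multivariate LoD** follows the pseudo-univariate capability-of-detection
construction: regress cross-validated predictions on known concentrations
(`predicted = a + b*known`, residual SD `s`) and report

```
LoD = delta * (s/b) * sqrt(1 + 1/n + xbar^2/Sxx)
```

with `delta = z_{1-alpha} + z_{1-beta} = 3.29` at `alpha = beta = 0.05`
under the normal approximation (a `qt`-based variant is available). The
leverage factor uses the calibration design's mean and spread.

## MCR-ALS

`fit_mcr_als()` alternates least-squares half-steps for `C` and `S` in
`X ~ C S'`, with non-negativity on `C` applied by clipping (the fast-ALS
variant) and no constraint on `S` in the working (derivative) domain,
where spectra are signed. Convergence is a relative lack-of-fit change
below 1e-6 or 100 iterations, with LOF defined as
`100 * sqrt(sum(resid^2)/sum(X^2))`; an iteration that increases LOF is
rejected and the fit stops flagged as non-converged, so the accepted LOF
trace is non-increasing by construction. Initialisation uses the processed
pure spectra; recovered components are matched to analytes by
permutation-search over absolute spectral correlations (C and S are
identifiable only up to scale and permutation).

Before regressing concentration profiles on known concentrations, the
workflow multiplies each profile row by that spectrum's SNV standard
deviation. SNV divides each spectrum by its own SD, so the recovered
`C[i, ]` carries a `1/sd_i` factor that is measurement scale, not
concentration; de-scaling removes a ~10% concentration-correlated
distortion that would otherwise cap the profile R^2 near 0.9.

The raw-versus-derivative comparison is the scientific point of this
module: SNV does not remove smooth baselines or the background continuum,
which act as extra un-modelled components and break the four-component
bilinear model — worst for the nearly collinear 2M3MB/2M3MP pair. The
first derivative suppresses everything smooth while sharpening the bands,
so derivative-domain MCR recovers all four components. The package's
standard MCR comparison runs with drift and background but no channel
noise, isolating exactly this mechanism.

## Workflows, determinism and problem sizes

The four workflow functions (`run_lod_study`, `run_multiplex_study`,
`run_blind_test`, `run_mcr_study`) chain the modules as a laboratory
would, write their metric tables, designs and config echo as CSV/JSON, and
are the package's interface — this is an analysis library used from R,
like the chemometrics packages it is modelled on, not a shell tool. All
randomness flows from the single root seed in `sersquant_config()`, split
deterministically per stage; identical config and seed give byte-identical
metric tables.

The validation suite runs the multiplex study at its full design size
(120 mixtures × 3 replicates, 901 channels) with 100 bootstrap resamples —
enough for stable pooled metrics while keeping a full run in tens of
seconds; 1000 resamples remain the workflow default. Monte-Carlo checks of
the LoD estimators use 200 repeats (100 per level for the
noise-monotonicity check).

## Known limitations

* Concentration information in normalised spectra rests on the stable
  background continuum; if a real background fluctuates as strongly as the
  analyte signal, absolute quantification from vector-normalised spectra
  degrades accordingly — a property of the method, not of this
  implementation.
* The batch-effect shape is random per batch: every 5% batch realisation
  degrades predictions on average, but an individual analyte in an
  individual batch can occasionally be left almost untouched (or hit
  several times harder). The blind-test contract should be read as
  distributional, not per-realisation.
* Non-negativity in MCR is enforced by clipping, not exact NNLS; with
  heavily rank-deficient initialisations the half-steps fall back to a
  tiny ridge.
* Univariate peak heights sit on Lorentzian tails, so calibration slopes
  run a few percent below the generator's band amplitudes; this cancels in
  `k*SD/m` to first order.
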