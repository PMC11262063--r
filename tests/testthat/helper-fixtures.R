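# small fixtures shared across the suite; everything generated in code

# short axis keeps unit tests fast
small_axis <- function() seq(400, 800, by = 2)

# two well-separated components on the small axis
small_library <- function() {
  component_library(list(
    A = list(peak_def(500, fwhm = 12, amplitude = 1),
             peak_def(650, fwhm = 12, amplitude = 0.4)),
    B = list(peak_def(560, fwhm = 12, amplitude = 1),
             peak_def(720, fwhm = 12, amplitude = 0.4))
  ), small_axis())
}

# fully noiseless model (no background, no drift)
noiseless <- function(seed = 1) zero_noise(seed = seed)

expect_all_finite <- function(x) expect_true(all(is.finite(x)))

# one-row explicit design over the small library's analytes
new_design_for_test <- function(conc)
  explicit_design(matrix(conc, nrow = 1), c("A", "B"))
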