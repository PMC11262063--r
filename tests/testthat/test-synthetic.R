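# synthetic spectrum generator: pure spectra, mixtures, competition, batches

test_that("pure spectrum peaks have the right apex, and superpose linearly", {
  axis <- default_axis()
  one <- build_pure_spectrum(list(peak_def(596, amplitude = 2)), axis)
  expect_equal(max(one$spectra), 2)
  expect_equal(axis[which.max(one$spectra)], 596)

  empty <- build_pure_spectrum(list(), axis)
  expect_true(all(empty$spectra == 0))

  two <- build_pure_spectrum(list(peak_def(596, amplitude = 2),
                                  peak_def(596, amplitude = 2)), axis)
  expect_equal(two$spectra, 2 * one$spectra)

  expect_error(build_pure_spectrum(list(peak_def(150)), axis), "off|outside")
  expect_error(peak_def(596, fwhm = -1), "fwhm")
})

test_that("mixture simulation follows the bilinear model", {
  lib <- small_library()
  d <- lhs_design(6, c("A", "B"), c(0.1, 1), seed = 3)
  s <- simulate_mixture_set(lib, d, noiseless(), replicates = 1)
  # rank = number of components at zero noise
  expect_equal(qr(s$spectra)$rank, 2L)
  # identity case
  d1 <- dilution_design("A", 1, include_blank = FALSE, other_analytes = "B")
  s1 <- simulate_mixture_set(lib, d1, noiseless(), replicates = 1)
  expect_equal(drop(s1$spectra), lib$pure["A", ], tolerance = 1e-12,
               ignore_attr = TRUE)
  # all-zero concentrations -> all-zero spectra
  d0 <- dilution_design("A", 0, include_blank = FALSE, other_analytes = "B")
  s0 <- simulate_mixture_set(lib, d0, noiseless(), replicates = 2)
  expect_true(all(s0$spectra == 0))
  # analyte mismatch is rejected with the missing names
  dbad <- lhs_design(4, c("A", "Z"), c(0.1, 1), seed = 1)
  expect_error(simulate_mixture_set(lib, dbad, noiseless()), "Z")
})

test_that("bilinearity: spectrum(c1 + c2) = spectrum(c1) + spectrum(c2)", {
  lib <- small_library()
  set.seed(5)
  for (i in 1:5) {
    c1 <- runif(2); c2 <- runif(2)
    sp <- function(cc) {
      d <- new_design_for_test(cc)
      simulate_mixture_set(lib, d, noiseless(), replicates = 1)$spectra
    }
    expect_equal(sp(c1 + c2), sp(c1) + sp(c2), tolerance = 1e-12)
  }
})

test_that("identical seeds give bit-identical spectra sets", {
  lib <- small_library()
  d <- lhs_design(5, c("A", "B"), c(0.1, 1), seed = 9)
  nm <- noise_model(seed = 11)
  s1 <- simulate_mixture_set(lib, d, nm, replicates = 3)
  s2 <- simulate_mixture_set(lib, d, nm, replicates = 3)
  expect_identical(s1$spectra, s2$spectra)
  expect_identical(s1$concentrations, s2$concentrations)
})

test_that("dilution series: blanks are blank and heights scale with concentration", {
  lib <- small_library()
  s <- simulate_dilution_series(lib, "A", c(1), noise = noiseless(),
                                replicates = 1, include_blank = TRUE)
  expect_true(all(s$spectra[1, ] == 0))           # blank row
  expect_equal(s$spectra[2, ], lib$pure["A", ], tolerance = 1e-12,
               ignore_attr = TRUE)
  # peak height proportional to concentration; slope = library amplitude
  conc <- c(0.2, 0.4, 0.8, 1.6)
  s2 <- simulate_dilution_series(lib, "A", conc, noise = noiseless(),
                                 replicates = 1, include_blank = FALSE)
  h <- peak_heights(s2, 500, half_width = 30)
  fit <- lm(h ~ conc)
  # the local two-point baseline sits on the lorentzian tails, so the
  # recovered slope is a few percent under the band amplitude
  expect_equal(unname(coef(fit)[2]), 1, tolerance = 0.05)
  expect_error(simulate_dilution_series(lib, "nope", c(1)), "nope")
})

test_that("monolayer competition preserves the linear regime and the capacity", {
  # below capacity: identity
  expect_equal(apply_monolayer_competition(c(4, 6), capacity = 20), c(4, 6))
  # symmetric overload splits the capacity
  expect_equal(apply_monolayer_competition(c(30, 30), capacity = 20),
               c(10, 10))
  # affinity-weighted reallocation, hand-computed
  expect_equal(apply_monolayer_competition(c(30, 10), c(3, 1), 20),
               c(18, 2))
  expect_error(apply_monolayer_competition(c(-1, 2)), ">= 0")
  # capacity conservation: sum <= capacity, equality iff input >= capacity
  set.seed(7)
  for (i in 1:20) {
    x <- runif(4, 0, 15)
    out <- apply_monolayer_competition(x, runif(4, 0.5, 2), 20)
    expect_lte(sum(out), 20 + 1e-12)
    if (sum(x) >= 20) expect_equal(sum(out), 20)
    else expect_equal(out, x)
  }
})

test_that("batch effect is batch-level, concentration-preserving, identity at 0", {
  lib <- small_library()
  d <- lhs_design(4, c("A", "B"), c(0.1, 1), seed = 2)
  s <- simulate_mixture_set(lib, d, noise_model(seed = 4), replicates = 2)
  expect_identical(apply_batch_effect(s, 0, seed = 1), s)
  b <- apply_batch_effect(s, 0.05, seed = 1)
  expect_identical(b$concentrations, s$concentrations)
  # all spectra of the batch share one gain curve
  ratio <- b$spectra / s$spectra
  for (i in 2:nrow(ratio))
    expect_equal(ratio[i, ], ratio[1, ], tolerance = 1e-12)
  # deterministic under seed
  expect_identical(apply_batch_effect(s, 0.05, seed = 1)$spectra, b$spectra)
})
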