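#' Concentration designs
#'
#' Mixture designs pair a concentration matrix (ppm) with analyte names,
#' per-analyte ranges and the seed that generated them; designs are pure
#' functions of their parameters and seed.
#'
#' @name mixture_design
NULL

new_design <- function(conc, analytes, type, ranges, seed = NULL) {
  conc <- as.matrix(conc)
  colnames(conc) <- analytes
  structure(list(concentrations = conc, analytes = analytes, type = type,
                 ranges = ranges, seed = seed), class = "mixture_design")
}

#' @export
print.mixture_design <- function(x, ...) {
  cat("mixture_design (", x$type, "): ", nrow(x$concentrations),
      " samples x ", length(x$analytes), " analytes\n", sep = "")
  invisible(x)
}

check_ranges <- function(ranges, analytes) {
  if (is.numeric(ranges) && length(ranges) == 2L)
    ranges <- rep(list(ranges), length(analytes))
  if (length(ranges) != length(analytes))
    stop_sq("need one (min, max) range per analyte")
  for (r in ranges)
    if (length(r) != 2L || r[1] >= r[2]) stop_sq("invalid range: min < max required")
  names(ranges) <- analytes
  ranges
}

#' Latin hypercube mixture design
#'
#' Stratified space-filling design: for each analyte the `n_samples`
#' concentrations occupy the `n_samples` equal-width strata of
#' `[min, max]` exactly once, with independent permutations per analyte.
#' Defaults match the multiplex study frame: 120 samples of the four thiols,
#' each between 0.05 and 1 ppm.
#'
#' @param n_samples number of mixtures (>= 2).
#' @param analytes analyte names.
#' @param ranges a `(min, max)` ppm pair shared by all analytes, or a list of
#'   one pair per analyte.
#' @param seed RNG seed; designs are reproducible from parameters + seed.
#' @param rule `"uniform"` draws uniformly within each stratum (default);
#'   `"midpoint"` uses stratum midpoints.
#' @return A `mixture_design`.
#' @export
lhs_design <- function(n_samples = 120,
                       analytes = c("3M3MH", "2M3MB", "3MH", "2M3MP"),
                       ranges = c(0.05, 1), seed = NULL,
                       rule = c("uniform", "midpoint")) {
  rule <- match.arg(rule)
  if (n_samples < 2) stop_sq("n_samples must be >= 2")
  ranges <- check_ranges(ranges, analytes)
  k <- length(analytes)
  u <- with_seed(seed, {
    if (rule == "uniform") {
      lhs::randomLHS(n_samples, k)
    } else {
      vapply(seq_len(k),
             function(j) (sample.int(n_samples) - 0.5) / n_samples,
             numeric(n_samples))
    }
  })
  conc <- vapply(seq_len(k), function(j) {
    r <- ranges[[j]]
    r[1] + u[, j] * (r[2] - r[1])
  }, numeric(n_samples))
  new_design(conc, analytes, "lhs", ranges, seed)
}

#' Random uniform mixture design
#'
#' i.i.d. uniform concentrations per analyte within range; the blind-test
#' frame is 15 such samples over the same ranges as the training design.
#'
#' @inheritParams lhs_design
#' @return A `mixture_design`.
#' @export
random_design <- function(n_samples = 15,
                          analytes = c("3M3MH", "2M3MB", "3MH", "2M3MP"),
                          ranges = c(0.05, 1), seed = NULL) {
  if (n_samples < 1) stop_sq("n_samples must be >= 1")
  ranges <- check_ranges(ranges, analytes)
  conc <- with_seed(seed, vapply(ranges, function(r)
    stats::runif(n_samples, r[1], r[2]), numeric(n_samples)))
  if (n_samples == 1L) conc <- matrix(conc, nrow = 1L)
  new_design(conc, analytes, "random", ranges, seed)
}

#' Explicit mixture design from a concentration matrix
#'
#' @param concentrations numeric matrix or data frame (`n_samples x
#'   n_analytes`, ppm, >= 0).
#' @param analytes analyte names (default: column names).
#' @return A `mixture_design` of type `"explicit"`.
#' @export
explicit_design <- function(concentrations,
                            analytes = colnames(concentrations)) {
  conc <- as.matrix(concentrations)
  if (is.null(analytes)) stop_sq("analyte names required")
  if (any(conc < 0)) stop_sq("concentrations must be >= 0")
  new_design(conc, analytes, "explicit",
             check_ranges(c(0, max(conc) + 1e-12), analytes))
}

#' Single-analyte dilution design
#'
#' @param analyte analyte name.
#' @param levels concentration levels in ppm (>= 0); sorted ascending.
#' @param include_blank prepend a 0-ppm blank row.
#' @param other_analytes additional zero-concentration columns so the design
#'   can align with a multi-analyte library.
#' @return A `mixture_design`.
#' @export
dilution_design <- function(analyte, levels = dilution_levels(),
                            include_blank = TRUE, other_analytes = NULL) {
  if (any(levels < 0)) stop_sq("concentration levels must be >= 0")
  levels <- sort(levels)
  if (include_blank) levels <- c(0, levels)
  analytes <- union(analyte, other_analytes)
  conc <- matrix(0, nrow = length(levels), ncol = length(analytes))
  conc[, match(analyte, analytes)] <- levels
  new_design(conc, analytes, "dilution",
             check_ranges(c(0, max(levels) + 1e-12), analytes))
}

#' Default dilution series for the limit-of-detection study
#'
#' Two-fold serial dilution; the default 8 levels run from 2 ppm down to
#' 2/2^7 = 0.016 ppm, the working range of the single-analyte calibration
#' series. `dilution_levels(3, 10)` reproduces the widest explored range,
#' 3 ppm down to 3/2^9 = 0.0059 ppm.
#'
#' @param top highest level, ppm.
#' @param n_levels number of two-fold dilutions.
#' @return Ascending numeric vector of concentrations.
#' @export
dilution_levels <- function(top = 2, n_levels = 8)
  sort(top / 2^(seq_len(n_levels) - 1))
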