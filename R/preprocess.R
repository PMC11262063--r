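#' Asymmetric least squares baseline correction
#'
#' Eilers-style AsLS: the baseline `z` minimises
#' `sum w_k (y_k - z_k)^2 + lambda * sum (d2 z)^2` with asymmetric weights
#' `w_k = p` where `y_k > z_k` and `1 - p` otherwise, iterated to weight
#' convergence. Points above the baseline (peaks) get the small weight `p`,
#' so the baseline hugs the lower envelope of the spectrum.
#'
#' @param y intensity vector (length >= 3, finite).
#' @param lambda smoothness penalty (> 0); default 1e5 on a 2 cm^-1 grid.
#' @param p asymmetry weight in (0, 1); default 0.001.
#' @param max_iter maximum weight-update iterations.
#' @return `list(baseline =, corrected =, iterations =)`.
#' @export
asls_baseline <- function(y, lambda = 1e5, p = 0.001, max_iter = 10) {
  if (length(y) < 3) stop_sq("need at least 3 channels")
  check_finite(y, "spectrum")
  if (lambda <= 0) stop_sq("lambda must be > 0")
  if (p <= 0 || p >= 1) stop_sq("p must be in (0, 1)")
  n <- length(y)
  D <- Matrix::bandSparse(n - 2, n, k = 0:2,
                          diagonals = list(rep(1, n - 2), rep(-2, n - 2),
                                           rep(1, n - 2)))
  DtD <- lambda * Matrix::crossprod(D)
  w <- rep(1, n)
  z <- y
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    z <- as.numeric(Matrix::solve(Matrix::Diagonal(x = w) + DtD, w * y))
    w_new <- ifelse(y > z, p, 1 - p)
    if (identical(w_new, w) && iter > 1L) break
    w <- w_new
  }
  list(baseline = z, corrected = y - z, iterations = iter)
}

#' Savitzky-Golay smoothing
#'
#' Least-squares local polynomial filter; interior points take the value of
#' the window-centred polynomial fit. Edge points use the polynomial fitted
#' to the full first/last window, evaluated at the edge positions (the
#' sgolay projection-matrix policy), so polynomials up to the filter order
#' are reproduced exactly everywhere.
#'
#' @param y intensity vector (length >= `window`).
#' @param window odd window width in points (default 11).
#' @param polyorder polynomial order (default 2), `< window`.
#' @return Smoothed vector.
#' @export
savgol_smooth <- function(y, window = 11, polyorder = 2) {
  if (window %% 2 == 0) stop_sq("window must be odd")
  if (polyorder >= window) stop_sq("polyorder must be < window")
  if (length(y) < window) stop_sq("spectrum shorter than window")
  as.numeric(signal::sgolayfilt(y, p = polyorder, n = window))
}

#' Savitzky-Golay first derivative
#'
#' First derivative in intensity per cm^-1, estimated with the same
#' window/order as the smoothing default and scaled by the channel spacing;
#' a linear ramp maps to its slope.
#'
#' @param y intensity vector.
#' @param wavenumber uniform axis (cm^-1).
#' @param window,polyorder filter settings, as [savgol_smooth()].
#' @return Derivative vector (intensity per cm^-1).
#' @export
first_derivative <- function(y, wavenumber, window = 11, polyorder = 2) {
  check_axis(wavenumber)
  if (length(y) != length(wavenumber)) stop_sq("length mismatch with axis")
  h <- wavenumber[2] - wavenumber[1]
  as.numeric(signal::sgolayfilt(y, p = polyorder, n = window, m = 1,
                                ts = h))
}

#' Vector (Euclidean) normalisation
#'
#' @param y intensity vector, not all zero.
#' @return `y / ||y||_2`, unit Euclidean norm.
#' @export
vector_normalize <- function(y) {
  nrm <- sqrt(sum(y^2))
  if (nrm == 0) stop_sq("cannot vector-normalise an all-zero spectrum")
  y / nrm
}

#' Standard normal variate (SNV) normalisation
#'
#' Per-spectrum centring and scaling to unit standard deviation (sample SD,
#' n - 1 denominator, the chemometrics convention).
#'
#' @param y intensity vector with non-zero spread.
#' @return `(y - mean(y)) / sd(y)`.
#' @export
snv_normalize <- function(y) {
  s <- stats::sd(y)
  if (!is.finite(s) || s == 0)
    stop_sq("cannot SNV-normalise a constant spectrum")
  (y - mean(y)) / s
}

# --- preprocessing chains ----------------------------------------------------

#' Preprocessing chains
#'
#' A chain is an ordered list of operator steps applied row-wise by
#' [apply_chain()]. The three named chains used by the pipeline:
#' \describe{
#'   \item{pca_chain}{AsLS baseline correction, Savitzky-Golay smoothing
#'     (window 11, order 2), vector normalisation.}
#'   \item{pls_chain}{vector normalisation only (no further pre-processing,
#'     to avoid overfitting).}
#'   \item{mcr_chain}{SNV normalisation followed by the Savitzky-Golay first
#'     derivative.}
#' }
#'
#' @param name one of `"pca_chain"`, `"pls_chain"`, `"mcr_chain"`, or
#'   `"custom"` with explicit `steps`.
#' @param steps for `"custom"`: list of `list(op =, ...params)` entries; the
#'   known ops are `"asls"`, `"savgol"`, `"vector_normalize"`, `"snv"`,
#'   `"first_derivative"`.
#' @return A `preprocessing_chain` object (serialisable with
#'   [jsonlite::toJSON()]).
#' @export
preprocessing_chain <- function(name = c("pca_chain", "pls_chain",
                                         "mcr_chain", "custom"),
                                steps = NULL) {
  name <- match.arg(name)
  if (name != "custom") {
    steps <- switch(name,
      pca_chain = list(list(op = "asls", lambda = 1e5, p = 0.001),
                       list(op = "savgol", window = 11, polyorder = 2),
                       list(op = "vector_normalize")),
      pls_chain = list(list(op = "vector_normalize")),
      mcr_chain = list(list(op = "snv"),
                       list(op = "first_derivative", window = 11,
                            polyorder = 2)))
  }
  if (is.null(steps)) steps <- list()
  known <- c("asls", "savgol", "vector_normalize", "snv",
             "first_derivative")
  for (st in steps)
    if (!st$op %in% known)
      stop_sq("unknown preprocessing op '", st$op, "'")
  structure(list(name = name, steps = steps), class = "preprocessing_chain")
}

#' @export
print.preprocessing_chain <- function(x, ...) {
  ops <- vapply(x$steps, `[[`, character(1), "op")
  cat("preprocessing_chain '", x$name, "': ",
      if (length(ops)) paste(ops, collapse = " -> ") else "(identity)",
      "\n", sep = "")
  invisible(x)
}

apply_step <- function(y, step, wavenumber) {
  switch(step$op,
    asls = asls_baseline(y, lambda = step$lambda %||% 1e5,
                         p = step$p %||% 0.001,
                         max_iter = step$max_iter %||% 10)$corrected,
    savgol = savgol_smooth(y, window = step$window %||% 11,
                           polyorder = step$polyorder %||% 2),
    vector_normalize = vector_normalize(y),
    snv = snv_normalize(y),
    first_derivative = first_derivative(y, wavenumber,
                                        window = step$window %||% 11,
                                        polyorder = step$polyorder %||% 2))
}

#' Apply a preprocessing chain to a spectra set
#'
#' Operators run strictly in listed order, row by row; the concentration
#' table and axis are untouched and the chain name is recorded in the
#' result's `chain_applied` attribute. Any operator failure is re-raised
#' with the offending sample id.
#'
#' @param set a [spectra_set()].
#' @param chain a [preprocessing_chain()] or a chain name.
#' @return The preprocessed `spectra_set`.
#' @export
apply_chain <- function(set, chain) {
  stopifnot(inherits(set, "spectra_set"))
  if (is.character(chain)) chain <- preprocessing_chain(chain)
  for (st in chain$steps) {
    for (i in seq_len(nrow(set$spectra))) {
      set$spectra[i, ] <- tryCatch(
        apply_step(set$spectra[i, ], st, set$wavenumber),
        error = function(e) stop_sq("sample '", set$metadata$sample_id[i],
                                    "', op '", st$op, "': ",
                                    conditionMessage(e)))
    }
  }
  attr(set, "chain_applied") <- chain$name
  set
}
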