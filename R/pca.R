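#' Principal component analysis of a spectra set
#'
#' Column-mean-centred PCA (no per-channel scaling, as is standard for
#' spectra). Component signs are fixed deterministically: the
#' largest-magnitude loading element of each component is made positive, so
#' repeated runs give identical score orientations.
#'
#' @param set a [spectra_set()] (usually after the PCA chain).
#' @param n_components number of components (defaults to the maximum,
#'   `min(n_samples - 1, n_channels)`).
#' @return A `pca_result`: `scores` (n_samples x k), `loadings`
#'   (n_channels x k, orthonormal columns), `tev` (percent total explained
#'   variance per component, non-increasing), `center` (mean spectrum).
#' @export
fit_pca <- function(set, n_components = NULL) {
  stopifnot(inherits(set, "spectra_set"))
  X <- set$spectra
  n <- nrow(X)
  if (n < 2) stop_sq("PCA needs at least 2 samples")
  kmax <- min(n - 1L, ncol(X))
  k <- n_components %||% kmax
  if (k > kmax) stop_sq("n_components must be <= min(n_samples - 1, ",
                        "n_channels) = ", kmax)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = k)
  total_var <- sum(apply(X, 2L, stats::var))
  tev <- 100 * pc$sdev[seq_len(k)]^2 / total_var
  loadings <- pc$rotation
  scores <- pc$x
  for (j in seq_len(k)) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(scores = scores, loadings = loadings, tev = tev,
                 center = pc$center, wavenumber = set$wavenumber),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("pca_result:", ncol(x$scores), "components; TEV (%):",
      paste(sprintf("%.2f", x$tev), collapse = ", "), "\n")
  invisible(x)
}

#' Select peaks from a PCA loading
#'
#' Finds local extrema of the absolute loading of one component, ranked by
#' magnitude, as candidate bands for univariate calibration. Extrema below
#' `min_prominence * max(|loading|)` are dropped; magnitude ties break to
#' the lower wavenumber.
#'
#' @param result a `pca_result`.
#' @param component component index (default 1, the concentration trend).
#' @param max_peaks maximum number of peaks returned.
#' @param min_prominence fraction of the maximum absolute loading below
#'   which extrema are ignored (default 0.1).
#' @return A `peak_selection` data frame with columns `wavenumber`,
#'   `channel`, `loading`, `sign`; zero rows (with a warning) when no
#'   extremum qualifies.
#' @export
select_peaks_from_loadings <- function(result, component = 1L,
                                       max_peaks = 3L,
                                       min_prominence = 0.1) {
  stopifnot(inherits(result, "pca_result"))
  if (component < 1L || component > ncol(result$loadings))
    stop_sq("component ", component, " not available")
  v <- result$loadings[, component]
  a <- abs(v)
  n <- length(a)
  empty <- data.frame(wavenumber = numeric(0), channel = integer(0),
                      loading = numeric(0), sign = numeric(0))
  class(empty) <- c("peak_selection", "data.frame")
  if (max_peaks < 1L) return(empty)
  interior <- 2:(n - 1L)
  is_max <- a[interior] > a[interior - 1L] & a[interior] >= a[interior + 1L]
  cand <- interior[is_max]
  cand <- cand[a[cand] >= min_prominence * max(a)]
  if (!length(cand)) {
    warning("no loading extremum above the prominence threshold")
    return(empty)
  }
  # rank by |loading| descending; exact ties -> lower wavenumber first
  cand <- cand[order(-a[cand], cand)]
  cand <- cand[seq_len(min(max_peaks, length(cand)))]
  out <- data.frame(wavenumber = result$wavenumber[cand], channel = cand,
                    loading = v[cand], sign = sign(v[cand]))
  attr(out, "component") <- component
  class(out) <- c("peak_selection", "data.frame")
  out
}
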