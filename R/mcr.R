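#' Multivariate curve resolution by alternating least squares
#'
#' Bilinear decomposition `X ~ C %*% t(S)` of mixture spectra into
#' concentration profiles `C` (n_samples x k, arbitrary scale) and spectral
#' profiles `S` (n_channels x k), alternating least-squares half-steps with
#' optional non-negativity (applied by clipping within each half-step).
#' Iterations are accepted only while the percent lack of fit,
#' `LOF = 100 * sqrt(sum(resid^2) / sum(X^2))`, does not increase; an
#' increasing step reverts to the previous profiles and stops with
#' `converged = FALSE`. C and S are recovered only up to scale and
#' permutation; comparisons against references are handled by
#' [assign_components()].
#'
#' @param X preprocessed mixture matrix (`n x p`).
#' @param S_init initial spectral profiles (`p x k`), linearly independent
#'   columns — typically [initialize_from_pure()].
#' @param nonneg_C,nonneg_S non-negativity constraints on the profiles;
#'   `nonneg_S` defaults to FALSE because derivative-domain spectra are
#'   signed.
#' @param tol relative lack-of-fit change below which iteration stops.
#' @param max_iter maximum ALS iterations.
#' @return An `mcr_result`: `C`, `S`, `lof` (percent, per accepted
#'   iteration, non-increasing), `converged`, `iterations`.
#' @export
fit_mcr_als <- function(X, S_init, nonneg_C = TRUE, nonneg_S = FALSE,
                        tol = 1e-6, max_iter = 100) {
  X <- as.matrix(X)
  S <- as.matrix(S_init)
  if (nrow(S) != ncol(X))
    stop_sq("S_init must be n_channels x n_components")
  k <- ncol(S)
  if (qr(S)$rank < k) stop_sq("S_init columns are linearly dependent")
  ssx <- sum(X^2)
  lof_of <- function(C, S) 100 * sqrt(sum((X - tcrossprod(C, S))^2) / ssx)
  solve_ls <- function(A, B) {
    # rows of result solve min || B - A %*% t(result) ||
    t(tryCatch(solve(crossprod(A), crossprod(A, B)),
               error = function(e) {
                 g <- crossprod(A) + diag(1e-10 * mean(diag(crossprod(A))),
                                          ncol(A))
                 solve(g, crossprod(A, B))
               }))
  }
  C <- solve_ls(S, t(X))
  if (nonneg_C) C[C < 0] <- 0
  lof <- lof_of(C, S)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    S_new <- solve_ls(C, X)
    if (nonneg_S) S_new[S_new < 0] <- 0
    C_new <- solve_ls(S_new, t(X))
    if (nonneg_C) C_new[C_new < 0] <- 0
    lof_new <- lof_of(C_new, S_new)
    if (lof_new > utils::tail(lof, 1L) * (1 + 1e-12) + 1e-12) {
      converged <- FALSE
      iter <- iter - 1L
      break
    }
    improved <- utils::tail(lof, 1L) - lof_new
    C <- C_new; S <- S_new
    lof <- c(lof, lof_new)
    if (lof_new < 1e-10 ||                      # numerically exact fit
        improved < tol * max(lof_new, 1e-12)) { converged <- TRUE; break }
  }
  structure(list(C = C, S = S, lof = lof, converged = converged,
                 iterations = iter),
            class = "mcr_result")
}

#' @export
print.mcr_result <- function(x, ...) {
  cat("mcr_result:", ncol(x$C), "components,", x$iterations,
      "iterations, final LOF", sprintf("%.4g%%", utils::tail(x$lof, 1L)),
      if (x$converged) "(converged)" else "(not converged)", "\n")
  invisible(x)
}

#' Initial spectral profiles from pure-component spectra
#'
#' Applies the given preprocessing chain (by default the MCR chain: SNV then
#' first derivative) to the library's pure spectra and returns them,
#' transposed, as the initial `S` for [fit_mcr_als()].
#'
#' @param library a [component_library()], or a [spectra_set()] of measured
#'   pure spectra (one row per component).
#' @param chain a [preprocessing_chain()] or chain name (`"mcr_chain"`
#'   default; use `preprocessing_chain("custom", list(list(op = "snv")))`
#'   for the raw SNV-only mode).
#' @param wavenumber axis the mixtures live on (checked for agreement).
#' @return `S_init` matrix (`n_channels x n_components`) with component
#'   names as column names.
#' @export
initialize_from_pure <- function(library, chain = "mcr_chain",
                                 wavenumber = NULL) {
  if (inherits(library, "component_library")) {
    set <- spectra_set(library$wavenumber, library$pure,
                       metadata = data.frame(
                         sample_id = library$components,
                         replicate = 1L, batch = "pure"))
  } else if (inherits(library, "spectra_set")) {
    set <- library
  } else stop_sq("library must be a component_library or spectra_set")
  if (!is.null(wavenumber) &&
      !isTRUE(all.equal(wavenumber, set$wavenumber)))
    stop_sq("pure spectra and mixtures are on different axes")
  set <- apply_chain(set, chain)
  S <- t(set$spectra)
  colnames(S) <- set$metadata$sample_id
  S
}

#' Assign resolved components to analytes
#'
#' Permutation matching between recovered spectral profiles and reference
#' profiles by Pearson correlation: for up to 6 components all permutations
#' are searched for the maximal total absolute correlation; larger problems
#' fall back to greedy matching.
#'
#' @param S recovered spectral profiles (`p x k`).
#' @param reference reference profiles (`p x k`), e.g. the processed pure
#'   spectra used for initialisation, with analyte column names.
#' @return Data frame: `component`, `analyte`, `correlation` (absolute
#'   Pearson correlation with the matched reference).
#' @export
assign_components <- function(S, reference) {
  S <- as.matrix(S); reference <- as.matrix(reference)
  k <- ncol(S)
  if (ncol(reference) != k) stop_sq("component count mismatch")
  cors <- abs(stats::cor(S, reference))
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      out <- c(out, lapply(perms(v[-i]), function(p) c(v[i], p)))
    out
  }
  if (k <= 6L) {
    best <- NULL; best_val <- -Inf
    for (p in perms(seq_len(k))) {
      val <- sum(cors[cbind(seq_len(k), p)])
      if (val > best_val) { best_val <- val; best <- p }
    }
    match_idx <- best
  } else {
    match_idx <- integer(k); taken <- logical(k)
    for (i in order(-apply(cors, 1L, max))) {
      j <- order(-cors[i, ])
      j <- j[!taken[j]][1L]
      match_idx[i] <- j; taken[j] <- TRUE
    }
  }
  data.frame(component = seq_len(k),
             analyte = (colnames(reference) %||%
                          paste0("C", seq_len(k)))[match_idx],
             correlation = cors[cbind(seq_len(k), match_idx)])
}

#' Regress concentration profiles on known concentrations
#'
#' One OLS model per assigned component: recovered profile column versus the
#' known concentration of the matched analyte; reports slope, intercept and
#' R^2 per component. Components whose assignment is missing are reported
#' unassigned and excluded.
#'
#' @param C concentration profiles (`n x k`) from [fit_mcr_als()].
#' @param known concentration table (`n x m` data frame or matrix, ppm).
#' @param assignment data frame from [assign_components()].
#' @return Data frame: `component`, `analyte`, `slope`, `intercept`, `r2`
#'   (`NA` for unassigned components).
#' @export
regress_profiles <- function(C, known, assignment) {
  C <- as.matrix(C); known <- as.matrix(known)
  out <- lapply(seq_len(ncol(C)), function(i) {
    an <- assignment$analyte[match(i, assignment$component)]
    if (is.na(an) || !an %in% colnames(known))
      return(data.frame(component = i, analyte = NA_character_,
                        slope = NA_real_, intercept = NA_real_,
                        r2 = NA_real_))
    fit <- stats::lm(C[, i] ~ known[, an])
    rss <- sum(stats::residuals(fit)^2)
    tss <- sum((C[, i] - mean(C[, i]))^2)
    data.frame(component = i, analyte = an,
               slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               r2 = 1 - rss / tss)
  })
  do.call(rbind, out)
}
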