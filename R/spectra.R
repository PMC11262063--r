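#' Spectra set container
#'
#' A `spectra_set` holds a sample-by-channel intensity matrix on a shared,
#' strictly increasing and uniformly spaced wavenumber axis, aligned row-wise
#' with a concentration table (ppm per analyte) and per-sample metadata
#' (sample id, replicate index, batch label).
#'
#' @param wavenumber numeric vector, uniformly spaced ascending wavenumbers
#'   (cm^-1).
#' @param spectra numeric matrix, `n_samples x n_channels`.
#' @param concentrations data frame (`n_samples` rows) of analyte
#'   concentrations in ppm, or `NULL` when unknown.
#' @param metadata data frame with columns `sample_id`, `replicate`, `batch`;
#'   generated if omitted.
#' @return An object of class `spectra_set`.
#' @export
spectra_set <- function(wavenumber, spectra, concentrations = NULL,
                        metadata = NULL) {
  wavenumber <- as.numeric(wavenumber)
  if (is.null(dim(spectra))) spectra <- matrix(spectra, nrow = 1L)
  spectra <- as.matrix(spectra)
  check_axis(wavenumber)
  if (ncol(spectra) != length(wavenumber))
    stop_sq("spectra has ", ncol(spectra), " channels but axis has ",
            length(wavenumber))
  check_finite(spectra, "spectra")
  n <- nrow(spectra)
  if (is.null(metadata)) {
    metadata <- data.frame(sample_id = sprintf("S%03d", seq_len(n)),
                           replicate = 1L, batch = "batch1",
                           stringsAsFactors = FALSE)
  }
  if (nrow(metadata) != n)
    stop_sq("metadata has ", nrow(metadata), " rows, spectra ", n)
  if (anyDuplicated(metadata$sample_id))
    stop_sq("duplicate sample ids: ",
            paste(unique(metadata$sample_id[duplicated(metadata$sample_id)]),
                  collapse = ", "))
  if (!is.null(concentrations)) {
    concentrations <- as.data.frame(concentrations)
    if (nrow(concentrations) != n)
      stop_sq("concentration table has ", nrow(concentrations),
              " rows, spectra ", n)
    rownames(concentrations) <- NULL
  }
  rownames(spectra) <- metadata$sample_id
  structure(list(wavenumber = wavenumber, spectra = spectra,
                 concentrations = concentrations, metadata = metadata),
            class = "spectra_set")
}

check_axis <- function(wavenumber) {
  if (length(wavenumber) < 2L) stop_sq("axis needs at least 2 channels")
  d <- diff(wavenumber)
  if (any(d <= 0)) stop_sq("wavenumber axis must be strictly increasing")
  if (max(d) - min(d) > 1e-8 * mean(d))
    stop_sq("wavenumber axis must be uniformly spaced")
  invisible(wavenumber)
}

#' @export
print.spectra_set <- function(x, ...) {
  cat("spectra_set:", nrow(x$spectra), "spectra x", ncol(x$spectra),
      "channels (", min(x$wavenumber), "-", max(x$wavenumber), "cm-1 )\n")
  if (!is.null(x$concentrations))
    cat("  analytes:", paste(names(x$concentrations), collapse = ", "), "\n")
  chain <- attr(x, "chain_applied")
  if (!is.null(chain)) cat("  preprocessing:", chain, "\n")
  invisible(x)
}

#' @export
dim.spectra_set <- function(x) dim(x$spectra)

#' Subset a spectra set by sample
#'
#' @param x a `spectra_set`.
#' @param i row (sample) index.
#' @param ... ignored.
#' @return A `spectra_set` with the selected samples.
#' @export
`[.spectra_set` <- function(x, i, ...) {
  out <- spectra_set(x$wavenumber, x$spectra[i, , drop = FALSE],
                     if (!is.null(x$concentrations))
                       x$concentrations[i, , drop = FALSE],
                     x$metadata[i, , drop = FALSE])
  attr(out, "chain_applied") <- attr(x, "chain_applied")
  out
}

channel_index <- function(wavenumber, value) {
  idx <- which.min(abs(wavenumber - value))
  if (abs(wavenumber[idx] - value) > diff(wavenumber[1:2]))
    stop_sq("wavenumber ", value, " cm-1 is off-axis (range ",
            min(wavenumber), "-", max(wavenumber), ")")
  idx
}

#' Write / read a spectra set as CSV
#'
#' Wide dialect: first column `wavenumber_cm1`, one column per sample id.
#' Concentrations and metadata go to a companion file `<stem>_conc.csv`
#' keyed by `sample_id` with `replicate`, `batch` and one ppm column per
#' analyte. Reading a file with a descending axis re-sorts it ascending with
#' a warning; missing intensity cells are rejected naming the sample and
#' wavenumber.
#'
#' @param set a `spectra_set`.
#' @param path path to the spectra CSV.
#' @return `write_spectra_csv` returns `path` invisibly; `read_spectra_csv`
#'   returns a `spectra_set`.
#' @export
write_spectra_csv <- function(set, path) {
  stopifnot(inherits(set, "spectra_set"))
  df <- data.frame(wavenumber_cm1 = set$wavenumber,
                   t(set$spectra), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  comp <- companion_path(path)
  meta <- set$metadata
  if (!is.null(set$concentrations)) meta <- cbind(meta, set$concentrations)
  utils::write.csv(meta, comp, row.names = FALSE)
  invisible(path)
}

companion_path <- function(path) sub("(\\.[Cc][Ss][Vv])?$", "_conc.csv",
                                     path)

#' @rdname write_spectra_csv
#' @export
read_spectra_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "wavenumber_cm1")
    stop_sq("first column must be 'wavenumber_cm1', got '", names(df)[1], "'")
  wn <- df[[1]]
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (is.unsorted(wn)) {
    if (is.unsorted(rev(wn)))
      stop_sq("wavenumber column is neither ascending nor descending")
    warning("descending wavenumber axis re-sorted ascending")
    o <- order(wn)
    wn <- wn[o]; mat <- mat[o, , drop = FALSE]
  }
  if (anyNA(mat)) {
    bad <- which(is.na(mat), arr.ind = TRUE)[1, ]
    stop_sq("missing intensity for sample '", colnames(mat)[bad[2]],
            "' at ", wn[bad[1]], " cm-1")
  }
  spectra <- t(mat)
  comp <- companion_path(path)
  conc <- NULL
  meta <- data.frame(sample_id = rownames(spectra), replicate = 1L,
                     batch = "batch1", stringsAsFactors = FALSE)
  if (file.exists(comp)) {
    cm <- utils::read.csv(comp, stringsAsFactors = FALSE)
    if (!"sample_id" %in% names(cm))
      stop_sq("companion file lacks a sample_id column")
    cm <- cm[match(rownames(spectra), cm$sample_id), , drop = FALSE]
    meta_cols <- intersect(c("sample_id", "replicate", "batch"), names(cm))
    meta <- cm[, meta_cols, drop = FALSE]
    if (!"replicate" %in% names(meta)) meta$replicate <- 1L
    if (!"batch" %in% names(meta)) meta$batch <- "batch1"
    analyte_cols <- setdiff(names(cm), c("sample_id", "replicate", "batch"))
    if (length(analyte_cols)) conc <- cm[, analyte_cols, drop = FALSE]
  }
  spectra_set(wn, spectra, conc, meta)
}
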