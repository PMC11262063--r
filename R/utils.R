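# internal helpers

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so simulation functions are deterministic
#' under their own seed without disturbing the caller's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# derive a stage seed from a root seed; keeps results < 2^31 and distinct
# per stage label
stage_seed <- function(root, stage) {
  stopifnot(is.numeric(root), length(root) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(root) * 7919 + h * 104729) %% 2147483647)
}

stop_sq <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

check_finite <- function(x, what) {
  if (!all(is.finite(x))) stop_sq(what, " contains non-finite values")
  invisible(x)
}
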