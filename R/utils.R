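# Internal helpers shared across modules.

#' Evaluate code under a fixed RNG seed without disturbing the caller's stream
#'
#' All generators in the package are pure functions of their arguments plus a
#' `seed`; this wrapper guarantees that by saving and restoring
#' `.Random.seed`.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  code
}

# Symmetric PSD check: min eigenvalue >= -1e-10 * max eigenvalue.
is_psd <- function(m, tol_factor = 1e-10) {
  ev <- eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values
  min(ev) >= -tol_factor * max(abs(ev))
}

assert_psd <- function(m, what = "covariance") {
  if (!is_psd(m)) {
    stop(sprintf("%s matrix is not positive semi-definite", what),
         call. = FALSE)
  }
  invisible(TRUE)
}

# Derive a 31-bit child seed from (seed, index) so that per-subject draws are
# independent but reproducible.
child_seed <- function(seed, index) {
  (as.integer(seed) %% 1000000L) * 2001L + 7L * as.integer(index) %% 2147483647L
}

# Stack a list of per-subject vectors (strength / plfcs / suvr objects or
# plain named numerics) into a subjects x regions matrix.
stack_values <- function(vectors) {
  vals <- lapply(vectors, function(v) if (is.list(v)) v$values else v)
  ids <- vapply(seq_along(vectors), function(i) {
    v <- vectors[[i]]
    if (is.list(v) && !is.null(v$subject_id)) v$subject_id else paste0("s", i)
  }, character(1))
  m <- do.call(rbind, vals)
  rownames(m) <- ids
  m
}

clip <- function(x, lo, hi) pmin(hi, pmax(lo, x))

stop_if_labels_differ <- function(a, b, what = "region labels") {
  if (length(a) != length(b) || any(a != b)) {
    stop(sprintf("%s do not match between inputs", what), call. = FALSE)
  }
  invisible(TRUE)
}
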