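# Association matrices and weighted node strength.

new_connectivity_matrix <- function(values, scale, region_labels,
                                    subject_id) {
  if (max(abs(values - t(values))) > 1e-12) {
    stop("connectivity matrix must be symmetric", call. = FALSE)
  }
  dimnames(values) <- list(as.character(region_labels),
                           as.character(region_labels))
  structure(list(values = values, scale = scale,
                 region_labels = as.integer(region_labels),
                 subject_id = subject_id),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("connectivity_matrix: subject %s, %d x %d, scale %s\n",
              x$subject_id, nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

#' Pearson association matrix of a parcellated time series
#'
#' Entry (i, j) is the Pearson correlation between the region-i and region-j
#' signals over the full scan; the diagonal is stored as 0 by convention
#' (self-connections are excluded from strength, and Fisher z of r = 1 is
#' infinite).
#'
#' @param ts a `parcellated_ts` with at least 3 timepoints.
#' @return a `connectivity_matrix` on the `pearson_r` scale.
#' @export
correlation_matrix <- function(ts) {
  stopifnot(inherits(ts, "parcellated_ts"))
  if (nrow(ts$data) < 3) stop("need at least 3 timepoints", call. = FALSE)
  v <- apply(ts$data, 2, stats::var)
  if (any(v == 0)) {
    stop(sprintf("zero-variance region(s): %s",
                 paste(ts$region_labels[v == 0], collapse = ", ")),
         call. = FALSE)
  }
  r <- stats::cor(ts$data)
  r <- (r + t(r)) / 2
  diag(r) <- 0
  new_connectivity_matrix(r, "pearson_r", ts$region_labels, ts$subject_id)
}

#' Fisher z-transform of a correlation matrix
#'
#' Applies `z = arctanh(r)` to every off-diagonal entry; the diagonal stays
#' 0.
#'
#' @param m a `connectivity_matrix` on the `pearson_r` scale with all
#'   off-diagonal `|r| < 1`.
#' @return a `connectivity_matrix` on the `fisher_z` scale.
#' @export
fisher_z <- function(m) {
  stopifnot(inherits(m, "connectivity_matrix"))
  if (m$scale != "pearson_r") {
    stop("fisher_z expects a pearson_r-scale matrix", call. = FALSE)
  }
  v <- m$values
  bad <- which(abs(v) >= 1 & row(v) != col(v), arr.ind = TRUE)
  if (nrow(bad)) {
    p <- bad[1, ]
    stop(sprintf(
      "|r| >= 1 between regions %s and %s; jitter the data or exclude the pair",
      m$region_labels[p[1]], m$region_labels[p[2]]), call. = FALSE)
  }
  z <- atanh(v)
  diag(z) <- 0
  new_connectivity_matrix(z, "fisher_z", m$region_labels, m$subject_id)
}

#' Weighted node strength (sum of absolute connection weights)
#'
#' `mu_i = sum_{j != i} |m_ij|`: each node's connection strength is the sum
#' of the absolute association values between it and every other node.
#'
#' @param m a `connectivity_matrix`.
#' @return a `strength_vector` (level `subject`) carrying the scale the
#'   matrix was on.
#' @export
node_strength <- function(m) {
  stopifnot(inherits(m, "connectivity_matrix"))
  v <- m$values
  diag(v) <- 0
  structure(list(values = stats::setNames(rowSums(abs(v)),
                                          as.character(m$region_labels)),
                 level = "subject", scale = m$scale,
                 region_labels = m$region_labels,
                 subject_id = m$subject_id),
            class = "strength_vector")
}

#' Group-average node strength
#'
#' Element-wise mean of per-subject strength vectors sharing labels and
#' scale; this defines a diagnostic group's connection strength per node.
#'
#' @param vectors list of `strength_vector`s (level `subject`).
#' @param group name recorded on the result.
#' @return a `strength_vector` with level `group_mean`.
#' @export
group_mean_strength <- function(vectors, group = "group") {
  stopifnot(length(vectors) >= 1,
            all(vapply(vectors, inherits, TRUE, "strength_vector")))
  ref <- vectors[[1]]
  for (v in vectors[-1]) {
    stop_if_labels_differ(v$region_labels, ref$region_labels)
    if (v$scale != ref$scale) {
      stop("strength vectors mix pearson_r and fisher_z scales", call. = FALSE)
    }
  }
  structure(list(values = colMeans(stack_values(vectors)),
                 level = "group_mean", scale = ref$scale,
                 region_labels = ref$region_labels, subject_id = group,
                 n_subjects = length(vectors)),
            class = "strength_vector")
}

#' @export
print.strength_vector <- function(x, ...) {
  cat(sprintf("strength_vector (%s, %s scale): %d nodes, mean %.4g\n",
              x$level, x$scale, length(x$values), mean(x$values)))
  invisible(x)
}
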