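# Semi-quantitative ROI PET analysis: standardized uptake value ratios
# against a reference-region mean (entire cerebellum in the intended use;
# the 246-region atlas excludes cerebellum, so the reference is a separate
# mask, not an atlas label).

#' Regional SUVR from region means and a reference-region mean
#'
#' `SUVR_k = region_mean_k / reference_mean`; invariant to any global
#' multiplicative rescaling of the PET volume (dose/decay normalisation).
#'
#' @param region_means named numeric vector of per-region mean uptake, in
#'   canonical atlas order.
#' @param reference_mean mean uptake over the reference-region mask (> 0).
#' @param subject_id identifier.
#' @param reference_region name recorded on the result.
#' @return object of class `suvr_vector`.
#' @export
compute_suvr <- function(region_means, reference_mean,
                         subject_id = "subject",
                         reference_region = "cerebellum") {
  if (!is.numeric(reference_mean) || length(reference_mean) != 1 ||
      reference_mean <= 0) {
    stop("reference_mean must be a positive scalar", call. = FALSE)
  }
  labels <- if (!is.null(names(region_means))) {
    suppressWarnings(as.integer(names(region_means)))
  } else {
    seq_along(region_means)
  }
  if (any(is.na(labels))) labels <- seq_along(region_means)
  structure(list(values = stats::setNames(region_means / reference_mean,
                                          as.character(labels)),
                 subject_id = subject_id, level = "subject",
                 reference_region = reference_region,
                 region_labels = labels),
            class = "suvr_vector")
}

#' Group-average SUVR
#'
#' @param vectors list of `suvr_vector`s sharing labels and reference
#'   region.
#' @param group name recorded on the result.
#' @return a `suvr_vector` with level `group_mean`.
#' @export
group_mean_suvr <- function(vectors, group = "group") {
  stopifnot(length(vectors) >= 1,
            all(vapply(vectors, inherits, TRUE, "suvr_vector")))
  ref <- vectors[[1]]
  for (v in vectors[-1]) {
    stop_if_labels_differ(v$region_labels, ref$region_labels)
    if (!identical(v$reference_region, ref$reference_region)) {
      stop("SUVR vectors mix reference regions", call. = FALSE)
    }
  }
  structure(list(values = colMeans(stack_values(vectors)),
                 subject_id = group, level = "group_mean",
                 reference_region = ref$reference_region,
                 region_labels = ref$region_labels,
                 n_subjects = length(vectors)),
            class = "suvr_vector")
}

#' Scalar global SUVR: the region-average of one SUVR vector
#'
#' @param x an `suvr_vector`.
#' @return scalar mean over regions.
#' @export
global_suvr <- function(x) {
  stopifnot(inherits(x, "suvr_vector"))
  mean(x$values)
}

#' @export
print.suvr_vector <- function(x, ...) {
  cat(sprintf("suvr_vector (%s, ref %s): %d regions, global %.4g\n",
              x$level, x$reference_region, length(x$values),
              mean(x$values)))
  invisible(x)
}
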