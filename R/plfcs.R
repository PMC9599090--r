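# Proportional loss of functional connectivity strength relative to a
# normal-control baseline:  Loss_i = (mu_i - sigma) / sigma.

#' Baseline connection-strength reference from the control group
#'
#' `global_scalar` (the default, matching the printed definition): sigma is
#' the average, over nodes, of the control group's group-mean node
#' strengths.  `per_node`: sigma_i is the control group-mean strength of
#' node i, making the loss a node-wise proportional change.
#'
#' @param nc_group_strength a `strength_vector` with level `group_mean`.
#' @param variant `"global_scalar"` or `"per_node"`.
#' @return object of class `baseline_sigma`.
#' @export
baseline_sigma <- function(nc_group_strength,
                           variant = c("global_scalar", "per_node")) {
  variant <- match.arg(variant)
  stopifnot(inherits(nc_group_strength, "strength_vector"))
  if (nc_group_strength$level != "group_mean") {
    stop("baseline must be built from a group_mean strength vector",
         call. = FALSE)
  }
  v <- nc_group_strength$values
  if (any(v < 0)) stop("strengths must be >= 0", call. = FALSE)
  if (all(v == 0)) {
    stop("baseline strengths are all zero; sigma would be 0", call. = FALSE)
  }
  if (variant == "per_node" && any(v == 0)) {
    stop(sprintf("per_node baseline has zero strength at node(s) %s",
                 paste(nc_group_strength$region_labels[v == 0],
                       collapse = ", ")), call. = FALSE)
  }
  structure(list(
    sigma = if (variant == "global_scalar") mean(v) else v,
    variant = variant,
    source_group = nc_group_strength$subject_id,
    n_baseline_subjects = nc_group_strength$n_subjects,
    scale = nc_group_strength$scale,
    region_labels = nc_group_strength$region_labels
  ), class = "baseline_sigma")
}

#' Per-node proportional loss of connection strength
#'
#' Computes `Loss_i = (mu_i - sigma) / sigma` (global-scalar baseline) or
#' `(mu_i - sigma_i) / sigma_i` (per-node baseline).  The default sign
#' convention follows the printed formula: positive values mean strength
#' above the baseline reference.  `sign = "inverted"` computes
#' `(sigma - mu_i) / sigma` so that loss of strength is positive.
#'
#' @param subject_strength a `strength_vector` on the same scale as the
#'   baseline.
#' @param baseline a `baseline_sigma`.
#' @param sign `"printed"` (default) or `"inverted"`.
#' @return object of class `plfcs_vector`.
#' @export
compute_plfcs <- function(subject_strength, baseline,
                          sign = c("printed", "inverted")) {
  sign <- match.arg(sign)
  stopifnot(inherits(subject_strength, "strength_vector"),
            inherits(baseline, "baseline_sigma"))
  if (subject_strength$scale != baseline$scale) {
    stop(sprintf("scale mismatch: strengths are %s but baseline is %s",
                 subject_strength$scale, baseline$scale), call. = FALSE)
  }
  stop_if_labels_differ(subject_strength$region_labels,
                        baseline$region_labels)
  loss <- (subject_strength$values - baseline$sigma) / baseline$sigma
  if (sign == "inverted") loss <- -loss
  structure(list(values = loss,
                 level = subject_strength$level,
                 subject_id = subject_strength$subject_id,
                 baseline = baseline, sign = sign,
                 region_labels = subject_strength$region_labels),
            class = "plfcs_vector")
}

#' Group-average proportional loss
#'
#' Element-wise mean of per-subject loss vectors that share one baseline
#' reference and sign convention.
#'
#' @param vectors list of `plfcs_vector`s.
#' @param group name recorded on the result.
#' @return a `plfcs_vector` with level `group_mean`.
#' @export
group_mean_plfcs <- function(vectors, group = "group") {
  stopifnot(length(vectors) >= 1,
            all(vapply(vectors, inherits, TRUE, "plfcs_vector")))
  ref <- vectors[[1]]
  for (v in vectors[-1]) {
    stop_if_labels_differ(v$region_labels, ref$region_labels)
    same <- identical(v$baseline$variant, ref$baseline$variant) &&
      identical(v$baseline$sigma, ref$baseline$sigma) &&
      identical(v$sign, ref$sign)
    if (!same) stop("loss vectors mix baselines or sign conventions",
                    call. = FALSE)
  }
  structure(list(values = colMeans(stack_values(vectors)),
                 level = "group_mean", subject_id = group,
                 baseline = ref$baseline, sign = ref$sign,
                 region_labels = ref$region_labels,
                 n_subjects = length(vectors)),
            class = "plfcs_vector")
}

#' Scalar global loss: the node-average of one loss vector
#'
#' @param x a `plfcs_vector`.
#' @return scalar mean over nodes.
#' @export
global_plfcs <- function(x) {
  stopifnot(inherits(x, "plfcs_vector"))
  mean(x$values)
}

#' @export
print.plfcs_vector <- function(x, ...) {
  cat(sprintf(
    "plfcs_vector (%s, %s baseline, %s sign): %d nodes, global %.4g\n",
    x$level, x$baseline$variant, x$sign, length(x$values), mean(x$values)))
  invisible(x)
}
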