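# Region-wise group comparison, permutation node selection, cross-modal and
# clinical correlation, hub-vulnerability analysis, and three-group ANOVA
# with Bonferroni post hoc.

# Accept either a subjects x regions matrix or a list of per-subject
# vector objects (plfcs_vector / strength_vector / suvr_vector).
as_region_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  if (is.list(x) && length(x) && is.list(x[[1]])) return(stack_values(x))
  stop("expected a subjects x regions matrix or a list of per-subject vectors",
       call. = FALSE)
}

region_names_of <- function(m) {
  if (is.null(colnames(m))) as.character(seq_len(ncol(m))) else colnames(m)
}

#' Region-wise two-sample t-test
#'
#' One two-sided two-sample t-test per region between the two groups;
#' regions with `p < alpha` are flagged as selected (potential biomarkers).
#' No multiplicity correction is applied to the selection (mirroring the
#' uncorrected p < 0.05 biomarker screen); Benjamini-Hochberg q-values are
#' reported alongside as a labelled extension.
#'
#' @param group_a,group_b subjects x regions matrices (or lists of
#'   per-subject vectors) with at least 2 subjects each.
#' @param alpha selection threshold on the uncorrected p-value.
#' @param var_equal pooled-variance t-test when TRUE (default); Welch
#'   otherwise.
#' @return data.frame with columns `region`, `t`, `df`, `p`, `q_bh`,
#'   `significant`, `degenerate`.  A region where both groups are constant
#'   gets `t = 0, p = 1` when the means agree and is otherwise marked
#'   `degenerate` (p = NA, never silent NaN).
#' @export
region_ttest <- function(group_a, group_b, alpha = 0.05, var_equal = TRUE) {
  a <- as_region_matrix(group_a)
  b <- as_region_matrix(group_b)
  if (ncol(a) != ncol(b)) stop("region counts differ", call. = FALSE)
  na <- nrow(a); nb <- nrow(b)
  if (na < 2 || nb < 2) stop("need >= 2 subjects per group", call. = FALSE)
  ma <- colMeans(a); mb <- colMeans(b)
  va <- apply(a, 2, stats::var); vb <- apply(b, 2, stats::var)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, ncol(a))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  tstat <- (ma - mb) / se
  p <- 2 * stats::pt(-abs(tstat), df)
  degenerate <- se == 0 & ma != mb
  zero_same <- se == 0 & ma == mb
  tstat[zero_same] <- 0
  p[zero_same] <- 1
  tstat[degenerate] <- sign(ma - mb)[degenerate] * Inf
  p[degenerate] <- NA_real_
  ok <- !is.na(p)
  q <- rep(NA_real_, length(p))
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  data.frame(region = region_names_of(a), t = tstat, df = df, p = p,
             q_bh = q, significant = !is.na(p) & p < alpha,
             degenerate = degenerate, row.names = NULL)
}

#' Region-wise permutation test on the difference of group means
#'
#' Subject labels are permuted jointly across regions; the statistic is the
#' absolute difference of group means per region.  Monte-Carlo p-values use
#' the add-one estimator `(1 + #{|d_perm| >= |d_obs|}) / (1 + B)`.  When the
#' number of distinct label splits `choose(n, n_a)` does not exceed
#' `n_permutations`, all splits are enumerated and the exact enumeration
#' p-value `#{|d_perm| >= |d_obs|} / n_splits` is returned instead.
#'
#' @inheritParams region_ttest
#' @param n_permutations Monte-Carlo draws (>= 100).
#' @param seed RNG seed for the label shuffles.
#' @return data.frame with `region`, `delta_obs`, `permutation_p`,
#'   `exhaustive` (logical), `n_permutations`.
#' @export
region_permutation_test <- function(group_a, group_b,
                                    n_permutations = 1000L, seed = 1L,
                                    alpha = 0.05) {
  a <- as_region_matrix(group_a)
  b <- as_region_matrix(group_b)
  if (ncol(a) != ncol(b)) stop("region counts differ", call. = FALSE)
  na <- nrow(a); nb <- nrow(b)
  if (na < 2 || nb < 2) stop("need >= 2 subjects per group", call. = FALSE)
  if (n_permutations < 100) stop("n_permutations must be >= 100",
                                 call. = FALSE)
  x <- rbind(a, b)
  n <- na + nb
  d_obs <- abs(colMeans(a) - colMeans(b))
  tol <- 1e-12
  n_splits <- choose(n, na)
  delta_for <- function(idx_a) {
    abs(colMeans(x[idx_a, , drop = FALSE]) -
          colMeans(x[-idx_a, , drop = FALSE]))
  }
  if (n_splits <= n_permutations) {
    splits <- utils::combn(n, na)
    count <- integer(ncol(a))
    for (s in seq_len(ncol(splits))) {
      count <- count + (delta_for(splits[, s]) >= d_obs - tol)
    }
    p <- count / n_splits
    exhaustive <- TRUE
    used <- n_splits
  } else {
    count <- integer(ncol(a))
    with_seed(seed, {
      for (s in seq_len(n_permutations)) {
        count <- count + (delta_for(sample.int(n, na)) >= d_obs - tol)
      }
    })
    p <- (1 + count) / (1 + n_permutations)
    exhaustive <- FALSE
    used <- n_permutations
  }
  data.frame(region = region_names_of(a), delta_obs = d_obs,
             permutation_p = p, significant = p < alpha,
             exhaustive = exhaustive, n_permutations = used,
             row.names = NULL)
}

# Pearson r and two-sided p for one pair of vectors, with a degenerate
# marker instead of silent NaN when either side is constant.
pearson_rp <- function(x, y) {
  if (length(x) < 3) stop("need n >= 3 for a correlation", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, degenerate = TRUE))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, degenerate = FALSE)
}

#' Region-wise cross-modal Pearson correlation (connectivity metric vs SUVR)
#'
#' For each selected region, correlates subjects' metric values (node
#' strength or proportional loss) with their tau SUVR within one diagnostic
#' group.
#'
#' @param metric_table subjects x regions matrix of FCs or loss values.
#' @param suvr_table subjects x regions matrix of SUVR; identical subject
#'   set (row order) as `metric_table`.
#' @param regions character or integer vector of region columns to analyse
#'   (default: all).
#' @param group label recorded in the output.
#' @return data.frame with `region`, `group`, `n`, `r`, `p`, `degenerate`.
#' @export
crossmodal_correlation <- function(metric_table, suvr_table, regions = NULL,
                                   group = NA_character_) {
  m <- as_region_matrix(metric_table)
  s <- as_region_matrix(suvr_table)
  if (nrow(m) != nrow(s)) stop("subject sets differ between tables",
                               call. = FALSE)
  if (nrow(m) < 3) stop("need >= 3 subjects", call. = FALSE)
  all_regions <- region_names_of(m)
  colnames(m) <- all_regions
  colnames(s) <- region_names_of(s)
  if (is.null(regions)) regions <- all_regions
  regions <- as.character(regions)
  if (!all(regions %in% all_regions)) {
    stop("requested regions not present in the metric table", call. = FALSE)
  }
  out <- lapply(regions, function(rg) {
    res <- pearson_rp(m[, rg], s[, rg])
    data.frame(region = rg, group = group, n = nrow(m), r = res$r,
               p = res$p, degenerate = res$degenerate)
  })
  do.call(rbind, out)
}

#' Hub-vulnerability correlation across regions
#'
#' Pearson correlation, over the N atlas regions, between the control
#' group's average node strength and a disease group's average proportional
#' loss.  A negative correlation means that regions with higher baseline
#' connection strength lose a larger proportion of it.
#'
#' @param nc_strength a `strength_vector` with level `group_mean`
#'   (conventionally on the un-transformed `pearson_r` scale).
#' @param disease_plfcs a `plfcs_vector` with level `group_mean`.
#' @return list with `r`, `p`, `n_regions`, and the scales/variants used.
#' @export
hub_vulnerability <- function(nc_strength, disease_plfcs) {
  stopifnot(inherits(nc_strength, "strength_vector"),
            inherits(disease_plfcs, "plfcs_vector"))
  stop_if_labels_differ(nc_strength$region_labels,
                        disease_plfcs$region_labels)
  if (length(nc_strength$values) < 3) {
    stop("need at least 3 regions", call. = FALSE)
  }
  res <- pearson_rp(nc_strength$values, disease_plfcs$values)
  list(r = res$r, p = res$p, n_regions = length(nc_strength$values),
       strength_scale = nc_strength$scale,
       plfcs_variant = disease_plfcs$baseline$variant,
       plfcs_sign = disease_plfcs$sign)
}

#' Correlation of imaging metrics with clinical scales
#'
#' Pearson r and p for every (metric, score) pair, typically global
#' proportional loss / global SUVR against MMSE and CDR-SB within each
#' diagnostic group.
#'
#' @param metrics data.frame (or matrix) of per-subject metric columns.
#' @param scores data.frame of per-subject clinical score columns; same
#'   subject order.
#' @param group label recorded in the output.
#' @return data.frame with `metric`, `score`, `group`, `n`, `r`, `p`,
#'   `degenerate`.
#' @export
clinical_correlation <- function(metrics, scores, group = NA_character_) {
  metrics <- as.data.frame(metrics)
  scores <- as.data.frame(scores)
  if (nrow(metrics) != nrow(scores)) stop("subject sets differ",
                                          call. = FALSE)
  if (nrow(metrics) < 3) stop("need >= 3 subjects", call. = FALSE)
  if (!all(vapply(scores, function(x) all(is.finite(x)), TRUE))) {
    stop("clinical scores must be finite", call. = FALSE)
  }
  grid <- expand.grid(metric = names(metrics), score = names(scores),
                      stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    res <- pearson_rp(metrics[[grid$metric[i]]], scores[[grid$score[i]]])
    data.frame(metric = grid$metric[i], score = grid$score[i], group = group,
               n = nrow(metrics), r = res$r, p = res$p,
               degenerate = res$degenerate)
  })
  do.call(rbind, out)
}

#' Three-group comparison: one-way ANOVA with Bonferroni post hoc
#'
#' One-way ANOVA across the groups followed by all pairwise pooled-variance
#' t-tests with Bonferroni correction (raw pairwise p multiplied by the
#' number of pairs, capped at 1).
#'
#' @param values numeric vector of per-subject global metric values.
#' @param groups factor/character of group membership, each level with at
#'   least 2 subjects.
#' @return list with `f`, `p`, `df`, and `posthoc` (data.frame: `pair`,
#'   `p_raw`, `p_bonferroni`).
#' @export
global_group_comparison <- function(values, groups) {
  groups <- factor(groups)
  if (any(table(groups) < 2)) {
    stop("every group needs at least 2 subjects", call. = FALSE)
  }
  fit <- stats::aov(values ~ groups)
  s <- summary(fit)[[1]]
  lv <- levels(groups)
  pairs <- utils::combn(lv, 2)
  n_pairs <- ncol(pairs)
  pw <- stats::pairwise.t.test(values, groups, p.adjust.method = "none",
                               pool.sd = TRUE)
  posthoc <- do.call(rbind, lapply(seq_len(n_pairs), function(i) {
    g1 <- pairs[1, i]; g2 <- pairs[2, i]
    praw <- pw$p.value[g2, g1]
    if (is.na(praw)) praw <- pw$p.value[g1, g2]
    data.frame(pair = paste(g1, g2, sep = " vs "), p_raw = praw,
               p_bonferroni = min(1, n_pairs * praw))
  }))
  list(f = s[["F value"]][1], p = s[["Pr(>F)"]][1],
       df = c(s[["Df"]][1], s[["Df"]][2]), posthoc = posthoc)
}
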