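# End-to-end orchestration: simulate/load -> connectivity -> proportional
# loss -> SUVR -> group statistics, with a config echo, per-stage logging
# and TSV outputs.

#' Pipeline run configuration
#'
#' Every analysis variant the pipeline supports is an explicit field here
#' and is echoed verbatim into the output directory, so no output can
#' depend on a silent default.
#'
#' @param mode `"simulate"` (generate a synthetic cohort), `"tables"`
#'   (pre-parcellated TSV inputs) or `"volumes"` (NIfTI inputs).
#' @param spec a [cohort_spec()] (simulate mode).
#' @param inputs named list of paths for `tables` mode (`manifest`, `suvr`;
#'   the manifest must carry a `timeseries_path` column) or `volumes` mode
#'   (`manifest` with `func_path`/`pet_path` columns, `atlas_label`,
#'   `atlas_table`, `reference_mask`).
#' @param strength_scale matrix scale on which node strength and loss are
#'   computed: `"fisher_z"` (default) or `"pearson_r"`.  The
#'   hub-vulnerability analysis always uses the un-transformed
#'   (`pearson_r`) strengths.
#' @param plfcs_variant baseline used for node selection and global loss:
#'   `"global_scalar"` (the printed definition) or `"per_node"`.
#' @param plfcs_sign `"printed"` (loss positive when strength exceeds
#'   baseline) or `"inverted"`.
#' @param selection_test `"t"` (default) or `"permutation"` for the NC vs
#'   CI node-selection stage.
#' @param alpha selection threshold.
#' @param n_permutations permutation count when `selection_test =
#'   "permutation"`.
#' @param seed integer seed governing all randomness in the run.
#' @param out_dir output directory; `NULL` suppresses file output.
#' @return object of class `run_config`.
#' @export
run_config <- function(mode = c("simulate", "tables", "volumes"),
                       spec = NULL, inputs = NULL,
                       strength_scale = c("fisher_z", "pearson_r"),
                       plfcs_variant = c("global_scalar", "per_node"),
                       plfcs_sign = c("printed", "inverted"),
                       selection_test = c("t", "permutation"),
                       alpha = 0.05, n_permutations = 1000L, seed = 1L,
                       out_dir = NULL) {
  mode <- match.arg(mode)
  if (mode == "simulate") {
    if (is.null(spec)) spec <- cohort_spec(seed = seed)
    stopifnot(inherits(spec, "cohort_spec"))
  } else if (is.null(inputs)) {
    stop(sprintf("mode '%s' requires an inputs list", mode), call. = FALSE)
  }
  structure(list(mode = mode, spec = spec, inputs = inputs,
                 strength_scale = match.arg(strength_scale),
                 plfcs_variant = match.arg(plfcs_variant),
                 plfcs_sign = match.arg(plfcs_sign),
                 selection_test = match.arg(selection_test),
                 alpha = alpha, n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

acquire_inputs <- function(config) {
  if (config$mode == "simulate") {
    bundle <- simulate_cohort(config$spec)
    return(list(timeseries = bundle$timeseries, suvr = bundle$suvr,
                manifest = bundle$manifest, cohort = bundle))
  }
  inp <- config$inputs
  manifest <- utils::read.delim(inp$manifest, sep = "\t",
                                stringsAsFactors = FALSE)
  if (config$mode == "tables") {
    ts <- lapply(seq_len(nrow(manifest)), function(i) {
      read_timeseries_tsv(manifest$timeseries_path[i],
                          subject_id = manifest$subject_id[i])
    })
    names(ts) <- manifest$subject_id
    suvr <- as.matrix(utils::read.delim(inp$suvr, sep = "\t",
                                        row.names = 1, check.names = FALSE))
    suvr <- suvr[manifest$subject_id, , drop = FALSE]
    return(list(timeseries = ts, suvr = suvr, manifest = manifest))
  }
  # volumes mode
  atlas <- load_atlas(inp$atlas_label, inp$atlas_table)
  ts <- lapply(seq_len(nrow(manifest)), function(i) {
    extract_roi_timeseries(manifest$func_path[i], atlas,
                           subject_id = manifest$subject_id[i])
  })
  names(ts) <- manifest$subject_id
  suvr <- t(vapply(seq_len(nrow(manifest)), function(i) {
    means <- extract_roi_means(manifest$pet_path[i], atlas)
    ref <- extract_mask_mean(manifest$pet_path[i], inp$reference_mask)
    compute_suvr(means, ref, subject_id = manifest$subject_id[i])$values
  }, numeric(nrow(atlas$table))))
  rownames(suvr) <- manifest$subject_id
  list(timeseries = ts, suvr = suvr, manifest = manifest, atlas = atlas)
}

#' Run the full cross-modal analysis pipeline
#'
#' Sequences: input acquisition (simulation, tables or volume extraction);
#' per-subject Pearson association matrices with Fisher z-transform;
#' weighted node strengths on both scales; NC baseline and per-subject
#' proportional loss; NC-vs-CI node selection (t or permutation test);
#' cross-modal strength/loss vs tau-SUVR correlation within each disease
#' group over the selected regions; hub-vulnerability correlation per
#' disease group (un-transformed NC strength vs per-node proportional
#' loss); clinical-scale correlations; and three-group ANOVA of the global
#' metrics.  Deterministic given the config (including its seed).
#'
#' @param config a [run_config()].
#' @return object of class `plfcs_run` (a list of result tables); also
#'   written as TSV/JSON under `config$out_dir` when set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log <- character(0)
  note <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log <<- c(log, msg)
    message(msg)
  }

  inputs <- stage("acquire", acquire_inputs(config))
  manifest <- inputs$manifest
  groups <- manifest$group
  sids <- manifest$subject_id
  note("acquire: %d subjects (%s), mode=%s", length(sids),
       paste(sprintf("%s=%d", names(table(groups)), table(groups)),
             collapse = ", "), config$mode)

  conn <- stage("connect", {
    lapply(inputs$timeseries, function(ts) {
      r <- correlation_matrix(ts)
      list(pearson_r = r, fisher_z = fisher_z(r))
    })
  })
  strengths <- stage("strength", {
    list(pearson_r = lapply(conn, function(m) node_strength(m$pearson_r)),
         fisher_z = lapply(conn, function(m) node_strength(m$fisher_z)))
  })
  note("connect: %d association matrices, %d regions",
       length(conn), length(strengths$pearson_r[[1]]$values))

  nc_ids <- sids[groups == "NC"]
  if (length(nc_ids) < 1) stop("stage 'baseline' failed: no NC subjects",
                               call. = FALSE)
  res <- stage("plfcs", {
    nc_strength <- lapply(c(pearson_r = "pearson_r", fisher_z = "fisher_z"),
                          function(sc) {
                            group_mean_strength(strengths[[sc]][nc_ids],
                                                group = "NC")
                          })
    sigma_sel <- baseline_sigma(nc_strength[[config$strength_scale]],
                                variant = config$plfcs_variant)
    sigma_hub <- baseline_sigma(nc_strength$pearson_r, variant = "per_node")
    plfcs_sel <- lapply(strengths[[config$strength_scale]], compute_plfcs,
                        baseline = sigma_sel, sign = config$plfcs_sign)
    plfcs_hub <- lapply(strengths$pearson_r, compute_plfcs,
                        baseline = sigma_hub, sign = config$plfcs_sign)
    list(nc_strength = nc_strength, sigma_sel = sigma_sel,
         sigma_hub = sigma_hub, plfcs_sel = plfcs_sel,
         plfcs_hub = plfcs_hub)
  })
  note("plfcs: baseline sigma (%s, %s scale) from %d NC subjects",
       config$plfcs_variant, config$strength_scale, length(nc_ids))

  suvr_mat <- inputs$suvr
  plfcs_mat <- stack_values(res$plfcs_sel)
  strength_mat <- stack_values(strengths[[config$strength_scale]])
  global_metrics <- data.frame(
    subject_id = sids, group = groups,
    global_fcs = rowMeans(strength_mat[sids, , drop = FALSE]),
    global_plfcs = rowMeans(plfcs_mat[sids, , drop = FALSE]),
    global_suvr = rowMeans(suvr_mat[sids, , drop = FALSE]))
  if (all(c("mmse", "cdr_sb") %in% names(manifest))) {
    global_metrics$mmse <- manifest$mmse
    global_metrics$cdr_sb <- manifest$cdr_sb
  }

  ci_ids <- sids[groups %in% c("MCI", "AD")]
  selection <- stage("select", {
    if (length(ci_ids) < 2) stop("need >= 2 CI subjects", call. = FALSE)
    ttab <- region_ttest(plfcs_mat[nc_ids, , drop = FALSE],
                         plfcs_mat[ci_ids, , drop = FALSE],
                         alpha = config$alpha)
    if (config$selection_test == "permutation") {
      ptab <- region_permutation_test(plfcs_mat[nc_ids, , drop = FALSE],
                                      plfcs_mat[ci_ids, , drop = FALSE],
                                      n_permutations = config$n_permutations,
                                      seed = config$seed,
                                      alpha = config$alpha)
      ttab$permutation_p <- ptab$permutation_p
      ttab$significant <- ptab$significant
    }
    ttab
  })
  selected <- selection$region[selection$significant]
  note("select: %d of %d regions at p < %g (%s test)",
       length(selected), nrow(selection), config$alpha,
       config$selection_test)

  crossmodal <- stage("crossmodal", {
    if (!length(selected)) {
      data.frame(region = character(0), group = character(0),
                 n = integer(0), r_fcs_tau = numeric(0),
                 p_fcs_tau = numeric(0), r_plfcs_tau = numeric(0),
                 p_plfcs_tau = numeric(0))
    } else {
      do.call(rbind, lapply(c("MCI", "AD"), function(g) {
        ids <- sids[groups == g]
        if (length(ids) < 3) return(NULL)
        fcs <- crossmodal_correlation(strength_mat[ids, , drop = FALSE],
                                      suvr_mat[ids, , drop = FALSE],
                                      regions = selected, group = g)
        pls <- crossmodal_correlation(plfcs_mat[ids, , drop = FALSE],
                                      suvr_mat[ids, , drop = FALSE],
                                      regions = selected, group = g)
        data.frame(region = fcs$region, group = g, n = fcs$n,
                   r_fcs_tau = fcs$r, p_fcs_tau = fcs$p,
                   r_plfcs_tau = pls$r, p_plfcs_tau = pls$p)
      }))
    }
  })

  hub <- stage("hub_vulnerability", {
    do.call(rbind, lapply(c("MCI", "AD"), function(g) {
      ids <- sids[groups == g]
      if (length(ids) < 1) return(NULL)
      gm <- group_mean_plfcs(res$plfcs_hub[ids], group = g)
      hv <- hub_vulnerability(res$nc_strength$pearson_r, gm)
      data.frame(group = g, r = hv$r, p = hv$p, n_regions = hv$n_regions,
                 strength_scale = hv$strength_scale,
                 plfcs_variant = hv$plfcs_variant,
                 plfcs_sign = hv$plfcs_sign)
    }))
  })
  note("hub_vulnerability: %s",
       paste(sprintf("%s r=%.3f", hub$group, hub$r), collapse = ", "))

  clinical <- stage("clinical", {
    if (!all(c("mmse", "cdr_sb") %in% names(global_metrics))) {
      NULL
    } else {
      do.call(rbind, lapply(c("MCI", "AD"), function(g) {
        sel <- global_metrics$group == g
        if (sum(sel) < 3) return(NULL)
        clinical_correlation(
          global_metrics[sel, c("global_plfcs", "global_suvr")],
          global_metrics[sel, c("mmse", "cdr_sb")], group = g)
      }))
    }
  })

  comparison <- stage("group_comparison", {
    do.call(rbind, lapply(c("global_fcs", "global_plfcs", "global_suvr"),
                          function(metric) {
      gc <- global_group_comparison(global_metrics[[metric]],
                                    global_metrics$group)
      out <- data.frame(metric = metric, f = gc$f, p = gc$p)
      for (i in seq_len(nrow(gc$posthoc))) {
        out[[paste0("p_", gsub(" vs ", "_", gc$posthoc$pair[i]))]] <-
          gc$posthoc$p_bonferroni[i]
      }
      out
    }))
  })

  run <- structure(list(
    config = config, manifest = manifest,
    global_metrics = global_metrics,
    nc_strength = res$nc_strength,
    baseline = list(selection = res$sigma_sel, hub = res$sigma_hub),
    strength = strength_mat, plfcs = plfcs_mat, suvr = suvr_mat,
    selection = selection, selected_regions = selected,
    crossmodal = crossmodal, hub_vulnerability = hub,
    clinical = clinical, group_comparison = comparison,
    designed = if (!is.null(inputs$cohort)) inputs$cohort$designed else NULL,
    log = log
  ), class = "plfcs_run")

  if (!is.null(config$out_dir)) write_run(run, config$out_dir)
  run
}

config_echo <- function(config) {
  e <- unclass(config)
  e$out_dir <- NULL
  if (!is.null(e$spec)) e$spec <- unclass(e$spec)
  e
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, name, rownames = FALSE) {
    utils::write.table(x, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = rownames,
                       col.names = if (rownames) NA else TRUE)
  }
  wt(run$global_metrics, "global_metrics.tsv")
  wt(run$selection, "node_selection.tsv")
  wt(run$crossmodal, "crossmodal.tsv")
  wt(run$hub_vulnerability, "hub_vulnerability.tsv")
  if (!is.null(run$clinical)) wt(run$clinical, "clinical_correlation.tsv")
  wt(run$group_comparison, "group_comparison.tsv")
  wt(as.data.frame(run$plfcs), "plfcs_subjects.tsv", rownames = TRUE)
  wt(as.data.frame(run$suvr), "suvr_subjects.tsv", rownames = TRUE)
  wt(data.frame(region = colnames(run$strength),
                strength_pearson_r = run$nc_strength$pearson_r$values,
                strength_fisher_z = run$nc_strength$fisher_z$values),
     "nc_mean_strength.tsv")
  jsonlite::write_json(
    list(variant = run$baseline$selection$variant,
         scale = run$baseline$selection$scale,
         source_group = run$baseline$selection$source_group,
         sigma = run$baseline$selection$sigma),
    file.path(out_dir, "baseline_sigma.json"), auto_unbox = TRUE,
    digits = NA)
  jsonlite::write_json(config_echo(run$config),
                       file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  writeLines(run$log, file.path(out_dir, "run_log.txt"))
  writeLines(make_report(run), file.path(out_dir, "report.md"))
  invisible(out_dir)
}

#' Reload the summary tables of a finished run from its output directory
#'
#' Returns a bundle sufficient to regenerate the run report.
#'
#' @param out_dir directory written by [run_pipeline()].
#' @return a `plfcs_run`-like list of summary tables.
#' @export
read_run <- function(out_dir) {
  rd <- function(name) {
    utils::read.delim(file.path(out_dir, name), sep = "\t",
                      stringsAsFactors = FALSE)
  }
  structure(list(global_metrics = rd("global_metrics.tsv"),
                 selection = rd("node_selection.tsv"),
                 crossmodal = rd("crossmodal.tsv"),
                 hub_vulnerability = rd("hub_vulnerability.tsv"),
                 group_comparison = rd("group_comparison.tsv")),
            class = "plfcs_run")
}

#' Human-readable summary report of a pipeline run
#'
#' @param run a `plfcs_run` (from [run_pipeline()] or [read_run()]).
#' @return character vector of markdown lines.
#' @export
make_report <- function(run) {
  needed <- c("global_metrics", "selection", "crossmodal",
              "hub_vulnerability")
  missing <- needed[!vapply(needed, function(n) !is.null(run[[n]]), TRUE)]
  if (length(missing)) {
    stop(sprintf("incomplete result bundle: missing %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  gm <- run$global_metrics
  fmt4 <- function(x) sub("^-(0\\.0{4})$", "\\1", sprintf("%.4f", x))
  lines <- c("# Cross-modal connectivity-loss analysis report", "",
             "## Group means of global metrics", "")
  for (g in unique(gm$group)) {
    sel <- gm$group == g
    lines <- c(lines, sprintf(
      "- %s (n=%d): FCs %s, PLFCS %s, SUVR %s", g, sum(sel),
      fmt4(mean(gm$global_fcs[sel])), fmt4(mean(gm$global_plfcs[sel])),
      fmt4(mean(gm$global_suvr[sel]))))
  }
  n_sel <- sum(run$selection$significant)
  lines <- c(lines, "", "## Node selection (NC vs CI)", "",
             sprintf("- %d of %d regions selected", n_sel,
                     nrow(run$selection)))
  lines <- c(lines, "", "## Cross-modal correlations (selected regions)", "")
  cm <- run$crossmodal
  sig <- cm[!is.na(cm$p_plfcs_tau) & cm$p_plfcs_tau < 0.05, , drop = FALSE]
  if (nrow(sig) == 0) {
    lines <- c(lines,
               "- no regions with significant loss-tau correlation")
  } else {
    lines <- c(lines, sprintf(
      "- region %s (%s): PLFCS-tau r = %.4f, p = %.4f", sig$region,
      sig$group, sig$r_plfcs_tau, sig$p_plfcs_tau))
  }
  lines <- c(lines, "", "## Hub vulnerability", "")
  hv <- run$hub_vulnerability
  lines <- c(lines, sprintf(
    "- %s: r = %.4f, p = %.3g over %d regions", hv$group, hv$r, hv$p,
    hv$n_regions))
  lines
}

#' @export
print.plfcs_run <- function(x, ...) {
  cat(paste(make_report(x), collapse = "\n"), "\n")
  invisible(x)
}
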