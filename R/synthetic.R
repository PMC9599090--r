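# Synthetic cohort generator: ground-truth hub networks, hub-proportional
# attenuation in disease groups, coupled regional tau SUVR and clinical
# scores.  Exists so the whole downstream pipeline can be validated without
# access to patient scans.

#' Specify a synthetic cohort
#'
#' Bundles every knob of the generator.  The generative model is a
#' single-factor-plus-noise covariance whose factor loadings are raised to
#' `hub_exponent` (larger exponent = more heterogeneous hubness), with
#' disease-group covariances attenuated node-wise in proportion to baseline
#' hubness (`beta`), regional tau SUVR coupled to each subject's designed
#' proportional loss with sign `rho_region`, and MMSE/CDR-SB-like scores
#' linear in the subject's effective attenuation.
#'
#' @param n_regions number of atlas regions (nodes). Default 246.
#' @param n_subjects named integer vector, subjects per group
#'   (`NC`, `MCI`, `AD`).
#' @param n_timepoints BOLD volumes per subject.
#' @param hub_exponent non-negative; controls spread of node hubness.
#' @param beta named non-negative vector (`MCI`, `AD`): fraction of
#'   connection strength lost per unit normalised baseline hubness.
#' @param rho_region length-`n_regions` vector in [-1, 1]: sign/weight of the
#'   designed association between proportional loss and tau SUVR per region.
#'   Default: +1 for the first half of the regions, -1 for the second half.
#' @param noise_sd sd of i.i.d. observation noise added to the BOLD signal.
#' @param severity_cv coefficient of variation of the per-subject disease
#'   severity multiplier applied to `beta`.
#' @param tau_base named vector: group-level mean SUVR offset per group.
#' @param tau_coupling_scale SUVR units per unit proportional loss.
#' @param suvr_noise_sd sd of regional SUVR measurement noise.
#' @param seed integer RNG seed; the generator is a pure function of the
#'   spec including this seed.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_regions = 246L,
                        n_subjects = c(NC = 22L, MCI = 26L, AD = 36L),
                        n_timepoints = 180L,
                        hub_exponent = 2,
                        beta = c(MCI = 0.2, AD = 0.4),
                        rho_region = NULL,
                        noise_sd = 0.5,
                        severity_cv = 0.3,
                        tau_base = c(NC = 1.0, MCI = 1.05, AD = 1.25),
                        tau_coupling_scale = 1,
                        suvr_noise_sd = 0.05,
                        seed = 1L) {
  if (n_regions < 2) stop("n_regions must be >= 2", call. = FALSE)
  if (n_timepoints < 2) stop("n_timepoints must be >= 2", call. = FALSE)
  if (!all(c("NC", "MCI", "AD") %in% names(n_subjects))) {
    stop("n_subjects must name the NC, MCI and AD groups", call. = FALSE)
  }
  if (any(n_subjects < 2)) stop("all group sizes must be >= 2", call. = FALSE)
  if (hub_exponent < 0) stop("hub_exponent must be >= 0", call. = FALSE)
  if (any(beta < 0)) stop("loss coefficients beta must be >= 0", call. = FALSE)
  if (is.null(rho_region)) {
    half <- floor(n_regions / 2)
    rho_region <- c(rep(1, half), rep(-1, n_regions - half))
  }
  if (length(rho_region) != n_regions || any(abs(rho_region) > 1)) {
    stop("rho_region must have length n_regions with values in [-1, 1]",
         call. = FALSE)
  }
  if (noise_sd < 0 || suvr_noise_sd < 0) {
    stop("noise standard deviations must be >= 0", call. = FALSE)
  }
  structure(list(
    n_regions = as.integer(n_regions),
    n_subjects = n_subjects[c("NC", "MCI", "AD")],
    n_timepoints = as.integer(n_timepoints),
    hub_exponent = hub_exponent,
    beta = c(NC = 0, beta[c("MCI", "AD")]),
    rho_region = rho_region,
    noise_sd = noise_sd,
    severity_cv = severity_cv,
    tau_base = tau_base,
    tau_coupling_scale = tau_coupling_scale,
    suvr_noise_sd = suvr_noise_sd,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Generate a ground-truth hub network
#'
#' Covariance model: `Sigma = L L' + I` with a dominant loading vector
#' `u^hub_exponent` (`u ~ U(0.3, 1)`) plus a weak second factor with mixed
#' signs (so that negative correlations occur, exercising the absolute-value
#' strength definition).  Hubness is the weighted node degree (sum of
#' absolute correlations) of the implied correlation matrix.
#'
#' @inheritParams cohort_spec
#' @return `ground_truth_network`: list with `covariance` (PSD, strictly
#'   positive diagonal), `correlation`, and `hubness`.
#' @export
generate_ground_truth_network <- function(n_regions, hub_exponent = 2,
                                          seed = 1L) {
  if (n_regions < 2) stop("n_regions must be >= 2", call. = FALSE)
  if (hub_exponent < 0) stop("hub_exponent must be >= 0", call. = FALSE)
  with_seed(seed, {
    u <- stats::runif(n_regions, 0.3, 1)
    loadings <- cbind(u^hub_exponent, 0.25 * stats::runif(n_regions, -1, 1))
    covariance <- tcrossprod(loadings)
    diag(covariance) <- diag(covariance) + 1
    new_ground_truth_network(covariance)
  })
}

new_ground_truth_network <- function(covariance, attenuation = NULL) {
  if (!isTRUE(all.equal(covariance, t(covariance), tolerance = 1e-12)) ||
      any(diag(covariance) <= 0)) {
    stop("covariance must be symmetric with strictly positive diagonal",
         call. = FALSE)
  }
  correlation <- stats::cov2cor(covariance)
  diag(correlation) <- 0
  structure(list(
    covariance = covariance,
    correlation = correlation,
    hubness = rowSums(abs(correlation)),
    attenuation = attenuation
  ), class = "ground_truth_network")
}

#' Attenuate a network's connections in proportion to hubness
#'
#' Node `i`'s off-diagonal covariances are multiplied by
#' `f_i = max(0, 1 - beta * h_i)` where `h_i` is hubness normalised to its
#' maximum; entry (i, j) is scaled by `f_i * f_j`, diagonals are untouched.
#' Because `0 <= f <= 1`, the result is again positive semi-definite; this is
#' verified and violation reported with the most-attenuated node named.
#'
#' @param net a `ground_truth_network`.
#' @param beta non-negative loss coefficient.
#' @param hubness_norm optional normalised hubness vector (defaults to the
#'   network's own hubness scaled to max 1).
#' @return an attenuated `ground_truth_network` with the attenuation factors
#'   recorded in `$attenuation`.
#' @export
attenuate_network <- function(net, beta, hubness_norm = NULL) {
  stopifnot(inherits(net, "ground_truth_network"))
  if (beta < 0) stop("beta must be >= 0", call. = FALSE)
  if (is.null(hubness_norm)) hubness_norm <- net$hubness / max(net$hubness)
  f <- pmax(0, 1 - beta * hubness_norm)
  s <- outer(f, f) * net$covariance
  diag(s) <- diag(net$covariance)
  if (!is_psd(s)) {
    stop(sprintf(
      "attenuation with beta = %g makes the covariance non-PSD (node %d is attenuated most)",
      beta, which.max(beta * hubness_norm)), call. = FALSE)
  }
  new_ground_truth_network(s, attenuation = f)
}

#' Designed (noise-free) node strength of a ground-truth network
#'
#' The node strength the connectivity module would recover from infinitely
#' long noise-free time series: weighted degree of the implied correlation
#' matrix, optionally on the Fisher-z scale.
#'
#' @param net a `ground_truth_network`.
#' @param scale `"pearson_r"` or `"fisher_z"`.
#' @return numeric vector of per-node strengths.
#' @export
designed_strength <- function(net, scale = c("pearson_r", "fisher_z")) {
  scale <- match.arg(scale)
  r <- net$correlation
  if (scale == "fisher_z") r <- atanh(r)
  rowSums(abs(r))
}

#' Simulate one subject's parcellated BOLD time series
#'
#' Rows are i.i.d. draws from a zero-mean multivariate normal with the
#' network covariance, plus independent measurement noise of sd `noise_sd`.
#'
#' @param net a `ground_truth_network` (its covariance must be PSD).
#' @param n_timepoints number of rows (>= 2).
#' @param noise_sd sd of i.i.d. Gaussian noise added to every entry.
#' @param seed integer seed; output is a pure function of the arguments.
#' @param subject_id identifier carried on the result.
#' @return a `parcellated_ts`.
#' @export
simulate_subject_timeseries <- function(net, n_timepoints, noise_sd = 0,
                                        seed = 1L, subject_id = "sim") {
  stopifnot(inherits(net, "ground_truth_network"))
  if (n_timepoints < 2) stop("n_timepoints must be >= 2", call. = FALSE)
  assert_psd(net$covariance)
  n <- nrow(net$covariance)
  with_seed(seed, {
    x <- MASS::mvrnorm(n_timepoints, mu = rep(0, n), Sigma = net$covariance)
    if (noise_sd > 0) {
      x <- x + matrix(stats::rnorm(length(x), sd = noise_sd), nrow(x))
    }
    parcellated_ts(x, region_labels = seq_len(n), subject_id = subject_id)
  })
}

#' Simulate a full three-group cohort
#'
#' NC subjects are drawn from the unattenuated ground-truth network.  Each
#' disease subject receives a severity multiplier `s ~ N(1, severity_cv)`
#' (truncated at 0) and is drawn from the network attenuated with
#' `beta_group * s`.  The subject's designed proportional loss per node is
#' `(mu_i_attenuated - mu_i_baseline) / mu_i_baseline` on the ground-truth
#' correlation scale; regional SUVR couples to it through `rho_region`:
#' `SUVR_i = tau_base_group + tau_coupling_scale * rho_i * loss_i + noise`.
#' MMSE-like scores decrease and CDR-SB-like scores increase linearly in the
#' subject's effective attenuation, clipped to [0, 30] and [0, 18].
#'
#' @param spec a `cohort_spec`.
#' @return a `cohort_bundle`: list with `spec`, `network`, `timeseries`
#'   (named list of `parcellated_ts`), `suvr` (subjects x regions matrix),
#'   `manifest` (subject_id, group, severity, mmse, cdr_sb) and `designed`
#'   (group-level designed strengths and losses, per-subject designed loss).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  net <- generate_ground_truth_network(spec$n_regions, spec$hub_exponent,
                                       spec$seed)
  hub_norm <- net$hubness / max(net$hubness)
  base_mu <- designed_strength(net, "pearson_r")

  groups <- names(spec$n_subjects)
  designed_group_strength <- matrix(NA_real_, length(groups), spec$n_regions,
                                    dimnames = list(groups, NULL))
  designed_group_loss <- designed_group_strength
  for (g in groups) {
    ng <- if (spec$beta[[g]] > 0) {
      attenuate_network(net, spec$beta[[g]], hub_norm)
    } else {
      net
    }
    mu_g <- designed_strength(ng, "pearson_r")
    designed_group_strength[g, ] <- mu_g
    designed_group_loss[g, ] <- (mu_g - base_mu) / base_mu
  }

  timeseries <- list()
  n_total <- sum(spec$n_subjects)
  suvr <- matrix(NA_real_, n_total, spec$n_regions)
  subject_loss <- matrix(NA_real_, n_total, spec$n_regions)
  manifest <- data.frame(subject_id = character(n_total),
                         group = character(n_total),
                         severity = NA_real_, mmse = NA_real_,
                         cdr_sb = NA_real_)
  idx <- 0L
  for (g in groups) {
    for (k in seq_len(spec$n_subjects[[g]])) {
      idx <- idx + 1L
      sid <- sprintf("%s_%02d", g, k)
      b_eff <- with_seed(child_seed(spec$seed, 3L * idx), {
        spec$beta[[g]] * max(0, stats::rnorm(1, 1, spec$severity_cv))
      })
      net_k <- if (b_eff > 0) attenuate_network(net, b_eff, hub_norm) else net
      timeseries[[sid]] <- simulate_subject_timeseries(
        net_k, spec$n_timepoints, spec$noise_sd,
        seed = child_seed(spec$seed, 3L * idx + 1L), subject_id = sid)
      loss_k <- (designed_strength(net_k, "pearson_r") - base_mu) / base_mu
      subject_loss[idx, ] <- loss_k
      with_seed(child_seed(spec$seed, 3L * idx + 2L), {
        suvr[idx, ] <- pmax(0.05,
          spec$tau_base[[g]] +
            spec$tau_coupling_scale * spec$rho_region * loss_k +
            stats::rnorm(spec$n_regions, 0, spec$suvr_noise_sd))
        manifest$mmse[idx] <- clip(29 - 20 * b_eff + stats::rnorm(1, 0, 1.5),
                                   0, 30)
        manifest$cdr_sb[idx] <- clip(0.3 + 15 * b_eff + stats::rnorm(1, 0, 0.8),
                                     0, 18)
      })
      manifest$subject_id[idx] <- sid
      manifest$group[idx] <- g
      manifest$severity[idx] <- if (spec$beta[[g]] > 0) {
        b_eff / spec$beta[[g]]
      } else {
        1
      }
    }
  }
  rownames(suvr) <- manifest$subject_id
  rownames(subject_loss) <- manifest$subject_id
  colnames(suvr) <- colnames(subject_loss) <- as.character(seq_len(spec$n_regions))
  attr(suvr, "reference_region") <- "cerebellum"

  structure(list(
    spec = spec,
    network = net,
    hubness_norm = hub_norm,
    timeseries = timeseries,
    suvr = suvr,
    manifest = manifest,
    designed = list(group_strength = designed_group_strength,
                    group_loss = designed_group_loss,
                    subject_loss = subject_loss,
                    rho_region = spec$rho_region)
  ), class = "cohort_bundle")
}

#' A small voxel geometry for rendering synthetic volumes
#'
#' Lays the regions out along the first axis, `voxels_per_region` voxels
#' each, followed by a disjoint block of reference-region voxels.  This is a
#' deliberately simple synthetic grid, not any standard brain space.
#'
#' @param n_regions number of atlas regions.
#' @param voxels_per_region voxels per region (>= 1).
#' @param n_reference_voxels voxels in the reference-region mask.
#' @return list with `dim`, integer `labels` array (0 = background/reference)
#'   and logical `reference_mask` array.
#' @export
make_toy_geometry <- function(n_regions, voxels_per_region = 2L,
                              n_reference_voxels = 4L) {
  stopifnot(voxels_per_region >= 1, n_reference_voxels >= 1)
  nx <- n_regions * voxels_per_region + n_reference_voxels
  labels <- array(0L, dim = c(nx, 1L, 1L))
  labels[seq_len(n_regions * voxels_per_region), 1, 1] <-
    rep(seq_len(n_regions), each = voxels_per_region)
  mask <- array(FALSE, dim = c(nx, 1L, 1L))
  mask[(n_regions * voxels_per_region + 1):nx, 1, 1] <- TRUE
  list(dim = c(nx, 1L, 1L), labels = labels, reference_mask = mask)
}

#' Render a cohort as NIfTI volumes
#'
#' Writes, per subject, a 4D functional volume whose region-`k` voxels carry
#' that subject's region-`k` time series, and a 3D PET volume whose region
#' voxels carry `SUVR_k * reference_uptake` (reference voxels carry
#' `reference_uptake`), plus a shared integer atlas volume, a reference-region
#' mask and a region lookup table.  With zero voxel noise, extraction through
#' the atlas reader reproduces the inputs to numerical precision.
#'
#' @param cohort a `cohort_bundle`.
#' @param geometry as produced by [make_toy_geometry()]; every region must
#'   own at least one voxel and the reference mask must be disjoint from all
#'   labelled voxels.
#' @param out_dir output directory (created if needed).
#' @param voxel_noise_sd sd of i.i.d. voxel noise added to both modalities.
#' @param reference_uptake PET uptake assigned to the reference region.
#' @param seed seed for voxel noise.
#' @return (invisibly) a manifest list of the written file paths.
#' @export
render_volumes <- function(cohort, geometry, out_dir, voxel_noise_sd = 0,
                           reference_uptake = 5, seed = 1L) {
  stopifnot(inherits(cohort, "cohort_bundle"))
  n <- cohort$spec$n_regions
  lab <- as.vector(geometry$labels)
  msk <- as.vector(geometry$reference_mask)
  counts <- tabulate(lab, nbins = n)
  if (any(counts == 0)) {
    stop(sprintf("region(s) with zero voxels in geometry: %s",
                 paste(which(counts == 0), collapse = ", ")), call. = FALSE)
  }
  if (any(msk & lab > 0)) {
    stop("reference-region mask overlaps labelled atlas voxels", call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  atlas_path <- file.path(out_dir, "atlas.nii.gz")
  mask_path <- file.path(out_dir, "reference_mask.nii.gz")
  table_path <- file.path(out_dir, "atlas_table.tsv")
  RNifti::writeNifti(array(as.numeric(lab), dim = geometry$dim), atlas_path)
  RNifti::writeNifti(array(as.numeric(msk), dim = geometry$dim), mask_path)
  utils::write.table(
    data.frame(label_id = seq_len(n), name = sprintf("R%03d", seq_len(n)),
               hemisphere = NA_character_),
    table_path, sep = "\t", quote = FALSE, row.names = FALSE)

  nvox <- prod(geometry$dim)
  func_paths <- pet_paths <- character(0)
  with_seed(seed, {
    for (sid in cohort$manifest$subject_id) {
      ts <- cohort$timeseries[[sid]]$data
      tt <- nrow(ts)
      vox <- matrix(0, nvox, tt)
      vox[lab > 0, ] <- t(ts[, lab[lab > 0], drop = FALSE])
      if (voxel_noise_sd > 0) {
        vox <- vox + matrix(stats::rnorm(length(vox), sd = voxel_noise_sd),
                            nvox)
      }
      fp <- file.path(out_dir, sprintf("func_%s.nii.gz", sid))
      RNifti::writeNifti(array(vox, dim = c(geometry$dim, tt)), fp)
      func_paths[sid] <- fp

      pet <- numeric(nvox)
      pet[lab > 0] <- cohort$suvr[sid, lab[lab > 0]] * reference_uptake
      pet[msk] <- reference_uptake
      if (voxel_noise_sd > 0) {
        pet <- pet + stats::rnorm(nvox, sd = voxel_noise_sd)
      }
      pp <- file.path(out_dir, sprintf("pet_%s.nii.gz", sid))
      RNifti::writeNifti(array(pet, dim = geometry$dim), pp)
      pet_paths[sid] <- pp
    }
  })
  invisible(list(atlas = atlas_path, reference_mask = mask_path,
                 table = table_path, func = func_paths, pet = pet_paths,
                 reference_uptake = reference_uptake))
}
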