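# Shared fixtures, all built in code at test time.

tiny_spec <- function(n_regions = 12, n = 4, n_timepoints = 60, seed = 42,
                      ...) {
  cohort_spec(n_regions = n_regions,
              n_subjects = c(NC = n, MCI = n, AD = n),
              n_timepoints = n_timepoints, seed = seed, ...)
}

# Write a toy atlas: labelled 1D strip plus a trailing reference block.
write_toy_atlas <- function(dir, n_regions = 3, voxels_per_region = 2,
                            n_reference_voxels = 2) {
  geom <- make_toy_geometry(n_regions, voxels_per_region,
                            n_reference_voxels)
  label_path <- file.path(dir, "atlas.nii.gz")
  table_path <- file.path(dir, "atlas_table.tsv")
  mask_path <- file.path(dir, "mask.nii.gz")
  RNifti::writeNifti(array(as.numeric(geom$labels), dim = geom$dim),
                     label_path)
  RNifti::writeNifti(array(as.numeric(geom$reference_mask), dim = geom$dim),
                     mask_path)
  write.table(data.frame(label_id = seq_len(n_regions),
                         name = sprintf("R%03d", seq_len(n_regions)),
                         hemisphere = NA_character_),
              table_path, sep = "\t", quote = FALSE, row.names = FALSE)
  list(geom = geom, label_path = label_path, table_path = table_path,
       mask_path = mask_path)
}

# A connectivity matrix built directly from a symmetric matrix of weights.
toy_conn <- function(values, scale = "pearson_r") {
  diag(values) <- 0
  plfcs:::new_connectivity_matrix(values, scale,
                                  seq_len(nrow(values)), "toy")
}

# Strength vector from raw values, for feeding the loss computations.
toy_strength <- function(values, level = "subject", scale = "fisher_z",
                         subject_id = "toy") {
  structure(list(values = setNames(values,
                                   as.character(seq_along(values))),
                 level = level, scale = scale,
                 region_labels = seq_along(values),
                 subject_id = subject_id,
                 n_subjects = if (level == "group_mean") 1L else NULL),
            class = "strength_vector")
}
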