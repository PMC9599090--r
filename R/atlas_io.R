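# Reading NIfTI volumes and atlas definitions; ROI-level extraction.
# Inputs are assumed parcel-ready (registered to a common grid); spatial
# preprocessing is out of scope.

#' Construct a parcellated time-series object
#'
#' @param data T x N numeric matrix (rows = timepoints, columns = regions).
#' @param region_labels ordered integer label ids, length N.
#' @param subject_id identifier.
#' @param sampling_interval repetition time in seconds (optional; required
#'   only for temporal filtering).
#' @return object of class `parcellated_ts`.
#' @export
parcellated_ts <- function(data, region_labels, subject_id = "subject",
                           sampling_interval = NA_real_) {
  data <- as.matrix(data)
  if (nrow(data) < 2) stop("need at least 2 timepoints", call. = FALSE)
  if (ncol(data) != length(region_labels)) {
    stop("number of columns must equal number of region labels", call. = FALSE)
  }
  all_nan <- apply(data, 2, function(x) all(is.na(x)))
  if (any(all_nan)) {
    stop(sprintf("column(s) entirely NaN: %s",
                 paste(region_labels[all_nan], collapse = ", ")),
         call. = FALSE)
  }
  colnames(data) <- as.character(region_labels)
  structure(list(data = data, region_labels = as.integer(region_labels),
                 subject_id = subject_id,
                 sampling_interval = sampling_interval),
            class = "parcellated_ts")
}

#' @export
print.parcellated_ts <- function(x, ...) {
  cat(sprintf("parcellated_ts: subject %s, %d timepoints x %d regions\n",
              x$subject_id, nrow(x$data), ncol(x$data)))
  invisible(x)
}

# NIfTI readers may drop trailing singleton dimensions; pad back to 3.
dim3 <- function(vol) {
  d <- dim(vol)
  if (is.null(d)) d <- length(vol)
  as.integer(c(d, rep(1L, max(0, 3 - length(d))))[1:3])
}

#' Load an atlas (label volume + region lookup table)
#'
#' The region table's row order is the canonical node order for every matrix
#' and vector downstream.
#'
#' @param label_path NIfTI-1 volume of integer region labels (0 = background).
#' @param table_path TSV with header columns `label_id`, `name`,
#'   `hemisphere`.
#' @return object of class `atlas` with `labels` (3D integer array) and
#'   `table` (data.frame in canonical order).
#' @export
load_atlas <- function(label_path, table_path) {
  vol <- RNifti::readNifti(label_path)
  lab <- as.vector(vol)
  if (any(abs(lab - round(lab)) > 1e-6)) {
    stop("atlas label volume is not integer-valued", call. = FALSE)
  }
  lab <- as.integer(round(lab))
  tab <- utils::read.delim(table_path, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("label_id", "name") %in% names(tab))) {
    stop("region table must have columns label_id and name", call. = FALSE)
  }
  if (anyDuplicated(tab$label_id)) {
    stop(sprintf("duplicate label ids in region table: %s",
                 paste(unique(tab$label_id[duplicated(tab$label_id)]),
                       collapse = ", ")), call. = FALSE)
  }
  present <- unique(lab[lab != 0])
  missing <- setdiff(present, tab$label_id)
  if (length(missing)) {
    stop(sprintf("voxel label(s) absent from region table: %s",
                 paste(sort(missing), collapse = ", ")), call. = FALSE)
  }
  structure(list(labels = array(lab, dim = dim3(vol)), table = tab),
            class = "atlas")
}

check_grid <- function(vol_dim, atlas) {
  adim <- dim(atlas$labels)
  if (!identical(as.integer(vol_dim[1:3]), as.integer(adim))) {
    stop(sprintf("volume grid %s does not match atlas grid %s",
                 paste(vol_dim[1:3], collapse = "x"),
                 paste(adim, collapse = "x")), call. = FALSE)
  }
}

# ROI means of a voxels x frames matrix, in canonical table order.
# NaN voxels are dropped per frame; an entirely-NaN region is an error.
roi_means <- function(vox, lab, atlas) {
  sapply(atlas$table$label_id, function(id) {
    rows <- which(lab == id)
    if (!length(rows)) {
      stop(sprintf("region %d has zero voxels in the volume", id),
           call. = FALSE)
    }
    m <- colMeans(vox[rows, , drop = FALSE], na.rm = TRUE)
    if (any(is.nan(m))) {
      stop(sprintf("region %d is entirely NaN", id), call. = FALSE)
    }
    m
  })
}

#' Extract ROI mean time series from a 4D functional volume
#'
#' Column `k` of the result is, per timepoint, the unweighted mean over all
#' voxels carrying label `k`.
#'
#' @param func_path path to a 4D NIfTI-1 volume on the atlas grid.
#' @param atlas an `atlas`.
#' @param subject_id identifier attached to the result.
#' @param sampling_interval repetition time in seconds (optional).
#' @return a `parcellated_ts` in canonical region order.
#' @export
extract_roi_timeseries <- function(func_path, atlas, subject_id = "subject",
                                   sampling_interval = NA_real_) {
  vol <- RNifti::readNifti(func_path)
  d <- dim(vol)
  if (length(d) != 4) stop("functional volume must be 4D", call. = FALSE)
  check_grid(dim3(vol), atlas)
  vox <- matrix(as.vector(vol), prod(d[1:3]), d[4])
  ts <- roi_means(vox, as.vector(atlas$labels), atlas)
  parcellated_ts(ts, region_labels = atlas$table$label_id,
                 subject_id = subject_id,
                 sampling_interval = sampling_interval)
}

#' Extract per-region mean uptake from a 3D PET volume
#'
#' @param pet_path path to a 3D NIfTI-1 volume on the atlas grid.
#' @param atlas an `atlas`.
#' @return named numeric vector of region mean uptakes in canonical order.
#' @export
extract_roi_means <- function(pet_path, atlas) {
  vol <- RNifti::readNifti(pet_path)
  d <- dim(vol)
  if (length(d) > 3) stop("PET volume must be 3D", call. = FALSE)
  check_grid(dim3(vol), atlas)
  vox <- matrix(as.vector(vol), ncol = 1)
  m <- roi_means(vox, as.vector(atlas$labels), atlas)
  stats::setNames(as.numeric(m), as.character(atlas$table$label_id))
}

#' Mean uptake within a binary mask (e.g. the cerebellar reference region)
#'
#' @param pet_path path to a 3D NIfTI-1 volume.
#' @param mask_path path to a congruent mask volume (non-zero = in mask).
#' @return scalar mean uptake over mask voxels.
#' @export
extract_mask_mean <- function(pet_path, mask_path) {
  vol <- RNifti::readNifti(pet_path)
  msk <- RNifti::readNifti(mask_path)
  if (!identical(dim3(vol), dim3(msk))) {
    stop(sprintf("PET grid %s does not match mask grid %s",
                 paste(dim(vol), collapse = "x"),
                 paste(dim(msk), collapse = "x")), call. = FALSE)
  }
  sel <- as.vector(msk) != 0
  if (!any(sel)) stop("mask contains no voxels", call. = FALSE)
  mean(as.vector(vol)[sel], na.rm = TRUE)
}

#' Zero-phase frequency-domain band-pass filter
#'
#' Columns are transformed with the FFT, Fourier coefficients outside
#' `[low_hz, high_hz]` are zeroed (a hard, perfectly zero-phase frequency
#' mask), and the inverse transform is taken.  A pure in-band sinusoid
#' passes essentially unchanged; out-of-band components (including the DC
#' mean whenever `low_hz > 0`) are removed.
#'
#' @param ts a `parcellated_ts` with `sampling_interval` set.
#' @param low_hz,high_hz passband edges in Hz; `0 <= low_hz < high_hz` and
#'   `high_hz` below the Nyquist frequency.
#' @return a filtered `parcellated_ts` of identical shape.
#' @export
bandpass_filter <- function(ts, low_hz = 0.01, high_hz = 0.08) {
  stopifnot(inherits(ts, "parcellated_ts"))
  dt <- ts$sampling_interval
  if (is.na(dt) || is.null(dt)) {
    stop("sampling_interval is required for filtering; supply it or skip the filter",
         call. = FALSE)
  }
  nyquist <- 1 / (2 * dt)
  if (!(low_hz >= 0 && low_hz < high_hz && high_hz < nyquist)) {
    stop(sprintf("need 0 <= low_hz < high_hz < Nyquist (%.4g Hz)", nyquist),
         call. = FALSE)
  }
  tt <- nrow(ts$data)
  freq <- pmin(0:(tt - 1), tt - (0:(tt - 1))) / (tt * dt)
  keep <- freq >= low_hz & freq <= high_hz
  y <- stats::mvfft(ts$data)
  y[!keep, ] <- 0
  out <- Re(stats::mvfft(y, inverse = TRUE)) / tt
  parcellated_ts(out, region_labels = ts$region_labels,
                 subject_id = ts$subject_id, sampling_interval = dt)
}

#' Write / read a parcellated time series as TSV
#'
#' Rows are timepoints; the header carries the region labels.
#'
#' @param ts a `parcellated_ts`.
#' @param path output path.
#' @export
write_timeseries_tsv <- function(ts, path) {
  utils::write.table(ts$data, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_timeseries_tsv
#' @param subject_id identifier for the loaded subject.
#' @param sampling_interval repetition time in seconds (optional).
#' @export
read_timeseries_tsv <- function(path, subject_id = "subject",
                                sampling_interval = NA_real_) {
  d <- utils::read.delim(path, sep = "\t", check.names = FALSE)
  labels <- suppressWarnings(as.integer(sub("^X", "", colnames(d))))
  if (any(is.na(labels))) labels <- seq_len(ncol(d))
  parcellated_ts(as.matrix(d), region_labels = labels,
                 subject_id = subject_id,
                 sampling_interval = sampling_interval)
}
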