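#' ROI time-series container
#'
#' A matrix of ROI-averaged signal (rows = ROIs, columns = volumes) together
#' with ROI names, the repetition time, and the original volume indices of
#' the retained columns (so censoring / task selection keep provenance).
#'
#' @param values Numeric ROI x volume matrix, no missing values.
#' @param roi_names Unique ROI labels, one per row.
#' @param tr_s Repetition time in seconds.
#' @param volume_index Strictly increasing original indices of the columns;
#'   defaults to `1:ncol(values)`.
#' @return An object of class `roi_timeseries`.
#' @export
roi_timeseries <- function(values, roi_names = rownames(values), tr_s = 2.5,
                           volume_index = seq_len(ncol(values))) {
  values <- as.matrix(values)
  if (any(!is.finite(values)))
    stop("time series contain non-finite values", call. = FALSE)
  if (is.null(roi_names)) roi_names <- default_roi_names(nrow(values))
  roi_names <- as.character(roi_names)
  if (length(roi_names) != nrow(values) || anyDuplicated(roi_names))
    stop("`roi_names` must be unique, one per ROI row", call. = FALSE)
  volume_index <- as.integer(volume_index)
  if (length(volume_index) != ncol(values) ||
      (length(volume_index) > 1 && any(diff(volume_index) <= 0)))
    stop("`volume_index` must be strictly increasing, one per column", call. = FALSE)
  dimnames(values) <- list(roi_names, NULL)
  structure(list(values = values, roi_names = roi_names, tr_s = tr_s,
                 volume_index = volume_index),
            class = "roi_timeseries")
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("ROI time series: %d ROIs x %d volumes (TR = %gs)\n",
              nrow(x$values), ncol(x$values), x$tr_s))
  invisible(x)
}

#' Extract ROI-averaged time series from a 4D volume
#'
#' Averages the 4D signal over the voxels of each atlas label, per volume.
#' Label 0 is background; labels with zero voxels are dropped with a warning
#' and recorded in the `dropped_labels` attribute. Arrays as returned by
#' `RNifti::readNifti()` can be passed directly.
#'
#' @param volume4d Numeric 4D array (x, y, z, volume).
#' @param labels Integer 3D array of atlas labels matching the spatial
#'   dimensions of `volume4d`.
#' @param roi_names Optional names for the nonzero labels in ascending label
#'   order; defaults to `ROI<label>`.
#' @param tr_s Repetition time, seconds.
#' @return A [roi_timeseries()] with one row per nonzero label present.
#' @export
extract_roi_timeseries <- function(volume4d, labels, roi_names = NULL,
                                   tr_s = 2.5) {
  dv <- dim(volume4d)
  if (length(dv) != 4L) stop("`volume4d` must be a 4D array", call. = FALSE)
  if (!identical(as.integer(dv[1:3]), as.integer(dim(labels))))
    stop("spatial dimensions of `volume4d` and `labels` differ", call. = FALSE)
  lab <- as.integer(labels)
  all_labels <- sort(unique(lab[lab > 0L]))
  if (!length(all_labels)) stop("`labels` contains no nonzero label", call. = FALSE)
  expected <- seq_len(max(all_labels))
  dropped <- setdiff(expected, all_labels)
  if (length(dropped))
    warning(sprintf("labels with zero voxels excluded: %s",
                    paste(dropped, collapse = ", ")), call. = FALSE)
  n_vol <- dv[4L]
  mat <- matrix(volume4d, nrow = prod(dv[1:3]), ncol = n_vol)
  keep <- lab > 0L
  # rowsum aggregates voxel signals by label; divide by voxel counts.
  sums <- rowsum(mat[keep, , drop = FALSE], group = lab[keep])
  counts <- as.vector(table(lab[keep]))
  values <- sums / counts
  if (is.null(roi_names)) roi_names <- sprintf("ROI%03d", all_labels)
  if (length(roi_names) != length(all_labels))
    stop("`roi_names` must have one name per nonzero label present", call. = FALSE)
  out <- roi_timeseries(values, roi_names = roi_names, tr_s = tr_s)
  attr(out, "dropped_labels") <- dropped
  out
}

#' Motion censoring mask
#'
#' Flags volumes whose differential movement exceeds the threshold. Strictly
#' greater-than movement is censored; a volume at exactly the threshold is
#' kept. Censored volumes are removed downstream, never interpolated.
#'
#' @param motion Non-negative numeric vector, mm of differential movement per
#'   TR, one value per volume.
#' @param threshold_mm Censoring threshold in mm (default 0.5).
#' @return Logical vector `keep`, `TRUE` for retained volumes.
#' @examples
#' censor_motion(c(0.1, 0.6, 0.5))  # TRUE FALSE TRUE
#' @export
censor_motion <- function(motion, threshold_mm = 0.5) {
  motion <- as.numeric(motion)
  if (any(!is.finite(motion)) || any(motion < 0))
    stop("`motion` must be finite and non-negative", call. = FALSE)
  motion <= threshold_mm
}

#' Restrict a time series to retained task volumes
#'
#' Keeps the volumes that are both task volumes in the block design and
#' retained by the censoring mask (intersection, so the order of censoring
#' and task selection is irrelevant).
#'
#' @param ts A [roi_timeseries()].
#' @param design A [make_block_design()] object whose mask length matches the
#'   current volume count of `ts`.
#' @param censor Optional logical keep-mask from [censor_motion()]; defaults
#'   to all-`TRUE`.
#' @return A [roi_timeseries()] with only the retained columns and updated
#'   `volume_index`.
#' @export
select_task_volumes <- function(ts, design, censor = NULL) {
  stopifnot(inherits(ts, "roi_timeseries"), inherits(design, "task_design"))
  n_vol <- ncol(ts$values)
  if (length(design$task_mask) != n_vol)
    stop(sprintf("design has %d volumes but time series has %d",
                 length(design$task_mask), n_vol), call. = FALSE)
  if (is.null(censor)) censor <- rep(TRUE, n_vol)
  if (length(censor) != n_vol)
    stop(sprintf("censor mask has %d volumes but time series has %d",
                 length(censor), n_vol), call. = FALSE)
  keep <- design$task_mask & censor
  if (!any(keep))
    stop(sprintf(
      "no volumes retained (task mask keeps %d, censor mask keeps %d, intersection empty)",
      sum(design$task_mask), sum(censor)), call. = FALSE)
  roi_timeseries(ts$values[, keep, drop = FALSE], roi_names = ts$roi_names,
                 tr_s = ts$tr_s, volume_index = ts$volume_index[keep])
}
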