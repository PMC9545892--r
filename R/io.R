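## Interchange helpers: event files, ROI time-series tables, and voxel
## collapsing from 4D data. All plain-text (CSV) or NIfTI.

#' Write / read a scan's stimulus events as CSV
#'
#' One row per image event: onset and duration in seconds, block number,
#' category, filter type, sequence type, and whether the following fixation
#' is a green attention target.
#'
#' @param design An [generate_exp2_design()].
#' @param path File path.
#' @param lead_in_s Fixation before the first block (must match the
#'   simulation).
#' @return `write_events_csv()` returns `path` invisibly;
#'   `read_events_csv()` returns the events data frame.
#' @export
write_events_csv <- function(design, path, lead_in_s = 9) {
  stopifnot(inherits(design, "exp2_design"))
  soa <- design$stim_s + design$isi_s
  cycle <- design$block_s + design$fixation_s
  nb <- nrow(design$blocks)
  ev <- do.call(rbind, lapply(seq_len(nb), function(b) {
    data.frame(onset_s = lead_in_s + (b - 1) * cycle +
                 (seq_len(design$images_per_block) - 1) * soa,
               duration_s = design$stim_s,
               block = b,
               category = design$blocks$category[b],
               filter_type = design$blocks$filter_type[b],
               sequence = design$blocks$sequence[b])
  }))
  ev$green_target <- seq_len(nrow(ev)) %in% design$green_targets
  write.csv(ev, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) read.csv(path)

#' Write / read an ROI time series as CSV
#'
#' Stores the samples with their TR, block onsets and block labels so a
#' series round-trips losslessly into the adaptation analysis.
#'
#' @param ts An `"roi_timeseries"`.
#' @param path File path.
#' @return `write_timeseries_csv()` returns `path` invisibly;
#'   `read_timeseries_csv()` returns an `"roi_timeseries"`.
#' @export
write_timeseries_csv <- function(ts, path) {
  stopifnot(inherits(ts, "roi_timeseries"))
  n <- length(ts$samples)
  pad <- function(x, what) c(x, rep(NA, n - length(x)))
  d <- data.frame(sample = ts$samples,
                  tr_s = ts$tr_s,
                  subject_id = ts$subject_id, roi_id = ts$roi_id,
                  psc = ts$psc,
                  block_onset = pad(ts$block_onsets),
                  block_category = pad(ts$blocks$category),
                  block_filter = pad(ts$blocks$filter_type),
                  block_sequence = pad(ts$blocks$sequence))
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_timeseries_csv
#' @export
read_timeseries_csv <- function(path) {
  d <- read.csv(path)
  nb <- sum(!is.na(d$block_onset))
  structure(list(subject_id = d$subject_id[1], roi_id = d$roi_id[1],
                 samples = d$sample, tr_s = d$tr_s[1],
                 block_onsets = as.integer(d$block_onset[seq_len(nb)]),
                 blocks = data.frame(
                   block = seq_len(nb),
                   category = d$block_category[seq_len(nb)],
                   filter_type = d$block_filter[seq_len(nb)],
                   sequence = d$block_sequence[seq_len(nb)]),
                 psc = as.logical(d$psc[1])),
            class = "roi_timeseries")
}

#' Collapse a 4D volume across an ROI into a mean time series
#'
#' Averages the voxels of `mask` at every volume of a 4D array (x, y, z,
#' time), e.g. one read with [read_zmap_nifti()] from a 4D NIfTI.
#'
#' @param data4d 4D numeric array.
#' @param mask An `"roi_mask"` or a logical/numeric 3D array.
#' @param tr_s Sampling interval in seconds.
#' @param block_onsets 1-based TR indices of block onsets.
#' @param blocks Optional data frame labelling the blocks (`category`,
#'   `filter_type`, `sequence`).
#' @param subject_id,roi_id Tokens recorded on the series.
#' @return An `"roi_timeseries"`.
#' @export
extract_roi_timeseries <- function(data4d, mask, tr_s = 3,
                                   block_onsets = integer(0), blocks = NULL,
                                   subject_id = "sub", roi_id = "roi") {
  stopifnot(is.array(data4d), length(dim(data4d)) == 4L)
  keep <- if (inherits(mask, "roi_mask")) roi_mask_array(mask)
          else (mask != 0)
  stopifnot(all(dim(keep) == dim(data4d)[1:3]))
  nt <- dim(data4d)[4]
  flat <- matrix(data4d, ncol = nt)
  samples <- colMeans(flat[as.vector(keep), , drop = FALSE])
  new_roi_timeseries(samples, tr_s, block_onsets, blocks,
                     subject_id = subject_id, roi_id = roi_id)
}

#' Write a simulated ROI time series as 4D NIfTI
#'
#' Stores the single collapsed series as a 1 x 1 x 1 x T volume so it can be
#' handled by standard imaging tools.
#'
#' @param ts An `"roi_timeseries"`.
#' @param path Output `.nii`/`.nii.gz` path.
#' @return The path, invisibly.
#' @export
write_timeseries_nifti <- function(ts, path) {
  stopifnot(inherits(ts, "roi_timeseries"))
  a <- array(ts$samples, c(1, 1, 1, length(ts$samples)))
  RNifti::writeNifti(RNifti::asNifti(a, pixdim = c(1, 1, 1, ts$tr_s)), path)
  invisible(path)
}

#' Read or write a greyscale image as TIFF
#'
#' Same contract as [read_image_png()] but for (optionally float) TIFF.
#' Requires the suggested \pkg{tiff} package.
#'
#' @inheritParams read_image_png
#' @return `read_image_tiff()` returns a [vt_image()]; `write_image_tiff()`
#'   returns `path` invisibly.
#' @export
read_image_tiff <- function(path, pixels_per_degree, category = NULL,
                            filter_label = "none") {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("package 'tiff' is required for TIFF I/O")
  a <- tiff::readTIFF(path)
  if (length(dim(a)) == 3L) a <- apply(a[, , seq_len(min(3L, dim(a)[3])),
                                         drop = FALSE], c(1, 2), mean)
  vt_image(a, pixels_per_degree, category, filter_label)
}

#' @rdname read_image_tiff
#' @param img A [vt_image()] to write.
#' @export
write_image_tiff <- function(img, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("package 'tiff' is required for TIFF I/O")
  stopifnot(inherits(img, "vt_image"))
  tiff::writeTIFF(pmin(pmax(img$pixels, 0), 1), path, bits.per.sample = 16L)
  invisible(path)
}
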