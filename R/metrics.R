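image_data <- function(image) {
  if (inherits(image, "ctlike_image")) image$data
  else if (is.array(image) && length(dim(image)) == 3) image
  else stop("image must be a ctlike_image or a 3-D numeric array", call. = FALSE)
}

image_voxel_size <- function(image) {
  if (inherits(image, "ctlike_image")) image$voxel_size else c(1, 1, 1)
}

#' ROI summary statistics
#'
#' Mean, sample SD (n - 1 denominator) and voxel count of the image intensities
#' inside a mask. A single-voxel ROI has no dispersion information; its SD is
#' reported as 0 with a warning rather than `NA`.
#'
#' @param image a `ctlike_image` or 3-D numeric array.
#' @param mask logical mask: either 3-D (same shape as the image) or a 2-D
#'   slice mask combined with `slice_index`.
#' @param slice_index slice along the third axis that a 2-D `mask` refers to.
#' @return A list of class `roi_stats` with `si_mean`, `si_sd`, `n_voxels`.
#' @export
#' @examples
#' a <- array(0, c(4, 4, 2)); a[2:3, 2:3, 1] <- c(90, 100, 110, 100)
#' m <- a[, , 1] > 0
#' roi_stats(a, m, slice_index = 1)
roi_stats <- function(image, mask, slice_index = NULL) {
  dat <- image_data(image)
  if (length(dim(mask)) == 2 || is.null(dim(mask))) {
    abort_if(is.null(slice_index), "slice_index is required with a 2-D mask")
    abort_if(slice_index < 1 || slice_index > dim(dat)[3], "slice_index out of bounds")
    abort_if(!all(dim(mask) == dim(dat)[1:2]), "mask does not match the slice shape")
    vals <- dat[, , slice_index][mask]
  } else {
    abort_if(!all(dim(mask) == dim(dat)), "mask does not match the image shape")
    vals <- dat[mask]
  }
  abort_if(length(vals) == 0, "ROI mask is empty")
  if (length(vals) == 1) {
    warning("single-voxel ROI: SD reported as 0", call. = FALSE)
    s <- 0
  } else {
    s <- sd(vals)
  }
  structure(list(si_mean = mean(vals), si_sd = s, n_voxels = length(vals)),
            class = "roi_stats")
}

#' @export
print.roi_stats <- function(x, ...) {
  cat(sprintf("<roi_stats> mean %.4g, sd %.4g, n = %d\n", x$si_mean, x$si_sd, x$n_voxels))
  invisible(x)
}

#' Signal-to-noise and contrast-to-noise ratios
#'
#' SNR of a region is its mean signal intensity divided by the SD of the noise
#' measured in background air; CNR between two regions is the difference of
#' their mean intensities over the same air-noise SD. Both are computed on
#' whatever image the ROI statistics came from — conventionally the processed
#' CT-like image, with the noise ROI drawn on that same image. Because the two
#' ratios share one denominator, `compute_cnr(a, b, air)` equals
#' `compute_snr(a, air) - compute_snr(b, air)` identically.
#'
#' @param roi,roi_a,roi_b `roi_stats` for the signal region(s).
#' @param air `roi_stats` for the background-air noise region; its `si_sd`
#'   must be positive (a noiseless image has no defined SNR).
#' @return A single numeric value.
#' @export
#' @examples
#' bone <- structure(list(si_mean = 100, si_sd = 5, n_voxels = 50), class = "roi_stats")
#' air <- structure(list(si_mean = 2, si_sd = 10, n_voxels = 200), class = "roi_stats")
#' compute_snr(bone, air)
compute_snr <- function(roi, air) {
  abort_if(!is_scalar_number(air$si_sd) || air$si_sd <= 0,
           "air-noise SD must be positive (SNR is undefined on a noiseless image)")
  roi$si_mean / air$si_sd
}

#' @rdname compute_snr
#' @export
compute_cnr <- function(roi_a, roi_b, air) {
  abort_if(!is_scalar_number(air$si_sd) || air$si_sd <= 0,
           "air-noise SD must be positive (CNR is undefined on a noiseless image)")
  (roi_a$si_mean - roi_b$si_mean) / air$si_sd
}

#' Per-image SNR/CNR metric record
#'
#' Applies the ROI set to one image and assembles a one-row tibble with bone
#' SNR, muscle SNR and bone-muscle CNR (signed, bone minus muscle), tagged
#' with the image's provenance. Rows from several subjects and conditions
#' stack into the factorial metrics table consumed by
#' [build_metrics_report()].
#'
#' @param image a `ctlike_image` (or 3-D array, in which case `sequence` and
#'   `processing` must be supplied).
#' @param rois a `roi_set` from [derive_roi_masks()].
#' @param subject_id identifier stored in the record.
#' @param sequence,processing provenance overrides for plain arrays.
#' @return A one-row tibble with columns `subject_id`, `sequence`,
#'   `processing`, `bone_snr`, `muscle_snr`, `bone_muscle_cnr`.
#' @export
compute_image_metrics <- function(image, rois, subject_id = "s1",
                                  sequence = NULL, processing = NULL) {
  abort_if(!inherits(rois, "roi_set"), "rois must be a roi_set")
  sequence <- sequence %||% if (inherits(image, "ctlike_image")) image$sequence else
    stop("sequence must be supplied for a plain array", call. = FALSE)
  processing <- processing %||% if (inherits(image, "ctlike_image")) image$mode else
    stop("processing must be supplied for a plain array", call. = FALSE)
  s <- rois$slice_index
  bone <- roi_stats(image, rois$bone_mask, s)
  muscle <- roi_stats(image, rois$muscle_mask, s)
  air <- roi_stats(image, rois$air_mask, s)
  tibble::tibble(subject_id = subject_id,
                 sequence = sequence,
                 processing = processing,
                 bone_snr = compute_snr(bone, air),
                 muscle_snr = compute_snr(muscle, air),
                 bone_muscle_cnr = compute_cnr(bone, muscle, air))
}

#' Slice-to-slice coefficient of variation
#'
#' Consistency QC across consecutive slices: the per-slice mean intensity of a
#' region (typically the bone ROI) is computed for `k >= 2` consecutive
#' slices, and the coefficient of variation `100 * SD / mean` of those k means
#' is returned as a percentage.
#'
#' @param image a `ctlike_image` or 3-D array.
#' @param mask region definition: a 3-D logical array, a single 2-D mask
#'   applied to every slice, or a list of 2-D masks (one per slice).
#' @param slices consecutive 1-based slice indices along the third axis.
#' @return CoV in percent.
#' @export
#' @examples
#' a <- array(rep(c(90, 100, 110), each = 16), c(4, 4, 3))
#' slice_cov(a, matrix(TRUE, 4, 4), slices = 1:3)  # 10
slice_cov <- function(image, mask, slices) {
  dat <- image_data(image)
  abort_if(length(slices) < 2, "at least 2 consecutive slices are required")
  abort_if(any(diff(slices) != 1), "slices must be consecutive and increasing")
  abort_if(min(slices) < 1 || max(slices) > dim(dat)[3], "slices out of bounds")
  slice_mask <- function(i) {
    m <- if (is.list(mask)) mask[[i]]
         else if (length(dim(mask)) == 3) mask[, , slices[i]]
         else mask
    abort_if(!all(dim(m) == dim(dat)[1:2]), "mask does not match the slice shape")
    m
  }
  if (is.list(mask)) abort_if(length(mask) != length(slices),
                              "need one mask per slice")
  means <- vapply(seq_along(slices), function(i) {
    m <- slice_mask(i)
    abort_if(sum(m) == 0, sprintf("mask is empty on slice %d", slices[i]))
    mean(dat[, , slices[i]][m])
  }, numeric(1))
  abort_if(isTRUE(all.equal(mean(means), 0)), "mean signal is zero; CoV undefined")
  100 * sd(means) / mean(means)
}

trilinear_sample <- function(dat, pts_mm, voxel_size) {
  dims <- dim(dat)
  fi <- sweep(pts_mm, 2, voxel_size, "/") + 1  # fractional 1-based indices
  ok <- fi >= 1 & sweep(fi, 2, dims, "<=")
  abort_if(!all(ok), "profile endpoints (or samples) fall outside the volume")
  i0 <- pmin(pmax(floor(fi), 1), matrix(dims - 1L, nrow(fi), 3, byrow = TRUE))
  tt <- fi - i0
  out <- numeric(nrow(fi))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) tt[, 1] else 1 - tt[, 1]) *
         (if (dy) tt[, 2] else 1 - tt[, 2]) *
         (if (dz) tt[, 3] else 1 - tt[, 3])
    idx <- cbind(i0[, 1] + dx, i0[, 2] + dy, i0[, 3] + dz)
    out <- out + w * dat[idx]
  }
  out
}

#' Extract a signal profile along a line
#'
#' Samples the image at `n_samples` evenly spaced points on the segment from
#' `start` to `end` (physical mm coordinates; the centre of the first voxel is
#' at 0 on each axis) using trilinear interpolation.
#'
#' @param image a `ctlike_image` or 3-D array.
#' @param start,end length-3 physical coordinates in mm.
#' @param n_samples number of sample points, `>= 2`.
#' @param voxel_size mm per axis; taken from a `ctlike_image` automatically.
#' @return A tibble of class `profile_measurement` with columns `position`
#'   (mm along the line, starting at 0) and `value`.
#' @export
extract_profile <- function(image, start, end, n_samples = 201,
                            voxel_size = image_voxel_size(image)) {
  dat <- image_data(image)
  abort_if(length(start) != 3 || length(end) != 3, "start and end must be length-3 mm points")
  abort_if(!is_scalar_number(n_samples) || n_samples < 2, "n_samples must be >= 2")
  t <- seq(0, 1, length.out = n_samples)
  pts <- outer(t, as.numeric(end) - as.numeric(start)) +
    matrix(as.numeric(start), n_samples, 3, byrow = TRUE)
  vals <- trilinear_sample(dat, pts, voxel_size)
  len <- sqrt(sum((end - start)^2))
  out <- tibble::tibble(position = t * len, value = vals)
  class(out) <- c("profile_measurement", class(out))
  attr(out, "start") <- as.numeric(start)
  attr(out, "end") <- as.numeric(end)
  out
}

#' Full width at half maximum of a profile
#'
#' Measures the width of a peak (bright feature) or dip (dark feature) in a
#' 1-D profile. The baseline is the mean of the outer 10% of samples at each
#' end; the half-height is `baseline + (extremum - baseline) / 2`; the two
#' half-height crossings adjacent to the global extremum are located by linear
#' interpolation between samples. If the extremum sits at a profile end, or a
#' crossing is missing on either side, the result carries `fwhm = NA` rather
#' than an error.
#'
#' @param profile a `profile_measurement` from [extract_profile()] (or any
#'   data frame with `position` and `value`).
#' @param orientation `"dip"` for a dark feature (e.g. a low-intensity gap in
#'   bright bone on a CT-like image) or `"peak"` for a bright one.
#' @return A list of class `fwhm_measurement`: `fwhm` (mm, or `NA` if no
#'   crossing), `baseline`, `half_height`, `extremum_position`,
#'   `extremum_value`, `left_crossing`, `right_crossing`, `orientation`.
#' @export
measure_fwhm <- function(profile, orientation = c("dip", "peak")) {
  orientation <- match.arg(orientation)
  pos <- profile$position
  val <- profile$value
  n <- length(val)
  abort_if(n < 5, "profile too short to measure a width")
  abort_if(any(diff(pos) <= 0), "positions must be strictly increasing")
  m <- max(1L, floor(0.1 * n))
  baseline <- mean(c(val[seq_len(m)], val[seq.int(n - m + 1L, n)]))
  w <- if (orientation == "peak") val else -val
  bw <- if (orientation == "peak") baseline else -baseline
  ext <- which.max(w)
  res <- list(fwhm = NA_real_, baseline = baseline,
              half_height = NA_real_, extremum_position = pos[ext],
              extremum_value = val[ext], left_crossing = NA_real_,
              right_crossing = NA_real_, orientation = orientation)
  class(res) <- "fwhm_measurement"
  if (ext == 1L || ext == n) return(res)
  half_w <- bw + (w[ext] - bw) / 2
  res$half_height <- if (orientation == "peak") half_w else -half_w
  cross <- function(i, j) {
    # linear interpolation of the half-height crossing between samples i and j
    pos[i] + (half_w - w[i]) / (w[j] - w[i]) * (pos[j] - pos[i])
  }
  left <- NA_real_
  for (i in seq.int(ext - 1L, 1L)) {
    if (w[i] <= half_w) { left <- cross(i, i + 1L); break }
  }
  right <- NA_real_
  for (i in seq.int(ext + 1L, n)) {
    if (w[i] <= half_w) { right <- cross(i - 1L, i); break }
  }
  res$left_crossing <- left
  res$right_crossing <- right
  if (!is.na(left) && !is.na(right)) res$fwhm <- right - left
  res
}

#' @export
print.fwhm_measurement <- function(x, ...) {
  if (is.na(x$fwhm)) {
    cat(sprintf("<fwhm_measurement> no half-height crossing (%s)\n", x$orientation))
  } else {
    cat(sprintf("<fwhm_measurement> %s FWHM = %.3f mm (half-height %.4g at %.4g-%.4g mm)\n",
                x$orientation, x$fwhm, x$half_height, x$left_crossing, x$right_crossing))
  }
  invisible(x)
}
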