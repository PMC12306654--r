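new_ctlike_image <- function(data, voxel_size, sequence, mode, inversion, epsilon) {
  structure(list(data = data,
                 voxel_size = as.numeric(voxel_size),
                 sequence = sequence,
                 mode = mode,
                 inversion = inversion,
                 epsilon = epsilon),
            class = "ctlike_image")
}

#' @export
print.ctlike_image <- function(x, ...) {
  cat(sprintf("<ctlike_image> %s / %s (%s inversion, epsilon = %.3g): %s voxels\n",
              x$sequence, x$mode, x$inversion, x$epsilon,
              paste(dim(x$data), collapse = "x")))
  invisible(x)
}

#' Default inversion clamp
#'
#' Epsilon used by the reciprocal inversion: `1e-3` times the 99th-percentile
#' intensity of the series (or volume), so the cap on inverted signal voids
#' scales with the data rather than being an absolute unit.
#'
#' @param x an `echo_series`, `ctlike_image` or numeric array.
#' @return A positive scalar.
#' @export
default_epsilon <- function(x) {
  v <- if (inherits(x, "echo_series")) unlist(x$volumes, use.names = FALSE)
       else if (inherits(x, "ctlike_image")) x$data
       else x
  eps <- 1e-3 * as.numeric(quantile(v, 0.99, names = FALSE))
  abort_if(!is.finite(eps) || eps <= 0,
           "cannot derive a positive epsilon: 99th-percentile intensity is not positive")
  eps
}

invert_values <- function(v, epsilon, inversion) {
  if (inversion == "reciprocal") {
    1 / pmax(v, epsilon)
  } else {
    pmax(max(v) - v, 0)
  }
}

#' Invert an intensity volume to CT-like contrast
#'
#' Maps low signal (cortical bone, which is dark on the source magnitude
#' images) to high output intensity so bone appears bright on a dark soft
#' tissue background, as in CT. The default is the literal reciprocal
#' `1 / max(SI, epsilon)`: monotone order-reversing, bounded above by
#' `1/epsilon` (the value taken by exact signal voids). A linear alternative
#' `max(SI) - SI`, common in bone-MRI post-processing, is available via
#' `inversion = "linear"`.
#'
#' @param volume non-negative 3-D intensity array.
#' @param epsilon positive clamp applied before the reciprocal; default
#'   [default_epsilon()] of the volume. Ignored by the linear mode.
#' @param inversion `"reciprocal"` (default) or `"linear"`.
#' @param voxel_size mm per axis (metadata).
#' @param sequence source sequence name (metadata).
#' @param mode processing label stored in the result's provenance.
#' @return A `ctlike_image`.
#' @export
invert_image <- function(volume, epsilon = default_epsilon(volume),
                         inversion = c("reciprocal", "linear"),
                         voxel_size = c(1, 1, 1), sequence = "unknown",
                         mode = "first_echo") {
  inversion <- match.arg(inversion)
  abort_if(!is_scalar_number(epsilon) || epsilon <= 0, "epsilon must be > 0")
  out <- invert_values(volume, epsilon, inversion)
  new_ctlike_image(out, voxel_size, sequence, mode, inversion, epsilon)
}

#' Produce a CT-like image from a multi-echo series
#'
#' `process_first_echo()` inverts the earliest-TE volume only. `process_multi_echo()`
#' first averages all echoes voxelwise with equal weights and inverts the
#' average; averaging reduces the noise level before the inversion amplifies
#' low-signal voxels, which is the mechanism behind the contrast-to-noise
#' benefit of multi-echo processing.
#'
#' @param series an `echo_series` with at least one echo.
#' @param epsilon positive reciprocal clamp; default [default_epsilon()] of the
#'   series (shared by both processing modes so they are comparable).
#' @param inversion `"reciprocal"` (default) or `"linear"`.
#' @return A `ctlike_image` with provenance `mode = "first_echo"` or
#'   `"multi_echo"`.
#' @export
#' @examples
#' lm <- build_phantom(phantom_spec(grid_shape = c(24, 24, 16)))
#' es <- simulate_echo_series(lm, ute_sequence(), noise_sigma = 0.03, seed = 1)
#' process_multi_echo(es)
process_first_echo <- function(series, epsilon = default_epsilon(series),
                               inversion = c("reciprocal", "linear")) {
  abort_if(!inherits(series, "echo_series") || length(series$volumes) < 1,
           "series must be an echo_series with at least one echo")
  inversion <- match.arg(inversion)
  first <- which.min(series$echo_times)
  img <- invert_image(series$volumes[[first]], epsilon, inversion,
                      voxel_size = series$voxel_size, sequence = series$sequence,
                      mode = "first_echo")
  img
}

#' @rdname process_first_echo
#' @export
process_multi_echo <- function(series, epsilon = default_epsilon(series),
                               inversion = c("reciprocal", "linear")) {
  abort_if(!inherits(series, "echo_series") || length(series$volumes) < 1,
           "series must be an echo_series with at least one echo")
  inversion <- match.arg(inversion)
  # rowMeans accumulates in extended precision, so a series whose echoes are
  # identical averages to exactly the first echo (bitwise)
  n_vox <- length(series$volumes[[1]])
  mean_vol <- rowMeans(matrix(unlist(series$volumes, use.names = FALSE), nrow = n_vox))
  dim(mean_vol) <- dim(series$volumes[[1]])
  img <- invert_image(mean_vol, epsilon, inversion,
                      voxel_size = series$voxel_size, sequence = series$sequence,
                      mode = "multi_echo")
  img
}
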