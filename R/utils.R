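# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_if <- function(cond, msg) {
  if (isTRUE(cond)) stop(msg, call. = FALSE)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# voxel-center physical coordinate of 1-based index i: (i - 1) * voxel_size
index_to_mm <- function(i, voxel_size) (i - 1) * voxel_size
mm_to_index <- function(x, voxel_size) x / voxel_size + 1

# zero out the one-voxel border of a logical matrix; erosion treats everything
# outside the array as background, which EBImage does not guarantee at edges
clear_border <- function(m) {
  m[1L, ] <- FALSE
  m[nrow(m), ] <- FALSE
  m[, 1L] <- FALSE
  m[, ncol(m)] <- FALSE
  m
}

erode_mask <- function(m) {
  stopifnot(is.matrix(m))
  e <- EBImage::erode(matrix(as.numeric(m), nrow(m), ncol(m)),
                      EBImage::makeBrush(3L, shape = "box"))
  clear_border(e > 0.5)
}
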