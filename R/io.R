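nifti_with_spacing <- function(arr, voxel_size) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- voxel_size
  img
}

#' Write or read a multi-echo series as NIfTI files
#'
#' Each echo is written as one NIfTI volume; a JSON sidecar records the
#' sequence name, echo times (ms) and voxel size so that a series can be
#' re-read without external bookkeeping.
#'
#' @param series an `echo_series`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix; files are named
#'   `<prefix>_echo<i>.nii.gz` plus `<prefix>.json`.
#' @return `write_echo_series()` returns the sidecar path invisibly.
#' @export
write_echo_series <- function(series, dir, prefix = tolower(series$sequence)) {
  abort_if(!inherits(series, "echo_series"), "series must be an echo_series")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, sprintf("%s_echo%d.nii.gz", prefix, seq_along(series$volumes)))
  for (i in seq_along(series$volumes)) {
    RNifti::writeNifti(nifti_with_spacing(series$volumes[[i]], series$voxel_size), paths[i])
  }
  sidecar <- file.path(dir, paste0(prefix, ".json"))
  jsonlite::write_json(list(sequence = series$sequence,
                            echo_times_ms = series$echo_times,
                            voxel_size_mm = series$voxel_size,
                            files = basename(paths)),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' @rdname write_echo_series
#' @param paths NIfTI file paths, one per echo, in echo order. Alternatively a
#'   single JSON sidecar path written by `write_echo_series()`.
#' @param echo_times echo times in ms matching `paths` (not needed when reading
#'   from a sidecar).
#' @param sequence sequence name (default taken from the sidecar, else
#'   `"unknown"`).
#' @return `read_echo_series()` returns an `echo_series`.
#' @export
read_echo_series <- function(paths, echo_times = NULL, sequence = NULL) {
  if (length(paths) == 1 && grepl("\\.json$", paths)) {
    side <- jsonlite::read_json(paths, simplifyVector = TRUE)
    return(read_echo_series(file.path(dirname(paths), side$files),
                            echo_times = side$echo_times_ms,
                            sequence = side$sequence))
  }
  abort_if(is.null(echo_times), "echo_times must be given when reading from NIfTI paths")
  abort_if(length(paths) != length(echo_times),
           sprintf("%d file(s) but %d echo time(s)", length(paths), length(echo_times)))
  abort_if(length(echo_times) > 1 && any(diff(echo_times) <= 0),
           "echo_times must be strictly increasing")
  missing <- paths[!file.exists(paths)]
  abort_if(length(missing) > 0, paste0("file(s) not found: ", paste(missing, collapse = ", ")))
  imgs <- lapply(paths, RNifti::readNifti)
  dims <- lapply(imgs, dim)
  abort_if(!all(vapply(dims, identical, logical(1), dims[[1]])),
           "echo volumes differ in shape")
  spacings <- lapply(imgs, function(x) RNifti::pixdim(x)[1:3])
  abort_if(!all(vapply(spacings, function(s) isTRUE(all.equal(s, spacings[[1]])), logical(1))),
           "echo volumes differ in voxel spacing")
  new_echo_series(lapply(imgs, function(x) {
    a <- as.array(x)
    attributes(a) <- list(dim = dim(a))
    a
  }), echo_times, spacings[[1]], sequence %||% "unknown")
}

#' Write a label map or CT-like image as NIfTI
#'
#' @param x a `label_map` (written with integer datatype) or `ctlike_image`.
#' @param path output NIfTI path.
#' @return `path`, invisibly.
#' @export
write_label_map <- function(x, path) {
  abort_if(!inherits(x, "label_map"), "x must be a label_map")
  img <- nifti_with_spacing(array(as.integer(x$labels), dim = dim(x$labels)),
                            x$voxel_size)
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}

#' @rdname write_label_map
#' @export
write_ctlike_image <- function(x, path) {
  abort_if(!inherits(x, "ctlike_image"), "x must be a ctlike_image")
  RNifti::writeNifti(nifti_with_spacing(x$data, x$voxel_size), path)
  invisible(path)
}
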