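#' Tissue parameter table
#'
#' Relaxation and proton-density parameters for the tissues of the digital
#' spine phantom. Signal in a magnitude image is modelled as
#' `rho * exp(-TE / t2star)`, so `rho` sets the asymptotic (TE = 0) intensity
#' and `t2star` the mono-exponential decay constant in milliseconds.
#'
#' @param name character tissue labels.
#' @param rho relative proton density, dimensionless, `>= 0` (0 for air).
#' @param t2star effective transverse relaxation time in ms, `> 0`.
#'
#' @return A tibble with columns `name`, `rho`, `t2star`. Row order defines the
#'   integer label codes used in a [build_phantom()] label map.
#' @export
#' @examples
#' tissue_params(c("air", "cortical_bone"), c(0, 0.25), c(1, 0.4))
tissue_params <- function(name, rho, t2star) {
  abort_if(!is.character(name) || anyDuplicated(name) > 0,
           "tissue names must be unique character strings")
  abort_if(!is.numeric(rho) || any(!is.finite(rho)) || any(rho < 0),
           "rho must be finite and >= 0")
  abort_if(!is.numeric(t2star) || any(!is.finite(t2star)) || any(t2star <= 0),
           "t2star must be finite and > 0")
  abort_if(length(name) != length(rho) || length(name) != length(t2star),
           "name, rho and t2star must have equal length")
  tibble::tibble(name = name, rho = as.numeric(rho), t2star = as.numeric(t2star))
}

#' Default phantom tissues
#'
#' Literature-typical 3-T values chosen to reproduce the qualitative contrast
#' of bone-oriented spine imaging: cortical bone has a very short T2* so it is
#' faintly visible at an ultrashort TE (0.1 ms) and a signal void at
#' conventional gradient-echo TEs (>= 4 ms), while muscle and marrow decay
#' slowly. Air carries no signal; its `t2star` is a placeholder.
#'
#' @return A tibble of tissue parameters (see [tissue_params()]) containing
#'   `air`, `cortical_bone`, `muscle` and `marrow`.
#' @export
default_tissues <- function() {
  tissue_params(
    name   = c("air", "cortical_bone", "muscle", "marrow"),
    rho    = c(0,     0.25,            1.0,      1.1),
    t2star = c(1,     0.4,             28,       45)
  )
}

required_tissues <- c("air", "cortical_bone", "muscle", "marrow")

# Slab-and-plate geometry, in 1-based voxel index boxes.
#
# A muscle slab fills the centre of the grid, surrounded by air. A cortical
# bone plate (the pars-like structure) runs along the third axis inside the
# muscle, with a marrow core box between the plate and the anterior muscle
# margin. All sizes scale with the grid so small test phantoms remain valid.
phantom_geometry <- function(grid_shape) {
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  mxy <- max(2L, round(0.19 * min(nx, ny)))
  mz <- max(1L, round(0.06 * nz))
  muscle <- list(x = c(mxy + 1L, nx - mxy),
                 y = c(mxy + 1L, ny - mxy),
                 z = c(mz + 1L, nz - mz))
  cx <- (nx + 1) / 2
  hl <- max(2L, round(0.16 * nx))          # plate half-length along x
  ht <- max(1L, round(0.035 * ny))         # plate half-thickness along y
  cy <- round(0.47 * ny)
  zgap <- max(1L, round(0.12 * nz))
  plate <- list(x = c(ceiling(cx - hl), floor(cx + hl)),
                y = c(cy - ht, cy + ht),
                z = c(muscle$z[1] + zgap, muscle$z[2] - zgap))
  marrow <- list(x = c(plate$x[1] + 2L, plate$x[2] - 2L),
                 y = c(muscle$y[1] + 1L, plate$y[1] - 1L),
                 z = c(plate$z[1] + 1L, plate$z[2] - 1L))
  geom <- list(muscle = muscle, plate = plate, marrow = marrow)
  for (nm in names(geom)) {
    b <- geom[[nm]]
    ok <- b$x[1] >= 1 && b$y[1] >= 1 && b$z[1] >= 1 &&
      b$x[2] <= nx && b$y[2] <= ny && b$z[2] <= nz &&
      b$x[1] <= b$x[2] && b$y[1] <= b$y[2] && b$z[1] <= b$z[2]
    abort_if(!ok, sprintf(
      "phantom geometry (%s box) does not fit in a %dx%dx%d grid; use a larger grid",
      nm, nx, ny, nz))
  }
  abort_if(plate$y[1] <= muscle$y[1] + 1L || plate$y[2] >= muscle$y[2],
           "phantom geometry: bone plate must be embedded in muscle; use a larger grid")
  geom
}

#' Specify a synthetic spine phantom
#'
#' Defines the voxel grid, tissue parameters, geometry, optional pars-defect
#' gap and acquisition noise level of a digital phantom. The geometry is a
#' simplified slab-and-plate model: a muscle slab in air, containing a
#' cortical-bone plate running along the third (slice) axis with a marrow core
#' alongside — enough structure to carry every downstream measurement without
#' pretending to be anatomy.
#'
#' @param grid_shape integer voxel counts per axis (default `c(64, 64, 32)`).
#' @param voxel_size voxel edge lengths in mm per axis (default 1 mm isotropic,
#'   matching a typical 1 mm reconstructed slice).
#' @param tissues tissue parameter tibble from [tissue_params()]; must contain
#'   at least `air`, `cortical_bone`, `muscle`, `marrow`.
#' @param defect_width width in mm of a gap interrupting the bone plate
#'   (0 = intact). Must be smaller than the plate extent.
#' @param defect_center position of the gap centre in mm along the plate axis
#'   (voxel-centre coordinates, first voxel centre at 0). Default: plate
#'   midpoint.
#' @param noise_sigma per-channel SD of the complex Gaussian acquisition noise,
#'   in signal units (default 0.03; see [simulate_echo_series()]).
#' @param seed integer seed for the noise realization (optional).
#'
#' @return An object of class `phantom_spec`.
#' @export
#' @examples
#' spec <- phantom_spec(defect_width = 2.5)
#' spec$geometry$plate
phantom_spec <- function(grid_shape = c(64L, 64L, 32L),
                         voxel_size = c(1, 1, 1),
                         tissues = default_tissues(),
                         defect_width = 0,
                         defect_center = NULL,
                         noise_sigma = 0.03,
                         seed = NULL) {
  abort_if(length(grid_shape) != 3 || any(grid_shape < 1),
           "grid_shape must be three positive voxel counts")
  abort_if(length(voxel_size) != 3 || any(voxel_size <= 0),
           "voxel_size must be positive on all axes")
  missing <- setdiff(required_tissues, tissues$name)
  abort_if(length(missing) > 0,
           paste0("tissues must include: ", paste(missing, collapse = ", ")))
  abort_if(!is_scalar_number(defect_width) || defect_width < 0,
           "defect_width must be a single number >= 0")
  abort_if(!is_scalar_number(noise_sigma) || noise_sigma < 0,
           "noise_sigma must be a single number >= 0")
  grid_shape <- as.integer(grid_shape)
  geom <- phantom_geometry(grid_shape)
  plate_mm <- plate_extent_mm(geom, voxel_size)
  abort_if(defect_width >= plate_mm$length,
           sprintf("defect_width (%g mm) must be smaller than the bone-plate extent (%g mm)",
                   defect_width, plate_mm$length))
  if (is.null(defect_center)) defect_center <- plate_mm$mid
  abort_if(!is_scalar_number(defect_center),
           "defect_center must be a single number (mm along the plate axis)")
  structure(list(grid_shape = grid_shape,
                 voxel_size = as.numeric(voxel_size),
                 tissues = tissues,
                 geometry = geom,
                 defect_width = defect_width,
                 defect_center = defect_center,
                 noise_sigma = noise_sigma,
                 seed = seed),
            class = "phantom_spec")
}

plate_extent_mm <- function(geom, voxel_size) {
  z0 <- index_to_mm(geom$plate$z[1], voxel_size[3])
  z1 <- index_to_mm(geom$plate$z[2], voxel_size[3])
  list(lo = z0, hi = z1, mid = (z0 + z1) / 2,
       length = (geom$plate$z[2] - geom$plate$z[1] + 1L) * voxel_size[3])
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %s voxels @ %s mm\n",
              paste(x$grid_shape, collapse = "x"),
              paste(signif(x$voxel_size, 3), collapse = "x")))
  cat(sprintf("  tissues: %s\n", paste(x$tissues$name, collapse = ", ")))
  cat(sprintf("  defect: %g mm at %g mm; noise_sigma = %g\n",
              x$defect_width, x$defect_center, x$noise_sigma))
  invisible(x)
}

fill_box <- function(labels, box, value) {
  labels[box$x[1]:box$x[2], box$y[1]:box$y[2], box$z[1]:box$z[2]] <- value
  labels
}

tissue_code <- function(tissues, name) {
  i <- match(name, tissues$name)
  abort_if(is.na(i), sprintf("tissue '%s' is missing from the parameter table", name))
  i
}

#' Build a phantom label map
#'
#' Voxelizes the geometry of a [phantom_spec()] into a 3-D grid of integer
#' tissue labels (row indices into `spec$tissues`) and applies the pars-defect
#' gap if `defect_width > 0`. Construction is purely geometric and therefore
#' bit-reproducible for a fixed spec.
#'
#' @param spec a `phantom_spec`.
#' @return An object of class `label_map`: a list with `labels` (3-D integer
#'   array), `voxel_size`, `tissues` and `geometry`.
#' @export
#' @examples
#' lm <- build_phantom(phantom_spec(grid_shape = c(24, 24, 16)))
#' table(lm$tissues$name[lm$labels])
build_phantom <- function(spec) {
  abort_if(!inherits(spec, "phantom_spec"), "spec must be a phantom_spec")
  geom <- spec$geometry
  labels <- array(tissue_code(spec$tissues, "air"), dim = spec$grid_shape)
  labels <- fill_box(labels, geom$muscle, tissue_code(spec$tissues, "muscle"))
  labels <- fill_box(labels, geom$marrow, tissue_code(spec$tissues, "marrow"))
  labels <- fill_box(labels, geom$plate, tissue_code(spec$tissues, "cortical_bone"))
  lm <- structure(list(labels = labels,
                       voxel_size = spec$voxel_size,
                       tissues = spec$tissues,
                       geometry = geom),
                  class = "label_map")
  if (spec$defect_width > 0) {
    lm <- insert_defect(lm, spec$defect_width, spec$defect_center)
  }
  lm
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map> %s voxels @ %s mm\n",
              paste(dim(x$labels), collapse = "x"),
              paste(signif(x$voxel_size, 3), collapse = "x")))
  counts <- table(factor(x$labels, levels = seq_len(nrow(x$tissues)),
                         labels = x$tissues$name))
  print(counts)
  invisible(x)
}

#' Interrupt the bone plate with a defect gap
#'
#' Relabels bone voxels as muscle over a contiguous run of voxel columns along
#' the plate axis, emulating a pars fracture gap (non-union). The gap covers
#' the `round(width / voxel)` columns nearest `center`, so its voxel extent is
#' the requested width rounded to whole voxels; no other voxel changes.
#'
#' @param labels a `label_map` from [build_phantom()].
#' @param width gap width in mm, `>= 0` (0 returns the input unchanged) and at
#'   most the plate length.
#' @param center gap centre in mm along the plate axis; must lie within the
#'   plate.
#' @return The modified `label_map`.
#' @export
insert_defect <- function(labels, width, center) {
  abort_if(!inherits(labels, "label_map"), "labels must be a label_map")
  abort_if(!is_scalar_number(width) || width < 0, "width must be a single number >= 0")
  vz <- labels$voxel_size[3]
  plate <- labels$geometry$plate
  ext <- plate_extent_mm(labels$geometry, labels$voxel_size)
  abort_if(!is_scalar_number(center) || center < ext$lo || center > ext$hi,
           sprintf("defect center %g mm is outside the bone plate (%g-%g mm)",
                   center, ext$lo, ext$hi))
  abort_if(width > ext$length,
           sprintf("defect width %g mm exceeds the plate length (%g mm)", width, ext$length))
  n <- round(width / vz)
  if (n == 0) return(labels)
  start <- ceiling(mm_to_index(center, vz) - n / 2)
  cols <- start:(start + n - 1L)
  cols <- cols[cols >= plate$z[1] & cols <= plate$z[2]]
  bone <- tissue_code(labels$tissues, "cortical_bone")
  muscle <- tissue_code(labels$tissues, "muscle")
  sub <- labels$labels[plate$x[1]:plate$x[2], plate$y[1]:plate$y[2], cols, drop = FALSE]
  sub[sub == bone] <- muscle
  labels$labels[plate$x[1]:plate$x[2], plate$y[1]:plate$y[2], cols] <- sub
  labels
}

#' Derive ROI masks for one slice
#'
#' Builds the three measurement regions used for SNR/CNR: cortical bone of the
#' plate, adjacent muscle, and background air, on a single slice along the
#' third axis. Each mask is the corresponding tissue label on that slice eroded
#' by one voxel (3x3 box), so partial-volume boundary voxels never enter the
#' statistics. Masks are pairwise disjoint by construction; each must retain at
#' least 25 voxels so ROI means and SDs are stable.
#'
#' @param labels a `label_map`.
#' @param slice_index 1-based index of the slice along the third axis.
#' @return An object of class `roi_set`: logical matrices `bone_mask`,
#'   `muscle_mask`, `air_mask`, plus `slice_index` and `voxel_size`.
#' @export
derive_roi_masks <- function(labels, slice_index) {
  abort_if(!inherits(labels, "label_map"), "labels must be a label_map")
  nz <- dim(labels$labels)[3]
  abort_if(!is_scalar_number(slice_index) || slice_index < 1 || slice_index > nz,
           sprintf("slice_index must be in 1..%d", nz))
  slice <- labels$labels[, , slice_index]
  masks <- lapply(c(bone = "cortical_bone", muscle = "muscle", air = "air"),
                  function(nm) erode_mask(slice == tissue_code(labels$tissues, nm)))
  for (nm in names(masks)) {
    abort_if(sum(masks[[nm]]) < 25,
             sprintf(paste0("%s ROI has fewer than 25 voxels after one-voxel erosion ",
                            "on slice %d; use a larger phantom or another slice"),
                     nm, slice_index))
  }
  structure(list(bone_mask = masks$bone,
                 muscle_mask = masks$muscle,
                 air_mask = masks$air,
                 slice_index = as.integer(slice_index),
                 voxel_size = labels$voxel_size),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> slice %d: bone %d, muscle %d, air %d voxels\n",
              x$slice_index, sum(x$bone_mask), sum(x$muscle_mask), sum(x$air_mask)))
  invisible(x)
}

#' Read or write a phantom specification file
#'
#' A `phantom_spec` serializes to a YAML key/value file holding `grid_shape`,
#' `voxel_size`, the tissue table, `defect_width`, `defect_center`,
#' `noise_sigma` and `seed`. Geometry is recomputed from the grid on read.
#'
#' @param spec a `phantom_spec`.
#' @param path file path.
#' @return `read_phantom_config()` returns a `phantom_spec`;
#'   `write_phantom_config()` returns `path` invisibly.
#' @export
write_phantom_config <- function(spec, path) {
  abort_if(!inherits(spec, "phantom_spec"), "spec must be a phantom_spec")
  yaml::write_yaml(list(
    grid_shape = spec$grid_shape,
    voxel_size = spec$voxel_size,
    tissues = lapply(seq_len(nrow(spec$tissues)), function(i) as.list(spec$tissues[i, ])),
    defect_width = spec$defect_width,
    defect_center = spec$defect_center,
    noise_sigma = spec$noise_sigma,
    seed = spec$seed
  ), path)
  invisible(path)
}

#' @rdname write_phantom_config
#' @export
read_phantom_config <- function(path) {
  abort_if(!file.exists(path), sprintf("config file '%s' not found", path))
  cfg <- yaml::read_yaml(path)
  tis <- dplyr::bind_rows(lapply(cfg$tissues, tibble::as_tibble))
  phantom_spec(grid_shape = cfg$grid_shape,
               voxel_size = cfg$voxel_size,
               tissues = tissue_params(tis$name, tis$rho, tis$t2star),
               defect_width = cfg$defect_width %||% 0,
               defect_center = cfg$defect_center,
               noise_sigma = cfg$noise_sigma %||% 0.03,
               seed = cfg$seed)
}
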