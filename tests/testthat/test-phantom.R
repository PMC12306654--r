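bone_code <- function(lm) match("cortical_bone", lm$tissues$name)
muscle_code <- function(lm) match("muscle", lm$tissues$name)

bone_slices <- function(lm) {
  which(apply(lm$labels == bone_code(lm), 3, any))
}

test_that("intact phantom contains all tissues and a connected bone plate", {
  lm <- build_phantom(tiny_spec())
  present <- sort(unique(as.vector(lm$labels)))
  expect_setequal(lm$tissues$name[present],
                  c("air", "cortical_bone", "muscle", "marrow"))
  z <- bone_slices(lm)
  expect_equal(z, seq(min(z), max(z)))  # no gap along the plate axis
})

test_that("phantom construction is deterministic and geometry-only", {
  expect_identical(build_phantom(tiny_spec())$labels,
                   build_phantom(tiny_spec())$labels)
  # relaxation/density values must not influence the geometry
  other <- tissue_params(c("air", "cortical_bone", "muscle", "marrow"),
                         rho = c(0, 0.9, 0.4, 0.2), t2star = c(5, 3, 2, 1))
  lm1 <- build_phantom(tiny_spec())
  lm2 <- build_phantom(tiny_spec(tissues = other))
  expect_identical(lm1$labels, lm2$labels)
})

test_that("a defect splits the plate into two components of the right gap", {
  lm <- build_phantom(phantom_spec(defect_width = 3))
  z <- bone_slices(lm)
  runs <- split(z, cumsum(c(1, diff(z) != 1)))
  expect_length(runs, 2)
  gap <- min(runs[[2]]) - max(runs[[1]]) - 1
  expect_equal(gap, 3)
})

test_that("insert_defect relabels exactly the expected voxels", {
  lm <- build_phantom(phantom_spec())
  mid <- mean(lm$geometry$plate$z) - 1  # voxel-centre mm at 1 mm voxels

  expect_identical(insert_defect(lm, 0, mid)$labels, lm$labels)

  per_col <- sum(lm$labels[, , lm$geometry$plate$z[1]] == bone_code(lm))
  for (w in c(2, 2.5)) {
    out <- insert_defect(lm, w, mid)
    changed <- which(out$labels != lm$labels)
    expect_length(changed, 2 * per_col)  # both widths round to 2 voxel columns
    expect_true(all(lm$labels[changed] == bone_code(lm)))
    expect_true(all(out$labels[changed] == muscle_code(lm)))
    expect_equal(length(out$labels), length(lm$labels))
  }

  out3 <- insert_defect(lm, 3, mid)
  expect_equal(sum(out3$labels != lm$labels), 3 * per_col)

  # limiting case: gap as long as the plate removes all bone
  full <- insert_defect(lm, diff(lm$geometry$plate$z) + 1, mid)
  expect_equal(sum(full$labels == bone_code(lm)), 0)

  expect_error(insert_defect(lm, 2, center = 1000), "outside the bone plate")
})

test_that("defect width is validated against the plate in phantom_spec", {
  expect_error(phantom_spec(defect_width = 1000), "smaller than the bone-plate")
  expect_error(phantom_spec(defect_width = -1), ">= 0")
})

test_that("ROI masks are eroded, disjoint, and geometry-determined", {
  lm <- build_phantom(roi_spec())
  s <- roi_slice_for(lm)
  rois <- derive_roi_masks(lm, s)
  slice <- lm$labels[, , s]

  for (nm in c("bone", "muscle", "air")) {
    mask <- rois[[paste0(nm, "_mask")]]
    code <- match(c(bone = "cortical_bone", muscle = "muscle", air = "air")[[nm]],
                  lm$tissues$name)
    expect_true(all(slice[mask] == code))          # subset of own label
    expect_lte(sum(mask), sum(slice == code))      # erosion shrinks
    expect_gte(sum(mask), 25)
  }
  expect_equal(sum(rois$bone_mask & rois$muscle_mask), 0)
  expect_equal(sum(rois$bone_mask & rois$air_mask), 0)
  expect_equal(sum(rois$muscle_mask & rois$air_mask), 0)

  # tissue parameter values cannot move the masks
  other <- tissue_params(c("air", "cortical_bone", "muscle", "marrow"),
                         rho = c(0, 2, 3, 4), t2star = c(9, 8, 7, 6))
  rois2 <- derive_roi_masks(build_phantom(roi_spec(tissues = other)), s)
  expect_identical(rois$bone_mask, rois2$bone_mask)
})

test_that("ROI derivation fails clearly on unusable slices", {
  lm <- build_phantom(roi_spec())
  expect_error(derive_roi_masks(lm, 1), "fewer than 25 voxels")  # air-only slice
  small <- build_phantom(phantom_spec(grid_shape = c(16, 16, 16)))
  expect_error(derive_roi_masks(small, roi_slice_for(small)), "larger phantom")
})

test_that("phantom spec survives a config-file round trip", {
  spec <- phantom_spec(grid_shape = c(32, 32, 16), defect_width = 2.5,
                       noise_sigma = 0.01, seed = 7L)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_phantom_config(spec, path)
  back <- read_phantom_config(path)
  expect_equal(back$grid_shape, spec$grid_shape)
  expect_equal(back$tissues, spec$tissues)
  expect_equal(back$defect_width, spec$defect_width)
  expect_equal(back$defect_center, spec$defect_center)
  expect_equal(back$noise_sigma, spec$noise_sigma)
  expect_identical(build_phantom(back)$labels, build_phantom(spec)$labels)
})

test_that("geometry that cannot fit the grid is rejected", {
  expect_error(phantom_spec(grid_shape = c(6, 6, 6)), "larger grid")
})
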