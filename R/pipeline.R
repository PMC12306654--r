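#' Configure an end-to-end phantom study
#'
#' Bundles everything [run_pipeline()] needs to emulate a small imaging study:
#' a phantom, a set of simulated subjects (one RNG seed each; subject-to-
#' subject variability comes from the noise realization plus a multiplicative
#' jitter on tissue proton densities), the sequences to acquire, and the
#' processing/measurement conventions.
#'
#' @param phantom a [phantom_spec()].
#' @param seeds integer RNG seeds, one per simulated subject; must be
#'   distinct. Default: 4 subjects seeded 101-104.
#' @param sequences list of [sequence_params()]; default UTE and FE.
#' @param inversion `"reciprocal"` or `"linear"` (see [invert_image()]).
#' @param epsilon reciprocal clamp; `NULL` (default) derives
#'   [default_epsilon()] per echo series.
#' @param rho_jitter half-width of the uniform multiplicative jitter applied
#'   to each tissue's proton density per subject (default 0.05, i.e. +/- 5%).
#' @param roi_slice slice used for SNR/CNR ROIs; `NULL` picks an intact slice
#'   near the start of the bone plate.
#' @param cov_slices consecutive slices for the slice-consistency CoV;
#'   `NULL` picks the 5 slices starting at `roi_slice`.
#' @param profile `NULL` for the default defect-crossing line (used when
#'   `phantom$defect_width > 0`), `FALSE` to skip profile measurement, or a
#'   list with elements `start`, `end` (mm points), and optionally
#'   `n_samples` and `orientation`.
#' @param out_dir directory for artifacts (NIfTI volumes, CSVs, manifest);
#'   `NULL` keeps everything in memory.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(phantom = phantom_spec(),
                            seeds = 101:104,
                            sequences = list(ute_sequence(), fe_sequence()),
                            inversion = c("reciprocal", "linear"),
                            epsilon = NULL,
                            rho_jitter = 0.05,
                            roi_slice = NULL,
                            cov_slices = NULL,
                            profile = NULL,
                            out_dir = NULL) {
  abort_if(!inherits(phantom, "phantom_spec"), "phantom must be a phantom_spec")
  abort_if(length(seeds) < 1 || anyDuplicated(seeds) > 0,
           "seeds must be distinct, one per simulated subject")
  abort_if(!all(vapply(sequences, inherits, logical(1), "sequence_params")),
           "sequences must be sequence_params objects")
  abort_if(anyDuplicated(vapply(sequences, function(s) s$name, character(1))) > 0,
           "sequence names must be distinct")
  inversion <- match.arg(inversion)
  abort_if(!is_scalar_number(rho_jitter) || rho_jitter < 0 || rho_jitter >= 1,
           "rho_jitter must be in [0, 1)")
  plate_z <- phantom$geometry$plate$z
  roi_slice <- roi_slice %||% (plate_z[1] + 3L)
  abort_if(roi_slice < plate_z[1] || roi_slice > plate_z[2],
           "roi_slice must intersect the bone plate")
  # default consistency slices hug the start of the plate, clear of the
  # (centred) defect gap
  cov_slices <- cov_slices %||% seq.int(plate_z[1] + 1L, min(plate_z[1] + 5L, plate_z[2]))
  structure(list(phantom = phantom, seeds = as.integer(seeds),
                 sequences = sequences, inversion = inversion,
                 epsilon = epsilon, rho_jitter = rho_jitter,
                 roi_slice = as.integer(roi_slice),
                 cov_slices = as.integer(cov_slices),
                 profile = profile, out_dir = out_dir),
            class = "pipeline_config")
}

default_profile_line <- function(labels) {
  g <- labels$geometry$plate
  vs <- labels$voxel_size
  cx <- index_to_mm(mean(g$x), vs[1])
  cy <- index_to_mm(mean(g$y), vs[2])
  z0 <- index_to_mm(g$z[1], vs[3]) + vs[3]
  z1 <- index_to_mm(g$z[2], vs[3]) - vs[3]
  list(start = c(cx, cy, z0), end = c(cx, cy, z1),
       n_samples = max(2L, round((z1 - z0) / (vs[3] / 4)) + 1L),
       orientation = "dip")
}

#' Run the full phantom-study pipeline
#'
#' For each simulated subject and sequence: simulate the multi-echo
#' acquisition, produce first-echo and multi-echo CT-like images, and measure
#' bone SNR, muscle SNR and bone-muscle CNR on the configured ROI slice. The
#' per-subject records are then summarised with [build_metrics_report()]
#' (condition means/SDs plus the sequence-by-processing ANOVA per measure).
#' When the phantom carries a defect, the gap width is additionally measured
#' as the FWHM of a dip in a profile along the bone plate of every multi-echo
#' image, and slice-to-slice consistency of the bone ROI is reported as a CoV
#' over consecutive slices.
#'
#' @param config a [pipeline_config()].
#' @return An object of class `pipeline_result`: `records` (one row per
#'   subject x sequence x processing), `report` (a `metrics_report`), `fwhm`
#'   (tibble or `NULL`), `slice_cov` (tibble), `manifest` (list of settings),
#'   and `rois`.
#' @export
#' @examples
#' \donttest{
#' cfg <- pipeline_config(phantom_spec(grid_shape = c(48, 48, 24)), seeds = 11:14)
#' res <- run_pipeline(cfg)
#' res$report
#' }
run_pipeline <- function(config) {
  abort_if(!inherits(config, "pipeline_config"), "config must be a pipeline_config")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  phantom <- config$phantom
  labels <- stage("phantom", build_phantom(phantom))
  rois <- stage("roi", derive_roi_masks(labels, config$roi_slice))
  cov_masks <- stage("roi", lapply(config$cov_slices, function(s)
    derive_roi_masks(labels, s)$bone_mask))

  profile_line <- config$profile
  measure_profile <- !isFALSE(profile_line) &&
    (!is.null(profile_line) || phantom$defect_width > 0)
  if (measure_profile && is.null(profile_line)) {
    profile_line <- default_profile_line(labels)
  }

  subjects <- sprintf("subj%02d", seq_along(config$seeds))
  records <- list(); fwhm_rows <- list(); cov_rows <- list()
  images_out <- list()
  for (i in seq_along(config$seeds)) {
    sid <- subjects[i]
    sims <- stage("simulate", withr::with_seed(config$seeds[i], {
      jit <- 1 + runif(nrow(phantom$tissues), -config$rho_jitter, config$rho_jitter)
      tissues_i <- phantom$tissues
      tissues_i$rho <- tissues_i$rho * jit
      lapply(config$sequences, function(sq)
        simulate_echo_series(labels, sq, tissues = tissues_i,
                             noise_sigma = phantom$noise_sigma))
    }))
    for (series in sims) {
      eps <- config$epsilon %||% default_epsilon(series)
      for (mode in c("first_echo", "multi_echo")) {
        img <- stage("process", switch(mode,
          first_echo = process_first_echo(series, eps, config$inversion),
          multi_echo = process_multi_echo(series, eps, config$inversion)))
        records[[length(records) + 1L]] <- stage("metrics",
          compute_image_metrics(img, rois, subject_id = sid))
        cov_rows[[length(cov_rows) + 1L]] <- tibble::tibble(
          subject_id = sid, sequence = series$sequence, processing = mode,
          cov_pct = stage("metrics", slice_cov(img, cov_masks, config$cov_slices)))
        if (measure_profile && mode == "multi_echo") {
          prof <- stage("profile", extract_profile(
            img, profile_line$start, profile_line$end,
            n_samples = profile_line$n_samples %||% 201))
          fw <- measure_fwhm(prof, orientation = profile_line$orientation %||% "dip")
          fwhm_rows[[length(fwhm_rows) + 1L]] <- tibble::tibble(
            subject_id = sid, sequence = series$sequence, fwhm = fw$fwhm)
        }
        if (!is.null(config$out_dir)) {
          images_out[[paste(sid, series$sequence, mode, sep = "_")]] <- img
        }
      }
      if (!is.null(config$out_dir)) {
        stage("write", write_echo_series(
          series, file.path(config$out_dir, sid),
          prefix = tolower(series$sequence)))
      }
    }
  }
  records <- dplyr::bind_rows(records)
  report <- stage("report", build_metrics_report(records))
  fwhm <- if (length(fwhm_rows)) dplyr::bind_rows(fwhm_rows) else NULL
  cov_tbl <- dplyr::bind_rows(cov_rows)
  manifest <- list(package_version = as.character(utils::packageVersion("bonemri")),
                   seeds = config$seeds,
                   grid_shape = phantom$grid_shape,
                   voxel_size = phantom$voxel_size,
                   noise_sigma = phantom$noise_sigma,
                   defect_width = phantom$defect_width,
                   defect_center = phantom$defect_center,
                   inversion = config$inversion,
                   epsilon = config$epsilon %||% "per-series 1e-3 x p99",
                   rho_jitter = config$rho_jitter,
                   roi_slice = config$roi_slice,
                   cov_slices = config$cov_slices,
                   sequences = lapply(config$sequences, unclass))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_report(report, config$out_dir)
    write.csv(cov_tbl, file.path(config$out_dir, "slice_cov.csv"), row.names = FALSE)
    if (!is.null(fwhm)) {
      write.csv(fwhm, file.path(config$out_dir, "fwhm.csv"), row.names = FALSE)
    }
    for (nm in names(images_out)) {
      write_ctlike_image(images_out[[nm]],
                         file.path(config$out_dir, paste0(nm, ".nii.gz")))
    }
    write_label_map(labels, file.path(config$out_dir, "labels.nii.gz"))
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(list(records = records, report = report, fwhm = fwhm,
                 slice_cov = cov_tbl, manifest = manifest, rois = rois),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d records (%d subjects)\n",
              nrow(x$records), dplyr::n_distinct(x$records$subject_id)))
  print(x$report)
  if (!is.null(x$fwhm)) {
    cat("\nDefect FWHM (mm) on multi-echo images\n")
    print(as.data.frame(x$fwhm), row.names = FALSE)
  }
  invisible(x)
}

#' Generate the tiny on-disk fixtures used by the test suite
#'
#' Writes 16-cubed noiseless and noisy UTE-like and FE-like echo series (NIfTI
#' volumes with JSON sidecars), the phantom label map and per-tissue mask
#' volumes, plus a small balanced factorial table CSV. Everything is generated
#' from code under fixed seeds, so repeated calls produce identical files.
#'
#' @param out_dir writable output directory.
#' @param seed RNG seed for the noisy series and the factorial table.
#' @return The output directory, invisibly.
#' @export
generate_fixtures <- function(out_dir, seed = 42L) {
  abort_if(!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE),
           sprintf("cannot create fixture directory '%s'", out_dir))
  spec <- phantom_spec(grid_shape = c(16L, 16L, 16L), noise_sigma = 0.03)
  labels <- build_phantom(spec)
  write_label_map(labels, file.path(out_dir, "labels.nii.gz"))
  for (nm in required_tissues) {
    mask <- array(as.integer(labels$labels == tissue_code(labels$tissues, nm)),
                  dim = dim(labels$labels))
    RNifti::writeNifti(nifti_with_spacing(mask, labels$voxel_size),
                       file.path(out_dir, paste0("mask_", nm, ".nii.gz")),
                       datatype = "uint8")
  }
  for (sq in list(ute_sequence(), fe_sequence())) {
    noiseless <- simulate_echo_series(labels, sq, noise_sigma = 0)
    write_echo_series(noiseless, out_dir,
                      prefix = paste0(tolower(sq$name), "_noiseless"))
    noisy <- simulate_echo_series(labels, sq, noise_sigma = spec$noise_sigma,
                                  seed = seed)
    write_echo_series(noisy, out_dir, prefix = paste0(tolower(sq$name), "_noisy"))
  }
  tab <- withr::with_seed(seed, tidyr::expand_grid(
    sequence = c("UTE", "FE"), processing = c("first_echo", "multi_echo"),
    replicate = 1:3))
  tab$value <- withr::with_seed(seed + 1L,
    round(rnorm(nrow(tab), mean = 20, sd = 4), 4))
  write.csv(tab, file.path(out_dir, "factorial_table.csv"), row.names = FALSE)
  invisible(out_dir)
}
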