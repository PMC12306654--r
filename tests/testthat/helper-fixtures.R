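# Shared fixtures and independent oracles. Phantom grids are kept small where
# geometry alone is under test; ROI-based measurements need at least a 48^3
# footprint so every eroded mask keeps >= 25 voxels.

tiny_spec <- function(...) phantom_spec(grid_shape = c(24L, 24L, 16L), ...)
roi_spec <- function(...) phantom_spec(grid_shape = c(48L, 48L, 24L), ...)

roi_slice_for <- function(labels) labels$geometry$plate$z[1] + 3L

# brute-force voxel-loop oracle for multi-echo inversion: n / sum_i SI_i with
# the same epsilon clamp, computed one voxel at a time
oracle_multi_echo <- function(volumes, epsilon) {
  dims <- dim(volumes[[1]])
  n <- length(volumes)
  out <- array(NA_real_, dims)
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2])) for (k in seq_len(dims[3])) {
    s <- 0
    for (v in volumes) s <- s + v[i, j, k]
    out[i, j, k] <- 1 / max(s / n, epsilon)
  }
  out
}

# least-squares saturated cell-means fit via base R, the independent route
# against the package's balanced sum-of-squares decomposition
oracle_anova <- function(d, response = "value", fa = "A", fb = "B") {
  d[[fa]] <- factor(d[[fa]])
  d[[fb]] <- factor(d[[fb]])
  form <- stats::as.formula(paste(response, "~", fa, "*", fb))
  as.data.frame(stats::anova(stats::lm(form, data = d)))
}

random_balanced_table <- function(a = 2, b = 2, r = 4) {
  d <- expand.grid(A = paste0("a", seq_len(a)),
                   B = paste0("b", seq_len(b)),
                   rep = seq_len(r), stringsAsFactors = FALSE)
  d$value <- rnorm(nrow(d), mean = 5, sd = 2) +
    2 * (d$A == "a1") + runif(1, -1, 1) * (d$B == "b1")
  d
}

# rich synthetic metrics records for report tests
fake_records <- function(n_subjects = 2, offset = 0) {
  grid <- tidyr::expand_grid(subject_id = sprintf("s%d", seq_len(n_subjects)),
                             sequence = c("UTE", "FE"),
                             processing = c("first_echo", "multi_echo"))
  grid$bone_snr <- seq_len(nrow(grid)) + offset
  grid$muscle_snr <- grid$bone_snr / 2
  grid$bone_muscle_cnr <- grid$bone_snr - grid$muscle_snr
  grid
}
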