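#' Balanced two-way factorial ANOVA
#'
#' Fixed-effects analysis of variance for a balanced two-factor design, as
#' used to compare acquisition sequence (UTE vs FE) crossed with processing
#' (first echo vs multi-echo) on an image-quality measure. Sums of squares are
#' computed from cell, marginal and grand means by the standard balanced
#' decomposition; with balance, Type I/II/III sums of squares coincide, so no
#' type choice arises. F statistics are mean squares over the within-cell mean
#' square and p-values come from the upper tail of the F distribution.
#'
#' @param data a data frame of observations, one row per replicate.
#' @param response name of the numeric response column.
#' @param factor_a,factor_b names of the two factor columns (each must have at
#'   least 2 levels and every cell the same replicate count `r >= 2`).
#' @param alpha significance level used to flag terms (default 0.05).
#' @return An object of class `bonemri_anova`; see [tidy.bonemri_anova()].
#' @export
#' @examples
#' d <- expand.grid(seq = c("UTE", "FE"), proc = c("first", "multi"),
#'                  rep = 1:3)
#' d$y <- rnorm(nrow(d)) + 2 * (d$proc == "multi")
#' two_way_anova(d, "y", "seq", "proc")
two_way_anova <- function(data, response = "value", factor_a = "sequence",
                          factor_b = "processing", alpha = 0.05) {
  abort_if(!is.data.frame(data), "data must be a data frame")
  for (col in c(response, factor_a, factor_b)) {
    abort_if(!col %in% names(data), sprintf("column '%s' not found", col))
  }
  y <- data[[response]]
  abort_if(!is.numeric(y) || any(!is.finite(y)), "response must be finite numeric")
  fa <- factor(data[[factor_a]])
  fb <- factor(data[[factor_b]])
  a <- nlevels(fa); b <- nlevels(fb)
  abort_if(a < 2 || b < 2, "each factor needs at least 2 levels")
  counts <- table(fa, fb)
  r <- counts[1]
  abort_if(any(counts != r), "design is unbalanced: every cell must have the same replicate count")
  abort_if(r < 2, "at least 2 replicates per cell are required")

  grand <- mean(y)
  cell <- tapply(y, list(fa, fb), mean)
  ma <- rowMeans(cell)
  mb <- colMeans(cell)
  ss_a <- b * r * sum((ma - grand)^2)
  ss_b <- a * r * sum((mb - grand)^2)
  ss_ab <- r * sum((cell - outer(ma, rep(1, b)) - outer(rep(1, a), mb) + grand)^2)
  fitted <- cell[cbind(as.integer(fa), as.integer(fb))]
  ss_within <- sum((y - fitted)^2)
  ss_total <- sum((y - grand)^2)
  abort_if(ss_within <= 0,
           "zero within-cell variance: F statistics are undefined")

  df <- c(a - 1, b - 1, (a - 1) * (b - 1), a * b * (r - 1))
  ss <- c(ss_a, ss_b, ss_ab, ss_within)
  ms <- ss / df
  f <- c(ms[1:3] / ms[4], NA_real_)
  p <- c(pf(f[1:3], df[1:3], df[4], lower.tail = FALSE), NA_real_)
  terms <- tibble::tibble(
    term = c(factor_a, factor_b, paste0(factor_a, ":", factor_b), "Residuals"),
    df = df, sumsq = ss, meansq = ms, statistic = f, p.value = p,
    significant = !is.na(p) & p < alpha)
  structure(list(terms = terms,
                 ss_total = ss_total,
                 factors = c(factor_a, factor_b),
                 levels = list(levels(fa), levels(fb)),
                 response = response,
                 r = as.integer(r), alpha = alpha,
                 n = length(y)),
            class = "bonemri_anova")
}

#' Tidy a factorial ANOVA fit
#'
#' @param x a `bonemri_anova` object.
#' @param ... unused.
#' @return `tidy()` returns one row per model term (`term`, `df`, `sumsq`,
#'   `meansq`, `statistic`, `p.value`, `significant`); `glance()` returns a
#'   one-row design summary (`n`, `r`, `alpha`, `ss_total`, `r.squared`).
#' @method tidy bonemri_anova
#' @export
tidy.bonemri_anova <- function(x, ...) x$terms

#' @rdname tidy.bonemri_anova
#' @method glance bonemri_anova
#' @export
glance.bonemri_anova <- function(x, ...) {
  explained <- sum(x$terms$sumsq[x$terms$term != "Residuals"])
  tibble::tibble(n = x$n, r = x$r, alpha = x$alpha,
                 ss_total = x$ss_total,
                 r.squared = explained / x$ss_total)
}

#' @export
print.bonemri_anova <- function(x, ...) {
  cat(sprintf("Balanced two-way ANOVA of %s (%s x %s, r = %d per cell)\n",
              x$response, x$factors[1], x$factors[2], x$r))
  df <- as.data.frame(x$terms)
  df$p.value <- format.pval(df$p.value, digits = 4, eps = 1e-16)
  print(df, row.names = FALSE, digits = 4)
  invisible(x)
}

measure_columns <- c(bone_snr = "Bone SNR",
                     muscle_snr = "Muscle SNR",
                     bone_muscle_cnr = "Bone-Muscle CNR")

#' Summary report over a factorial metrics table
#'
#' Aggregates per-subject SNR/CNR records into the standard report layout:
#' per (sequence x processing) condition mean and SD for bone SNR, muscle SNR
#' and bone-muscle CNR, plus a balanced two-way ANOVA (sequence, processing,
#' interaction) for each measure. Every subject must contribute all four
#' sequence-by-processing combinations.
#'
#' @param records tibble of rows from [compute_image_metrics()] (columns
#'   `subject_id`, `sequence`, `processing`, `bone_snr`, `muscle_snr`,
#'   `bone_muscle_cnr`); at least 2 subjects.
#' @param alpha significance level for the ANOVA flags.
#' @return An object of class `metrics_report`: `summary` (tibble of
#'   per-condition mean/SD per measure), `anova` (tibble of ANOVA terms per
#'   measure), `records` and `alpha`.
#' @export
build_metrics_report <- function(records, alpha = 0.05) {
  needed <- c("subject_id", "sequence", "processing", names(measure_columns))
  missing <- setdiff(needed, names(records))
  abort_if(length(missing) > 0,
           paste0("records is missing column(s): ", paste(missing, collapse = ", ")))
  abort_if(dplyr::n_distinct(records$subject_id) < 2, "at least 2 subjects are required")
  combos <- tidyr::expand_grid(subject_id = unique(records$subject_id),
                               sequence = unique(records$sequence),
                               processing = unique(records$processing))
  have <- dplyr::distinct(records[, c("subject_id", "sequence", "processing")])
  gap <- dplyr::anti_join(combos, have, by = names(combos))
  abort_if(nrow(gap) > 0,
           sprintf("subject '%s' is missing the %s / %s condition",
                   gap$subject_id[1], gap$sequence[1], gap$processing[1]))

  long <- tidyr::pivot_longer(records, cols = dplyr::all_of(names(measure_columns)),
                              names_to = "measure", values_to = "value")
  long$measure <- factor(long$measure, levels = names(measure_columns))
  summary <- long |>
    dplyr::group_by(.data$measure, .data$sequence, .data$processing) |>
    dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
                     n = dplyr::n(), .groups = "drop")
  anova_tbl <- long |>
    dplyr::group_by(.data$measure) |>
    dplyr::group_modify(function(d, key) {
      tryCatch(
        tidy(two_way_anova(d, "value", "sequence", "processing", alpha = alpha)),
        error = function(e) {
          # degenerate input (e.g. zero within-cell variance) leaves the
          # summary intact but carries no F test
          warning(sprintf("ANOVA unavailable for %s: %s",
                          key$measure, conditionMessage(e)), call. = FALSE)
          tibble::tibble(term = c("sequence", "processing",
                                  "sequence:processing", "Residuals"),
                         df = NA_integer_, sumsq = NA_real_, meansq = NA_real_,
                         statistic = NA_real_, p.value = NA_real_,
                         significant = NA)
        })
    }) |>
    dplyr::ungroup()
  structure(list(summary = summary, anova = anova_tbl,
                 records = records, alpha = alpha),
            class = "metrics_report")
}

#' @rdname build_metrics_report
#' @param x a `metrics_report`.
#' @param ... unused.
#' @return `tidy()` on a report returns the per-condition summary tibble.
#' @method tidy metrics_report
#' @export
tidy.metrics_report <- function(x, ...) x$summary

#' @export
print.metrics_report <- function(x, ...) {
  cat("Mean (+/- SD) values for each sequence and processing\n")
  wide <- x$summary |>
    dplyr::mutate(cell = sprintf("%.3g (%.3g)", .data$mean, .data$sd),
                  condition = paste(.data$sequence, .data$processing)) |>
    dplyr::select("measure", "condition", "cell") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "cell") |>
    dplyr::mutate(measure = measure_columns[as.character(.data$measure)])
  print(as.data.frame(wide), row.names = FALSE)
  cat(sprintf("\nTwo-way ANOVA p-values (alpha = %g)\n", x$alpha))
  pv <- x$anova |>
    dplyr::filter(.data$term != "Residuals") |>
    dplyr::mutate(term = c(sequence = "sequence", processing = "processing",
                           `sequence:processing` = "interaction")[.data$term],
                  p = signif(.data$p.value, 3)) |>
    dplyr::select("measure", "term", "p") |>
    tidyr::pivot_wider(names_from = "term", values_from = "p") |>
    dplyr::mutate(measure = measure_columns[as.character(.data$measure)])
  print(as.data.frame(pv), row.names = FALSE)
  invisible(x)
}

#' Write a metrics report as CSV files
#'
#' @param report a `metrics_report`.
#' @param dir output directory (created if needed).
#' @return Paths of the written files, invisibly.
#' @export
write_report <- function(report, dir) {
  abort_if(!inherits(report, "metrics_report"), "report must be a metrics_report")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("metrics_records.csv", "metrics_summary.csv", "anova.csv"))
  write.csv(report$records, paths[1], row.names = FALSE)
  write.csv(report$summary, paths[2], row.names = FALSE)
  write.csv(report$anova, paths[3], row.names = FALSE)
  invisible(paths)
}
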