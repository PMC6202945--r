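#' Per-task share of the most salient features
#'
#' Maps each of the top-k unified-ranked features to its task by name
#' prefix and returns the percentage of the top-k attributable to each of
#' the 7 tasks (summing to 100). This is the task-salience breakdown behind
#' the pie-chart style summaries.
#'
#' @param ranking A `ranking_result` (or a character vector of feature
#'   names already ordered by salience).
#' @param k Number of top features to attribute (default 30).
#' @return Named numeric vector of 7 percentages (protocol task order).
#' @export
task_salience <- function(ranking, k = 30L) {
  feats <- if (inherits(ranking, "ranking_result"))
    ranking$feature[order(ranking$unified)] else as.character(ranking)
  if (k > length(feats)) stop("k exceeds the number of ranked features", call. = FALSE)
  top <- feats[seq_len(k)]
  tasks <- task_of_feature(top)          # errors on unknown prefix
  counts <- table(factor(tasks, levels = TASKS))
  out <- 100 * as.numeric(counts) / k
  names(out) <- TASKS
  out
}

#' Render the run report
#'
#' Writes, deterministically from its inputs: `curves.csv` (mean and SD of
#' sensitivity/specificity vs feature count per contrast/scheme/sex
#' filter), `salience.csv` (per-task percentages per comparison),
#' `summary.md` (plain-text summary including the train/validation
#' mismatch diagnostic when supplied). Numbers are re-derivations of the
#' per-iteration tables — nothing is recomputed from raw data.
#'
#' @param results List of `cv_result` objects (e.g. the concatenated output
#'   of [sweep_features()] over contrasts).
#' @param salience Named list of task-salience vectors (names label the
#'   comparison, e.g. `"control_vs_PD/all"`).
#' @param out_dir Output directory.
#' @param mismatch Optional [mismatch_diagnostic()] result (or named list of
#'   them) to include in the summary.
#' @return Invisibly, the paths written.
#' @export
render_report <- function(results, salience, out_dir, mismatch = NULL) {
  if (inherits(results, "cv_result")) results <- list(results)
  if (!length(results)) stop("render_report: empty results", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  curves <- do.call(rbind, lapply(results, function(r)
    data.frame(contrast = r$config$contrast, scheme = r$config$scheme,
               sex_filter = r$config$sex_filter,
               n_features = r$config$n_features,
               mean_sensitivity = r$mean_sensitivity,
               sd_sensitivity = r$sd_sensitivity,
               mean_specificity = r$mean_specificity,
               sd_specificity = r$sd_specificity,
               n_iterations = nrow(r$iterations),
               n_undefined = r$n_undefined, stringsAsFactors = FALSE)))
  curves <- curves[order(curves$contrast, curves$scheme, curves$sex_filter,
                         curves$n_features), ]
  p_curves <- file.path(out_dir, "curves.csv")
  write.csv(curves, p_curves, row.names = FALSE)

  p_sal <- file.path(out_dir, "salience.csv")
  if (length(salience)) {
    if (!is.list(salience)) salience <- list(overall = salience)
    sal <- do.call(rbind, lapply(names(salience), function(nm)
      data.frame(comparison = nm, task = names(salience[[nm]]),
                 percent = as.numeric(salience[[nm]]),
                 stringsAsFactors = FALSE)))
    write.csv(sal, p_sal, row.names = FALSE)
  }

  p_sum <- file.path(out_dir, "summary.md")
  lines <- c("# Smartphone motor-test discrimination report", "",
             "## Accuracy vs number of salient features", "")
  for (i in seq_len(nrow(curves)))
    lines <- c(lines, sprintf(
      "- %s / %s / %s, %d features: sensitivity %.1f%% (SD %.1f), specificity %.1f%% (SD %.1f)",
      curves$contrast[i], curves$scheme[i], curves$sex_filter[i],
      curves$n_features[i], 100 * curves$mean_sensitivity[i],
      100 * curves$sd_sensitivity[i], 100 * curves$mean_specificity[i],
      100 * curves$sd_specificity[i]))
  if (length(salience)) {
    lines <- c(lines, "", "## Task salience (percentage of top features per task)", "")
    for (nm in names(salience))
      lines <- c(lines, sprintf("- %s: %s", nm,
                                paste(sprintf("%s %.1f%%", names(salience[[nm]]),
                                              salience[[nm]]), collapse = ", ")))
  }
  if (!is.null(mismatch)) {
    if (!is.null(mismatch$per_feature)) mismatch <- list(overall = mismatch)
    lines <- c(lines, "", "## Train/validation mismatch diagnostic", "")
    for (nm in names(mismatch))
      lines <- c(lines, sprintf(
        "- %s: mean mismatch %.1f%%%s", nm, mismatch[[nm]]$mean_mismatch,
        if (isTRUE(mismatch[[nm]]$unreliable))
          " — too large for this validation to be considered statistically reliable"
        else ""))
  }
  writeLines(lines, p_sum)
  invisible(c(p_curves, if (length(salience)) p_sal, p_sum))
}
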