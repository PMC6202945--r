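#' Cross-validation configuration
#'
#' @param contrast Pairwise contrast label (see [parse_contrast()]).
#' @param scheme `"kfold10"` (per repetition: balanced subsample, then 10
#'   random folds, each validated once), `"loso"` (per repetition every
#'   subject is held out once) or `"loo"` (each repetition holds out one
#'   random recording).
#' @param repetitions Repetition count (default 10 for kfold10, 1 for loso,
#'   100 for loo).
#' @param n_features Number of top-ranked features fed to the classifier:
#'   an even number in 2..30, or `"all"` (998).
#' @param sex_filter `"all"`, `"female"` or `"male"` — recordings are
#'   filtered before balancing.
#' @param seed Integer seed; the whole CV run is deterministic given it.
#' @param n_trees,mtry Random-forest size and features per split (`mtry`
#'   defaults to `sqrt(p)`).
#' @param first_recording_only For `loo`: keep only each subject's first
#'   recording before balancing (single-recording-per-participant design).
#' @param rank_greedy Greedy depth passed to [rank_features()].
#' @return A `cv_config` object.
#' @export
cv_config <- function(contrast, scheme = c("kfold10", "loso", "loo"),
                      repetitions = NULL, n_features = 30L,
                      sex_filter = c("all", "female", "male"), seed = 1L,
                      n_trees = 500L, mtry = NULL,
                      first_recording_only = FALSE, rank_greedy = 40L) {
  scheme <- match.arg(scheme)
  sex_filter <- match.arg(sex_filter)
  parse_contrast(contrast)
  if (is.null(repetitions))
    repetitions <- switch(scheme, kfold10 = 10L, loso = 1L, loo = 100L)
  if (repetitions < 1L) stop("repetitions must be >= 1", call. = FALSE)
  if (identical(n_features, "all")) n_features <- 998L
  if (!n_features %in% c(seq(2L, 30L, 2L), 998L))
    stop("n_features must be in {2, 4, ..., 30} or 'all' (998)", call. = FALSE)
  structure(list(contrast = contrast, scheme = scheme,
                 repetitions = as.integer(repetitions),
                 n_features = as.integer(n_features), sex_filter = sex_filter,
                 seed = as.integer(seed), n_trees = as.integer(n_trees),
                 mtry = mtry, first_recording_only = first_recording_only,
                 rank_greedy = as.integer(rank_greedy)),
            class = "cv_config")
}

#' Balanced subsampling of the two contrast groups
#'
#' Downsamples both groups, uniformly at random, to the minority group's
#' recording count; applied before the train/validation split of each CV
#' repetition so class counts are equal at every iteration.
#'
#' @param matrix A `feature_matrix`.
#' @param contrast Contrast label.
#' @param seed Integer seed.
#' @return The subsampled `feature_matrix` (row order preserved).
#' @export
balanced_subsample <- function(matrix, contrast, seed = 1L) {
  ct <- parse_contrast(contrast)
  ia <- which(matrix$group == ct$a)
  ib <- which(matrix$group == ct$b)
  if (!length(ia) || !length(ib))
    stop(sprintf("contrast %s: group '%s' has no recordings", contrast,
                 if (length(ia)) ct$b else ct$a), call. = FALSE)
  m <- min(length(ia), length(ib))
  keep <- with_seed(seed, c(sample(ia, m), sample(ib, m)))
  matrix[sort(keep), , drop = FALSE]
}

# One repetition's iteration list: each element list(train=idx, val=idx)
# over the rows of the (already balanced) matrix.
make_splits <- function(bs, cfg, rep_seed) {
  n <- nrow(bs)
  switch(cfg$scheme,
    kfold10 = with_seed(rep_seed, {
      fold <- sample(rep_len(1:10, n))
      lapply(1:10, function(k) list(train = which(fold != k),
                                    val = which(fold == k)))
    }),
    loso = {
      subs <- unique(bs$subject_id)
      lapply(subs, function(s) list(train = which(bs$subject_id != s),
                                    val = which(bs$subject_id == s)))
    },
    loo = with_seed(rep_seed, {
      i <- sample.int(n, 1L)
      list(list(train = setdiff(seq_len(n), i), val = i))
    }))
}

#' Enumerate the train/validation splits a CV run would use
#'
#' Exposes the split machinery of [run_cv()] (balanced subsample per
#' repetition, then scheme-specific folds) so diagnostics such as
#' [mismatch_diagnostic()] can inspect the very same splits.
#'
#' @param matrix A `feature_matrix`.
#' @param cfg A [cv_config()].
#' @return List over repetitions; each element holds the subsampled matrix
#'   (`data`) and the list of `splits`.
#' @export
cv_splits <- function(matrix, cfg) {
  matrix <- filter_recordings(matrix, cfg)
  lapply(seq_len(cfg$repetitions), function(r) {
    rs <- child_seed(cfg$seed, r)
    bs <- balanced_subsample(matrix, cfg$contrast, rs)
    list(data = bs, splits = make_splits(bs, cfg, child_seed(rs, 7L)))
  })
}

filter_recordings <- function(matrix, cfg) {
  stopifnot(inherits(matrix, "feature_matrix") || is.data.frame(matrix))
  if (cfg$sex_filter != "all")
    matrix <- matrix[matrix$sex == cfg$sex_filter, , drop = FALSE]
  ct <- parse_contrast(cfg$contrast)
  matrix <- matrix[matrix$group %in% c(ct$a, ct$b), , drop = FALSE]
  if (cfg$first_recording_only) {
    ord <- order(matrix$subject_id, matrix$session_id)
    matrix <- matrix[ord, , drop = FALSE]
    matrix <- matrix[!duplicated(matrix$subject_id), , drop = FALSE]
  }
  if (!nrow(matrix)) stop("no recordings left after filtering", call. = FALSE)
  matrix
}

rf_predict <- function(Xtr, ytr, Xte, n_trees, mtry, seed) {
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(Xtr))))
  pr <- .rf_cpp(Xtr, as.integer(ytr), Xte, as.integer(n_trees),
                as.integer(mtry), 2L, as.integer(seed))
  as.integer(pr >= 0.5)
}

# Fit one CV iteration: every data-dependent artifact (imputation medians,
# standardization moments, feature ranking, forest) is learned from `tr`
# alone; `va` only ever flows through the fitted transforms into
# predictions. Returns the artifacts so leakage can be audited.
fit_iteration <- function(tr, va, cfg, seed) {
  ct <- parse_contrast(cfg$contrast)
  tr_imp <- impute_features(tr)
  va_imp <- impute_features(tr, va)
  Xtr <- feature_cols(tr_imp); Xva <- feature_cols(va_imp)
  std <- standardize_train(Xtr)
  Xtr <- std$X
  Xva <- sweep(sweep(Xva, 2L, std$center, "-"), 2L, std$scale, "/")
  selected <- colnames(Xtr)
  ranking <- NULL
  if (cfg$n_features < ncol(Xtr)) {
    ranking <- rank_features(tr_imp, cfg$contrast, n_greedy = cfg$rank_greedy)
    selected <- top_features(ranking, cfg$n_features)
    Xtr <- Xtr[, selected, drop = FALSE]
    Xva <- Xva[, selected, drop = FALSE]
  }
  ytr <- as.integer(tr$group == ct$positive)
  pred <- rf_predict(Xtr, ytr, Xva, cfg$n_trees, cfg$mtry, seed)
  list(pred = pred, selected = selected, ranking = ranking,
       center = std$center, scale = std$scale)
}

# Core CV engine. predictor: "rf" or "random" (uniform label guessing on
# the same splits, for the null baseline).
run_cv_core <- function(matrix, cfg, predictor = "rf") {
  ct <- parse_contrast(cfg$contrast)
  reps <- cv_splits(matrix, cfg)
  rows <- list()
  for (r in seq_along(reps)) {
    bs <- reps[[r]]$data
    y <- as.integer(bs$group == ct$positive)
    rs <- child_seed(cfg$seed, r)
    for (it in seq_along(reps[[r]]$splits)) {
      sp <- reps[[r]]$splits[[it]]
      it_seed <- child_seed(rs, 100L + it)
      yva <- y[sp$val]
      if (predictor == "random") {
        pred <- with_seed(it_seed, rbinom(length(yva), 1L, 0.5))
      } else {
        pred <- fit_iteration(bs[sp$train, , drop = FALSE],
                              bs[sp$val, , drop = FALSE], cfg, it_seed)$pred
      }
      sens <- if (any(yva == 1L)) mean(pred[yva == 1L] == 1L) else NA_real_
      spec <- if (any(yva == 0L)) mean(pred[yva == 0L] == 0L) else NA_real_
      rows[[length(rows) + 1L]] <-
        data.frame(repetition = r, iteration = it, sensitivity = sens,
                   specificity = spec, accuracy = mean(pred == yva),
                   n_val = length(yva), n_pos = sum(yva == 1L),
                   n_neg = sum(yva == 0L))
    }
  }
  iters <- do.call(rbind, rows)
  structure(list(
    iterations = iters,
    mean_sensitivity = mean(iters$sensitivity, na.rm = TRUE),
    sd_sensitivity = sd(iters$sensitivity[is.finite(iters$sensitivity)]),
    mean_specificity = mean(iters$specificity, na.rm = TRUE),
    sd_specificity = sd(iters$specificity[is.finite(iters$specificity)]),
    mean_accuracy = mean(iters$accuracy, na.rm = TRUE),
    n_undefined = sum(!is.finite(iters$sensitivity)) +
      sum(!is.finite(iters$specificity)),
    config = cfg, predictor = predictor), class = "cv_result")
}

#' Run class-balanced random-forest cross-validation
#'
#' Per repetition: filter recordings (sex, contrast), balance the two groups
#' by downsampling to the minority count, split per the scheme, and for each
#' iteration impute (training medians), standardize (training moments), rank
#' features (training split only, majority-vote ensemble), train a random
#' forest on the top `n_features`, and score the held-out split.
#' Sensitivity is the recall of the disease-positive class (iRBD or PD
#' against control; PD in iRBD-vs-PD), specificity the recall of the other
#' group. Iterations whose validation split lacks a class record an NA rate,
#' excluded from the mean/SD with a count in `n_undefined`.
#'
#' @param matrix A `feature_matrix`.
#' @param cfg A [cv_config()].
#' @return A `cv_result`: per-iteration rates plus mean/SD summaries.
#' @export
run_cv <- function(matrix, cfg) run_cv_core(matrix, cfg, "rf")

#' Randomized-prediction baseline on the same CV splits
#'
#' Identical split machinery to [run_cv()], but every validation label is
#' predicted uniformly at random — the null distribution the real
#' per-iteration accuracies are compared against.
#'
#' @inheritParams run_cv
#' @return A `cv_result`.
#' @export
randomized_baseline <- function(matrix, cfg) run_cv_core(matrix, cfg, "random")

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: %s / %s / top-%d (%s predictions)\n",
              x$config$contrast, x$config$scheme, x$config$n_features,
              x$predictor))
  cat(sprintf("  sensitivity %.3f (SD %.3f), specificity %.3f (SD %.3f), %d iterations (%d undefined rate(s))\n",
              x$mean_sensitivity, x$sd_sensitivity, x$mean_specificity,
              x$sd_specificity, nrow(x$iterations), x$n_undefined))
  invisible(x)
}

#' Two-sample two-sided Kolmogorov-Smirnov comparison
#'
#' Compares two sets of per-iteration accuracies (real vs randomized
#' baseline); asymptotic p-value, ties resolved by the asymptotic
#' approximation.
#'
#' @param a,b Numeric vectors, each of length >= 5.
#' @return List with `statistic` and `p_value`.
#' @export
ks_compare <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 5L || length(b) < 5L)
    stop("ks_compare needs at least 5 finite values per sample", call. = FALSE)
  kt <- suppressWarnings(ks.test(a, b, alternative = "two.sided", exact = FALSE))
  list(statistic = unname(kt$statistic), p_value = unname(kt$p.value))
}

#' Accuracy as a function of the number of salient features
#'
#' Re-runs the whole train/validate process at n_features = 2, 4, ..., 30
#' (15 points; higher-ranked features added first), optionally plus the
#' all-998-features point.
#'
#' @param matrix A `feature_matrix`.
#' @param cfg A [cv_config()]; its `n_features` is overridden.
#' @param include_all Append the `"all"` (998-feature) point.
#' @return List of `cv_result`, named by feature count.
#' @details Within one iteration the training split — hence its imputation,
#'   standardization and ranking — is identical across feature counts, so
#'   those artifacts are fitted once per iteration and only the forest is
#'   retrained as features are added two at a time.
#' @export
sweep_features <- function(matrix, cfg, include_all = FALSE) {
  counts <- seq(2L, 30L, 2L)
  if (include_all) counts <- c(counts, 998L)
  ct <- parse_contrast(cfg$contrast)
  reps <- cv_splits(matrix, cfg)
  rows <- lapply(counts, function(k) list())
  names(rows) <- as.character(counts)
  for (r in seq_along(reps)) {
    bs <- reps[[r]]$data
    y <- as.integer(bs$group == ct$positive)
    rs <- child_seed(cfg$seed, r)
    for (it in seq_along(reps[[r]]$splits)) {
      sp <- reps[[r]]$splits[[it]]
      it_seed <- child_seed(rs, 100L + it)
      tr <- bs[sp$train, , drop = FALSE]
      va <- bs[sp$val, , drop = FALSE]
      tr_imp <- impute_features(tr)
      va_imp <- impute_features(tr, va)
      Xtr <- feature_cols(tr_imp); Xva <- feature_cols(va_imp)
      std <- standardize_train(Xtr)
      Xtr <- std$X
      Xva <- sweep(sweep(Xva, 2L, std$center, "-"), 2L, std$scale, "/")
      rk <- rank_features(tr_imp, cfg$contrast, n_greedy = cfg$rank_greedy)
      ord <- top_features(rk, 998L)
      ytr <- y[sp$train]; yva <- y[sp$val]
      for (k in counts) {
        sel <- if (k >= ncol(Xtr)) colnames(Xtr) else ord[seq_len(k)]
        pred <- rf_predict(Xtr[, sel, drop = FALSE], ytr,
                           Xva[, sel, drop = FALSE], cfg$n_trees, cfg$mtry,
                           it_seed)
        sens <- if (any(yva == 1L)) mean(pred[yva == 1L] == 1L) else NA_real_
        spec <- if (any(yva == 0L)) mean(pred[yva == 0L] == 0L) else NA_real_
        rows[[as.character(k)]][[length(rows[[as.character(k)]]) + 1L]] <-
          data.frame(repetition = r, iteration = it, sensitivity = sens,
                     specificity = spec, accuracy = mean(pred == yva),
                     n_val = length(yva), n_pos = sum(yva == 1L),
                     n_neg = sum(yva == 0L))
      }
    }
  }
  out <- lapply(counts, function(k) {
    iters <- do.call(rbind, rows[[as.character(k)]])
    cfg_k <- cfg; cfg_k$n_features <- as.integer(k)
    structure(list(
      iterations = iters,
      mean_sensitivity = mean(iters$sensitivity, na.rm = TRUE),
      sd_sensitivity = sd(iters$sensitivity[is.finite(iters$sensitivity)]),
      mean_specificity = mean(iters$specificity, na.rm = TRUE),
      sd_specificity = sd(iters$specificity[is.finite(iters$specificity)]),
      mean_accuracy = mean(iters$accuracy, na.rm = TRUE),
      n_undefined = sum(!is.finite(iters$sensitivity)) +
        sum(!is.finite(iters$specificity)),
      config = cfg_k, predictor = "rf"), class = "cv_result")
  })
  names(out) <- as.character(counts)
  out
}

#' Train/validation feature-range mismatch diagnostic
#'
#' For every feature, the percentage of validation values falling outside
#' the training split's observed [min, max] range; the summary is the mean
#' over features. Large mismatch (default threshold 25\%) flags a validation
#' scheme whose accuracy estimates are not statistically reliable — the
#' caveat raised for leave-one-subject-out validation.
#'
#' @param train,validation Feature matrices (or plain data.frames sharing
#'   feature columns).
#' @param threshold Mean-mismatch percentage above which the validation is
#'   flagged unreliable.
#' @return List with `per_feature` (named percentages), `mean_mismatch`,
#'   `unreliable`.
#' @export
mismatch_diagnostic <- function(train, validation, threshold = 25) {
  feats <- intersect(feature_names(), intersect(names(train), names(validation)))
  if (!length(feats)) {
    feats <- intersect(names(train)[vapply(train, is.numeric, logical(1))],
                       names(validation))
  }
  if (!nrow(train) || !nrow(validation))
    stop("mismatch_diagnostic: empty split", call. = FALSE)
  per <- vapply(feats, function(f) {
    tr <- train[[f]][is.finite(train[[f]])]
    va <- validation[[f]][is.finite(validation[[f]])]
    if (!length(tr) || !length(va)) return(NA_real_)
    100 * mean(va < min(tr) | va > max(tr))
  }, numeric(1))
  m <- mean(per, na.rm = TRUE)
  list(per_feature = per, mean_mismatch = m, unreliable = is.finite(m) && m > threshold)
}

#' Tidy per-iteration CV results
#'
#' @param results List of `cv_result` (e.g. from [sweep_features()]).
#' @return data.frame: contrast, scheme, sex_filter, n_features, repetition,
#'   iteration, sensitivity, specificity.
#' @export
cv_results_table <- function(results) {
  if (inherits(results, "cv_result")) results <- list(results)
  do.call(rbind, lapply(results, function(r) {
    cbind(data.frame(contrast = r$config$contrast, scheme = r$config$scheme,
                     sex_filter = r$config$sex_filter,
                     n_features = r$config$n_features,
                     stringsAsFactors = FALSE),
          r$iterations[, c("repetition", "iteration", "sensitivity",
                           "specificity")])
  }))
}
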