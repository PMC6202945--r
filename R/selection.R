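#' Impute missing features with training-split column medians
#'
#' Medians are learned from `train` only and applied to `apply_to`, so
#' validation data never influence the fill values (no leakage). A column
#' that is entirely missing in `train` is filled with 0 and flagged with a
#' warning.
#'
#' @param train Feature matrix (or data.frame containing the feature
#'   columns) the medians are learned from.
#' @param apply_to Data to fill; defaults to `train`.
#' @return `apply_to` with missing feature entries replaced.
#' @export
impute_features <- function(train, apply_to = train) {
  feats <- intersect(feature_names(), names(train))
  if (!length(feats)) feats <- names(train)[vapply(train, is.numeric, logical(1))]
  med <- vapply(feats, function(f) median(train[[f]], na.rm = TRUE), numeric(1))
  all_missing <- names(med)[!is.finite(med)]
  if (length(all_missing)) {
    warning(sprintf("%d feature(s) entirely missing in training split; filled with 0",
                    length(all_missing)), call. = FALSE)
    med[!is.finite(med)] <- 0
  }
  for (f in feats) {
    v <- apply_to[[f]]
    v[!is.finite(v)] <- med[[f]]
    apply_to[[f]] <- v
  }
  apply_to
}

# --- contrasts --------------------------------------------------------------

#' Parse a pairwise contrast label
#'
#' The three contrasts are `"control_vs_iRBD"`, `"control_vs_PD"` and
#' `"iRBD_vs_PD"`. The positive (sensitivity) class is the disease class:
#' iRBD or PD against control, and PD in iRBD-vs-PD.
#'
#' @param contrast Contrast string.
#' @return List with `a`, `b` (group labels) and `positive`.
#' @export
parse_contrast <- function(contrast) {
  valid <- c("control_vs_iRBD", "control_vs_PD", "iRBD_vs_PD")
  hit <- match(tolower(contrast), tolower(valid))   # CLI uses lowercase labels
  if (length(hit) != 1L || is.na(hit))
    stop("contrast must be one of: ", paste(valid, collapse = ", "), call. = FALSE)
  contrast <- valid[hit]
  parts <- strsplit(contrast, "_vs_")[[1L]]
  list(a = parts[1L], b = parts[2L],
       positive = if (contrast == "iRBD_vs_PD") "PD" else parts[2L])
}

# z-score columns using train statistics; constant columns -> 0.
standardize_train <- function(X, center = NULL, scale = NULL) {
  if (is.null(center)) center <- colMeans(X)
  if (is.null(scale)) {
    scale <- apply(X, 2L, sd)
    scale[!is.finite(scale) | scale == 0] <- 1
  }
  list(X = sweep(sweep(X, 2L, center, "-"), 2L, scale, "/"),
       center = center, scale = scale)
}

# Ranks (1 = best) from scores (higher better); ties broken by column order,
# with `force_last` indices pushed to the end.
score_to_rank <- function(score, force_last = integer(0)) {
  score[force_last] <- -Inf
  ord <- order(-score, seq_along(score))
  rk <- integer(length(score))
  rk[ord] <- seq_along(score)
  rk
}

rank_lasso <- function(X, y, force_last) {
  p <- ncol(X)
  relev <- abs(suppressWarnings(cor(X, y)))
  relev[!is.finite(relev)] <- 0
  entry <- rep(Inf, p)
  if (p >= 2L && length(unique(y)) == 2L) {
    fit <- tryCatch(
      suppressWarnings(                 # tiny folds trip glmnet's n-per-class note
        glmnet::glmnet(X, factor(y), family = "binomial", standardize = FALSE,
                       nlambda = 100)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      beta <- as.matrix(fit$beta)            # p x nlambda
      for (j in seq_len(p)) {
        nz <- which(abs(beta[j, ]) > 0)
        if (length(nz)) entry[j] <- nz[1L]
      }
    }
  }
  # earlier entry = better; never-entered ordered by |cor|
  score <- -entry + relev * 1e-6
  score[!is.finite(score)] <- -1e9 + relev[!is.finite(score)]
  score_to_rank(score, force_last)
}

# equal-frequency binning into nb bins
bin_equal_freq <- function(x, nb) {
  qs <- unique(quantile(x, probs = seq(0, 1, length.out = nb + 1L), type = 1))
  if (length(qs) < 2L) return(rep(1L, length(x)))
  as.integer(cut(x, qs, include.lowest = TRUE, labels = FALSE))
}

mi_xy <- function(bx, nbx, by, nby) {
  n <- length(bx)
  joint <- tabulate((bx - 1L) * nby + by, nbx * nby) / n
  px <- tabulate(bx, nbx) / n
  py <- tabulate(by, nby) / n
  nz <- which(joint > 0)
  i <- (nz - 1L) %/% nby + 1L
  j <- (nz - 1L) %% nby + 1L
  sum(joint[nz] * log(joint[nz] / (px[i] * py[j])))
}

rank_mrmr <- function(X, y, force_last, n_greedy = 60L, n_bins = 10L) {
  p <- ncol(X)
  yb <- as.integer(y) + 1L
  bins <- lapply(seq_len(p), function(j) bin_equal_freq(X[, j], n_bins))
  relev <- vapply(seq_len(p), function(j) mi_xy(bins[[j]], n_bins, yb, 2L),
                  numeric(1))
  avail <- setdiff(seq_len(p), force_last)
  k <- min(length(avail), n_greedy)
  selected <- integer(0)
  red_sum <- numeric(p)                       # sum of MI with selected set
  score_final <- relev
  for (step in seq_len(k)) {
    cand <- setdiff(avail, selected)
    sc <- relev[cand] - if (length(selected)) red_sum[cand] / length(selected) else 0
    pick <- cand[order(-sc, cand)[1L]]
    selected <- c(selected, pick)
    if (step < k) {
      rest <- setdiff(avail, selected)
      add <- vapply(rest, function(j) mi_xy(bins[[pick]], n_bins, bins[[j]],
                                            n_bins), numeric(1))
      red_sum[rest] <- red_sum[rest] + add
    }
  }
  # greedy picks get descending pseudo-scores; the remainder keeps its
  # saturation-time mRMR score
  score <- relev - if (length(selected)) red_sum / max(1L, length(selected)) else 0
  score <- score - min(score, na.rm = TRUE)
  score[selected] <- max(score, na.rm = TRUE) + (length(selected):1)
  score[!is.finite(score)] <- 0
  score_to_rank(score, force_last)
}

rank_relief <- function(X, y, force_last, k = 10L) {
  k <- min(k, max(1L, min(table(y)) - 1L))
  w <- as.numeric(.relief_cpp(X, as.integer(y), as.integer(k)))
  score_to_rank(w, force_last)
}

rank_gso <- function(X, y, force_last, n_greedy = 60L) {
  p <- ncol(X)
  R <- X
  yv <- y - mean(y)
  avail <- setdiff(seq_len(p), force_last)
  k <- min(length(avail), n_greedy)
  selected <- integer(0)
  score <- numeric(p)
  for (step in seq_len(k)) {
    cand <- setdiff(avail, selected)
    nrm <- sqrt(colSums(R[, cand, drop = FALSE]^2))
    cc <- abs(as.numeric(crossprod(R[, cand, drop = FALSE], yv))) /
      (nrm * sqrt(sum(yv^2)) + 1e-300)
    cc[nrm < 1e-10] <- 0
    score[cand] <- cc                          # saturation-time residual score
    pick <- cand[order(-cc, cand)[1L]]
    selected <- c(selected, pick)
    u <- R[, pick]
    un <- sum(u^2)
    if (un > 1e-20) {
      rest <- setdiff(avail, selected)
      proj <- as.numeric(crossprod(R[, rest, drop = FALSE], u)) / un
      R[, rest] <- R[, rest, drop = FALSE] - outer(u, proj)
    }
  }
  score[selected] <- max(score, 1) + (length(selected):1)
  score_to_rank(score, force_last)
}

rank_llbfs <- function(X, y, force_last, iters = 5L, lambda = 1e-3) {
  w <- as.numeric(.llbfs_cpp(X, as.integer(y), as.integer(iters), lambda))
  score_to_rank(w, force_last)
}

#' Rank features with the five-algorithm ensemble
#'
#' Standardizes the training features (z-score), runs LASSO (order of entry
#' along the L1-penalized logistic regularization path), mRMR (greedy
#' maximal relevance minus mean redundancy, 10 equal-frequency bins),
#' RELIEF (k = 10 nearest hits/misses), GSO (greedy forward correlation
#' with Gram-Schmidt residualization) and LLBFS (iterative local-learning
#' margin weights), and aggregates the five rank vectors by majority vote.
#' Constant columns are ranked last by every algorithm.
#'
#' @param train A `feature_matrix` (training split only).
#' @param contrast Pairwise contrast label, see [parse_contrast()].
#' @param n_greedy Greedy-depth of the sequential algorithms; beyond it,
#'   features are ranked by the algorithm's saturation-time score.
#' @return A `ranking_result`: `feature` (names), `algorithms` (998 x 5 rank
#'   matrix), `unified` (majority-vote rank vector), `contrast`.
#' @export
rank_features <- function(train, contrast, n_greedy = 60L) {
  ct <- parse_contrast(contrast)
  keep <- train$group %in% c(ct$a, ct$b)
  train <- train[keep, , drop = FALSE]
  if (!nrow(train)) stop("no rows for contrast ", contrast, call. = FALSE)
  y <- as.integer(train$group == ct$positive)
  if (length(unique(y)) < 2L) stop("contrast needs both groups", call. = FALSE)
  train <- impute_features(train)
  X <- feature_cols(train)
  const <- which(apply(X, 2L, function(v) !any(is.finite(v)) || sd(v) == 0))
  Z <- standardize_train(X)$X
  Z[, const] <- 0
  algos <- cbind(
    lasso = rank_lasso(Z, y, const),
    mrmr = rank_mrmr(Z, y, const, n_greedy),
    relief = rank_relief(Z, y, const),
    gso = rank_gso(Z, y, const, n_greedy),
    llbfs = rank_llbfs(Z, y, const))
  rownames(algos) <- colnames(X)
  structure(list(feature = colnames(X), algorithms = algos,
                 unified = majority_vote(algos), contrast = contrast),
            class = "ranking_result")
}

#' Aggregate per-algorithm rankings by majority vote
#'
#' The unified rank orders features by the median of their per-algorithm
#' ranks; ties are broken by mean rank, then by the best single rank, then
#' by column order. The output is always a permutation of `1..p`.
#'
#' @param rankings A p x k matrix of rank vectors (each column a permutation
#'   of `1..p`).
#' @return Integer vector: unified rank per feature (1 = most salient).
#' @export
majority_vote <- function(rankings) {
  rankings <- as.matrix(rankings)
  p <- nrow(rankings)
  for (j in seq_len(ncol(rankings)))
    if (!identical(sort(as.integer(rankings[, j])), seq_len(p)))
      stop("each ranking must be a permutation of 1..p over the same features",
           call. = FALSE)
  med <- apply(rankings, 1L, median)
  mea <- rowMeans(rankings)
  best <- apply(rankings, 1L, min)
  ord <- order(med, mea, best, seq_len(p))
  rk <- integer(p)
  rk[ord] <- seq_len(p)
  rk
}

#' Top-k feature names from a ranking
#' @param ranking A `ranking_result`.
#' @param k Number of features.
#' @return Character vector of the k most salient feature names.
#' @export
top_features <- function(ranking, k = 30L) {
  ranking$feature[order(ranking$unified)][seq_len(min(k, length(ranking$feature)))]
}

#' Write a ranking to CSV (feature, per-algorithm ranks, unified rank)
#' @param ranking A `ranking_result`.
#' @param path Output CSV path.
#' @export
write_ranking <- function(ranking, path) {
  df <- data.frame(feature = ranking$feature, ranking$algorithms,
                   unified = ranking$unified, contrast = ranking$contrast)
  write.csv(df[order(df$unified), ], path, row.names = FALSE)
  invisible(path)
}
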