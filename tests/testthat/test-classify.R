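# Balanced CV machinery: subsampling, schemes, leakage audit, KS, sweep,
# mismatch diagnostic.

sep_synth_fm <- function() fixture("sep_synth_fm", function() {
  set.seed(10)
  n <- 100
  X <- matrix(rnorm(n * 10), n, 10)
  y <- rep(0:1, each = n / 2)
  X[, 1] <- y * 3 + rnorm(n, 0, 0.3)
  X[, 2] <- -y * 2 + rnorm(n, 0, 0.3)
  make_fm(X, groups = ifelse(y == 1, "PD", "control"),
          subject_id = sprintf("S%03d", rep(1:50, each = 2)))
})

fast_cfg <- function(seed = 2) cv_config("control_vs_PD", "kfold10",
                                         repetitions = 1, n_features = 4,
                                         seed = seed, n_trees = 100,
                                         rank_greedy = 6L)

test_that("balanced_subsample equalizes recording counts", {
  set.seed(1)
  X <- matrix(rnorm(140 * 2), 140, 2)
  fm <- make_fm(X, groups = c(rep("control", 100), rep("PD", 40)))
  bs <- balanced_subsample(fm, "control_vs_PD", seed = 3)
  expect_equal(as.vector(table(bs$group)[c("control", "PD")]), c(40L, 40L))
  expect_identical(balanced_subsample(fm, "control_vs_PD", 3),
                   balanced_subsample(fm, "control_vs_PD", 3))
  eq <- make_fm(matrix(rnorm(40), 20, 2),
                groups = rep(c("control", "PD"), each = 10))
  expect_equal(nrow(balanced_subsample(eq, "control_vs_PD", 1)), 20L)
  expect_error(balanced_subsample(eq[eq$group == "PD", ], "control_vs_PD", 1),
               "no recordings")
})

test_that("cv_config validates its fields", {
  expect_error(cv_config("control_vs_PD", n_features = 3), "n_features")
  expect_error(cv_config("control_vs_PD", n_features = 32), "n_features")
  expect_error(cv_config("PD_vs_iRBD"), "contrast")
  expect_equal(cv_config("control_vs_PD", n_features = "all")$n_features, 998L)
  expect_equal(cv_config("control_vs_PD", scheme = "loo")$repetitions, 100L)
})

test_that("kfold10 validates about a tenth of the recordings per iteration", {
  fm <- sep_synth_fm()  # 50+50 after balancing -> 80 is the spec's example
  cfg <- fast_cfg()
  res <- run_cv(fm, cfg)
  expect_equal(nrow(res$iterations), 10L)
  expect_true(all(abs(res$iterations$n_val - 10) <= 1))
  expect_gte(res$mean_sensitivity, 0.9)   # strongly separable by design
  expect_identical(run_cv(fm, cfg)$iterations, res$iterations)  # determinism
})

test_that("loso holds out whole subjects; loo single recordings", {
  fm <- sep_synth_fm()
  cfg <- cv_config("control_vs_PD", "loso", n_features = 4, seed = 4,
                   n_trees = 50, rank_greedy = 6L)
  sp <- cv_splits(fm, cfg)[[1]]
  for (s in sp$splits) {
    vs <- unique(sp$data$subject_id[s$val])
    expect_length(vs, 1L)
    expect_false(vs %in% sp$data$subject_id[s$train])
  }
  cfgl <- cv_config("control_vs_PD", "loo", repetitions = 5, n_features = 4,
                    seed = 4, n_trees = 50, rank_greedy = 6L)
  resl <- run_cv(fm, cfgl)
  expect_equal(nrow(resl$iterations), 5L)
  expect_true(all(resl$iterations$n_val == 1L))
  # first-recording-only mode keeps one recording per subject
  cfgf <- cv_config("control_vs_PD", "loo", repetitions = 2,
                    first_recording_only = TRUE, seed = 4, n_trees = 50,
                    n_features = 4, rank_greedy = 6L)
  spf <- cv_splits(fm, cfgf)[[1]]
  expect_false(any(duplicated(spf$data$subject_id)))
})

test_that("undefined rates are excluded from summaries and counted", {
  set.seed(6)
  X <- matrix(rnorm(12 * 3), 12, 3)
  X[, 1] <- rep(0:1, each = 6) * 3 + rnorm(12, 0, 0.2)
  fm <- make_fm(X, groups = rep(c("control", "PD"), each = 6))
  cfg <- fast_cfg(seed = 7)
  res <- run_cv(fm, cfg)     # 12 recordings in 10 folds: single-class folds
  expect_gt(res$n_undefined, 0)
  expect_false(is.na(res$mean_sensitivity))
})

test_that("no leakage: validation corruption leaves training artifacts intact", {
  fm <- sep_synth_fm()
  cfg <- fast_cfg()
  tr <- fm[1:80, ]; va <- fm[81:100, ]
  a <- pdmotor:::fit_iteration(tr, va, cfg, seed = 9)
  vb <- va
  vb[, feature_names()] <- vb[, feature_names()] + 50   # corrupt features
  vb$group <- rev(vb$group)                              # corrupt labels
  b <- pdmotor:::fit_iteration(tr, vb, cfg, seed = 9)
  expect_identical(a$selected, b$selected)
  expect_identical(a$ranking$unified, b$ranking$unified)
  expect_identical(a$center, b$center)
  expect_identical(a$scale, b$scale)
  # and an untouched validation row keeps its prediction
  vc <- va
  vc[2:20, feature_names()] <- vc[2:20, feature_names()] + 50
  cpred <- pdmotor:::fit_iteration(tr, vc, cfg, seed = 9)$pred
  expect_identical(cpred[1], a$pred[1])
})

test_that("randomized baseline sits at chance and KS behaves", {
  fm <- sep_synth_fm()
  cfg <- cv_config("control_vs_PD", "kfold10", repetitions = 5,
                   n_features = 4, seed = 11, n_trees = 50, rank_greedy = 6L)
  rb <- randomized_baseline(fm, cfg)
  expect_equal(nrow(rb$iterations), 50L)
  expect_lt(abs(rb$mean_sensitivity - 0.5), 0.1)
  expect_lt(abs(rb$mean_specificity - 0.5), 0.1)
  expect_identical(randomized_baseline(fm, cfg)$iterations, rb$iterations)

  a <- c(0.5, 0.52, 0.48, 0.51, 0.49)
  expect_equal(ks_compare(a, a)$statistic, 0)
  expect_equal(ks_compare(a, a)$p_value, 1)
  b <- a + 10
  expect_equal(ks_compare(a, b)$statistic, 1)   # disjoint supports
  expect_error(ks_compare(a[1:3], b), "at least 5")
})

test_that("sweep produces the 15 feature-count points of 2..30", {
  fm <- sep_synth_fm()
  cfg <- cv_config("control_vs_PD", "loo", repetitions = 3, seed = 12,
                   n_trees = 50, rank_greedy = 6L)
  sw <- sweep_features(fm, cfg)
  expect_length(sw, 15L)
  expect_identical(names(sw), as.character(seq(2, 30, 2)))
  for (r in sw) expect_equal(nrow(r$iterations), 3L)
  sw_all <- sweep_features(fm, cfg, include_all = TRUE)
  expect_length(sw_all, 16L)
  expect_equal(sw_all[["998"]]$config$n_features, 998L)
})

test_that("mismatch diagnostic: hand counts and the LOSO caveat", {
  fn <- feature_names()
  tr <- make_fm(matrix(rep(1:9, 3), 9, 3), groups = rep_len(c("control", "PD"), 9))
  va <- make_fm(matrix(rep(c(0, 5, 10), 3), 3, 3),
                groups = c("control", "PD", "control"))
  # keep only the first feature deterministic
  mm <- mismatch_diagnostic(tr[, c("subject_id", "session_id", "group", "sex",
                                   fn[1])],
                            va[, c("subject_id", "session_id", "group", "sex",
                                   fn[1])])
  expect_equal(unname(mm$per_feature[fn[1]]), 200 / 3, tolerance = 1e-9)

  # validation inside the train hull -> zero mismatch
  mz <- mismatch_diagnostic(tr[, c("subject_id", "session_id", "group", "sex",
                                   fn[1])],
                            tr[1:3, c("subject_id", "session_id", "group",
                                      "sex", fn[1])])
  expect_equal(unname(mz$per_feature[fn[1]]), 0)
  expect_false(mz$unreliable)
  expect_error(mismatch_diagnostic(tr[0, ], va), "empty")

  # subject-level offsets: LOSO mismatch exceeds kfold10 mismatch
  set.seed(13)
  subj <- rep(1:10, each = 4)
  off <- rnorm(10, 0, 3)[subj]
  X <- matrix(rnorm(40 * 5), 40, 5) + off
  fms <- make_fm(X, groups = rep(c("control", "PD"), each = 20),
                 subject_id = sprintf("S%02d", subj))
  mean_mm <- function(scheme) {
    cfg <- cv_config("control_vs_PD", scheme, repetitions = 1, seed = 5,
                     n_features = 4, n_trees = 10, rank_greedy = 4L)
    sp <- cv_splits(fms, cfg)[[1]]
    mean(vapply(sp$splits, function(s)
      mismatch_diagnostic(sp$data[s$train, ], sp$data[s$val, ])$mean_mismatch,
      numeric(1)))
  }
  expect_gt(mean_mm("loso"), mean_mm("kfold10"))
})
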