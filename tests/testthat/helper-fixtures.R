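# Shared fixtures, built lazily once per test run and cached.
.fx <- new.env(parent = emptyenv())
fixture <- function(name, builder) {
  if (!exists(name, envir = .fx)) assign(name, builder(), envir = .fx)
  get(name, envir = .fx)
}

# Task durations scaled down for test runtime; generator effect sizes are
# never scaled.
short_dur <- list(voice = 4, balance = 15, gait = 15, rest = 20, postural = 20,
                  tap_s = 15, rt_trials = 25)
tiny_dur <- list(voice = 2, balance = 10, gait = 10, rest = 10, postural = 10,
                 tap_s = 10, rt_trials = 12)

# group_params with selected fields overridden
gp <- function(base = default_group_params("control"), ...) {
  do.call(group_params, utils::modifyList(unclass(base), list(...)))
}

# Small separable cohort (control vs PD at default documented effect sizes)
sep_fm <- function() fixture("sep_fm", function() {
  cfg <- cohort_config(n_per_group = c(control = 8, iRBD = 2, PD = 8),
                       sessions_per_subject = 2, seed = 11,
                       durations = short_dur)
  extract_cohort(generate_cohort(cfg))
})

# Synthetic 998-column feature matrix from an explicit design matrix
make_fm <- function(X, groups, subject_id = NULL,
                    sex = rep_len(c("male", "female"), nrow(X))) {
  fn <- feature_names()
  stopifnot(ncol(X) <= length(fn))
  full <- matrix(rnorm(nrow(X) * length(fn)), nrow(X), length(fn),
                 dimnames = list(NULL, fn))
  full[, seq_len(ncol(X))] <- X
  if (is.null(subject_id)) subject_id <- sprintf("S%04d", seq_len(nrow(X)))
  as_feature_matrix(cbind(
    data.frame(subject_id = subject_id,
               session_id = sprintf("r%04d", seq_len(nrow(X))),
               group = groups, sex = sex, stringsAsFactors = FALSE),
    as.data.frame(full, check.names = FALSE)))
}

# relative comparison with a floor on the denominator (quantities that are
# exactly zero by construction would otherwise amplify float dust)
expect_rel_equal <- function(a, b, tol, floor = 1e-12) {
  expect_lt(max(abs(a - b) / pmax(abs(b), floor)), tol)
}

with_seed_rnorm <- function(seed, n, ...) {
  set.seed(seed)
  rnorm(n, ...)
}
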