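# Protocol task order (paper's task numbering 1-7).
TASKS <- c("voice", "balance", "gait", "tapping", "reaction",
           "rest_tremor", "postural_tremor")

#' Synthesize one complete 7-task session
#'
#' Builds all seven task payloads from a single [group_params()] object.
#' Task start times are strictly increasing, spaced 10-60 s apart so that
#' session-assembly windows are exercised.
#'
#' @param params A [group_params()] object.
#' @param subject_id Subject identifier string.
#' @param session_time Session start, seconds since epoch (UTC).
#' @param seed Integer seed.
#' @param durations,accel_rate_hz,voice_rate_hz See [cohort_config()].
#' @param f0_hz Optional per-session fundamental override.
#' @return A `pdm_session` object: subject/session ids, `task_times` (named
#'   epoch seconds, protocol order), and payloads `voice`, `balance`,
#'   `gait`, `rest_tremor`, `postural_tremor`, `taps`, `reactions`.
#' @export
synth_session <- function(params, subject_id = "S001",
                          session_time = 1500000000, seed = 1L,
                          durations = list(voice = 10, balance = 30, gait = 30,
                                           rest = 45, postural = 45,
                                           tap_s = 20, rt_trials = 40),
                          accel_rate_hz = 100, voice_rate_hz = 16000,
                          f0_hz = NULL) {
  dd <- list(voice = 10, balance = 30, gait = 30, rest = 45, postural = 45,
             tap_s = 20, rt_trials = 40)
  dd[names(durations)] <- durations
  voice <- synth_voice(params, dd$voice, voice_rate_hz, child_seed(seed, 1L),
                       f0_hz = f0_hz)
  balance <- synth_accel("balance", params, dd$balance, accel_rate_hz,
                         child_seed(seed, 2L))
  gait <- synth_accel("gait", params, dd$gait, accel_rate_hz, child_seed(seed, 3L))
  taps <- synth_taps(params, dd$tap_s, child_seed(seed, 4L))
  reactions <- synth_reactions(params, dd$rt_trials, child_seed(seed, 5L))
  rest <- synth_accel("rest_tremor", params, dd$rest, accel_rate_hz,
                      child_seed(seed, 6L))
  postural <- synth_accel("postural_tremor", params, dd$postural, accel_rate_hz,
                          child_seed(seed, 7L))
  task_len <- c(voice = dd$voice, balance = dd$balance, gait = dd$gait,
                tapping = dd$tap_s, reaction = 3 * dd$rt_trials,
                rest_tremor = dd$rest, postural_tremor = dd$postural)
  gaps <- with_seed(child_seed(seed, 8L), runif(7, 10, 60))
  starts <- session_time + cumsum(c(0, utils::head(task_len, -1) + utils::head(gaps, -1)))
  names(starts) <- TASKS
  structure(list(subject_id = subject_id,
                 session_id = sprintf("%s_%010d", subject_id, as.integer(session_time %% 1e10)),
                 session_time = session_time, task_times = starts,
                 voice = voice, balance = balance, gait = gait,
                 rest_tremor = rest, postural_tremor = postural,
                 taps = taps, reactions = reactions),
            class = "pdm_session")
}

# Apply a stable per-subject lognormal perturbation to the positive dials and
# an additive one to iti_drift, so subjects have individual signatures.
subject_params <- function(params, subject_cv, seed) {
  if (subject_cv <= 0) return(params)
  with_seed(seed, {
    p <- unclass(params)
    dials <- c("jitter_frac", "shimmer_frac", "tremor_amp_rest_ms2",
               "tremor_amp_post_ms2", "sway_rms_ms2", "cadence_hz",
               "iti_mean_s", "iti_cv", "tap_scatter_px",
               "rt_mu_s", "rt_sigma_s", "rt_tau_s", "step_amp_ms2")
    sdlog <- sqrt(log(1 + subject_cv^2))
    for (f in dials) p[[f]] <- p[[f]] * exp(rnorm(1, -sdlog^2 / 2, sdlog))
    if (is.finite(p$hnr_db)) p$hnr_db <- p$hnr_db + rnorm(1, 0, 4 * subject_cv / 0.12)
    p$tremor_freq_hz <- min(8, max(3, p$tremor_freq_hz + rnorm(1, 0, 0.3)))
    p$iti_drift <- p$iti_drift + rnorm(1, 0, 5e-4)
    do.call(group_params, p)
  })
}

#' Generate a full synthetic cohort
#'
#' Draws subjects for each group (sex per the group's `sex_ratio`, age from a
#' plausible clinic range), gives each subject a stable parameter signature,
#' draws a session count from a Poisson truncated at 1 with the configured
#' mean, and synthesizes every session. Deterministic given `config$seed`.
#'
#' @param config A [cohort_config()].
#' @param progress Print a line per subject (default `FALSE`).
#' @return A list with `subjects` (data.frame: `subject_id`, `group`, `sex`,
#'   `age`, `n_sessions`) and `sessions` (list of `pdm_session`).
#' @export
generate_cohort <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "cohort_config"))
  groups <- c("control", "iRBD", "PD")
  subj_rows <- list(); sessions <- list()
  sidx <- 0L
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    n <- config$n_per_group[[g]]
    for (i in seq_len(n)) {
      sidx <- sidx + 1L
      sub_seed <- child_seed(config$seed, sidx * 101L)
      subject_id <- sprintf("%s%03d", c(control = "C", iRBD = "R", PD = "P")[[g]], i)
      meta <- with_seed(child_seed(sub_seed, 1L), {
        sex <- if (runif(1) < config$sex_ratio[[g]]) "male" else "female"
        age <- round(runif(1, 55, 80))
        n_ses <- 0L
        while (n_ses < 1L) n_ses <- rpois(1, config$sessions_per_subject)
        f0_base <- rnorm(1, config$params[[g]]$f0_hz, config$params[[g]]$f0_sd_hz)
        list(sex = sex, age = age, n_ses = n_ses, f0 = max(80, f0_base))
      })
      sp <- subject_params(config$params[[g]], config$subject_cv,
                           child_seed(sub_seed, 2L))
      subj_rows[[sidx]] <- data.frame(subject_id = subject_id, group = g,
                                      sex = meta$sex, age = meta$age,
                                      n_sessions = meta$n_ses,
                                      stringsAsFactors = FALSE)
      base_time <- 1500000000 + sidx * 86400
      for (k in seq_len(meta$n_ses)) {
        # subject_cv = 0 means no stable subject signatures at all: the
        # fundamental is then redrawn per session, keeping recordings
        # exchangeable (needed for null-configuration calibration)
        f0_k <- with_seed(child_seed(sub_seed, 100L + k),
                          if (config$subject_cv > 0)
                            max(80, meta$f0 + rnorm(1, 0, 2))
                          else
                            max(80, rnorm(1, config$params[[g]]$f0_hz,
                                          config$params[[g]]$f0_sd_hz)))
        ses <- synth_session(sp, subject_id,
                             session_time = base_time + (k - 1) * 43200,
                             seed = child_seed(sub_seed, 10L + k),
                             durations = config$durations,
                             accel_rate_hz = config$accel_rate_hz,
                             voice_rate_hz = config$voice_rate_hz,
                             f0_hz = f0_k)
        sessions[[length(sessions) + 1L]] <- ses
      }
      if (progress) message(sprintf("generated %s (%d sessions)", subject_id, meta$n_ses))
    }
  }
  list(subjects = do.call(rbind, subj_rows), sessions = sessions)
}
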