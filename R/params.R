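#' Generative parameters for one clinical group
#'
#' Bundles every dial of the synthetic recording generator for one group
#' (control, iRBD or PD). All values are physical quantities with units; the
#' defaults describe a healthy control. Group-level disease effects are
#' encoded by [default_group_params()].
#'
#' @param f0_hz Mean fundamental frequency of the sustained phonation (Hz).
#' @param f0_sd_hz Between-session SD of the fundamental (Hz).
#' @param jitter_frac Cycle-to-cycle period perturbation, as a coefficient of
#'   variation (e.g. 0.005 = 0.5\% jitter).
#' @param shimmer_frac Cycle-to-cycle amplitude perturbation CV.
#' @param hnr_db Target harmonics-to-noise ratio of the phonation (dB); `Inf`
#'   means noiseless.
#' @param tremor_amp_rest_ms2,tremor_amp_post_ms2 Tremor acceleration
#'   amplitude (m/s^2) for the rest and postural tremor tasks.
#' @param tremor_freq_hz Tremor frequency in Hz, constrained to the 3-8 Hz
#'   band that encloses the 4-6 Hz parkinsonian rest tremor.
#' @param sway_rms_ms2 RMS of the pink-noise postural sway acceleration
#'   (m/s^2), used by all four IMU tasks as background motion.
#' @param cadence_hz Gait step rate (steps per second).
#' @param step_amp_ms2 Amplitude of the vertical step impulses during gait.
#' @param iti_mean_s Mean inter-tap interval for alternating finger tapping
#'   (s).
#' @param iti_cv Inter-tap interval coefficient of variation.
#' @param iti_drift Per-tap fractional change of the interval (hastening < 0,
#'   fatigue-slowing > 0).
#' @param tap_scatter_px Spatial SD of tap positions around the button
#'   centers (screen pixels).
#' @param rt_mu_s,rt_sigma_s,rt_tau_s Ex-Gaussian reaction-latency
#'   parameters: Gaussian mean and SD plus exponential tail mean (s). The
#'   latency mean is `rt_mu_s + rt_tau_s`.
#'
#' @return An object of class `group_params` (a validated named list).
#' @seealso [default_group_params()], [cohort_config()]
#' @export
group_params <- function(f0_hz = 120, f0_sd_hz = 10,
                         jitter_frac = 0.005, shimmer_frac = 0.03,
                         hnr_db = 25,
                         tremor_amp_rest_ms2 = 0.02,
                         tremor_amp_post_ms2 = 0.02,
                         tremor_freq_hz = 5,
                         sway_rms_ms2 = 0.05,
                         cadence_hz = 1.9, step_amp_ms2 = 2.0,
                         iti_mean_s = 0.35, iti_cv = 0.08,
                         iti_drift = 0, tap_scatter_px = 12,
                         rt_mu_s = 0.30, rt_sigma_s = 0.04, rt_tau_s = 0.06) {
  p <- list(f0_hz = f0_hz, f0_sd_hz = f0_sd_hz, jitter_frac = jitter_frac,
            shimmer_frac = shimmer_frac, hnr_db = hnr_db,
            tremor_amp_rest_ms2 = tremor_amp_rest_ms2,
            tremor_amp_post_ms2 = tremor_amp_post_ms2,
            tremor_freq_hz = tremor_freq_hz, sway_rms_ms2 = sway_rms_ms2,
            cadence_hz = cadence_hz, step_amp_ms2 = step_amp_ms2,
            iti_mean_s = iti_mean_s, iti_cv = iti_cv, iti_drift = iti_drift,
            tap_scatter_px = tap_scatter_px, rt_mu_s = rt_mu_s,
            rt_sigma_s = rt_sigma_s, rt_tau_s = rt_tau_s)
  validate_group_params(p)
  structure(p, class = "group_params")
}

validate_group_params <- function(p) {
  nonneg <- c("f0_sd_hz", "jitter_frac", "shimmer_frac",
              "tremor_amp_rest_ms2", "tremor_amp_post_ms2", "sway_rms_ms2",
              "step_amp_ms2", "iti_cv", "tap_scatter_px", "rt_sigma_s",
              "rt_tau_s")
  for (f in nonneg)
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1L || is.na(p[[f]]) || p[[f]] < 0)
      stop(sprintf("invalid group_params: '%s' must be a single nonnegative number", f),
           call. = FALSE)
  pos <- c("f0_hz", "cadence_hz", "iti_mean_s", "rt_mu_s")
  for (f in pos)
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1L || is.na(p[[f]]) || p[[f]] <= 0)
      stop(sprintf("invalid group_params: '%s' must be positive", f), call. = FALSE)
  if (p$tremor_freq_hz < 3 || p$tremor_freq_hz > 8)
    stop("invalid group_params: 'tremor_freq_hz' must lie in [3, 8]", call. = FALSE)
  if (!(is.infinite(p$hnr_db) || is.finite(p$hnr_db)))
    stop("invalid group_params: 'hnr_db' must be finite or Inf", call. = FALSE)
  invisible(p)
}

#' Default generative parameters per clinical group
#'
#' Encodes the documented disease-effect directions used by the synthetic
#' cohort: PD has increased tremor amplitude, vocal jitter/shimmer, reduced
#' HNR, slowed and more variable tapping, slowed reaction latency, higher
#' sway and lower cadence; iRBD shows the same directions at roughly one
#' third of the PD magnitude. Magnitudes are free modelling choices of this
#' package, not estimates from any clinical dataset.
#'
#' @param group One of `"control"`, `"iRBD"`, `"PD"`.
#' @return A [group_params()] object.
#' @export
default_group_params <- function(group = c("control", "iRBD", "PD")) {
  group <- match.arg(group)
  ctrl <- group_params()
  if (group == "control") return(ctrl)
  # PD deltas relative to control; iRBD applies 1/3 of each delta.
  pd <- list(jitter_frac = 0.018, shimmer_frac = 0.09, hnr_db = 14,
             tremor_amp_rest_ms2 = 0.9, tremor_amp_post_ms2 = 0.7,
             tremor_freq_hz = 5, sway_rms_ms2 = 0.14,
             cadence_hz = 1.55, iti_mean_s = 0.55, iti_cv = 0.22,
             iti_drift = -0.0015, tap_scatter_px = 28,
             rt_mu_s = 0.38, rt_sigma_s = 0.07, rt_tau_s = 0.12)
  w <- if (group == "PD") 1 else 1 / 3
  out <- unclass(ctrl)
  for (f in names(pd)) out[[f]] <- out[[f]] + w * (pd[[f]] - out[[f]])
  do.call(group_params, out)
}

#' Cohort-level configuration for the synthetic generator
#'
#' Describes the cohort the generator emulates: three groups (control, iRBD,
#' PD), a male-predominant iRBD group, and several recording sessions per
#' subject (the study collected on average 8-13 recordings per participant;
#' desk-scale defaults are smaller).
#'
#' @param n_per_group Subjects per group (>= 2). Either a single count or a
#'   named vector with entries `control`, `iRBD`, `PD`.
#' @param sessions_per_subject Mean sessions per subject; actual counts are
#'   drawn from a Poisson truncated at 1.
#' @param sex_ratio Fraction of male subjects per group, recycled across
#'   groups if scalar.
#' @param seed Integer seed; the whole cohort is a pure function of it.
#' @param params Named list of [group_params()] for `control`, `iRBD`, `PD`.
#'   Passing the same object for all three yields the null (zero-effect)
#'   configuration.
#' @param subject_cv Between-subject lognormal coefficient of variation
#'   applied to the positive generator dials, giving each subject a stable
#'   individual signature (needed for leave-one-subject-out behaviour).
#' @param durations List of task durations in seconds:
#'   `voice`, `balance`, `gait`, `rest`, `postural` plus `tap_s` and
#'   `rt_trials`. Defaults follow the test protocol (tremor tasks about
#'   45 s; the 5-task battery under 5 minutes).
#' @param accel_rate_hz Accelerometer sampling rate (>= 50 Hz).
#' @param voice_rate_hz Audio sampling rate (>= 16 kHz).
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = 10, sessions_per_subject = 3,
                          sex_ratio = c(control = 0.5, iRBD = 0.8, PD = 0.6),
                          seed = 1L,
                          params = list(control = default_group_params("control"),
                                        iRBD = default_group_params("iRBD"),
                                        PD = default_group_params("PD")),
                          subject_cv = 0.12,
                          durations = list(voice = 10, balance = 30, gait = 30,
                                           rest = 45, postural = 45,
                                           tap_s = 20, rt_trials = 40),
                          accel_rate_hz = 100, voice_rate_hz = 16000) {
  groups <- c("control", "iRBD", "PD")
  if (length(n_per_group) == 1L) n_per_group <- setNames(rep(n_per_group, 3), groups)
  if (length(sex_ratio) == 1L) sex_ratio <- setNames(rep(sex_ratio, 3), groups)
  n_per_group <- n_per_group[groups]; sex_ratio <- sex_ratio[groups]
  if (any(is.na(n_per_group)) || any(n_per_group < 2))
    stop("invalid cohort_config: 'n_per_group' must be >= 2 for every group", call. = FALSE)
  if (!is.numeric(sessions_per_subject) || sessions_per_subject < 1)
    stop("invalid cohort_config: 'sessions_per_subject' must be >= 1", call. = FALSE)
  if (any(!is.finite(sex_ratio)) || any(sex_ratio < 0) || any(sex_ratio > 1))
    stop("invalid cohort_config: 'sex_ratio' must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(subject_cv) || subject_cv < 0)
    stop("invalid cohort_config: 'subject_cv' must be >= 0", call. = FALSE)
  if (!setequal(names(params), groups))
    stop("invalid cohort_config: 'params' must name control, iRBD and PD", call. = FALSE)
  for (g in groups) validate_group_params(params[[g]])
  dd <- list(voice = 10, balance = 30, gait = 30, rest = 45, postural = 45,
             tap_s = 20, rt_trials = 40)
  dd[names(durations)] <- durations
  if (dd$voice < 1) stop("invalid cohort_config: 'durations$voice' must be >= 1 s", call. = FALSE)
  for (f in c("balance", "gait", "rest", "postural"))
    if (dd[[f]] < 10)
      stop(sprintf("invalid cohort_config: 'durations$%s' must be >= 10 s", f), call. = FALSE)
  if (accel_rate_hz < 50)
    stop("invalid cohort_config: 'accel_rate_hz' must be >= 50", call. = FALSE)
  if (voice_rate_hz < 16000)
    stop("invalid cohort_config: 'voice_rate_hz' must be >= 16000", call. = FALSE)
  structure(list(n_per_group = n_per_group,
                 sessions_per_subject = sessions_per_subject,
                 sex_ratio = sex_ratio, seed = as.integer(seed),
                 params = params, subject_cv = subject_cv, durations = dd,
                 accel_rate_hz = accel_rate_hz, voice_rate_hz = voice_rate_hz),
            class = "cohort_config")
}

#' Null (zero-effect) cohort configuration
#'
#' All three groups share the control generative parameters, so group labels
#' carry no signal; used for chance-level calibration of the classifier.
#' The chance-level expectation additionally requires recordings to be
#' exchangeable across labels, so the default `subject_cv = 0` removes all
#' stable subject signatures (including the per-subject fundamental
#' frequency, which is then redrawn per session): with stable signatures
#' and repeated sessions per subject, a classifier scores above chance on
#' a zero-effect cohort purely by recognizing subjects — the same
#' identity-confound phenomenon the leave-one-subject-out mismatch
#' diagnostic exists to expose.
#'
#' @param subject_cv See [cohort_config()]; 0 enforces exchangeability.
#' @param ... Passed to [cohort_config()].
#' @return A `cohort_config`.
#' @export
null_cohort_config <- function(subject_cv = 0, ...) {
  p <- default_group_params("control")
  cohort_config(params = list(control = p, iRBD = p, PD = p),
                subject_cv = subject_cv, ...)
}
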