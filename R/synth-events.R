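#' Synthesize an alternating finger-tapping event log
#'
#' Taps alternate between two fixed on-screen buttons. The k-th inter-tap
#' interval is `iti_mean_s * (1 + iti_drift * k)` times a lognormal noise
#' factor with coefficient of variation `iti_cv` (mean 1); negative
#' `iti_drift` models hastening. Tap positions are Gaussian around the
#' button centers with SD `tap_scatter_px`.
#'
#' @param params A [group_params()] object.
#' @param duration_s Tapping duration in seconds (> 0).
#' @param seed Integer seed.
#' @return A data.frame of tap events: `t` (s), `x`, `y` (px), `target_id`
#'   (`"left"`/`"right"`).
#' @export
synth_taps <- function(params, duration_s = 20, seed = 1L) {
  validate_group_params(params)
  if (duration_s <= 0) stop("duration_s must be > 0", call. = FALSE)
  centers <- tap_button_centers()
  with_seed(seed, {
    n_max <- ceiling(4 * duration_s / params$iti_mean_s) + 16L
    k <- seq_len(n_max)
    base <- params$iti_mean_s * pmax(1 + params$iti_drift * k, 0.05)
    if (params$iti_cv > 0) {
      sdlog <- sqrt(log(1 + params$iti_cv^2))
      noise <- exp(rnorm(n_max, -sdlog^2 / 2, sdlog))  # mean exactly 1
    } else noise <- rep(1, n_max)
    iti <- base * noise
    t <- cumsum(c(0.5, iti))            # first tap half a second in
    keep <- t <= duration_s
    t <- t[keep]
    n <- length(t)
    side <- rep_len(c("left", "right"), n)
    cx <- centers$x[match(side, centers$target_id)]
    cy <- centers$y[match(side, centers$target_id)]
    data.frame(t = t,
               x = cx + params$tap_scatter_px * rnorm(n),
               y = cy + params$tap_scatter_px * rnorm(n),
               target_id = side, stringsAsFactors = FALSE)
  })
}

# Button geometry shared by generator and spatial tapping features.
tap_button_centers <- function() {
  data.frame(target_id = c("left", "right"),
             x = c(90, 230), y = c(240, 240), radius = c(50, 50),
             stringsAsFactors = FALSE)
}

#' Synthesize a simple reaction-time event log
#'
#' Each trial shows a button at a jittered onset; the press latency follows
#' an ex-Gaussian with parameters (`rt_mu_s`, `rt_sigma_s`, `rt_tau_s`), the
#' release latency (after stimulus offset) an independent draw from the same
#' law. Non-positive latency draws are rejected and redrawn.
#'
#' @param params A [group_params()] object.
#' @param n_trials Number of trials (>= 1).
#' @param seed Integer seed.
#' @return A data.frame of events: `stim_on_t`, `press_t`, `stim_off_t`,
#'   `release_t` (s), `x`, `y` (px).
#' @export
synth_reactions <- function(params, n_trials = 40, seed = 1L) {
  validate_group_params(params)
  if (!is.numeric(n_trials) || n_trials < 1)
    stop("n_trials must be >= 1", call. = FALSE)
  n_trials <- as.integer(n_trials)
  with_seed(seed, {
    lat <- function(n) {
      x <- rnorm(n, params$rt_mu_s, params$rt_sigma_s) +
        (if (params$rt_tau_s > 0) rexp(n, 1 / params$rt_tau_s) else 0)
      bad <- which(x <= 0)
      guard <- 0L
      while (length(bad) && guard < 100L) {
        x[bad] <- rnorm(length(bad), params$rt_mu_s, params$rt_sigma_s) +
          (if (params$rt_tau_s > 0) rexp(length(bad), 1 / params$rt_tau_s) else 0)
        bad <- which(x <= 0)
        guard <- guard + 1L
      }
      if (length(bad)) x[bad] <- params$rt_mu_s + params$rt_tau_s
      x
    }
    iti <- runif(n_trials, 1.5, 3)
    stim_on <- cumsum(iti)
    press <- stim_on + lat(n_trials)
    stim_off <- press + runif(n_trials, 0.5, 1.5)
    release <- stim_off + lat(n_trials)
    data.frame(stim_on_t = stim_on, press_t = press,
               stim_off_t = stim_off, release_t = release,
               x = 160 + 15 * rnorm(n_trials), y = 320 + 15 * rnorm(n_trials))
  })
}
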