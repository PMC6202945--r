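# Pink (1/f) noise via frequency-domain shaping of white noise; zero mean,
# unit RMS. Standard posturography assumption for sway background.
pink_noise <- function(n) {
  nf <- 2L * (n %/% 2L + 1L)
  white <- rnorm(nf)
  spec <- fft(white)
  f <- c(1, seq_len(nf - 1L))           # avoid DC blowup
  spec <- spec / sqrt(f)
  x <- Re(fft(spec, inverse = TRUE)) / nf
  x <- x[seq_len(n)]
  x <- x - mean(x)
  s <- sd(x)
  if (s > 0) x / s else x
}

#' Synthesize a triaxial accelerometer recording for one IMU task
#'
#' All four tasks share a gravity offset on the z axis plus pink-noise
#' postural sway on each axis (RMS `sway_rms_ms2` per axis). The tremor tasks
#' add a sinusoid at `tremor_freq_hz` with slow random amplitude modulation,
#' split across the x/y axes as a hand-held phone would see it; the gait task
#' adds periodic step impulses at `cadence_hz` on the vertical axis with a
#' decaying impulse shape.
#'
#' @param task One of `"balance"`, `"gait"`, `"rest_tremor"`,
#'   `"postural_tremor"`.
#' @param params A [group_params()] object.
#' @param duration_s Duration in seconds (>= 10; tremor tasks run about 45 s
#'   in the protocol).
#' @param rate_hz Sampling rate (>= 50 Hz).
#' @param seed Integer seed.
#' @return An `accel_stream`: list with `t`, `ax`, `ay`, `az` (m/s^2).
#' @export
synth_accel <- function(task, params, duration_s = 45, rate_hz = 100, seed = 1L) {
  task <- as.character(task)
  if (!task %in% c("balance", "gait", "rest_tremor", "postural_tremor"))
    stop(sprintf("unknown IMU task '%s'", task), call. = FALSE)
  validate_group_params(params)
  if (duration_s < 10) stop("duration_s must be >= 10 s", call. = FALSE)
  if (rate_hz < 50) stop("rate_hz must be >= 50", call. = FALSE)
  with_seed(seed, {
    n <- floor(duration_s * rate_hz)
    t <- (seq_len(n) - 1L) / rate_hz
    sway <- params$sway_rms_ms2
    ax <- sway * pink_noise(n)
    ay <- sway * pink_noise(n)
    az <- 9.81 + sway * pink_noise(n)
    if (task %in% c("rest_tremor", "postural_tremor")) {
      amp <- if (task == "rest_tremor") params$tremor_amp_rest_ms2 else
        params$tremor_amp_post_ms2
      if (amp > 0) {
        # slow (~0.3 Hz) amplitude modulation, bounded away from 0
        m <- 1 + 0.3 * sin(2 * pi * 0.3 * t + runif(1, 0, 2 * pi)) +
          0.1 * pink_noise(n)
        m <- pmax(m, 0.2)
        ph <- runif(1, 0, 2 * pi)
        osc <- sin(2 * pi * params$tremor_freq_hz * t + ph)
        ax <- ax + amp * 0.8 * m * osc
        ay <- ay + amp * 0.6 * m * cos(2 * pi * params$tremor_freq_hz * t + ph)
        az <- az + amp * 0.5 * m * sin(2 * pi * params$tremor_freq_hz * t +
                                         ph + runif(1, 0, 2 * pi))
      }
    } else if (task == "gait") {
      # step impulses: decaying half-sine bursts at the cadence
      step_period <- 1 / params$cadence_hz
      n_steps <- ceiling(duration_s / step_period) + 2L
      intervals <- step_period * (1 + 0.02 * rnorm(n_steps))
      onsets <- runif(1, 0, step_period) + cumsum(c(0, intervals))
      onsets <- onsets[onsets <= duration_s]
      shape_t <- seq(0, 0.25, by = 1 / rate_hz)
      shape <- exp(-shape_t / 0.07) * sin(2 * pi * 8 * shape_t)
      imp <- numeric(n)
      idx <- round(onsets * rate_hz) + 1L
      idx <- idx[idx >= 1L & idx <= n]
      imp[idx] <- params$step_amp_ms2 * (1 + 0.1 * rnorm(length(idx)))
      z <- convolve(imp, rev(shape), type = "open")[seq_len(n)]
      az <- az + z
      ax <- ax + 0.3 * convolve(imp * rnorm(n, 1, 0.1), rev(shape),
                                type = "open")[seq_len(n)]
    }
    structure(list(t = t, ax = ax, ay = ay, az = az), class = "accel_stream")
  })
}
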