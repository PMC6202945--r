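#' Synthesize a sustained phonation recording
#'
#' Generates the vowel /a:/ as a harmonic source: the first five harmonics of
#' the fundamental with a fixed formant-like amplitude rolloff, built cycle by
#' cycle so that cycle periods carry exactly the requested jitter and cycle
#' amplitudes the requested shimmer, plus additive Gaussian noise scaled to
#' hit the target harmonics-to-noise ratio. This is deliberately not an
#' articulatory vowel model; it is sufficient to drive jitter, shimmer, HNR,
#' MFCC and related dysphonia measures.
#'
#' @param params A [group_params()] object (uses `f0_hz`, `jitter_frac`,
#'   `shimmer_frac`, `hnr_db`).
#' @param duration_s Duration in seconds (>= 1).
#' @param rate_hz Sampling rate; must be at least twice the fifth harmonic
#'   (10 * f0).
#' @param seed Integer seed.
#' @param f0_hz Optional fundamental override (defaults to `params$f0_hz`,
#'   i.e. no between-session variation; [generate_cohort()] draws it).
#' @return A `voice_recording`: list with `samples` (numeric, roughly unit
#'   amplitude) and `rate_hz`.
#' @export
synth_voice <- function(params, duration_s = 10, rate_hz = 16000, seed = 1L,
                        f0_hz = NULL) {
  validate_group_params(params)
  if (duration_s < 1) stop("duration_s must be >= 1 s", call. = FALSE)
  f0 <- f0_hz %||% params$f0_hz
  if (rate_hz < 2 * 5 * f0)
    stop(sprintf("rate_hz = %g below the Nyquist need of the 5th harmonic (%g Hz)",
                 rate_hz, 5 * f0), call. = FALSE)
  with_seed(seed, {
    n_cycles <- ceiling(duration_s * f0) + 2L
    t0 <- 1 / f0
    periods <- t0 * (1 + params$jitter_frac * rnorm(n_cycles))
    periods <- pmax(periods, 0.2 * t0)
    amps <- 1 + params$shimmer_frac * rnorm(n_cycles)
    amps <- pmax(amps, 0.05)
    # harmonic rolloff ~ -6 dB/harmonic with a formant-like bump on h2
    h_amp <- c(1, 0.7, 0.35, 0.2, 0.1)
    n <- floor(duration_s * rate_hz)
    starts <- cumsum(c(0, periods))
    x <- numeric(n)
    tt <- (seq_len(n) - 1L) / rate_hz
    cyc <- findInterval(tt, starts)          # cycle index per sample, 1-based
    cyc[cyc < 1L] <- 1L; cyc[cyc > n_cycles] <- n_cycles
    phase_frac <- (tt - starts[cyc]) / periods[cyc]  # in [0,1) within cycle
    for (h in seq_along(h_amp))
      x <- x + h_amp[h] * sin(2 * pi * h * phase_frac)
    x <- x * amps[cyc]
    if (is.finite(params$hnr_db)) {
      p_sig <- mean(x^2)
      p_noise <- p_sig / 10^(params$hnr_db / 10)
      x <- x + rnorm(n, sd = sqrt(p_noise))
    }
    x <- 0.9 * x / max(abs(x))           # audio-range, PCM-16 safe
    structure(list(samples = x, rate_hz = rate_hz), class = "voice_recording")
  })
}
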