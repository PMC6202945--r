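# Discretize a numeric vector into nb equal-width bins (1..nb).
bin_equal_width <- function(x, nb) {
  r <- range(x, finite = TRUE)
  if (!all(is.finite(r)) || r[1] == r[2]) return(rep(1L, length(x)))
  b <- pmin(pmax(floor((x - r[1]) / (r[2] - r[1]) * nb) + 1L, 1L), nb)
  as.integer(b)
}

# Mutual information (nats) between two discretized vectors.
mutual_info_binned <- function(bx, by, nb) {
  n <- length(bx)
  joint <- tabulate((bx - 1L) * nb + by, nb * nb) / n
  px <- tabulate(bx, nb) / n
  py <- tabulate(by, nb) / n
  pij <- joint[joint > 0]
  idx <- which(joint > 0) - 1L
  i <- idx %/% nb + 1L; j <- idx %% nb + 1L
  sum(pij * log(pij / (px[i] * py[j])))
}

# Cadence estimate (Hz) from the step-impulse envelope: band-pass to the
# impulse band, rectify, smooth ~0.15 s, then take the strongest
# autocorrelation peak in the 0.25-2 s step-interval range. The raw
# magnitude autocorrelation is dominated by slow sway, so the envelope is
# the reliable carrier of step periodicity.
cadence_estimate <- function(s, rate) {
  env <- abs(bandpass(s, rate, 2, min(20, rate / 2 - 1)))
  k <- max(1L, round(0.15 * rate))
  env <- as.numeric(stats::filter(env, rep(1 / k, k), sides = 2))
  env[!is.finite(env)] <- 0
  ac <- acf_fft(env)
  lags <- round(rate / 4):round(rate * 2)
  lags <- lags[lags + 1L <= length(ac) & lags >= 1L]
  if (!length(lags)) return(NA_real_)
  rate / lags[which.max(ac[lags + 1L])]
}

#' Extract the 147-feature battery from one IMU task recording
#'
#' Computes five categories of summary measures on four derived signals
#' (the three detrended axes and the detrended vector magnitude):
#' time-domain descriptive statistics; Welch-PSD frequency-domain measures
#' including 3-8 Hz tremor-band power; nonlinear measures (sample entropy,
#' Higuchi fractal dimension, DFA, recurrence rate, autocorrelation decay);
#' jerk measures; and cross-axis measures (correlations, mutual
#' information, covariance eigenvalue ratios, axis energy fractions).
#' Detrending is a 0.25 Hz high-pass, which removes gravity and slow
#' orientation change. Non-uniform sampling beyond 5\% timestamp jitter is
#' resampled to a uniform grid.
#'
#' @param stream An `accel_stream` (see [synth_accel()]), ideally after
#'   [segment_task()].
#' @param task Prefix used for the feature names: `"balance"`, `"gait"`,
#'   `"rest"` or `"postural"`. For gait the dominant frequency slot doubles
#'   as the cadence estimate.
#' @return Named numeric vector of length 147.
#' @export
motion_features <- function(stream, task = c("balance", "gait", "rest", "postural")) {
  task <- match.arg(task)
  nm <- motion_feature_names(task)
  out <- setNames(rep(NA_real_, length(nm)), nm)
  t <- as.numeric(stream$t)
  if (length(t) < 16L) return(out)
  dt <- diff(t)
  rate <- 1 / median(dt)
  if (any(abs(dt - median(dt)) > 0.05 * median(dt))) {
    grid <- seq(t[1L], t[length(t)], by = median(dt))
    ax <- approx(t, stream$ax, grid)$y
    ay <- approx(t, stream$ay, grid)$y
    az <- approx(t, stream$az, grid)$y
  } else {
    ax <- as.numeric(stream$ax); ay <- as.numeric(stream$ay)
    az <- as.numeric(stream$az)
  }
  n <- length(ax)
  if (n / rate < 5) return(out)
  mag <- sqrt(ax^2 + ay^2 + az^2)
  sigs <- list(x = highpass(ax, rate), y = highpass(ay, rate),
               z = highpass(az, rate), mag = highpass(mag, rate))

  set <- function(name, value) {
    key <- paste0(task, ".", name)
    v <- suppressWarnings(as.numeric(value))
    out[key] <<- if (length(v) == 1L && is.finite(v)) v else NA_real_
  }

  for (sname in names(sigs)) {
    s <- sigs[[sname]]
    pre <- function(f) paste(sname, f, sep = "_")

    ## category 1: time domain
    mu <- mean(s); sdev <- sd(s)
    set(pre("t_mean"), mu)
    set(pre("t_sd"), sdev)
    set(pre("t_rms"), sqrt(mean(s^2)))
    set(pre("t_iqr"), iqr_(s))
    set(pre("t_skew"), skewness(s))
    set(pre("t_kurt"), kurtosis(s))
    sgn <- sign(s - mu)
    set(pre("t_zcr"), mean(diff(sgn) != 0) * rate)
    set(pre("t_p2p"), diff(range(s)))
    set(pre("t_mad"), mean(abs(s - mu)))
    lag1s <- round(rate)
    ac <- acf_fft(s)
    set(pre("t_ac1s"), if (lag1s + 1L <= length(ac)) ac[lag1s + 1L] else NA)

    ## category 2: frequency domain (Welch, 4 s Hann, 50% overlap)
    wp <- welch_psd(s, rate, window_s = 4)
    total <- sum(wp$psd) * wp$df
    bp <- c(low = band_power(wp, 0.5, 3), tremor = band_power(wp, 3, 8),
            mid = band_power(wp, 8, 12), high = band_power(wp, 12, 20))
    set(pre("f_total"), total)
    set(pre("f_bp_low"), bp["low"]); set(pre("f_bp_tremor"), bp["tremor"])
    set(pre("f_bp_mid"), bp["mid"]); set(pre("f_bp_high"), bp["high"])
    set(pre("f_rel_tremor"), if (total > 0) bp["tremor"] / total else NA)
    sel <- wp$freq >= 0.5
    psel <- wp$psd[sel]; fsel <- wp$freq[sel]
    if (length(psel) && sum(psel) > 0) {
      k <- which.max(psel)
      if (task == "gait") {
        # the dominant-frequency slot doubles as the cadence estimate
        set(pre("f_domfreq"), cadence_estimate(s, rate))
      } else {
        set(pre("f_domfreq"), fsel[k])
      }
      set(pre("f_domprom"), psel[k] / mean(psel))
      pcent <- sum(psel * fsel) / sum(psel)
      set(pre("f_centroid"), pcent)
      set(pre("f_spread"), sqrt(sum(psel * (fsel - pcent)^2) / sum(psel)))
      set(pre("f_entropy"), norm_entropy(psel))
      cs <- cumsum(psel) / sum(psel)
      set(pre("f_edge95"), fsel[which(cs >= 0.95)[1L]])
    }

    ## category 3: nonlinear
    set(pre("n_sampen"), .sampen_cpp(s[seq_len(min(n, 3000L))], 2L, 0.2 * sdev))
    set(pre("n_higuchi"), .higuchi_cpp(s, 8L))
    set(pre("n_dfa"), dfa_exponent(s, 16L, max(64L, n %/% 8L)))
    zs <- (s - mu) / (sdev + 1e-12)
    set(pre("n_recrate"), .recurrence_rate_cpp(zs, 3L, max(1L, round(rate / 10)),
                                               0.5, 600L))
    below <- which(abs(ac) < exp(-1))
    set(pre("n_acdecay"), if (length(below)) (below[1L] - 1L) / rate else
      length(ac) / rate)

    ## category 4: jerk
    j <- diff(s) * rate
    set(pre("j_mean"), mean(j)); set(pre("j_sd"), sd(j))
    jr <- sqrt(mean(j^2))
    set(pre("j_rms"), jr)
    set(pre("j_ratio"), jr / (sqrt(mean(s^2)) + 1e-12))
    # negated log dimensionless jerk (movement-smoothness convention)
    dur <- n / rate
    peak <- max(abs(s))
    if (peak > 0)
      set(pre("j_smooth"), -log(sum(j^2) / rate * dur / peak^2 + 1e-12))
    wj <- welch_psd(j, rate, window_s = 4)
    set(pre("j_specent"), norm_entropy(wj$psd))
  }

  ## category 5: cross-axis (15)
  xyz <- cbind(sigs$x, sigs$y, sigs$z)
  cc <- suppressWarnings(cor(xyz))
  cc[!is.finite(cc)] <- 1  # identical/constant axes correlate perfectly
  set("c_rxy", cc[1, 2]); set("c_rxz", cc[1, 3]); set("c_ryz", cc[2, 3])
  nb <- 16L
  bx <- bin_equal_width(sigs$x, nb); by <- bin_equal_width(sigs$y, nb)
  bz <- bin_equal_width(sigs$z, nb)
  set("c_mixy", mutual_info_binned(bx, by, nb))
  set("c_mixz", mutual_info_binned(bx, bz, nb))
  set("c_miyz", mutual_info_binned(by, bz, nb))
  ev <- sort(eigen(stats::cov(xyz), symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ev <- pmax(ev, 0)
  eps <- 1e-12 * max(ev[1], 1e-300)
  set("c_eig12", ev[1] / max(ev[2], eps))
  set("c_eig23", ev[2] / max(ev[3], eps))
  set("c_eig13", ev[1] / max(ev[3], eps))
  tot <- sum(ev)
  if (tot > 0) for (i in 1:3) set(paste0("c_eigfrac", i), ev[i] / tot)
  en <- c(sum(sigs$x^2), sum(sigs$y^2), sum(sigs$z^2))
  if (sum(en) > 0) {
    set("c_enfrac_x", en[1] / sum(en))
    set("c_enfrac_y", en[2] / sum(en))
    set("c_enfrac_z", en[3] / sum(en))
  }
  out
}
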