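#' Track the fundamental frequency of a sustained phonation
#'
#' Frame-wise autocorrelation pitch tracker: 40 ms frames, 10 ms hop, search
#' range 50-500 Hz, with parabolic interpolation of the autocorrelation peak.
#' Cycle marks are then placed by waveform peak picking guided by the local
#' period, so cycle-level jitter/shimmer measures can be computed.
#'
#' @param voice A `voice_recording` (see [synth_voice()]), ideally after
#'   [segment_task()].
#' @param f_min,f_max Pitch search range (Hz).
#' @param voicing_threshold Minimum normalized autocorrelation at the pitch
#'   lag for a frame to count as voiced.
#' @return An `f0_contour`: `time` (frame centers, s), `f0` (Hz, NA when
#'   unvoiced), `voiced` (logical), `hnr_frame` (dB), `cycle_marks` (s),
#'   `cycle_amps`, `voiced_frac`.
#' @export
track_f0 <- function(voice, f_min = 50, f_max = 500, voicing_threshold = 0.45) {
  stopifnot(is.list(voice), !is.null(voice$samples), !is.null(voice$rate_hz))
  x <- as.numeric(voice$samples)
  fs <- voice$rate_hz
  frame <- round(0.040 * fs); hop <- round(0.010 * fs)
  fr <- frame_signal(x, frame, hop)
  nfr <- ncol(fr)
  lag_min <- max(2L, floor(fs / f_max))
  lag_max <- min(frame - 1L, ceiling(fs / f_min))
  f0 <- rep(NA_real_, nfr); hnrf <- rep(NA_real_, nfr)
  voiced <- logical(nfr)
  rms_all <- if (nfr) sqrt(colMeans(fr^2)) else numeric(0)
  rms_gate <- 0.1 * median(rms_all)
  for (i in seq_len(nfr)) {
    if (rms_all[i] < rms_gate) next
    r <- acf_fft(fr[, i])
    seg <- r[(lag_min + 1L):(lag_max + 1L)]
    k <- which.max(seg)
    rmax <- seg[k]
    if (!is.finite(rmax) || rmax < voicing_threshold) next
    lag <- lag_min + k - 1L
    # parabolic interpolation around the peak
    if (lag > lag_min && lag < lag_max) {
      y1 <- r[lag]; y2 <- r[lag + 1L]; y3 <- r[lag + 2L]
      denom <- y1 - 2 * y2 + y3
      if (is.finite(denom) && abs(denom) > 1e-12)
        lag <- lag + 0.5 * (y1 - y3) / denom
    }
    f0[i] <- fs / lag
    voiced[i] <- TRUE
    # unbiased harmonicity at the pitch lag (divide out rectangular taper)
    li <- as.integer(round(lag))
    rc <- r[li + 1L] * frame / (frame - li)
    rc <- min(max(rc, 1e-6), 1 - 1e-6)
    hnrf[i] <- 10 * log10(rc / (1 - rc))
  }
  times <- (seq_len(nfr) - 1L) * hop / fs + frame / (2 * fs)
  marks <- cycle_marks(x, fs, times, f0, voiced)
  structure(list(time = times, f0 = f0, voiced = voiced, hnr_frame = hnrf,
                 cycle_marks = marks$t, cycle_amps = marks$amps,
                 voiced_frac = if (nfr) mean(voiced) else 0, rate_hz = fs),
            class = "f0_contour")
}

# Peak picking on the fundamental-band signal: from the strongest peak in
# the longest voiced run, walk in both directions in steps of the local
# period, refining each mark by parabolic interpolation for sub-sample
# accuracy. Cycle amplitudes are taken as the per-cycle peak magnitude of
# the original waveform.
cycle_marks <- function(x, fs, times, f0, voiced) {
  none <- list(t = numeric(0), idx = integer(0), amps = numeric(0))
  if (!any(voiced)) return(none)
  f0_med <- median(f0[voiced], na.rm = TRUE)
  if (!is.finite(f0_med) || f0_med <= 0) return(none)
  xb <- bandpass(x, fs, 0.6 * f0_med, 1.5 * f0_med)
  r <- rle(voiced)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  i0 <- starts[best]; i1 <- ends[best]
  s0 <- max(2L, round(times[i0] * fs)); s1 <- min(length(x) - 1L, round(times[i1] * fs))
  if (s1 - s0 < 8L) return(none)
  local_period <- function(s) {
    fi <- findInterval(s / fs, times)
    fi <- min(max(fi, 1L), length(f0))
    p <- f0[fi]
    if (!is.finite(p)) p <- f0_med
    fs / p
  }
  seed <- s0 + which.max(xb[s0:s1]) - 1L
  marks <- seed
  cur <- seed
  repeat {                                # forward
    per <- local_period(cur)
    lo <- round(cur + 0.7 * per); hi <- round(cur + 1.3 * per)
    if (hi > s1) break
    nxt <- lo + which.max(xb[lo:hi]) - 1L
    marks <- c(marks, nxt); cur <- nxt
  }
  cur <- seed
  repeat {                                # backward
    per <- local_period(cur)
    lo <- round(cur - 1.3 * per); hi <- round(cur - 0.7 * per)
    if (lo < s0) break
    prv <- lo + which.max(xb[lo:hi]) - 1L
    marks <- c(prv, marks); cur <- prv
  }
  marks <- sort(unique(marks))
  # sub-sample refinement: parabola through the peak and its neighbours
  tm <- vapply(marks, function(s) {
    y1 <- xb[s - 1L]; y2 <- xb[s]; y3 <- xb[s + 1L]
    denom <- y1 - 2 * y2 + y3
    off <- if (is.finite(denom) && abs(denom) > 1e-15)
      0.5 * (y1 - y3) / denom else 0
    (s - 1L + max(min(off, 0.5), -0.5)) / fs
  }, numeric(1))
  # one amplitude per complete cycle, endpoint-inclusive so the multiset is
  # exactly symmetric under time reversal
  amps <- if (length(marks) > 1L)
    vapply(seq_len(length(marks) - 1L), function(k)
      max(abs(x[marks[k]:marks[k + 1L]])), numeric(1))
  else numeric(0)
  list(t = tm, idx = marks, amps = amps)
}

# Praat-style k-point amplitude perturbation quotient.
apq <- function(a, k) {
  n <- length(a)
  if (n < k) return(NA_real_)
  half <- (k - 1L) %/% 2L
  sm <- vapply((half + 1L):(n - half), function(i) mean(a[(i - half):(i + half)]),
               numeric(1))
  mean(abs(a[(half + 1L):(n - half)] - sm)) / mean(a)
}

#' Extract the 330-feature voice battery
#'
#' Computes the dysphonia-measure catalog from a segmented sustained
#' phonation: jitter and shimmer families on cycle marks (Praat-style local
#' definitions), harmonics-to-noise measures, pitch period entropy (PPE),
#' recurrence period density entropy (RPDE), detrended fluctuation analysis
#' (DFA) of the waveform, vocal-fold excitation ratios on the linear
#' prediction residual, glottal-quotient proxies, MFCC 0-12 with deltas,
#' f0-contour statistics, 3-15 Hz vocal tremor modulation, frame-wise
#' spectral shape statistics, and Haar wavelet log-energies/entropies of the
#' f0 and amplitude-envelope series.
#'
#' If fewer than half the frames are voiced the whole block is returned as
#' missing (NA), mirroring a failed phonation.
#'
#' @param voice A `voice_recording`.
#' @param contour Optional precomputed [track_f0()] result.
#' @return Named numeric vector of length 330 (`voice.` prefix).
#' @export
voice_features <- function(voice, contour = NULL) {
  nm <- voice_feature_names()
  out <- setNames(rep(NA_real_, length(nm)), nm)
  if (is.null(contour)) contour <- track_f0(voice)
  if (contour$voiced_frac < 0.5) return(out)
  x <- as.numeric(voice$samples); fs <- voice$rate_hz
  set <- function(name, value) {
    key <- paste0("voice.", name)
    if (!key %in% nm) stop("internal: unknown voice feature ", name)
    v <- suppressWarnings(as.numeric(value))
    out[key] <<- if (length(v) == 1L && is.finite(v)) v else NA_real_
  }

  ## jitter / shimmer on cycle marks ----------------------------------------
  tm <- contour$cycle_marks
  if (length(tm) >= 12L) {
    per <- diff(tm)
    mp <- mean(per)
    set("period_mean", mp)
    set("period_sd", sd(per))
    set("jit_cv", sd(per) / mp)
    set("jit_local", mean(abs(diff(per))) / mp)
    set("jit_local_abs", mean(abs(diff(per))))
    n <- length(per)
    rap <- mean(abs(per[2:(n - 1)] -
                      (per[1:(n - 2)] + per[2:(n - 1)] + per[3:n]) / 3)) / mp
    set("jit_rap", rap)
    if (n >= 5L) {
      sm5 <- vapply(3:(n - 2), function(i) mean(per[(i - 2):(i + 2)]), numeric(1))
      set("jit_ppq5", mean(abs(per[3:(n - 2)] - sm5)) / mp)
    }
    set("jit_ddp", mean(abs(diff(diff(per)))) / mp)
    a <- contour$cycle_amps
    a <- a[a > 0]
    if (length(a) >= 12L) {
      ma <- mean(a)
      set("amp_mean", ma); set("amp_sd", sd(a)); set("amp_range", diff(range(a)))
      set("shim_cv", sd(a) / ma)
      set("shim_local", mean(abs(diff(a))) / ma)
      set("shim_db", mean(abs(20 * log10(a[-1] / a[-length(a)]))))
      set("shim_apq3", apq(a, 3L))
      set("shim_apq5", apq(a, 5L))
      set("shim_apq11", apq(a, 11L))
      set("shim_dda", mean(abs(diff(diff(a)))) / ma)
    }
  }

  ## HNR / NHR ---------------------------------------------------------------
  h <- contour$hnr_frame[contour$voiced]
  h <- h[is.finite(h)]
  if (length(h) >= 3L) {
    # average the noise fraction in the power domain: per-frame dB values
    # have a convex, heavy-tailed mapping that biases the plain mean upward
    nhr <- 10^(-h / 10)
    set("hnr_mean", -10 * log10(mean(nhr)))
    set("hnr_sd", sd(h))
    set("nhr_mean", mean(nhr)); set("nhr_sd", sd(nhr))
  }

  ## PPE ---------------------------------------------------------------------
  f0v <- contour$f0[contour$voiced]
  f0v <- f0v[is.finite(f0v) & f0v > 0]
  if (length(f0v) >= 20L) {
    st <- 12 * log2(f0v / median(f0v))
    ar1 <- if (sd(st) > 1e-12) suppressWarnings(cor(st[-1], st[-length(st)])) else 0
    if (!is.finite(ar1)) ar1 <- 0
    res <- st[-1] - ar1 * st[-length(st)]  # AR(1) whitening
    br <- seq(-6, 6, length.out = 31L)
    cnt <- tabulate(cut(pmin(pmax(res, -6), 6), br, include.lowest = TRUE), 30L)
    set("ppe", norm_entropy(cnt, n_ref = 30L))
  }

  ## RPDE + DFA on the waveform ---------------------------------------------
  dec <- max(1L, floor(fs / 2000))
  xd <- x[seq(1L, length(x), by = dec)]
  mid <- max(1L, (length(xd) - 4000L) %/% 2L)
  xd <- xd[mid:min(length(xd), mid + 3999L)]
  xd <- (xd - mean(xd)) / (sd(xd) + 1e-12)
  rp <- .rpde_cpp(xd, 4L, 2L, 0.12, 60L)
  set("rpde", rp$rpde)
  set("dfa", dfa_exponent(x, 50L, 1000L))

  ## VFER on LPC residual ----------------------------------------------------
  seg <- x[seq_len(min(length(x), 4L * fs))]
  e <- lpc_residual(seg, 12L)
  wps <- welch_psd(e, fs, window_s = 0.05)
  bands <- rbind(c(0, 500), c(500, 1000), c(1000, 2500), c(2500, 5000),
                 c(5000, min(8000, fs / 2)))
  be <- vapply(seq_len(5L), function(i) band_power(wps, bands[i, 1], bands[i, 2]),
               numeric(1))
  tot <- sum(be)
  if (tot > 0) {
    for (i in 1:5) set(paste0("vfer_e_b", i), be[i] / tot)
    hi <- be[4] + be[5]
    set("vfer_low_high_ratio", (be[1] + be[2] + be[3]) / max(hi, 1e-12))
  }
  set("vfer_spec_entropy", norm_entropy(wps$psd))
  cnt <- tabulate(cut(e, seq(min(e), max(e), length.out = 33L),
                      include.lowest = TRUE), 32L)
  set("vfer_amp_entropy", norm_entropy(cnt, n_ref = 32L))
  set("vfer_energy_db", 10 * log10(mean(e^2) / mean(seg^2)))

  ## glottal quotient proxy ---------------------------------------------------
  if (length(contour$cycle_marks) >= 12L) {
    idx <- round(contour$cycle_marks * fs) + 1L
    gq <- vapply(seq_len(length(idx) - 1L), function(k) {
      cyc <- e[idx[k]:min(idx[k + 1L], length(e))]
      if (length(cyc) < 4L) return(NA_real_)
      mean(abs(cyc) < 0.1 * max(abs(cyc)))
    }, numeric(1))
    gq <- gq[is.finite(gq)]
    if (length(gq) >= 5L) {
      set("gq_mean", mean(gq)); set("gq_sd", sd(gq))
      set("gq_min", min(gq)); set("gq_max", max(gq))
    }
  }

  ## MFCC + deltas ------------------------------------------------------------
  mf <- mfcc(x, fs)
  if (ncol(mf) >= 5L) {
    dmf <- t(apply(mf, 1L, function(r) c(0, diff(r))))
    st4 <- function(v) c(mean(v), sd(v), skewness(v), kurtosis(v))
    for (ci in 0:12) {
      s <- st4(mf[ci + 1L, ])
      d <- st4(dmf[ci + 1L, ])
      for (j in 1:4) {
        suf <- c("mean", "sd", "skew", "kurt")[j]
        set(sprintf("mfcc%d_%s", ci, suf), s[j])
        set(sprintf("dmfcc%d_%s", ci, suf), d[j])
      }
    }
  }

  ## f0 contour statistics -----------------------------------------------------
  tv <- contour$time[contour$voiced]
  if (length(f0v) >= 5L) {
    set("f0_mean", mean(f0v)); set("f0_sd", sd(f0v))
    set("f0_cv", sd(f0v) / mean(f0v)); set("f0_median", median(f0v))
    set("f0_iqr", iqr_(f0v)); set("f0_min", min(f0v)); set("f0_max", max(f0v))
    set("f0_range_st", 12 * log2(max(f0v) / min(f0v)))
    set("f0_slope", ls_slope(f0v, tv[seq_along(f0v)])["slope"])
    set("voiced_frac", contour$voiced_frac)
    set("df0_mean_abs", mean(abs(diff(f0v))))
    set("df0_sd", sd(diff(f0v)))
  }

  ## vocal tremor modulation (3-15 Hz) -----------------------------------------
  frate <- 100  # frame rate of the 10 ms hop contour
  envf <- frame_signal(x, round(0.040 * fs), round(0.010 * fs))
  env <- if (ncol(envf)) sqrt(colMeans(envf^2)) else numeric(0)
  mod_feats <- function(series, tag) {
    s <- series[is.finite(series)]
    if (length(s) < 64L) return(invisible(NULL))
    s <- (s - mean(s)) / (mean(abs(s)) + 1e-12)
    wm <- welch_psd(s, frate, window_s = 1.28)
    pow <- band_power(wm, 3, 15)
    tot <- band_power(wm, 0.5, frate / 2)
    sel <- wm$freq >= 3 & wm$freq < 15
    set(paste0(tag, "_pow"), pow)
    set(paste0(tag, "_relpow"), if (tot > 0) pow / tot else NA_real_)
    set(paste0(tag, "_freq"), wm$freq[sel][which.max(wm$psd[sel])])
    set(paste0(tag, "_entropy"), norm_entropy(wm$psd[sel]))
    invisible(NULL)
  }
  f0full <- contour$f0
  f0full[!contour$voiced] <- median(f0v)
  mod_feats(f0full, "ftrem")
  mod_feats(env, "atrem")

  ## spectral shape -------------------------------------------------------------
  frame <- round(0.025 * fs); hop <- round(0.010 * fs)
  fr <- frame_signal(x, frame, hop)
  if (ncol(fr) >= 5L) {
    w <- hann_window(frame)
    nfft <- 2L^ceiling(log2(frame))
    fax <- (seq_len(nfft %/% 2 + 1L) - 1L) * fs / nfft
    mag <- apply(fr, 2L, function(col)
      Mod(fft(c(col * w, numeric(nfft - frame))))[seq_len(nfft %/% 2 + 1L)])
    psum <- colSums(mag) + 1e-12
    cent <- colSums(mag * fax) / psum
    sprd <- sqrt(colSums(mag * sweep(matrix(fax, nrow(mag), ncol(mag)), 2L,
                                     cent, "-")^2) / psum)
    nrm <- sweep(mag, 2L, psum, "/")
    flux <- c(0, sqrt(colSums((nrm[, -1L, drop = FALSE] -
                                 nrm[, -ncol(nrm), drop = FALSE])^2)))
    roll <- apply(mag, 2L, function(cl) {
      cs <- cumsum(cl^2); fax[which(cs >= 0.85 * cs[length(cs)])[1L]]
    })
    st4 <- function(v) c(mean(v), sd(v), skewness(v), kurtosis(v))
    for (feat in c("centroid", "spread", "flux", "rolloff")) {
      v <- switch(feat, centroid = cent, spread = sprd, flux = flux,
                  rolloff = roll)
      s <- st4(v)
      for (j in 1:4) set(paste(feat, c("mean", "sd", "skew", "kurt")[j],
                               sep = "_"), s[j])
    }
  }

  ## wavelet block ----------------------------------------------------------------
  wv_block <- function(series, tag) {
    s <- series[is.finite(series)]
    if (length(s) < 2L^7) return(invisible(NULL))
    s <- s - mean(s)
    a <- s
    energies <- numeric(6)
    for (lev in 1:6) {
      dw <- haar_dwt(a, 1L)
      d <- dw$details[[1L]]; a <- dw$approx
      for (kind in c("d", "a")) {
        cfs <- if (kind == "d") d else a
        base <- paste(tag, paste0(kind, lev), sep = "_")
        if (length(cfs) < 3L) next
        tk <- tkeo(cfs)
        set(paste0(base, "_loge"), log(sum(cfs^2) + 1e-12))
        set(paste0(base, "_ent"), norm_entropy(cfs^2))
        set(paste0(base, "_tkeo_mean"), mean(tk))
        set(paste0(base, "_tkeo_sd"), sd(tk))
        set(paste0(base, "_meanabs"), mean(abs(cfs)))
        set(paste0(base, "_sd"), sd(cfs))
      }
      energies[lev] <- sum(d^2)
    }
    tot <- sum(energies) + sum(a^2)
    if (tot > 0) {
      set(paste0(tag, "_erat_d13"), sum(energies[1:3]) / tot)
      set(paste0(tag, "_erat_d46"), sum(energies[4:6]) / tot)
      set(paste0(tag, "_lvl_entropy"), norm_entropy(energies))
      set(paste0(tag, "_app_ratio"), sum(a^2) / tot)
    }
    invisible(NULL)
  }
  wv_block(f0full, "wvf0")
  wv_block(env, "wvamp")

  out
}
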