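# Shared signal-processing primitives (FFT-based; no external DSP deps).

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))

# Welch power spectral density. Returns freq (Hz) and density such that
# sum(psd * df) equals the mean squared value of the (windowed) signal, so
# band powers partition total power (Parseval).
welch_psd <- function(x, rate_hz, window_s = 4, overlap = 0.5) {
  n <- length(x)
  nw <- min(n, max(16L, floor(window_s * rate_hz)))
  step <- max(1L, floor(nw * (1 - overlap)))
  starts <- seq(1L, n - nw + 1L, by = step)
  w <- hann_window(nw)
  scale <- sum(w^2)
  nfft <- nw
  acc <- numeric(nfft %/% 2 + 1L)
  for (s in starts) {
    seg <- x[s:(s + nw - 1L)] * w
    sp <- Mod(fft(seg))^2
    acc <- acc + sp[seq_len(nfft %/% 2 + 1L)]
  }
  acc <- acc / (length(starts) * scale * rate_hz)
  # one-sided: double everything except DC (and Nyquist if nfft even)
  one <- acc * 2
  one[1L] <- acc[1L]
  if (nfft %% 2L == 0L) one[length(one)] <- acc[length(acc)]
  f <- (seq_len(nfft %/% 2 + 1L) - 1L) * rate_hz / nfft
  list(freq = f, psd = one, df = rate_hz / nfft)
}

band_power <- function(w, lo, hi) {
  sel <- w$freq >= lo & w$freq < hi
  sum(w$psd[sel]) * w$df
}

# Brick-wall FFT high-pass: removes components below cutoff_hz (and DC).
highpass <- function(x, rate_hz, cutoff_hz = 0.25) {
  n <- length(x)
  sp <- fft(x)
  f <- (seq_len(n) - 1L) / n * rate_hz
  f <- pmin(f, rate_hz - f)              # two-sided frequency axis
  sp[f < cutoff_hz] <- 0
  Re(fft(sp, inverse = TRUE)) / n
}

# Frame a signal into a matrix (frames in columns).
frame_signal <- function(x, frame, hop) {
  n <- length(x)
  if (n < frame) return(matrix(x, ncol = 0, nrow = frame))
  starts <- seq(1L, n - frame + 1L, by = hop)
  vapply(starts, function(s) x[s:(s + frame - 1L)], numeric(frame))
}

# Normalized autocorrelation of one frame via FFT, lags 0..(n-1). The
# unbiased variant divides out the (n-lag)/n rectangular-window taper (used
# for harmonicity estimates, where the bias matters at the pitch lag).
acf_fft <- function(x, unbiased = FALSE) {
  n <- length(x)
  x <- x - mean(x)
  nfft <- 2L^ceiling(log2(2L * n))
  sp <- Mod(fft(c(x, numeric(nfft - n))))^2
  r <- Re(fft(sp, inverse = TRUE))[seq_len(n)] / nfft
  if (r[1L] <= 0) return(rep(0, n))
  r <- r / r[1L]
  if (unbiased) r <- pmin(r * n / (n - seq_len(n) + 1L), 1)
  r
}

# Brick-wall FFT band-pass.
bandpass <- function(x, rate_hz, lo_hz, hi_hz) {
  n <- length(x)
  sp <- fft(x)
  f <- (seq_len(n) - 1L) / n * rate_hz
  f <- pmin(f, rate_hz - f)
  sp[f < lo_hz | f > hi_hz] <- 0
  Re(fft(sp, inverse = TRUE)) / n
}

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

mel_filterbank <- function(n_filters, nfft, rate_hz, f_lo = 0, f_hi = rate_hz / 2) {
  mels <- seq(hz_to_mel(f_lo), hz_to_mel(f_hi), length.out = n_filters + 2L)
  hz <- mel_to_hz(mels)
  bins <- floor((nfft + 1) * hz / rate_hz) + 1L
  nb <- nfft %/% 2 + 1L
  fb <- matrix(0, n_filters, nb)
  for (i in seq_len(n_filters)) {
    l <- bins[i]; c <- bins[i + 1L]; r <- bins[i + 2L]
    if (c > l) fb[i, l:c] <- (seq(l, c) - l) / (c - l)
    if (r > c) fb[i, c:r] <- (r - seq(c, r)) / (r - c)
  }
  fb
}

dct_ii <- function(n_out, n_in) {
  k <- seq_len(n_out) - 1L
  m <- seq_len(n_in) - 0.5
  outer(k, m, function(k, m) cos(pi * k * m / n_in)) * sqrt(2 / n_in)
}

# MFCC matrix: rows = coefficients (c0..c{n_coef-1}), cols = frames.
mfcc <- function(x, rate_hz, n_coef = 13L, n_filters = 26L,
                 frame_s = 0.025, hop_s = 0.010) {
  frame <- max(32L, round(frame_s * rate_hz))
  hop <- max(1L, round(hop_s * rate_hz))
  fr <- frame_signal(x, frame, hop)
  if (ncol(fr) < 3L) return(matrix(NA_real_, n_coef, 0))
  w <- hann_window(frame)
  nfft <- 2L^ceiling(log2(frame))
  fb <- mel_filterbank(n_filters, nfft, rate_hz)
  dct <- dct_ii(n_coef, n_filters)
  pw <- apply(fr, 2L, function(col) {
    sp <- Mod(fft(c(col * w, numeric(nfft - frame))))^2
    sp[seq_len(nfft %/% 2 + 1L)]
  })
  fe <- fb %*% pw
  fe[fe < 1e-12] <- 1e-12
  dct %*% log(fe)
}

# Multilevel Haar DWT. Returns list of detail vectors d1..dL and final
# approximation; odd-length inputs are truncated by one sample per level.
haar_dwt <- function(x, levels) {
  details <- vector("list", levels)
  a <- as.numeric(x)
  for (l in seq_len(levels)) {
    n <- length(a)
    if (n < 2L) { details[l:levels] <- list(numeric(0)); break }
    if (n %% 2L == 1L) a <- a[-n]
    e <- a[seq(1L, length(a), by = 2L)]
    o <- a[seq(2L, length(a), by = 2L)]
    details[[l]] <- (e - o) / sqrt(2)
    a <- (e + o) / sqrt(2)
  }
  list(details = details, approx = a)
}

# Teager-Kaiser energy operator.
tkeo <- function(x) {
  n <- length(x)
  if (n < 3L) return(numeric(0))
  x[2:(n - 1)]^2 - x[1:(n - 2)] * x[3:n]
}

# Linear prediction coefficients (autocorrelation method, Levinson-Durbin).
lpc_coefs <- function(x, order = 12L) {
  n <- length(x)
  x <- x - mean(x)
  r <- acf_fft(x)[seq_len(order + 1L)] * sum((x - mean(x))^2) / n
  a <- numeric(order); e <- r[1L]
  if (e <= 0) return(rep(0, order))
  for (i in seq_len(order)) {
    acc <- r[i + 1L] - if (i > 1L) sum(a[1:(i - 1L)] * r[i:2L]) else 0
    k <- acc / e
    a_new <- a
    a_new[i] <- k
    if (i > 1L) a_new[1:(i - 1L)] <- a[1:(i - 1L)] - k * a[(i - 1L):1L]
    a <- a_new
    e <- e * (1 - k^2)
    if (e <= 0) break
  }
  a
}

# LPC residual (excitation proxy).
lpc_residual <- function(x, order = 12L) {
  a <- lpc_coefs(x, order)
  n <- length(x)
  pred <- numeric(n)
  for (i in seq_len(order))
    pred[(i + 1L):n] <- pred[(i + 1L):n] + a[i] * x[1:(n - i)]
  x - pred
}

# Detrended fluctuation analysis scaling exponent over log-spaced box sizes.
dfa_exponent <- function(x, min_box = 50L, max_box = 1000L, n_scales = 12L) {
  x <- x[is.finite(x)]
  n <- length(x)
  max_box <- min(max_box, n %/% 4L)
  if (max_box <= min_box + 1L || n < 4L * min_box) return(NA_real_)
  y <- cumsum(x - mean(x))
  boxes <- unique(round(exp(seq(log(min_box), log(max_box), length.out = n_scales))))
  fluct <- vapply(boxes, function(b) {
    nb <- n %/% b
    idx <- seq_len(nb * b)
    m <- matrix(y[idx], nrow = b)
    tt <- seq_len(b)
    tc <- tt - mean(tt)
    ss <- sum(tc^2)
    beta <- colSums(m * tc) / ss
    alpha <- colMeans(m)
    res <- m - outer(tc, beta) - rep(alpha, each = b)
    sqrt(mean(res^2))
  }, numeric(1))
  ok <- fluct > 0
  if (sum(ok) < 3L) return(NA_real_)
  unname(ls_slope(log(fluct[ok]), log(boxes[ok]))["slope"])
}
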