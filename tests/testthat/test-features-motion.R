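# IMU battery: planted-signal recovery, closed-form oracles, invariances.

mk_stream <- function(ax, ay, az, rate = 100) {
  n <- length(ax)
  structure(list(t = (0:(n - 1)) / rate, ax = ax, ay = ay, az = az),
            class = "accel_stream")
}

test_that("planted 5 Hz sinusoid dominates the tremor band", {
  t <- (0:1999) / 100
  s <- mk_stream(sin(2 * pi * 5 * t), numeric(2000), rep(9.81, 2000))
  got <- motion_features(s, "rest")
  expect_length(got, 147L)
  expect_lt(abs(got[["rest.x_f_domfreq"]] - 5), 0.2)
  expect_gte(got[["rest.x_f_rel_tremor"]], 0.9)
})

test_that("white-noise closed forms: RMS and flat-spectrum entropy", {
  set.seed(5)
  n <- 3000
  s <- mk_stream(rnorm(n, 0, 0.1), rnorm(n, 0, 0.1), 9.81 + rnorm(n, 0, 0.1))
  got <- motion_features(s, "balance")
  expect_gt(got[["balance.x_t_rms"]], 0.09)
  expect_lt(got[["balance.x_t_rms"]], 0.11)
  expect_gte(got[["balance.x_f_entropy"]], 0.95)
})

test_that("Welch band powers match a brute-force oracle to 1e-6", {
  set.seed(9)
  n <- 1000                      # toy signal per the oracle contract
  x <- rnorm(n) + sin(2 * pi * 5 * (0:(n - 1)) / 100)
  s <- mk_stream(x, rnorm(n, 0, 0.2), 9.81 + rnorm(n, 0, 0.2))
  got <- motion_features(s, "rest")

  # independent re-implementation: detrend (brick-wall 0.25 Hz high-pass),
  # 4 s Hann windows, 50% overlap, one-sided density
  rate <- 100
  hp <- function(v) {
    sp <- fft(v)
    f <- (seq_along(v) - 1) / length(v) * rate
    f <- pmin(f, rate - f)
    sp[f < 0.25] <- 0
    Re(fft(sp, inverse = TRUE)) / length(v)
  }
  xd <- hp(x)
  nw <- 400; step <- 200
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(nw - 1)) / (nw - 1))
  starts <- seq(1, n - nw + 1, by = step)
  acc <- 0
  for (st in starts) {
    seg <- xd[st:(st + nw - 1)] * w
    acc <- acc + (Mod(fft(seg))^2)[1:(nw / 2 + 1)]
  }
  psd <- acc / (length(starts) * sum(w^2) * rate)
  psd <- psd * c(1, rep(2, nw / 2 - 1), 1)
  f <- (0:(nw / 2)) * rate / nw
  df <- rate / nw
  oracle_bands <- c(sum(psd[f >= 0.5 & f < 3]), sum(psd[f >= 3 & f < 8]),
                    sum(psd[f >= 8 & f < 12]), sum(psd[f >= 12 & f < 20])) * df
  keys <- paste0("rest.x_f_bp_", c("low", "tremor", "mid", "high"))
  expect_rel_equal(as.numeric(got[keys]), oracle_bands, 1e-6)

  # Parseval: the four bands plus out-of-band equal total power within 1%
  tot <- got[["rest.x_f_total"]]
  out_of_band <- tot - sum(got[keys])
  expect_gte(out_of_band, 0)
  expect_lt(abs(sum(got[keys]) + out_of_band - tot) / tot, 0.01)
  # and total tracks the signal variance
  expect_lt(abs(tot - var(xd)) / var(xd), 0.05)
})

test_that("degenerate identical axes stay finite with unit correlations", {
  set.seed(3)
  v <- rnorm(1200, 0, 0.5)
  s <- mk_stream(v, v, v + 9.81)
  got <- motion_features(s, "balance")
  expect_equal(unname(got[["balance.c_rxy"]]), 1, tolerance = 1e-9)
  expect_equal(unname(got[["balance.c_rxz"]]), 1, tolerance = 1e-9)
  expect_true(all(is.finite(got[c("balance.c_eig12", "balance.c_eig23",
                                  "balance.c_eigfrac1")])))
})

test_that("magnitude features are rotation invariant", {
  b <- synth_accel("rest_tremor", default_group_params("PD"), 20, 100, seed = 2)
  R <- qr.Q(qr(matrix(c(1, 2, 3, 0, 1, 4, 5, 6, 0), 3)))
  m1 <- motion_features(b, "rest")
  xyz <- cbind(b$ax, b$ay, b$az) %*% t(R)
  b2 <- mk_stream(xyz[, 1], xyz[, 2], xyz[, 3])
  m2 <- motion_features(b2, "rest")
  magk <- grep("\\.mag_", names(m1), value = TRUE)
  expect_rel_equal(as.numeric(m2[magk]), as.numeric(m1[magk]), 1e-6,
                   floor = 1e-6)
})

test_that("tremor-band power is monotone in planted amplitude", {
  amps <- c(0.05, 0.2, 0.5, 1, 2)
  bp <- vapply(amps, function(a) {
    s <- synth_accel("rest_tremor", gp(tremor_amp_rest_ms2 = a), 15, 100,
                     seed = 7)
    motion_features(s, "rest")[["rest.mag_f_bp_tremor"]]
  }, numeric(1))
  expect_identical(order(bp), seq_along(amps))   # Spearman rho = 1
})

test_that("non-uniform sampling is resampled; short input goes missing", {
  set.seed(11)
  t <- sort(runif(1500, 0, 15))
  s <- structure(list(t = t, ax = sin(2 * pi * 5 * t) + rnorm(1500, 0, 0.1),
                      ay = rnorm(1500, 0, 0.1), az = 9.81 + rnorm(1500, 0, 0.1)),
                 class = "accel_stream")
  got <- motion_features(s, "rest")
  expect_true(mean(is.finite(got)) > 0.9)
  expect_lt(abs(got[["rest.x_f_domfreq"]] - 5), 0.3)

  tiny <- mk_stream(rnorm(300), rnorm(300), rnorm(300))  # 3 s at 100 Hz
  gtiny <- motion_features(tiny, "gait")
  expect_true(all(is.na(gtiny)))
  expect_identical(names(gtiny), pdmotor:::motion_feature_names("gait"))
})
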