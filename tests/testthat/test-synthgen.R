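# Synthetic-cohort generator: determinism, stated distributions, and
# generator-extractor recovery at the signal level.

test_that("generate_cohort is deterministic and honours the cohort config", {
  cfg <- cohort_config(n_per_group = 10, sessions_per_subject = 3, seed = 1,
                       durations = tiny_dur)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)

  expect_equal(nrow(a$subjects), 30L)
  expect_true(all(table(a$subjects$group) == 10L))
  expect_true(all(a$subjects$n_sessions >= 1L))
  # law of large numbers on the truncated-Poisson session sampler
  expect_lt(abs(mean(a$subjects$n_sessions) - 3), 1)
  expect_equal(length(a$sessions), sum(a$subjects$n_sessions))

  male <- generate_cohort(cohort_config(n_per_group = 3, sex_ratio = 1,
                                        seed = 2, durations = tiny_dur))
  expect_true(all(male$subjects$sex == "male"))
})

test_that("invalid configurations fail naming the field", {
  expect_error(cohort_config(n_per_group = 1), "n_per_group")
  expect_error(cohort_config(sessions_per_subject = 0), "sessions_per_subject")
  expect_error(cohort_config(sex_ratio = 1.2), "sex_ratio")
  expect_error(group_params(tremor_freq_hz = 9), "tremor_freq_hz")
  expect_error(group_params(iti_mean_s = 0), "iti_mean_s")
  expect_error(group_params(jitter_frac = -0.1), "jitter_frac")
})

test_that("sessions have 7 task payloads with strictly increasing start times", {
  ses <- synth_session(default_group_params("control"), seed = 4,
                       durations = tiny_dur)
  expect_s3_class(ses, "pdm_session")
  expect_length(ses$task_times, 7L)
  expect_true(all(diff(ses$task_times) > 0))
  gaps <- diff(ses$task_times)
  expect_true(all(gaps >= 10))
  for (f in c("voice", "balance", "gait", "rest_tremor", "postural_tremor",
              "taps", "reactions"))
    expect_false(is.null(ses[[f]]))
})

test_that("synth_voice: noiseless limit is strictly periodic; dials recover", {
  # f0 commensurate with the sampling rate so the noiseless limit is exact
  pure <- gp(jitter_frac = 0, shimmer_frac = 0, hnr_db = Inf, f0_hz = 125,
             f0_sd_hz = 0)
  v <- synth_voice(pure, 3, seed = 1)
  ct <- track_f0(v)
  per <- diff(ct$cycle_marks)
  expect_gt(length(per), 100L)
  expect_lt(sd(per) / mean(per), 1e-6)

  # jitter recovery via the features_voice extractor (parameter-recovery
  # oracle); n syntheses averaged
  cvs <- vapply(1:50, function(s) {
    vj <- synth_voice(gp(jitter_frac = 0.02), 2, seed = s)
    co <- track_f0(vj)
    p <- diff(co$cycle_marks)
    sd(p) / mean(p)
  }, numeric(1))
  expect_gt(mean(cvs), 0.015)
  expect_lt(mean(cvs), 0.025)

  hs <- vapply(1:6, function(s) {
    vh <- synth_voice(gp(hnr_db = 20), 3, seed = s)
    unname(voice_features(vh)["voice.hnr_mean"])
  }, numeric(1))
  expect_gt(mean(hs), 17)
  expect_lt(mean(hs), 23)

  expect_error(synth_voice(gp(f0_hz = 200), rate_hz = 1500), "Nyquist")
  expect_error(synth_voice(gp(), duration_s = 0.5), ">= 1")
})

test_that("synth_accel: planted oscillations and step periodicity", {
  p0 <- gp(tremor_amp_rest_ms2 = 0, tremor_amp_post_ms2 = 0)
  bandpow <- function(a) {
    # independent periodogram oracle on the detrended x axis
    x <- a$ax - mean(a$ax)
    n <- length(x)
    pw <- Mod(fft(x))^2 / n
    f <- (seq_len(n) - 1L) / n * 100
    sum(pw[f >= 3 & f < 8])
  }
  rest0 <- synth_accel("rest_tremor", p0, 20, 100, seed = 1)
  base <- synth_accel("balance", p0, 20, 100, seed = 1)
  expect_lt(bandpow(rest0), 1.5 * bandpow(base))

  big <- gp(tremor_amp_rest_ms2 = 1.5, tremor_freq_hz = 5)
  rest <- synth_accel("rest_tremor", big, 20, 100, seed = 2)
  mag <- sqrt(rest$ax^2 + rest$ay^2 + rest$az^2)
  mag <- mag - mean(mag)
  pw <- Mod(fft(mag))^2
  f <- (seq_along(pw) - 1) / length(pw) * 100
  sel <- f > 0.5 & f < 50
  expect_lt(abs(f[sel][which.max(pw[sel])] - 5), 0.2)

  # autocorrelation oracle: step interval of a 1.8 Hz gait
  pg <- gp(cadence_hz = 1.8)
  g <- synth_accel("gait", pg, 30, 100, seed = 3)
  magg <- sqrt(g$ax^2 + g$ay^2 + g$az^2)
  env <- abs(diff(magg))
  env <- stats::filter(env, rep(1 / 15, 15), sides = 2)
  env <- env[is.finite(env)]
  ac <- stats::acf(env, lag.max = 200, plot = FALSE)$acf[, 1, 1]
  lag_s <- (25:200)[which.max(ac[26:201])] / 100
  expect_lt(abs(lag_s - 1 / 1.8), 0.05)

  expect_error(synth_accel("jogging", p0, 20, 100), "unknown")
  expect_error(synth_accel("gait", p0, 5, 100), ">= 10")
})

test_that("synth_taps: degenerate noise, hastening drift, exact centers", {
  p <- gp(iti_cv = 0, iti_drift = 0)
  taps <- synth_taps(p, 10, seed = 1)
  expect_true(all(abs(diff(taps$t) - p$iti_mean_s) < 1e-12))
  expect_true(all(taps$target_id[seq(1, nrow(taps), 2)] ==
                    taps$target_id[1]))

  ph <- gp(iti_drift = -0.002, iti_cv = 0.05)
  taps_h <- synth_taps(ph, 40, seed = 2)
  expect_gte(nrow(taps_h), 100L)
  iti <- diff(taps_h$t)
  fit <- summary(lm(iti ~ seq_along(iti)))$coefficients
  expect_lt(fit[2, 1], 0)
  expect_lt(fit[2, 4], 0.05)

  p0 <- gp(tap_scatter_px = 0)
  t0 <- synth_taps(p0, 5, seed = 3)
  ctr <- pdmotor:::tap_button_centers()
  expect_true(all(t0$x %in% ctr$x & t0$y %in% ctr$y))

  expect_error(synth_taps(p, 0), "> 0")
})

test_that("synth_reactions: ex-Gaussian latencies", {
  pc <- gp(rt_sigma_s = 0, rt_tau_s = 0, rt_mu_s = 0.3)
  rx <- synth_reactions(pc, 20, seed = 1)
  expect_true(all(abs(rx$press_t - rx$stim_on_t - 0.3) < 1e-12))
  expect_true(all(rx$press_t >= rx$stim_on_t))
  expect_true(all(rx$release_t >= rx$stim_off_t))

  pe <- gp(rt_mu_s = 0.3, rt_sigma_s = 0.05, rt_tau_s = 0.1)
  rx2 <- synth_reactions(pe, 1000, seed = 2)
  lat <- rx2$press_t - rx2$stim_on_t
  expect_lt(abs(mean(lat) - 0.4), 0.02)   # exGaussian mean = mu + tau

  expect_error(synth_reactions(pc, 0), ">= 1")
})

test_that("all synth operations are seed-deterministic", {
  p <- default_group_params("PD")
  expect_identical(synth_voice(p, 2, seed = 9), synth_voice(p, 2, seed = 9))
  expect_identical(synth_accel("gait", p, 12, 100, 9),
                   synth_accel("gait", p, 12, 100, 9))
  expect_identical(synth_taps(p, 10, 9), synth_taps(p, 10, 9))
  expect_identical(synth_reactions(p, 20, 9), synth_reactions(p, 20, 9))
})

test_that("null configuration produces no group separation in feature means", {
  # Exchangeable null (identical GroupParams, no subject signatures, one
  # session each). Group-mean differences must stay below 0.2 pooled SD for
  # at least 95% of features; 300 sessions per group keep the sampling
  # noise of a mean difference near 0.08 SD so the test probes the
  # generator, not small-sample noise.
  cfg <- null_cohort_config(n_per_group = c(control = 300, iRBD = 2, PD = 300),
                            sessions_per_subject = 1, seed = 77,
                            durations = tiny_dur)
  coh <- generate_cohort(cfg)
  fm <- extract_cohort(coh)
  A <- as.matrix(fm[fm$group == "control", feature_names()])
  B <- as.matrix(fm[fm$group == "PD", feature_names()])
  d <- abs(colMeans(A, na.rm = TRUE) - colMeans(B, na.rm = TRUE))
  sp <- sqrt((apply(A, 2, sd, na.rm = TRUE)^2 +
                apply(B, 2, sd, na.rm = TRUE)^2) / 2)
  ratio <- ifelse(sp > 0, d / sp, 0)
  ratio[!is.finite(ratio)] <- 0
  expect_gte(mean(ratio < 0.2), 0.95)
})
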