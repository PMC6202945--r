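# Voice battery: pitch tracking, cycle-level oracles, invariances.

pure_tone <- function(f0, dur = 2, fs = 16000, amp = 0.5) {
  structure(list(samples = amp * sin(2 * pi * f0 * (0:(dur * fs - 1)) / fs),
                 rate_hz = fs), class = "voice_recording")
}

test_that("track_f0: known tone, chirp, and unvoiced input", {
  ct <- track_f0(pure_tone(120))
  expect_gt(median(ct$f0[ct$voiced]), 119)
  expect_lt(median(ct$f0[ct$voiced]), 121)

  fs <- 16000; dur <- 3
  t <- (0:(dur * fs - 1)) / fs
  inst_f <- 100 + (200 - 100) * t / dur
  phase <- 2 * pi * cumsum(inst_f) / fs
  chirp <- structure(list(samples = 0.5 * sin(phase), rate_hz = fs),
                     class = "voice_recording")
  cc <- track_f0(chirp)
  f0v <- cc$f0[cc$voiced]
  expect_gt(suppressWarnings(cor(seq_along(f0v), f0v, method = "spearman")), 0.99)
  expect_gt(tail(f0v, 1) - f0v[1], 80)

  noise <- structure(list(samples = with_seed_rnorm(7, 32000, 0, 0.3),
                          rate_hz = fs), class = "voice_recording")
  cn <- track_f0(noise)
  expect_lt(cn$voiced_frac, 0.5)
  vf <- voice_features(noise, cn)
  expect_length(vf, 330L)
  expect_true(all(is.na(vf)))
})

test_that("jitter/shimmer/HNR match brute-force oracles to 1e-6", {
  # contour with exactly known cycle periods and amplitudes
  set.seed(42)
  n <- 80L
  per <- 1 / 120 * (1 + 0.02 * rnorm(n))
  marks <- cumsum(c(0.5, per))
  amps <- abs(1 + 0.05 * rnorm(n + 1L))
  hnr <- rnorm(40, 18, 3)
  contour <- structure(list(
    time = seq(0, 2, by = 0.01), f0 = rep(120, 201),
    voiced = rep(TRUE, 201), hnr_frame = hnr, cycle_marks = marks,
    cycle_amps = amps, voiced_frac = 1, rate_hz = 16000),
    class = "f0_contour")
  v <- pure_tone(120, 2.2)
  got <- voice_features(v, contour)

  mp <- mean(per)
  expect_rel_equal(got[["voice.jit_local"]], mean(abs(diff(per))) / mp, 1e-6)
  expect_rel_equal(got[["voice.jit_local_abs"]], mean(abs(diff(per))), 1e-6)
  expect_rel_equal(got[["voice.jit_cv"]], sd(per) / mp, 1e-6)
  rap <- mean(abs(per[2:(n - 1)] -
                    (per[1:(n - 2)] + per[2:(n - 1)] + per[3:n]) / 3)) / mp
  expect_rel_equal(got[["voice.jit_rap"]], rap, 1e-6)
  ppq5 <- mean(abs(vapply(3:(n - 2), function(i)
    per[i] - mean(per[(i - 2):(i + 2)]), numeric(1)))) / mp
  expect_rel_equal(got[["voice.jit_ppq5"]], ppq5, 1e-6)
  expect_rel_equal(got[["voice.jit_ddp"]], mean(abs(diff(diff(per)))) / mp, 1e-6)

  ma <- mean(amps)
  expect_rel_equal(got[["voice.shim_local"]], mean(abs(diff(amps))) / ma, 1e-6)
  expect_rel_equal(got[["voice.shim_db"]],
                   mean(abs(20 * log10(amps[-1] / amps[-length(amps)]))), 1e-6)
  apq3 <- mean(abs(vapply(2:n, function(i)
    amps[i] - mean(amps[(i - 1):(i + 1)]), numeric(1)))) / ma
  expect_rel_equal(got[["voice.shim_apq3"]], apq3, 1e-6)

  expect_rel_equal(got[["voice.hnr_mean"]],
                   -10 * log10(mean(10^(-hnr / 10))), 1e-6)
  expect_rel_equal(got[["voice.nhr_mean"]], mean(10^(-hnr / 10)), 1e-6)
})

test_that("noiseless periodic synthesis has vanishing jitter and shimmer", {
  v <- synth_voice(gp(jitter_frac = 0, shimmer_frac = 0, hnr_db = Inf,
                      f0_hz = 125, f0_sd_hz = 0), 2, seed = 1)
  got <- voice_features(v)
  expect_lt(got[["voice.jit_local"]], 1e-4)
  expect_lt(got[["voice.shim_local"]], 1e-4)
})

test_that("jitter dial recovers through the full extractor", {
  jl <- vapply(1:12, function(s) {
    v <- synth_voice(gp(jitter_frac = 0.01), 2, seed = s)
    unname(voice_features(v)["voice.jit_local"])
  }, numeric(1))
  expect_gt(mean(jl), 0.007)
  expect_lt(mean(jl), 0.013)
})

test_that("voice feature vector contract and invariances", {
  v <- fixture("ctrl_voice", function()
    synth_voice(default_group_params("control"), 4, seed = 3))
  got <- voice_features(v)
  expect_length(got, 330L)
  expect_identical(names(got), pdmotor:::voice_feature_names())
  expect_true(all(is.finite(got)))

  # scale invariance of the dimensionless measures
  v2 <- v; v2$samples <- 2 * v$samples
  got2 <- voice_features(v2)
  keys <- paste0("voice.", c("jit_local", "shim_local", "hnr_mean", "rpde",
                             "dfa", "ppe"))
  expect_rel_equal(got2[keys], got[keys], 1e-6)

  # time reversal leaves the perturbation distributions unchanged
  v3 <- v; v3$samples <- rev(v$samples)
  got3 <- voice_features(v3)
  keys3 <- paste0("voice.", c("jit_cv", "shim_cv", "period_mean"))
  expect_rel_equal(got3[keys3], got[keys3], 1e-3)

  expect_gte(got[["voice.ppe"]], 0); expect_lte(got[["voice.ppe"]], 1)
  expect_gte(got[["voice.rpde"]], 0); expect_lte(got[["voice.rpde"]], 1)
})

test_that("DFA engine calibrates on white and Brownian noise", {
  ab <- vapply(1:20, function(s) {
    w <- with_seed_rnorm(s, 6000)
    c(pdmotor:::dfa_exponent(w, 50, 1000),
      pdmotor:::dfa_exponent(cumsum(w), 50, 1000))
  }, numeric(2))
  expect_lt(abs(mean(ab[1, ]) - 0.5), 0.1)
  expect_lt(abs(mean(ab[2, ]) - 1.5), 0.1)
})
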