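# Session IO: directory round-trips, WAV fidelity, timestamp assembly and
# the segmentation/QC gate.

test_that("write/read cohort round-trips sessions", {
  cfg <- cohort_config(n_per_group = 2, sessions_per_subject = 1, seed = 5,
                       durations = tiny_dur)
  coh <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_equal(back$subjects, coh$subjects)
  expect_length(back$sessions, length(coh$sessions))
  ids <- vapply(coh$sessions, `[[`, "", "session_id")
  for (ses in back$sessions) {
    orig <- coh$sessions[[match(ses$session_id, ids)]]
    # timestamps to ms
    expect_lt(max(abs(ses$task_times - orig$task_times)), 1e-3)
    # audio: written PCM-16 samples read back bit-exactly
    q <- round(pmin(pmax(orig$voice$samples, -1), 32767 / 32768) * 32768) / 32768
    expect_identical(ses$voice$samples, q)
    expect_equal(ses$voice$rate_hz, orig$voice$rate_hz)
    expect_lt(max(abs(ses$balance$ax - orig$balance$ax)), 1e-5)
    expect_equal(nrow(ses$taps), nrow(orig$taps))
    expect_lt(max(abs(ses$reactions$press_t - orig$reactions$press_t)), 1e-5)
  }
  # a second write of what was read is byte-identical (WAV fidelity)
  dir2 <- withr::local_tempdir()
  write_cohort(back, dir2)
  w1 <- sort(list.files(dir, "voice.wav", recursive = TRUE, full.names = TRUE))
  w2 <- sort(list.files(dir2, "voice.wav", recursive = TRUE, full.names = TRUE))
  for (k in seq_along(w1))
    expect_identical(readBin(w1[k], "raw", file.size(w1[k])),
                     readBin(w2[k], "raw", file.size(w2[k])))
})

make_records <- function(ses, t0 = 1000, gap = 60, subject = "S1") {
  tasks <- pdmotor:::TASKS
  payloads <- list(ses$voice, ses$balance, ses$gait, ses$taps, ses$reactions,
                   ses$rest_tremor, ses$postural_tremor)
  lapply(seq_along(tasks), function(i)
    list(subject_id = subject, task = tasks[i],
         start_time = t0 + (i - 1) * gap, payload = payloads[[i]]))
}

test_that("assemble_sessions: window rule, exclusions, interleaved sets", {
  ses <- fixture("tiny_session", function()
    synth_session(default_group_params("control"), seed = 8,
                  durations = tiny_dur))
  # 7 tasks spanning ~6 minutes -> one session
  recs <- make_records(ses, gap = 55)
  out <- assemble_sessions(recs)
  expect_length(out$sessions, 1L)
  expect_equal(out$n_excluded, 0L)
  expect_true(all(diff(out$sessions[[1]]$task_times) > 0))

  # 6 of 7 tasks -> no session, exclusions logged
  out6 <- suppressMessages(assemble_sessions(recs[-3]))
  expect_length(out6$sessions, 0L)
  expect_equal(out6$n_excluded, 6L)

  # spanning more than the window -> dropped
  wide <- make_records(ses, gap = 6.5 * 60)
  outw <- suppressMessages(assemble_sessions(wide))
  expect_length(outw$sessions, 0L)

  # two interleaved complete sets -> two sessions by nearest-in-time greedy
  r1 <- make_records(ses, t0 = 0, gap = 120)
  r2 <- make_records(ses, t0 = 50, gap = 120)
  out2 <- assemble_sessions(c(r1, r2))
  expect_length(out2$sessions, 2L)
  starts <- sort(vapply(out2$sessions, `[[`, 0, "session_time"))
  expect_equal(starts, c(0, 50))
  # greedy assignment matches the exhaustive optimum on this instance:
  # within each session, consecutive tasks are the nearest available
  for (s in out2$sessions) expect_true(all(diff(s$task_times) == 120))

  # unparseable timestamp -> skipped with warning, not fatal
  bad <- recs
  bad[[2]]$start_time <- "not-a-time"
  expect_warning(outb <- suppressMessages(assemble_sessions(bad)),
                 "timestamp")
  expect_length(outb$sessions, 0L)
})

test_that("segment_task trims phonation silence and gates IMU quality", {
  fs <- 16000
  v <- synth_voice(default_group_params("control"), 3, seed = 2)
  padded <- structure(list(samples = c(numeric(fs), v$samples, numeric(fs)),
                           rate_hz = fs), class = "voice_recording")
  sg <- segment_task(padded, "voice")
  expect_true(sg$qc_pass)
  kept_s <- length(sg$payload$samples) / fs
  expect_lt(abs(kept_s - 3), 0.2)
  expect_gt(sg$interval[1], 0.8)

  # segmentation never extends the signal, and is idempotent
  expect_lte(length(sg$payload$samples), length(padded$samples))
  sg2 <- segment_task(sg$payload, "voice")
  expect_identical(sg2$payload$samples, sg$payload$samples)

  flat <- structure(list(t = seq(0, 20, by = 0.01),
                         ax = rep(1, 2001), ay = rep(2, 2001),
                         az = rep(9.81, 2001)), class = "accel_stream")
  sf <- segment_task(flat, "balance")
  expect_false(sf$qc_pass)
  expect_match(sf$qc_reason, "flat")

  short <- synth_accel("balance", default_group_params("control"), 10, 100, 1)
  short$t <- short$t[1:400]; short$ax <- short$ax[1:400]
  short$ay <- short$ay[1:400]; short$az <- short$az[1:400]
  ss <- segment_task(short, "balance")   # 4 s recording: under minimum
  expect_false(ss$qc_pass)

  imu <- synth_accel("gait", default_group_params("control"), 12, 100, 1)
  si <- segment_task(imu, "gait")
  expect_true(si$qc_pass)
  expect_lt(diff(range(si$payload$t)), diff(range(imu$t)))
  si2 <- segment_task(si$payload, "gait")
  expect_identical(si2$payload, si$payload)

  empty <- structure(list(samples = numeric(0), rate_hz = fs),
                     class = "voice_recording")
  se <- segment_task(empty, "voice")
  expect_false(se$qc_pass)
  expect_match(se$qc_reason, "empty")

  taps <- synth_taps(default_group_params("control"), 10, 1)
  st <- segment_task(taps, "tapping")
  expect_true(st$qc_pass)
  expect_true(all(st$payload$t >= min(taps$t) + 1))
})

test_that("JSON-lines ingestion feeds assembly", {
  ses <- fixture("tiny_session", function()
    synth_session(default_group_params("control"), seed = 8,
                  durations = tiny_dur))
  recs <- make_records(ses, gap = 30)
  path <- withr::local_tempfile(fileext = ".jsonl")
  lines <- vapply(recs, function(r) {
    payload <- if (inherits(r$payload, "voice_recording"))
      list(samples = round(r$payload$samples, 5), rate_hz = r$payload$rate_hz)
    else if (inherits(r$payload, "accel_stream"))
      r$payload[c("t", "ax", "ay", "az")]
    else r$payload
    jsonlite::toJSON(list(subject_id = r$subject_id, task = r$task,
                          start_time = r$start_time, payload = payload),
                     auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  back <- read_jsonl_recordings(path)
  out <- assemble_sessions(back)
  expect_length(out$sessions, 1L)
  expect_s3_class(out$sessions[[1]]$voice, "voice_recording")
  fv <- extract_features(out$sessions[[1]])
  expect_length(fv, 998L)
})
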