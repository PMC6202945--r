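# Minimal mono PCM-16 WAV reader/writer (base R binary IO; no audio
# package is assumed by the deployment environment).
write_wav <- function(samples, rate_hz, path) {
  x <- as.numeric(samples)
  x[!is.finite(x)] <- 0
  peak <- max(abs(x), 1e-9)
  if (peak > 1) x <- x / peak           # normalize only if clipping
  pcm <- as.integer(round(pmin(pmax(x, -1), 32767 / 32768) * 32768))
  con <- file(path, "wb")
  on.exit(close(con))
  data_len <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_len), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")    # PCM
  writeBin(1L, con, size = 2, endian = "little")    # mono
  writeBin(as.integer(rate_hz), con, size = 4, endian = "little")
  writeBin(as.integer(rate_hz * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_len, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAV file: ", path, call. = FALSE)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  readChar(con, 4)                       # "WAVE"
  rate <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4L) break
    len <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      invisible(readBin(con, "raw", len - 8))
      if (fmt[1] != 1L || fmt[2] != 1L)
        stop("only mono PCM WAV supported", call. = FALSE)
    } else if (id == "data") {
      samples <- readBin(con, "integer", len %/% 2L, size = 2,
                         endian = "little", signed = TRUE)
      break
    } else invisible(readBin(con, "raw", len))
  }
  structure(list(samples = samples / 32768, rate_hz = rate),
            class = "voice_recording")
}

#' Automated segmentation / quality control of one task payload
#'
#' The gate is a documented stand-in for the study's unpublished
#' segmentation step: voice recordings are trimmed of leading/trailing
#' silence by a frame-RMS threshold (10\% of the median active-frame RMS,
#' keeping the longest voiced run); IMU streams lose their first and last
#' 2 s (pocket/hand placement transients) and fail QC if under 5 s remain
#' or any axis is constant; tap/reaction logs drop events in the first
#' second. Segmentation is idempotent: an already-segmented payload is
#' returned unchanged.
#'
#' @param payload A `voice_recording`, `accel_stream`, or tap/reaction
#'   data.frame.
#' @param task Task label carried through to the result (for data frames,
#'   `"tapping"` or `"reaction"`; inferred from columns if missing).
#' @param imu_trim_s,imu_min_s,voice_gate_frac,event_skip_s Tunable gate
#'   parameters (defaults: 2 s, 5 s, 0.1, 1 s).
#' @return A `segmented_task`: `task`, `payload` (trimmed), `interval`
#'   (retained `[start_s, end_s)` relative to the recording), `qc_pass`,
#'   `qc_reason`.
#' @export
segment_task <- function(payload, task = NULL, imu_trim_s = 2, imu_min_s = 5,
                         voice_gate_frac = 0.1, event_skip_s = 1) {
  res <- function(task, payload, interval, pass, reason = "") {
    attr(payload, "segmented") <- TRUE
    structure(list(task = task, payload = payload, interval = interval,
                   qc_pass = pass, qc_reason = reason),
              class = "segmented_task")
  }
  if (inherits(payload, "segmented_task")) return(payload)
  already <- isTRUE(attr(payload, "segmented"))
  if (inherits(payload, "voice_recording")) {
    task <- task %||% "voice"
    x <- payload$samples; fs <- payload$rate_hz
    if (!length(x)) return(res(task, payload, c(0, 0), FALSE, "empty"))
    if (already) return(res(task, payload, c(0, length(x) / fs), TRUE))
    frame <- max(16L, round(0.025 * fs)); hop <- max(8L, round(0.010 * fs))
    fr <- frame_signal(x, frame, hop)
    if (!ncol(fr)) return(res(task, payload, c(0, 0), FALSE, "too short"))
    rms <- sqrt(colMeans(fr^2))
    active <- rms[rms > 0.1 * max(rms)]
    gate <- voice_gate_frac * median(active)
    voiced <- rms >= gate
    if (!any(voiced)) return(res(task, payload, c(0, 0), FALSE, "silent"))
    r <- rle(voiced)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    b <- runs[which.max(r$lengths[runs])]
    s0 <- (starts[b] - 1L) * hop + 1L
    s1 <- min(length(x), (ends[b] - 1L) * hop + frame)
    kept <- structure(list(samples = x[s0:s1], rate_hz = fs),
                      class = "voice_recording")
    if ((s1 - s0 + 1L) / fs < 1)
      return(res(task, kept, c(s0 - 1L, s1) / fs, FALSE, "voiced run under 1 s"))
    return(res(task, kept, c(s0 - 1L, s1) / fs, TRUE))
  }
  if (inherits(payload, "accel_stream")) {
    task <- task %||% "imu"
    t <- payload$t
    if (!length(t)) return(res(task, payload, c(0, 0), FALSE, "empty"))
    if (already) {
      keep <- rep(TRUE, length(t))
    } else {
      keep <- t >= t[1L] + imu_trim_s & t <= t[length(t)] - imu_trim_s
    }
    kept <- structure(list(t = t[keep], ax = payload$ax[keep],
                           ay = payload$ay[keep], az = payload$az[keep]),
                      class = "accel_stream")
    if (length(kept$t) < 2L || diff(range(kept$t)) < imu_min_s)
      return(res(task, kept, if (length(kept$t)) range(kept$t) - t[1L] else c(0, 0),
                 FALSE, "retained under minimum duration"))
    if (any(vapply(kept[c("ax", "ay", "az")], function(a) sd(a) == 0, logical(1))))
      return(res(task, kept, range(kept$t) - t[1L], FALSE, "flat signal"))
    return(res(task, kept, range(kept$t) - t[1L], TRUE))
  }
  if (is.data.frame(payload)) {
    if (is.null(task))
      task <- if ("target_id" %in% names(payload)) "tapping" else "reaction"
    if (!nrow(payload)) return(res(task, payload, c(0, 0), FALSE, "empty"))
    tcol <- if (task == "tapping") "t" else "stim_on_t"
    if (already) kept <- payload else {
      t0 <- min(payload[[tcol]])
      kept <- payload[payload[[tcol]] >= t0 + event_skip_s, , drop = FALSE]
    }
    if (!nrow(kept))
      return(res(task, kept, c(0, 0), FALSE, "no events after skip"))
    return(res(task, kept, range(kept[[tcol]]) - min(payload[[tcol]]), TRUE))
  }
  stop("unknown payload type for segment_task", call. = FALSE)
}

#' Assemble 7-task sessions from loose recordings by timestamp
#'
#' A session is emitted iff all 7 tasks by the same subject occur within the
#' window (default 30 minutes) in protocol order (voice, balance, gait,
#' tapping, reaction, rest tremor, postural tremor). Matching is greedy and
#' nearest-in-time: recordings are scanned in time order, each candidate
#' session starts at an unused voice recording and claims the earliest
#' unused recording of each subsequent task. Partial sets are dropped and
#' counted.
#'
#' @param recordings List of records: each a list with `subject_id`, `task`,
#'   `start_time` (epoch seconds) and `payload`.
#' @param window_min Assembly window in minutes.
#' @return List with `sessions` (list of `pdm_session`) and `n_excluded`
#'   (count of recordings not used in any complete session).
#' @export
assemble_sessions <- function(recordings, window_min = 30) {
  ok <- vapply(recordings, function(r) {
    t <- suppressWarnings(as.numeric(r$start_time))
    if (!length(t) || is.na(t)) {
      warning("skipping recording with unparseable timestamp", call. = FALSE)
      FALSE
    } else TRUE
  }, logical(1))
  recordings <- recordings[ok]
  subj <- vapply(recordings, function(r) as.character(r$subject_id %||% "unknown"),
                 character(1))
  sessions <- list(); used_total <- 0L
  for (s in unique(subj)) {
    recs <- recordings[subj == s]
    times <- vapply(recs, function(r) as.numeric(r$start_time), numeric(1))
    tasks <- vapply(recs, function(r) as.character(r$task), character(1))
    ord <- order(times)
    recs <- recs[ord]; times <- times[ord]; tasks <- tasks[ord]
    used <- logical(length(recs))
    for (i in seq_along(recs)) {
      if (used[i] || tasks[i] != TASKS[1L]) next
      picks <- i
      t_prev <- times[i]
      complete <- TRUE
      for (k in 2:7) {
        cand <- which(!used & tasks == TASKS[k] & times > t_prev &
                        times <= times[i] + window_min * 60)
        if (!length(cand)) { complete <- FALSE; break }
        picks <- c(picks, cand[1L])
        t_prev <- times[cand[1L]]
      }
      if (!complete) next
      used[picks] <- TRUE
      pl <- setNames(lapply(picks, function(j) recs[[j]]$payload), TASKS)
      ses <- structure(list(subject_id = s,
                            session_id = sprintf("%s_%010d", s,
                                                 as.integer(times[i] %% 1e10)),
                            session_time = times[i],
                            task_times = setNames(times[picks], TASKS),
                            voice = pl$voice, balance = pl$balance,
                            gait = pl$gait, rest_tremor = pl$rest_tremor,
                            postural_tremor = pl$postural_tremor,
                            taps = pl$tapping, reactions = pl$reaction),
                       class = "pdm_session")
      sessions[[length(sessions) + 1L]] <- ses
    }
    used_total <- used_total + sum(used)
  }
  n_excl <- length(recordings) - used_total
  if (n_excl > 0)
    message(sprintf("assemble_sessions: %d recording(s) not part of any complete session",
                    n_excl))
  list(sessions = sessions, n_excluded = n_excl)
}

accel_to_df <- function(a) data.frame(t = a$t, ax = a$ax, ay = a$ay, az = a$az)
df_to_accel <- function(d) structure(list(t = d$t, ax = d$ax, ay = d$ay,
                                          az = d$az), class = "accel_stream")

#' Write a cohort to the on-disk session layout
#'
#' Layout: `subjects.csv` at the root; one directory per session
#' (`<subject>/<session_id>/`) holding `voice.wav` (PCM 16-bit),
#' `balance.csv`, `gait.csv`, `rest.csv`, `postural.csv` (columns
#' `t,ax,ay,az`), `taps.csv`, `reactions.csv` and `session.json` metadata.
#' All CSVs are RFC-4180 with a header row; timestamps are written with
#' millisecond precision.
#'
#' @param cohort List with `subjects` and `sessions` (see
#'   [generate_cohort()]).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(cohort$subjects, file.path(dir, "subjects.csv"), row.names = FALSE)
  for (ses in cohort$sessions) {
    sd <- file.path(dir, ses$subject_id, ses$session_id)
    dir.create(sd, recursive = TRUE, showWarnings = FALSE)
    write_wav(ses$voice$samples, ses$voice$rate_hz, file.path(sd, "voice.wav"))
    wcsv <- function(df, name) {
      num <- vapply(df, is.numeric, logical(1))
      df[num] <- lapply(df[num], function(x) round(x, 6))
      write.csv(df, file.path(sd, name), row.names = FALSE)
    }
    wcsv(accel_to_df(ses$balance), "balance.csv")
    wcsv(accel_to_df(ses$gait), "gait.csv")
    wcsv(accel_to_df(ses$rest_tremor), "rest.csv")
    wcsv(accel_to_df(ses$postural_tremor), "postural.csv")
    wcsv(ses$taps, "taps.csv")
    wcsv(ses$reactions, "reactions.csv")
    meta <- list(subject_id = ses$subject_id, session_id = ses$session_id,
                 session_time = round(ses$session_time, 3),
                 task_times = as.list(round(ses$task_times, 3)),
                 voice_rate_hz = ses$voice$rate_hz)
    writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
               file.path(sd, "session.json"))
  }
  invisible(dir)
}

#' Read a cohort from the on-disk session layout
#'
#' Inverse of [write_cohort()].
#'
#' @param dir Cohort directory.
#' @return List with `subjects` and `sessions`.
#' @export
read_cohort <- function(dir) {
  subjects <- read.csv(file.path(dir, "subjects.csv"), stringsAsFactors = FALSE)
  metas <- sort(list.files(dir, pattern = "^session\\.json$", recursive = TRUE,
                           full.names = TRUE))
  sessions <- lapply(metas, function(mp) {
    sd <- dirname(mp)
    meta <- jsonlite::fromJSON(mp)
    rcsv <- function(name) read.csv(file.path(sd, name), stringsAsFactors = FALSE)
    structure(list(subject_id = meta$subject_id, session_id = meta$session_id,
                   session_time = meta$session_time,
                   task_times = unlist(meta$task_times)[TASKS],
                   voice = read_wav(file.path(sd, "voice.wav")),
                   balance = df_to_accel(rcsv("balance.csv")),
                   gait = df_to_accel(rcsv("gait.csv")),
                   rest_tremor = df_to_accel(rcsv("rest.csv")),
                   postural_tremor = df_to_accel(rcsv("postural.csv")),
                   taps = rcsv("taps.csv"),
                   reactions = rcsv("reactions.csv")),
              class = "pdm_session")
  })
  list(subjects = subjects, sessions = sessions)
}

#' Read typed recordings from a JSON-lines stream
#'
#' Accepts one JSON object per line with fields `subject_id`, `task`,
#' `start_time` and a task-appropriate `payload` (`samples`+`rate_hz` for
#' voice; `t`,`ax`,`ay`,`az` for IMU tasks; event columns for tapping and
#' reaction). Intended as the ingestion path for real-device exports;
#' output feeds [assemble_sessions()].
#'
#' @param path JSON-lines file.
#' @return List of recording records.
#' @export
read_jsonl_recordings <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(l) {
    r <- jsonlite::fromJSON(l)
    payload <- r$payload
    if (identical(r$task, "voice")) {
      payload <- structure(list(samples = as.numeric(payload$samples),
                                rate_hz = payload$rate_hz),
                           class = "voice_recording")
    } else if (r$task %in% c("balance", "gait", "rest_tremor", "postural_tremor")) {
      payload <- structure(lapply(payload[c("t", "ax", "ay", "az")], as.numeric),
                           class = "accel_stream")
    } else {
      payload <- as.data.frame(payload, stringsAsFactors = FALSE)
    }
    list(subject_id = r$subject_id, task = r$task, start_time = r$start_time,
         payload = payload)
  })
}
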