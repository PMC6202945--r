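#' Extract the full 998-feature battery from one session
#'
#' Runs the segmentation/QC gate on every task payload and then the four
#' task-family extractors. A task that fails QC yields NA (missing) for its
#' whole feature block; the vector length and names are invariant.
#'
#' @param session A `pdm_session`.
#' @return Named numeric vector of length 998, ordered as [feature_names()].
#' @export
extract_features <- function(session) {
  stopifnot(inherits(session, "pdm_session"))
  sv <- segment_task(session$voice, "voice")
  vf <- if (sv$qc_pass) voice_features(sv$payload) else
    setNames(rep(NA_real_, 330L), voice_feature_names())
  st <- segment_task(session$taps, "tapping")
  tf <- if (st$qc_pass) tapping_features(st$payload) else
    setNames(rep(NA_real_, 60L), tapping_feature_names())
  sr <- segment_task(session$reactions, "reaction")
  rf <- if (sr$qc_pass) reaction_features(sr$payload) else
    setNames(rep(NA_real_, 20L), reaction_feature_names())
  imu <- mapply(function(field, prefix) {
    sg <- segment_task(session[[field]], field)
    if (sg$qc_pass) motion_features(sg$payload, prefix) else
      setNames(rep(NA_real_, 147L), motion_feature_names(prefix))
  }, c("balance", "gait", "rest_tremor", "postural_tremor"),
  c("balance", "gait", "rest", "postural"), SIMPLIFY = FALSE)
  out <- c(vf, tf, rf, imu[[1L]], imu[[2L]], imu[[3L]], imu[[4L]])
  stopifnot(identical(names(out), feature_names()))
  out
}

#' Extract features for a whole cohort into a feature matrix
#'
#' @param cohort List with `subjects` and `sessions` (from
#'   [generate_cohort()] or [read_cohort()]).
#' @param progress Print one line per session.
#' @return A `feature_matrix`: data.frame with `subject_id`, `session_id`,
#'   `group`, `sex` and the 998 feature columns.
#' @export
extract_cohort <- function(cohort, progress = FALSE) {
  subs <- cohort$subjects
  rows <- lapply(seq_along(cohort$sessions), function(i) {
    ses <- cohort$sessions[[i]]
    if (progress) message(sprintf("extracting %s (%d/%d)", ses$session_id, i,
                                  length(cohort$sessions)))
    fv <- extract_features(ses)
    si <- match(ses$subject_id, subs$subject_id)
    cbind(data.frame(subject_id = ses$subject_id, session_id = ses$session_id,
                     group = subs$group[si], sex = subs$sex[si],
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(fv), check.names = FALSE))
  })
  out <- do.call(rbind, rows)
  as_feature_matrix(out)
}

#' Validate and tag a feature matrix
#'
#' A feature matrix holds one row per recording session: metadata columns
#' `subject_id`, `session_id`, `group`, `sex` plus exactly the 998 canonical
#' feature columns.
#'
#' @param df A data.frame.
#' @return `df` with class `feature_matrix`.
#' @export
as_feature_matrix <- function(df) {
  meta <- c("subject_id", "session_id", "group", "sex")
  missing_meta <- setdiff(meta, names(df))
  if (length(missing_meta))
    stop("feature matrix lacks metadata columns: ",
         paste(missing_meta, collapse = ", "), call. = FALSE)
  feats <- setdiff(names(df), meta)
  if (!identical(sort(feats), sort(feature_names())))
    stop("feature matrix must contain exactly the 998 canonical feature columns",
         call. = FALSE)
  if (!all(df$group %in% c("control", "iRBD", "PD")))
    stop("groups must be control, iRBD or PD", call. = FALSE)
  df <- df[, c(meta, feature_names())]
  class(df) <- c("feature_matrix", "data.frame")
  df
}

feature_cols <- function(fm) as.matrix(fm[, feature_names(), drop = FALSE])
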