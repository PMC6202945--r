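rmssd <- function(x) if (length(x) < 2L) NA_real_ else sqrt(mean(diff(x)^2))

# 7 summary stats used for the half-split fatigue block.
half_stats <- function(iti) {
  if (length(iti) < 3L)
    return(setNames(rep(NA_real_, 7L),
                    c("mean", "sd", "cv", "median", "iqr", "rmssd", "slope")))
  c(mean = mean(iti), sd = sd(iti), cv = sd(iti) / mean(iti),
    median = median(iti), iqr = iqr_(iti), rmssd = rmssd(iti),
    slope = unname(ls_slope(iti)["slope"]))
}

#' Extract the 60-feature finger-tapping battery
#'
#' Temporal features (40) quantify inter-tap interval (ITI) level,
#' variability, drift (hastening when the drift slope is negative),
#' freezing/hastening proxies, alternation failures, and a half-split
#' fatigue block comparing the first and second half of the run. Spatial
#' features (20) quantify accuracy around the two button centers, inter-tap
#' travel, per-button scatter and centroid drift.
#'
#' @param taps data.frame of tap events (`t`, `x`, `y`, `target_id`), ideally
#'   after [segment_task()].
#' @param centers Button geometry (data.frame `target_id`, `x`, `y`,
#'   `radius`); defaults to the generator's layout.
#' @return Named numeric vector of length 60; all NA when fewer than 10 taps.
#' @export
tapping_features <- function(taps, centers = tap_button_centers()) {
  nm <- tapping_feature_names()
  out <- setNames(rep(NA_real_, length(nm)), nm)
  if (is.null(taps) || nrow(taps) < 10L) return(out)
  taps <- taps[order(taps$t), , drop = FALSE]
  set <- function(name, value) {
    v <- suppressWarnings(as.numeric(value))
    out[paste0("tap.", name)] <<- if (length(v) == 1L && is.finite(v)) v else NA_real_
  }
  iti <- diff(taps$t)
  mp <- mean(iti); md <- median(iti)
  set("iti_mean", mp); set("iti_sd", sd(iti)); set("iti_cv", sd(iti) / mp)
  set("iti_median", md); set("iti_iqr", iqr_(iti))
  set("iti_min", min(iti)); set("iti_max", max(iti))
  set("iti_skew", skewness(iti)); set("iti_kurt", kurtosis(iti))
  set("iti_rmssd", rmssd(iti))
  dr <- ls_slope(iti)
  set("drift_slope", dr["slope"]); set("drift_intercept", dr["intercept"])
  set("drift_tstat", dr["tstat"])
  set("n_freeze", sum(iti > 2 * md))
  set("n_hasten", sum(iti < 0.5 * md))
  dur <- diff(range(taps$t))
  set("tap_rate", nrow(taps) / max(dur, 1e-9))
  set("n_alt_fail", sum(taps$target_id[-1] == taps$target_id[-nrow(taps)]))
  half <- length(iti) %/% 2L
  h1 <- half_stats(iti[seq_len(half)])
  h2 <- half_stats(iti[(half + 1L):length(iti)])
  for (s in names(h1)) {
    set(paste0("h1_", s), h1[[s]])
    set(paste0("h2_", s), h2[[s]])
    set(paste0("d_", s), h2[[s]] - h1[[s]])
  }
  set("n_taps", nrow(taps)); set("duration_s", dur)

  ## spatial
  for (side in c("left", "right")) {
    ctr <- centers[centers$target_id == side, , drop = FALSE]
    sel <- taps$target_id == side
    if (nrow(ctr) != 1L || sum(sel) < 3L) next
    d <- sqrt((taps$x[sel] - ctr$x)^2 + (taps$y[sel] - ctr$y)^2)
    set(paste0("dist_mean_", side), mean(d))
    set(paste0("dist_sd_", side), sd(d))
    set(paste0("dist_median_", side), median(d))
    set(paste0("dist_max_", side), max(d))
    set(paste0("xsd_", side), sd(taps$x[sel]))
    set(paste0("ysd_", side), sd(taps$y[sel]))
    set(paste0("hit_frac_", side), mean(d <= ctr$radius))
    k <- sum(sel)
    c1 <- c(mean(taps$x[sel][seq_len(k %/% 2L)]), mean(taps$y[sel][seq_len(k %/% 2L)]))
    c2 <- c(mean(taps$x[sel][(k %/% 2L + 1L):k]), mean(taps$y[sel][(k %/% 2L + 1L):k]))
    set(paste0("cdrift_", side), sqrt(sum((c2 - c1)^2)))
  }
  trav <- sqrt(diff(taps$x)^2 + diff(taps$y)^2)
  set("travel_mean", mean(trav)); set("travel_sd", sd(trav))
  set("travel_median", median(trav)); set("travel_max", max(trav))
  out
}

#' Extract the 20-feature simple reaction-time battery
#'
#' Descriptive statistics of press latencies (stimulus onset to press) and
#' release latencies (stimulus offset to release), plus lapse fraction
#' (latency > 0.5 s), anticipation fraction (< 0.1 s), press-vs-release mean
#' difference and the valid-trial count. The 0.5 s / 0.1 s cut-offs are
#' conventional simple-RT bounds.
#'
#' @param events data.frame of reaction events (`stim_on_t`, `press_t`,
#'   `stim_off_t`, `release_t`).
#' @param lapse_s,anticipation_s Latency cut-offs in seconds.
#' @return Named numeric vector of length 20; all NA when fewer than 5
#'   valid trials.
#' @export
reaction_features <- function(events, lapse_s = 0.5, anticipation_s = 0.1) {
  nm <- reaction_feature_names()
  out <- setNames(rep(NA_real_, length(nm)), nm)
  if (is.null(events) || nrow(events) < 5L) return(out)
  press <- events$press_t - events$stim_on_t
  rel <- events$release_t - events$stim_off_t
  valid <- is.finite(press) & is.finite(rel) & press > 0 & rel > 0
  if (sum(valid) < 5L) return(out)
  press <- press[valid]; rel <- rel[valid]
  set <- function(name, value) {
    v <- suppressWarnings(as.numeric(value))
    out[paste0("rt.", name)] <<- if (length(v) == 1L && is.finite(v)) v else NA_real_
  }
  blk <- function(lat, tag) {
    set(paste0(tag, "_mean"), mean(lat))
    set(paste0(tag, "_sd"), sd(lat))
    set(paste0(tag, "_median"), median(lat))
    set(paste0(tag, "_iqr"), iqr_(lat))
    set(paste0(tag, "_min"), min(lat))
    set(paste0(tag, "_max"), max(lat))
    set(paste0(tag, "_skew"), skewness(lat))
    set(paste0(tag, "_slope"), ls_slope(lat)["slope"])
  }
  blk(press, "press")
  blk(rel, "rel")
  set("lapse_frac", mean(press > lapse_s))
  set("anticip_frac", mean(press < anticipation_s))
  set("press_rel_diff", mean(press) - mean(rel))
  set("n_valid", sum(valid))
  out
}
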