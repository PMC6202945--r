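# Canonical catalog of the 998 feature names. The task totals (330 voice +
# 60 tapping + 20 reaction + 4 x 147 IMU = 998) are a fixed contract; every
# extractor emits exactly its block, as values or NA (missing).

voice_feature_names <- function() {
  jit <- c("jit_local", "jit_local_abs", "jit_rap", "jit_ppq5", "jit_ddp",
           "jit_cv", "period_mean", "period_sd")
  shim <- c("shim_local", "shim_db", "shim_apq3", "shim_apq5", "shim_apq11",
            "shim_dda", "shim_cv", "amp_mean", "amp_sd", "amp_range")
  hnr <- c("hnr_mean", "hnr_sd", "nhr_mean", "nhr_sd")
  nl <- c("ppe", "rpde", "dfa")
  vfer <- c(paste0("vfer_e_b", 1:5), "vfer_low_high_ratio",
            "vfer_spec_entropy", "vfer_amp_entropy", "vfer_energy_db")
  gq <- c("gq_mean", "gq_sd", "gq_min", "gq_max")
  st4 <- c("mean", "sd", "skew", "kurt")
  mf <- as.vector(t(outer(paste0("mfcc", 0:12), st4, paste, sep = "_")))
  dmf <- as.vector(t(outer(paste0("dmfcc", 0:12), st4, paste, sep = "_")))
  f0s <- c("f0_mean", "f0_sd", "f0_cv", "f0_median", "f0_iqr", "f0_min",
           "f0_max", "f0_range_st", "f0_slope", "voiced_frac",
           "df0_mean_abs", "df0_sd")
  trem <- as.vector(t(outer(c("ftrem", "atrem"),
                            c("pow", "relpow", "freq", "entropy"),
                            paste, sep = "_")))
  spec <- as.vector(t(outer(c("centroid", "spread", "flux", "rolloff"),
                            st4, paste, sep = "_")))
  wstats <- c("loge", "ent", "tkeo_mean", "tkeo_sd", "meanabs", "sd")
  wv <- character(0)
  for (series in c("wvf0", "wvamp")) {
    for (lev in 1:6)
      for (kind in c("d", "a"))
        wv <- c(wv, paste(series, paste0(kind, lev), wstats, sep = "_"))
    wv <- c(wv, paste(series, c("erat_d13", "erat_d46", "lvl_entropy",
                                "app_ratio"), sep = "_"))
  }
  out <- c(jit, shim, hnr, nl, vfer, gq, mf, dmf, f0s, trem, spec, wv)
  stopifnot(length(out) == 330L)
  paste0("voice.", out)
}

motion_feature_names <- function(task) {
  sigs <- c("x", "y", "z", "mag")
  cat1 <- c("t_mean", "t_sd", "t_rms", "t_iqr", "t_skew", "t_kurt", "t_zcr",
            "t_p2p", "t_mad", "t_ac1s")
  cat2 <- c("f_total", "f_bp_low", "f_bp_tremor", "f_bp_mid", "f_bp_high",
            "f_rel_tremor", "f_domfreq", "f_domprom", "f_centroid",
            "f_spread", "f_entropy", "f_edge95")
  cat3 <- c("n_sampen", "n_higuchi", "n_dfa", "n_recrate", "n_acdecay")
  cat4 <- c("j_mean", "j_sd", "j_rms", "j_ratio", "j_smooth", "j_specent")
  per_sig <- as.vector(vapply(sigs, function(s)
    paste(s, c(cat1, cat2, cat3, cat4), sep = "_"), character(33L)))
  cat5 <- c("c_rxy", "c_rxz", "c_ryz", "c_mixy", "c_mixz", "c_miyz",
            "c_eig12", "c_eig23", "c_eig13", "c_eigfrac1", "c_eigfrac2",
            "c_eigfrac3", "c_enfrac_x", "c_enfrac_y", "c_enfrac_z")
  out <- c(per_sig, cat5)
  stopifnot(length(out) == 147L)
  paste0(task, ".", out)
}

tapping_feature_names <- function() {
  core <- c("iti_mean", "iti_sd", "iti_cv", "iti_median", "iti_iqr",
            "iti_min", "iti_max", "iti_skew", "iti_kurt", "iti_rmssd",
            "drift_slope", "drift_intercept", "drift_tstat")
  extra <- c("n_freeze", "n_hasten", "tap_rate", "n_alt_fail")
  hstats <- c("mean", "sd", "cv", "median", "iqr", "rmssd", "slope")
  halves <- c(paste0("h1_", hstats), paste0("h2_", hstats), paste0("d_", hstats))
  glob <- c("n_taps", "duration_s")
  spatial <- c(as.vector(t(outer(c("dist_mean", "dist_sd", "dist_median",
                                   "dist_max"), c("left", "right"),
                                 paste, sep = "_"))),
               paste0("travel_", c("mean", "sd", "median", "max")),
               "xsd_left", "xsd_right", "ysd_left", "ysd_right",
               "hit_frac_left", "hit_frac_right", "cdrift_left", "cdrift_right")
  out <- c(core, extra, halves, glob, spatial)
  stopifnot(length(out) == 60L)
  paste0("tap.", out)
}

reaction_feature_names <- function() {
  st <- c("mean", "sd", "median", "iqr", "min", "max", "skew", "slope")
  out <- c(paste0("press_", st), paste0("rel_", st),
           "lapse_frac", "anticip_frac", "press_rel_diff", "n_valid")
  stopifnot(length(out) == 20L)
  paste0("rt.", out)
}

#' Canonical names of the 998-feature battery
#'
#' Returns the full ordered feature catalog: 330 voice, 60 tapping, 20
#' reaction-time and 147 features for each of the four IMU tasks (balance,
#' gait, rest tremor, postural tremor). Names are prefixed by task
#' (`voice.`, `tap.`, `rt.`, `balance.`, `gait.`, `rest.`, `postural.`),
#' which is what the task-salience report keys on.
#'
#' @return Character vector of length 998.
#' @export
feature_names <- function() {
  out <- c(voice_feature_names(),
           tapping_feature_names(),
           reaction_feature_names(),
           motion_feature_names("balance"),
           motion_feature_names("gait"),
           motion_feature_names("rest"),
           motion_feature_names("postural"))
  stopifnot(length(out) == 998L)
  out
}

# task prefix -> protocol task label
task_of_feature <- function(names) {
  pre <- sub("\\..*$", "", names)
  map <- c(voice = "voice", tap = "tapping", rt = "reaction",
           balance = "balance", gait = "gait", rest = "rest_tremor",
           postural = "postural_tremor")
  unknown <- setdiff(unique(pre), names(map))
  if (length(unknown))
    stop(sprintf("unknown feature prefix: %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  unname(map[pre])
}
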