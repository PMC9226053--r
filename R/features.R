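# Assembly of the 23-variable feature record per analysis window: FHR
# summary, time-domain HRV over the most recent 540 intervals, STV/LTV on
# the 4-Hz series, wavelet LF/HF/HFnu on the 8-Hz series, FSI, morphology
# of the last deceleration before the window, and deltas from baseline.

window_indices <- function(session) {
  kinds <- vapply(session$windows, `[[`, character(1), "kind")
  list(baseline = which(kinds == "baseline"),
       stable = which(kinds == "stable_period"))
}

compute_window_features <- function(series, window, fsi_scale, n_intervals = 540) {
  s <- extract_window(series, window)
  fs <- fhr_summary(s)
  u4 <- resample_rr(s, 4)
  # a 5-min window yields 4 complete minutes plus a partial one whose
  # dropping is routine here, not worth a warning per window
  sl <- suppressWarnings(stv_ltv(u4))
  u8 <- resample_rr(s, 8)
  sp <- wavelet_band_powers(u8)
  f <- fsi(s, scale = fsi_scale)
  c(FHRmean = fs$fhr_mean, FHRmax = fs$fhr_max, FHRmin = fs$fhr_min,
    SDNN = as.numeric(sdnn(s, n_intervals)),
    RMSSD = as.numeric(rmssd(s, n_intervals)),
    LF = sp$lf, HF = sp$hf, HFnu = sp$hfnu,
    FSI = f$averaged, STV = sl$stv, LTV = sl$ltv)
}

decel_features <- function(session, window, lookback_min = 20,
                           auc_mode = "last_only") {
  start <- max(min(session$series$beat_times),
               window$start - lookback_min * 60000)
  if (window$start - start < 60000) {
    return(c(Duration = NA, Amplitude = NA, Slope = NA, AUCdec = NA))
  }
  pre <- extract_window(session$series,
                        list(start = start, end = window$start))
  u4 <- resample_rr(pre, 4)
  fhr <- uniform_series(60000 / u4$values, rate = 4, t0 = u4$t0)
  dec <- detect_decelerations(fhr, baseline = session$params$baseline_fhr)
  summ <- auc_dec(dec, mode = auc_mode)
  if (is.null(summ$last_decel)) {
    return(c(Duration = NA, Amplitude = NA, Slope = NA, AUCdec = NA))
  }
  c(Duration = summ$last_decel$duration_s,
    Amplitude = summ$last_decel$amplitude_bpm,
    Slope = summ$last_decel$slope_bpm_s,
    AUCdec = summ$auc_dec)
}

#' Extract the 23-variable feature table from a session
#'
#' Computes one feature record per stable period of a session: FHR summary
#' statistics, RMSSD/SDNN (most recent 540 intervals), STV/LTV, wavelet
#' LF/HF/HFnu, FSI, morphology of the last deceleration in the preceding
#' interval, and deltas of the HRV indices from the baseline window. Rows
#' carry the modelled pH at the window and the acidosis label `ph < 7.10`.
#'
#' @param session A `uco_session` from [generate_uco_session], or any list
#'   with `series`, `windows`, `ph_at_windows` and `params$baseline_fhr`.
#' @param delta_mode `"percent"` (default) or `"absolute"` deltas.
#' @param fsi_scale FSI scale constant.
#' @param auc_mode Deceleration-area scope, `"last_only"` (default) or
#'   `"sum"` over the preceding interval.
#' @return Data.frame: 23 feature columns ([fhrv_feature_names()]), `ph`,
#'   `acidosis`, `window_start_ms`, `phase`.
#' @export
extract_features <- function(session, delta_mode = c("percent", "absolute"),
                             fsi_scale = fsi_default_scale(),
                             auc_mode = c("last_only", "sum")) {
  delta_mode <- match.arg(delta_mode)
  auc_mode <- match.arg(auc_mode)
  wi <- window_indices(session)
  if (!length(wi$baseline)) stop("session has no baseline window")
  if (!length(wi$stable)) stop("session has no stable-period windows")
  base <- compute_window_features(session$series,
                                  session$windows[[wi$baseline[1L]]],
                                  fsi_scale)
  delta_vars <- c("SDNN", "RMSSD", "LF", "HF", "HFnu", "FSI", "STV", "LTV")
  rows <- lapply(wi$stable, function(i) {
    w <- session$windows[[i]]
    f <- compute_window_features(session$series, w, fsi_scale)
    deltas <- vapply(delta_vars, function(v) {
      as.numeric(delta_from_baseline(f[[v]], base[[v]], mode = delta_mode))
    }, numeric(1))
    names(deltas) <- paste0("Delta_", delta_vars)
    dec <- decel_features(session, w, auc_mode = auc_mode)
    ph <- session$ph_at_windows[i]
    out <- c(f, deltas, dec)
    d <- as.data.frame(as.list(out[fhrv_feature_names()]))
    d$ph <- ph
    d$acidosis <- ph < 7.10
    d$window_start_ms <- w$start
    d$phase <- w$phase
    d
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
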