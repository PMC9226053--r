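# Time-domain HRV indices. RMSSD/SDNN are computed on the raw (irregular)
# RR sequence; STV/LTV on a 4-Hz resampled series, in 3.75-s epochs,
# 16 epochs per minute.

rr_intervals_for <- function(series, n_intervals = NULL) {
  stopifnot(inherits(series, "rr_series"))
  x <- series$rr
  flagged <- FALSE
  if (!is.null(n_intervals)) {
    if (length(x) > n_intervals) {
      x <- x[(length(x) - n_intervals + 1L):length(x)]  # most recent
    } else if (length(x) < n_intervals) {
      flagged <- TRUE
    }
  }
  attr(x, "short_window") <- flagged
  x
}

#' Root mean square of successive RR differences (RMSSD)
#'
#' RMSSD indexes parasympathetic (vagal) activity. It is nominally computed
#' over 540 RR intervals (about 3 min at a basal FHR of 180 bpm); when the
#' window holds more, the most recent 540 are used, and when fewer, the
#' result is computed on what exists and flagged via the `n_intervals`
#' attribute.
#'
#' @param series An [rr_series].
#' @param n_intervals Target number of RR intervals (default 540); `NULL`
#'   uses all.
#' @return RMSSD in ms, with attributes `n_intervals` (number used) and
#'   `short_window`.
#' @examples
#' s <- rr_series(cumsum(c(0, rep(c(330, 340), 10))))
#' rmssd(s, n_intervals = NULL)  # 10: every successive difference is 10 ms
#' @export
rmssd <- function(series, n_intervals = 540) {
  x <- rr_intervals_for(series, n_intervals)
  if (length(x) < 2L) stop("RMSSD needs at least 2 RR intervals")
  out <- sqrt(mean(diff(x)^2))
  attr(out, "n_intervals") <- length(x)
  attr(out, "short_window") <- attr(x, "short_window")
  out
}

#' Standard deviation of RR intervals (SDNN)
#'
#' SDNN indexes global autonomic variability. The population (divide by n)
#' convention is used; see `convention` attribute on the result.
#'
#' @inheritParams rmssd
#' @return SDNN in ms.
#' @export
sdnn <- function(series, n_intervals = 540) {
  x <- rr_intervals_for(series, n_intervals)
  if (length(x) < 2L) stop("SDNN needs at least 2 RR intervals")
  out <- sqrt(mean((x - mean(x))^2))
  attr(out, "n_intervals") <- length(x)
  attr(out, "short_window") <- attr(x, "short_window")
  attr(out, "convention") <- "population"
  out
}

#' Fetal short- and long-term variability (STV, LTV)
#'
#' On a 4-Hz resampled RR series, each minute is divided into 16 contiguous
#' 3.75-s epochs (15 samples each) aligned to the window start. Per minute,
#' with epoch means m1..m16: STV is the mean absolute difference between
#' successive epoch means (15 pairs) and LTV is `max(m) - min(m)`. Windows
#' longer than one minute return the mean of the per-minute values; an
#' incomplete final minute is dropped with a warning.
#'
#' @param series A `uniform_series` at 4 Hz (see [resample_rr]), at least one
#'   full minute long.
#' @return List with `stv` and `ltv` in ms and `n_minutes` used.
#' @export
stv_ltv <- function(series) {
  stopifnot(inherits(series, "uniform_series"))
  if (series$rate != 4) stop("STV/LTV are defined on a 4-Hz series")
  samples_per_epoch <- 15L          # 3.75 s at 4 Hz
  epochs_per_minute <- 16L
  spm <- samples_per_epoch * epochs_per_minute
  n_min <- length(series$values) %/% spm
  if (n_min < 1L) stop("STV/LTV need at least one full minute (240 samples)")
  if (length(series$values) %% spm != 0L) {
    warning("incomplete final minute dropped from STV/LTV")
  }
  stv_min <- ltv_min <- numeric(n_min)
  for (m in seq_len(n_min)) {
    seg <- series$values[((m - 1L) * spm + 1L):(m * spm)]
    em <- colMeans(matrix(seg, nrow = samples_per_epoch))
    stv_min[m] <- mean(abs(diff(em)))
    ltv_min[m] <- max(em) - min(em)
  }
  list(stv = mean(stv_min), ltv = mean(ltv_min), n_minutes = n_min)
}

#' Change of an index from its baseline value
#'
#' Stable-period indices are compared to the pre-occlusion baseline either
#' as a percentage difference (default, `100 * (value - baseline) /
#' baseline`) or as an absolute difference. The mode used is recorded on the
#' result.
#'
#' @param value Index value in the analysis window.
#' @param baseline Index value in the baseline window.
#' @param mode `"percent"` or `"absolute"`.
#' @return The delta, with attribute `mode`.
#' @examples
#' delta_from_baseline(75, 50)                     # 50 percent
#' delta_from_baseline(0.12, 0.11, "absolute")     # 0.01
#' @export
delta_from_baseline <- function(value, baseline, mode = c("percent", "absolute")) {
  mode <- match.arg(mode)
  if (!is.finite(baseline)) stop("baseline must be finite")
  if (mode == "percent") {
    if (baseline == 0) stop("percent delta undefined for zero baseline")
    out <- 100 * (value - baseline) / baseline
  } else {
    out <- value - baseline
  }
  attr(out, "mode") <- mode
  out
}
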