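# Morphological analysis of FHR decelerations: transient drops of the FHR
# below baseline, here occlusion-locked. Duration, amplitude (baseline to
# nadir), slope (amplitude/duration) and the triangular area
# 0.5 * duration * amplitude are the feature-table quantities.

#' Detect FHR decelerations on a uniform FHR trace
#'
#' A deceleration is a maximal run of samples with FHR below
#' `baseline - drop_bpm` lasting at least `min_duration_s`. The nadir is the
#' run minimum; amplitude is baseline minus nadir. When no baseline is
#' supplied, a rolling-median baseline (10-min span) of the trace is used.
#'
#' @param fhr A `uniform_series` of FHR values in bpm (e.g.
#'   `60000 / resample_rr(series, 4)$values`).
#' @param baseline Baseline FHR in bpm; `NULL` for the rolling-median
#'   estimate.
#' @param drop_bpm Drop threshold below baseline (default 15 bpm).
#' @param min_duration_s Minimum run duration (default 10 s).
#' @return A data.frame with one row per deceleration: `onset_ms`,
#'   `nadir_time_ms`, `end_ms`, `duration_s`, `amplitude_bpm`, `slope_bpm_s`,
#'   `area` (bpm.s). Zero rows when none detected.
#' @export
detect_decelerations <- function(fhr, baseline = NULL, drop_bpm = 15,
                                 min_duration_s = 10) {
  stopifnot(inherits(fhr, "uniform_series"))
  x <- fhr$values
  if (is.null(baseline)) {
    span <- min(length(x), round(600 * fhr$rate))
    baseline <- stats::runmed(x, k = span - (1 - span %% 2), endrule = "median")
  }
  if (any(baseline <= 0)) stop("baseline must be positive")
  below <- x < baseline - drop_bpm
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_duration_s * fhr$rate
  out <- data.frame(onset_ms = numeric(0), nadir_time_ms = numeric(0),
                    end_ms = numeric(0), duration_s = numeric(0),
                    amplitude_bpm = numeric(0), slope_bpm_s = numeric(0),
                    area = numeric(0))
  bl <- if (length(baseline) == 1L) rep(baseline, length(x)) else baseline
  for (k in which(keep)) {
    i1 <- starts[k]; i2 <- ends[k]
    seg <- x[i1:i2]
    nadir_i <- i1 + which.min(seg) - 1L
    dur <- (i2 - i1 + 1L) / fhr$rate
    amp <- bl[nadir_i] - x[nadir_i]
    t_ms <- function(i) fhr$t0 + (i - 1L) * 1000 / fhr$rate
    out <- rbind(out, data.frame(
      onset_ms = t_ms(i1), nadir_time_ms = t_ms(nadir_i), end_ms = t_ms(i2),
      duration_s = dur, amplitude_bpm = amp, slope_bpm_s = amp / dur,
      area = deceleration_area(dur, amp)
    ))
  }
  out
}

#' Triangular deceleration area
#'
#' `0.5 * duration * amplitude` in bpm.s, the standard triangular
#' approximation of the area between baseline and the FHR trace.
#'
#' @param duration_s Deceleration duration in seconds.
#' @param amplitude_bpm Baseline-to-nadir amplitude in bpm.
#' @return Area in bpm.s.
#' @examples
#' deceleration_area(40, 100)  # 2000
#' @export
deceleration_area <- function(duration_s, amplitude_bpm) {
  0.5 * duration_s * amplitude_bpm
}

#' Summarise deceleration areas
#'
#' Either the sum of all areas (`mode = "sum"`) or the area and morphology
#' of the last deceleration before the analysis window
#' (`mode = "last_only"`, the default scope of the feature table).
#'
#' @param decels Data.frame from [detect_decelerations].
#' @param mode `"last_only"` or `"sum"`.
#' @return List with `auc_dec` (bpm.s) and `last_decel` (one-row data.frame
#'   or `NULL`).
#' @export
auc_dec <- function(decels, mode = c("last_only", "sum")) {
  mode <- match.arg(mode)
  if (nrow(decels) == 0L) return(list(auc_dec = 0, last_decel = NULL))
  decels <- decels[order(decels$onset_ms), , drop = FALSE]
  last <- decels[nrow(decels), , drop = FALSE]
  total <- if (mode == "sum") sum(decels$area) else last$area
  list(auc_dec = total, last_decel = last)
}

#' Write detected decelerations to CSV
#'
#' @param decels Data.frame from [detect_decelerations].
#' @param path Output path.
#' @export
write_decelerations_csv <- function(decels, path) {
  utils::write.csv(decels, path, row.names = FALSE)
  invisible(path)
}
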