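#' fetalhrv: fetal heart rate variability analysis and acidosis prediction
#'
#' Beat-to-beat RR-interval analysis of the fetal heart rate (FHR): time- and
#' frequency-domain heart rate variability (HRV) indices, the Fetal Stress
#' Index (FSI), deceleration morphology, synthetic umbilical-cord-occlusion
#' data generation, and the multivariable statistics used to predict fetal
#' acidosis (arterial pH < 7.10) from those indices.
#'
#' @keywords internal
"_PACKAGE"

#' Construct an RR-interval series
#'
#' An `rr_series` holds beat times (ms from recording start, strictly
#' increasing) together with the RR intervals they close: `rr[i]` is the
#' interval ending at `beat_times[i + 1]`, so `length(rr) ==
#' length(beat_times) - 1` and the first beat carries no interval.
#'
#' @param beat_times Numeric vector of beat times in ms, strictly increasing.
#' @param rr Optional RR intervals in ms; when omitted they are computed as
#'   `diff(beat_times)`. If supplied they must equal `diff(beat_times)` up to
#'   a small tolerance.
#' @param max_delta_rr Optional sanity filter: maximum allowed absolute
#'   successive RR change in ms. Beats violating it raise an error. Off
#'   (`NULL`) by default; whole-recording quality control, not beat editing,
#'   is the intended use of this package.
#' @return An object of class `rr_series` with elements `beat_times` and `rr`.
#' @examples
#' s <- rr_series(seq(0, 5000, by = 500))
#' s$rr
#' @export
rr_series <- function(beat_times, rr = NULL, max_delta_rr = NULL) {
  beat_times <- as.numeric(beat_times)
  if (length(beat_times) < 1L || anyNA(beat_times)) {
    stop("beat_times must be non-empty and free of NA")
  }
  d <- diff(beat_times)
  if (any(d <= 0)) stop("beat_times must be strictly increasing")
  if (is.null(rr)) {
    rr <- d
  } else {
    rr <- as.numeric(rr)
    if (length(rr) != length(beat_times) - 1L) {
      stop("rr must have length(beat_times) - 1 (interval i ends at beat i + 1)")
    }
    if (any(abs(rr - d) > 1e-6)) {
      stop("rr is inconsistent with diff(beat_times)")
    }
  }
  if (any(rr <= 0)) stop("all RR intervals must be positive")
  if (!is.null(max_delta_rr) && length(rr) > 1L &&
      any(abs(diff(rr)) > max_delta_rr)) {
    stop("successive RR change exceeds max_delta_rr")
  }
  structure(list(beat_times = beat_times, rr = rr), class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf(
    "<rr_series> %d beats, %.1f s, mean RR %.1f ms (%.1f bpm)\n",
    length(x$beat_times),
    diff(range(x$beat_times)) / 1000,
    mean(x$rr), mean(fhr_from_rr(x$rr))
  ))
  invisible(x)
}

#' @export
length.rr_series <- function(x) length(x$beat_times)

#' Instantaneous FHR from RR intervals
#'
#' Converts RR intervals in ms to instantaneous fetal heart rate in beats
#' per minute: `60000 / rr`.
#'
#' @param rr Numeric vector of RR intervals in ms, all positive.
#' @return FHR in bpm.
#' @examples
#' fhr_from_rr(c(333.33, 600))
#' @export
fhr_from_rr <- function(rr) {
  rr <- as.numeric(rr)
  if (any(!is.finite(rr)) || any(rr <= 0)) stop("rr must be finite and positive")
  60000 / rr
}

#' Construct an analysis window
#'
#' Half-open time window `[start, end)` in ms on which one feature record is
#' computed: either the pre-occlusion baseline or a 5-min occlusion-free
#' "stable period".
#'
#' @param start,end Window bounds in ms, `end > start`.
#' @param kind `"baseline"` or `"stable_period"`.
#' @param phase Protocol phase: `"baseline"`, `"A"`, `"B"` or `"C"`.
#' @return An `analysis_window` object.
#' @export
analysis_window <- function(start, end,
                            kind = c("stable_period", "baseline"),
                            phase = c("baseline", "A", "B", "C")) {
  kind <- match.arg(kind)
  phase <- match.arg(phase)
  start <- as.numeric(start); end <- as.numeric(end)
  if (!is.finite(start) || !is.finite(end) || end <= start) {
    stop("analysis window requires finite end > start")
  }
  structure(list(start = start, end = end, kind = kind, phase = phase),
            class = "analysis_window")
}

#' Extract the beats of a window from an RR series
#'
#' Keeps the beats with `beat_times` in the half-open interval
#' `[window$start, window$end)` and recomputes RR intervals from the retained
#' beat times.
#'
#' @param series An [rr_series].
#' @param window An [analysis_window], or anything with `start`/`end` in ms.
#' @return The windowed [rr_series].
#' @export
extract_window <- function(series, window) {
  stopifnot(inherits(series, "rr_series"))
  keep <- series$beat_times >= window$start & series$beat_times < window$end
  if (sum(keep) < 2L) {
    stop("window overlaps fewer than two beats of the series")
  }
  rr_series(series$beat_times[keep])
}

#' Uniformly resample an RR series
#'
#' Interpolates the RR tachogram (RR value against the time of the beat that
#' closes it) onto a uniform grid, the standard preprocessing step before
#' epoch-based (4 Hz) and spectral (8 Hz) HRV analysis.
#'
#' @param series An [rr_series] with at least 2 beats.
#' @param rate Sampling rate in Hz; 4 for STV/LTV epochs, 8 for spectral
#'   analysis and the FSI.
#' @param method `"linear"` (default) or `"cubic"` (Hermite spline).
#' @return A `uniform_series`: list with `values` (ms), `rate` (Hz) and `t0`
#'   (ms, time of the first sample).
#' @examples
#' s <- rr_series(cumsum(c(0, rep(500, 20))))
#' u <- resample_rr(s, 4)
#' all(u$values == 500)
#' @export
resample_rr <- function(series, rate = 4, method = c("linear", "cubic")) {
  stopifnot(inherits(series, "rr_series"))
  method <- match.arg(method)
  if (length(series$beat_times) < 2L) stop("resampling needs at least 2 beats")
  if (!is.numeric(rate) || rate <= 0) stop("rate must be positive")
  tt <- series$beat_times[-1L]           # time each interval ends
  vv <- series$rr
  step <- 1000 / rate
  grid <- seq(tt[1L], tt[length(tt)], by = step)
  values <- if (length(vv) == 1L) {
    rep(vv, length(grid))
  } else if (method == "linear") {
    stats::approx(tt, vv, xout = grid, rule = 2)$y
  } else {
    stats::spline(tt, vv, xout = grid, method = "fmm")$y
  }
  uniform_series(values, rate = rate, t0 = grid[1L])
}

#' @rdname resample_rr
#' @param values Numeric vector of uniformly sampled RR values (ms).
#' @param t0 Time of the first sample in ms.
#' @export
uniform_series <- function(values, rate, t0 = 0) {
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop("uniform series values must be finite")
  if (!is.numeric(rate) || rate <= 0) stop("rate must be positive")
  structure(list(values = values, rate = rate, t0 = as.numeric(t0)),
            class = "uniform_series")
}

#' @export
print.uniform_series <- function(x, ...) {
  cat(sprintf("<uniform_series> %d samples @ %g Hz (%.1f s)\n",
              length(x$values), x$rate, length(x$values) / x$rate))
  invisible(x)
}

#' FHR summary statistics over a window
#'
#' Mean, maximum and minimum instantaneous FHR (bpm) over an analysis
#' window, the `FHRmean`/`FHRmax`/`FHRmin` variables of the feature table.
#' Values are computed from the beat-to-beat series inside the window; a
#' monitor computing min/max over a different span (e.g. including
#' decelerations outside the window) may differ.
#'
#' @param series An [rr_series].
#' @param window Optional [analysis_window]; when omitted the whole series
#'   is used.
#' @return List with `fhr_mean`, `fhr_max`, `fhr_min` in bpm.
#' @export
fhr_summary <- function(series, window = NULL) {
  if (!is.null(window)) series <- extract_window(series, window)
  fhr <- fhr_from_rr(series$rr)
  list(fhr_mean = mean(fhr), fhr_max = max(fhr), fhr_min = min(fhr))
}

#' Read and write RR-interval CSV files
#'
#' The on-disk format is a two-column CSV with header
#' `beat_time_ms,rr_ms`, one row per beat; the first beat's `rr_ms` is
#' empty (it closes no interval).
#'
#' @param path File path.
#' @return `read_rr_csv` returns an [rr_series].
#' @export
read_rr_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("beat_time_ms", "rr_ms") %in% names(d))) {
    stop("RR CSV must have columns beat_time_ms and rr_ms")
  }
  rr_series(d$beat_time_ms, rr = d$rr_ms[-1L])
}

#' @rdname read_rr_csv
#' @param series An [rr_series] to write.
#' @export
write_rr_csv <- function(series, path) {
  stopifnot(inherits(series, "rr_series"))
  utils::write.csv(
    data.frame(beat_time_ms = series$beat_times,
               rr_ms = c(NA, series$rr)),
    path, row.names = FALSE, na = ""
  )
  invisible(path)
}

#' Read and write analysis-window JSON files
#'
#' Windows are stored as a JSON array of objects with fields `start_ms`,
#' `end_ms`, `kind` and `phase`.
#'
#' @param path File path.
#' @return `read_windows_json` returns a list of [analysis_window] objects.
#' @export
read_windows_json <- function(path) {
  d <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  lapply(seq_len(nrow(d)), function(i) {
    analysis_window(d$start_ms[i], d$end_ms[i], kind = d$kind[i],
                    phase = d$phase[i])
  })
}

#' @rdname read_windows_json
#' @param windows List of [analysis_window] objects.
#' @export
write_windows_json <- function(windows, path) {
  d <- data.frame(
    start_ms = vapply(windows, `[[`, numeric(1), "start"),
    end_ms = vapply(windows, `[[`, numeric(1), "end"),
    kind = vapply(windows, `[[`, character(1), "kind"),
    phase = vapply(windows, `[[`, character(1), "phase")
  )
  jsonlite::write_json(d, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
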