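# Synthetic data generators. Two levels:
#  * RR-series level: umbilical-cord-occlusion (UCO) sessions with the
#    experimental structure (1-h baseline, then three 1-h phases with
#    occlusions every 5/3/2 min, 1-min total occlusions, 5-min stable
#    periods every 20 min, protocol stop when pH < 7.00).
#  * cohort level: a 130-recording two-group feature table whose 23
#    variables follow the published group summaries (normal or log-normal
#    marginals matched to mean +/- SD or median [IQR]), with an optional
#    Gaussian copula inducing the factor-block correlation structure seen
#    in the real cohort.

#' Occlusion protocol configuration
#'
#' @param baseline_minutes Pre-occlusion baseline duration (60).
#' @param phase_minutes Duration of each occlusion phase A/B/C (60 each).
#' @param occlusion_interval_min Minutes between occlusion onsets per phase
#'   (A 5, B 3, C 2).
#' @param occlusion_duration_min Total-occlusion duration (1 min).
#' @param stable_period_minutes Stable (occlusion-free) period length (5).
#' @param stable_every_min A stable period ends every this many minutes,
#'   the first at the end of the baseline phase (20).
#' @param stop_ph Protocol stop threshold: session truncates once arterial
#'   pH drops below it (7.00).
#' @param acidosis_ph Acidosis definition: pH < this value (7.10).
#' @return A `protocol_config` list.
#' @export
protocol_config <- function(baseline_minutes = 60,
                            phase_minutes = c(A = 60, B = 60, C = 60),
                            occlusion_interval_min = c(A = 5, B = 3, C = 2),
                            occlusion_duration_min = 1,
                            stable_period_minutes = 5,
                            stable_every_min = 20,
                            stop_ph = 7.00,
                            acidosis_ph = 7.10) {
  stopifnot(all(occlusion_interval_min >= occlusion_duration_min),
            stop_ph < acidosis_ph)
  structure(list(baseline_minutes = baseline_minutes,
                 phase_minutes = phase_minutes,
                 occlusion_interval_min = occlusion_interval_min,
                 occlusion_duration_min = occlusion_duration_min,
                 stable_period_minutes = stable_period_minutes,
                 stable_every_min = stable_every_min,
                 stop_ph = stop_ph, acidosis_ph = acidosis_ph),
            class = "protocol_config")
}

#' RR-series session parameters
#'
#' The beat-level model is
#' `RR(t) = 60000 / FHR(t) + lf_amp sin(2 pi lf_freq t) +
#'  hf_amp sin(2 pi hf_freq t) + N(0, noise_sd^2)`,
#' with `FHR(t)` equal to `baseline_fhr` except during occlusion-locked
#' triangular decelerations. Once the modelled pH crosses the acidosis
#' threshold the HF amplitude is multiplied by `acidosis_hf_gain` — the
#' minimal mechanism for the observed rise of parasympathetic HRV markers
#' with acidosis.
#'
#' @param baseline_fhr Baseline FHR in bpm (180).
#' @param lf_amp,lf_freq LF oscillation amplitude (ms) and frequency (Hz).
#' @param hf_amp,hf_freq HF oscillation amplitude (ms) and frequency (Hz).
#' @param noise_sd Per-beat Gaussian RR noise SD in ms.
#' @param decel_amplitude Deceleration depth in bpm (baseline to nadir).
#' @param decel_duration_s Deceleration duration in s (within the 1-min
#'   occlusion).
#' @param ph0 Initial arterial pH.
#' @param ph_decline pH drop per delivered occlusion.
#' @param acidosis_hf_gain Multiplier on `hf_amp` once pH < 7.10.
#' @param seed Optional RNG seed for reproducibility.
#' @return A `session_params` list.
#' @export
session_params <- function(baseline_fhr = 180,
                           lf_amp = 15, lf_freq = 0.1,
                           hf_amp = 5, hf_freq = 0.8,
                           noise_sd = 3,
                           decel_amplitude = 95, decel_duration_s = 45,
                           ph0 = 7.35, ph_decline = 0.01,
                           acidosis_hf_gain = 1.2,
                           seed = NULL) {
  p <- structure(list(baseline_fhr = baseline_fhr,
                      lf_amp = lf_amp, lf_freq = lf_freq,
                      hf_amp = hf_amp, hf_freq = hf_freq,
                      noise_sd = noise_sd,
                      decel_amplitude = decel_amplitude,
                      decel_duration_s = decel_duration_s,
                      ph0 = ph0, ph_decline = ph_decline,
                      acidosis_hf_gain = acidosis_hf_gain,
                      seed = seed),
                 class = "session_params")
  stopifnot(all(c(lf_amp, hf_amp, noise_sd) >= 0), ph_decline >= 0)
  rr_floor <- 60000 / baseline_fhr - lf_amp - hf_amp * max(1, acidosis_hf_gain) -
    5 * noise_sd
  if (baseline_fhr - decel_amplitude <= 0 || rr_floor <= 0) {
    stop("session parameters imply non-positive RR intervals")
  }
  p
}

# Beat-by-beat integration of the instantaneous RR model. fhr_fun and
# hf_gain_fun map time in ms to the deceleration-modulated FHR and the
# HF amplitude gain.
generate_beats <- function(params, t_end_ms, fhr_fun, hf_gain_fun) {
  est_n <- ceiling(t_end_ms / (60000 / params$baseline_fhr) * 1.6) + 2L
  times <- numeric(est_n)
  t <- 0
  n <- 1L
  times[1L] <- 0
  noise <- stats::rnorm(est_n, 0, params$noise_sd)
  while (TRUE) {
    ts <- t / 1000
    rr <- 60000 / fhr_fun(t) +
      params$lf_amp * sin(2 * pi * params$lf_freq * ts) +
      hf_gain_fun(t) * params$hf_amp * sin(2 * pi * params$hf_freq * ts) +
      noise[n]
    if (rr <= 0) stop("generated a non-positive RR interval")
    t <- t + rr
    if (t >= t_end_ms) break
    n <- n + 1L
    times[n] <- t
  }
  rr_series(times[seq_len(n)])
}

#' Generate a plain RR segment
#'
#' A stationary segment of the session RR model (no occlusions, no pH
#' dynamics): baseline FHR plus LF and HF sinusoidal oscillations plus
#' per-beat Gaussian noise, with beats placed by integrating the
#' instantaneous RR.
#'
#' @param params A [session_params].
#' @param minutes Segment duration.
#' @return An [rr_series].
#' @examples
#' s <- generate_rr_segment(session_params(noise_sd = 0, lf_amp = 0,
#'                                         hf_amp = 0), 1)
#' range(s$rr)  # constant 333.33 ms at 180 bpm
#' @export
generate_rr_segment <- function(params, minutes) {
  stopifnot(inherits(params, "session_params"), minutes > 0)
  if (!is.null(params$seed)) set.seed(params$seed)
  generate_beats(params, minutes * 60000,
                 fhr_fun = function(t) params$baseline_fhr,
                 hf_gain_fun = function(t) 1)
}

#' Generate a full umbilical-cord-occlusion session
#'
#' Builds the occlusion schedule (phases A/B/C at 5/3/2-min intervals),
#' places 5-min stable periods ending every 20 min (the first at the end of
#' the baseline hour), suppresses occlusions overlapping a stable period
#' (stable periods are occlusion-free by definition; the per-phase schedule
#' counts are unchanged), declines pH by `ph_decline` per delivered
#' occlusion, truncates the session once pH < `stop_ph`, and generates the
#' beat series with occlusion-locked triangular decelerations and the
#' acidosis HF gain applied from the moment pH < `acidosis_ph`.
#'
#' @param protocol A [protocol_config].
#' @param params A [session_params].
#' @return A `uco_session`: list with `series` ([rr_series]), `windows`
#'   (list of [analysis_window]), `ph_at_windows`, `occlusions` (data.frame
#'   with `onset_ms`, `end_ms`, `phase`, `delivered`, `ph_after`),
#'   `protocol`, `params`.
#' @export
generate_uco_session <- function(protocol = protocol_config(),
                                 params = session_params()) {
  stopifnot(inherits(protocol, "protocol_config"),
            inherits(params, "session_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  min2ms <- 60000
  base_end <- protocol$baseline_minutes * min2ms
  phases <- names(protocol$phase_minutes)
  phase_start <- base_end +
    c(0, cumsum(protocol$phase_minutes))[seq_along(phases)] * min2ms
  session_end <- base_end + sum(protocol$phase_minutes) * min2ms

  # stable periods end every stable_every_min, first at baseline end
  stable_ends <- seq(protocol$baseline_minutes, session_end / min2ms,
                     by = protocol$stable_every_min) * min2ms
  stable_starts <- stable_ends - protocol$stable_period_minutes * min2ms

  # occlusion schedule
  occ <- do.call(rbind, lapply(seq_along(phases), function(i) {
    n <- protocol$phase_minutes[i] %/% protocol$occlusion_interval_min[i]
    onset <- phase_start[i] +
      (seq_len(n) - 1L) * protocol$occlusion_interval_min[i] * min2ms
    data.frame(onset_ms = onset,
               end_ms = onset + protocol$occlusion_duration_min * min2ms,
               phase = phases[i])
  }))
  occ$delivered <- !vapply(seq_len(nrow(occ)), function(k) {
    any(occ$onset_ms[k] < stable_ends & occ$end_ms[k] > stable_starts)
  }, logical(1))

  # pH declines per delivered occlusion, at occlusion end
  n_del <- cumsum(occ$delivered)
  occ$ph_after <- params$ph0 - params$ph_decline * n_del
  ph_at <- function(t) {
    done <- occ$delivered & occ$end_ms <= t
    params$ph0 - params$ph_decline * sum(done)
  }
  crossed <- which(occ$delivered & occ$ph_after < protocol$stop_ph)
  t_stop <- if (length(crossed)) occ$end_ms[crossed[1L]] else session_end
  occ <- occ[occ$onset_ms < t_stop, , drop = FALSE]

  # acidosis onset time (first delivered occlusion end taking pH < 7.10)
  acid <- which(occ$delivered & occ$ph_after < protocol$acidosis_ph)
  t_acid <- if (length(acid)) occ$end_ms[acid[1L]] else Inf

  dec_half <- params$decel_duration_s * 1000 / 2
  delivered <- occ[occ$delivered, , drop = FALSE]
  dec_centre <- (delivered$onset_ms + delivered$end_ms) / 2
  fhr_fun <- function(t) {
    k <- findInterval(t, dec_centre - dec_half)
    if (k >= 1L && t < dec_centre[k] + dec_half) {
      frac <- 1 - abs(t - dec_centre[k]) / dec_half
      params$baseline_fhr - params$decel_amplitude * frac
    } else params$baseline_fhr
  }
  hf_gain_fun <- function(t) {
    if (t >= t_acid) params$acidosis_hf_gain else 1
  }
  series <- generate_beats(params, t_stop, fhr_fun, hf_gain_fun)

  keep <- stable_ends <= t_stop
  windows <- lapply(which(keep), function(i) {
    analysis_window(stable_starts[i], stable_ends[i],
                    kind = if (stable_ends[i] <= base_end) "baseline"
                           else "stable_period",
                    phase = if (stable_ends[i] <= base_end) "baseline" else {
                      phases[findInterval(stable_starts[i], phase_start)]
                    })
  })
  ph_at_windows <- vapply(stable_starts[keep], ph_at, numeric(1))

  structure(list(series = series, windows = windows,
                 ph_at_windows = ph_at_windows, occlusions = occ,
                 protocol = protocol, params = params),
            class = "uco_session")
}

#' @export
print.uco_session <- function(x, ...) {
  cat(sprintf(
    "<uco_session> %d beats, %.0f min, %d occlusions (%d delivered), %d windows, final pH %.2f\n",
    length(x$series$beat_times),
    max(x$series$beat_times) / 60000,
    nrow(x$occlusions), sum(x$occlusions$delivered),
    length(x$windows), min(x$occlusions$ph_after)
  ))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Cohort-level generator

#' Canonical feature-table variable names
#'
#' The 23 FHR/HRV/deceleration variables of the cohort feature table, in
#' canonical order.
#'
#' @return Character vector of length 23.
#' @export
fhrv_feature_names <- function() {
  c("FHRmean", "FHRmax", "FHRmin",
    "SDNN", "Delta_SDNN", "RMSSD", "Delta_RMSSD",
    "LF", "Delta_LF", "HF", "Delta_HF",
    "HFnu", "Delta_HFnu", "FSI", "Delta_FSI",
    "STV", "Delta_STV", "LTV", "Delta_LTV",
    "Duration", "Amplitude", "Slope", "AUCdec")
}

#' Marginal distribution specs of the synthetic cohort
#'
#' The published two-group summaries driving the cohort marginals, one row
#' per variable: normal marginals are matched to mean +/- SD (or
#' median/IQR via `sd = IQR/1.349`); log-normal marginals (positive,
#' right-skewed variables such as band powers, durations and deceleration
#' areas) to median and IQR. Modify and pass to [cohort_params()] to
#' simulate alternative group separations.
#'
#' @return Data.frame with columns `variable`, `dist`, `non_p1`, `non_p2`,
#'   `aci_p1`, `aci_p2` (location/scale per group).
#' @export
cohort_marginal_specs <- function() {
  spec <- function(var, dist, non, aci) {
    data.frame(variable = var, dist = dist,
               non_p1 = non[1], non_p2 = non[2],
               aci_p1 = aci[1], aci_p2 = aci[2])
  }
  norm_iqr <- function(med, q1, q3) c(med, (q3 - q1) / 1.349)
  lnorm_iqr <- function(med, q1, q3) c(log(med), log(q3 / q1) / 1.349)
  rbind(
    spec("FHRmean", "normal", norm_iqr(181, 169, 187), norm_iqr(182, 164, 195)),
    spec("FHRmax", "normal", norm_iqr(179, 169, 190), norm_iqr(181, 164, 196)),
    spec("FHRmin", "normal", norm_iqr(80, 73, 96), norm_iqr(87, 68, 96)),
    spec("SDNN", "lognormal", lnorm_iqr(49.85, 36.69, 65.26),
         lnorm_iqr(44.89, 28.97, 56.56)),
    spec("Delta_SDNN", "normal", norm_iqr(28.24, 11.10, 48.34),
         norm_iqr(23.02, 6.71, 37.55)),
    spec("RMSSD", "lognormal", lnorm_iqr(19.95, 13.34, 42.13),
         lnorm_iqr(23.80, 18.12, 35.18)),
    spec("Delta_RMSSD", "normal", norm_iqr(8.82, -0.28, 29.00),
         norm_iqr(9.17, 1.20, 26.50)),
    spec("LF", "lognormal", lnorm_iqr(0.11, 0.05, 0.18),
         lnorm_iqr(0.17, 0.10, 0.31)),
    spec("Delta_LF", "normal", norm_iqr(0.01, -0.03, 0.05),
         norm_iqr(0.02, 0.00, 0.11)),
    spec("HF", "lognormal", lnorm_iqr(0.05, 0.02, 0.11),
         lnorm_iqr(0.10, 0.04, 0.17)),
    # quartiles as printed are inconsistent (lower quartile above the
    # median); sign-corrected lower quartile
    spec("Delta_HF", "normal", norm_iqr(0.01, -0.03, 0.05),
         norm_iqr(0.02, 0.00, 0.11)),
    spec("HFnu", "normal", c(0.31, 0.09), c(0.35, 0.08)),
    spec("Delta_HFnu", "normal", c(-0.00, 0.10), c(0.03, 0.08)),
    spec("FSI", "normal", c(57.59, 10.08), c(69.75, 10.22)),
    spec("Delta_FSI", "normal", norm_iqr(-0.82, -7.78, 6.74),
         norm_iqr(4.14, 0.93, 15.24)),
    spec("STV", "lognormal", lnorm_iqr(3.79, 2.96, 5.06),
         lnorm_iqr(4.67, 3.62, 5.58)),
    spec("Delta_STV", "normal", norm_iqr(0.40, -0.80, 1.93),
         norm_iqr(0.65, -0.36, 2.04)),
    spec("LTV", "lognormal", lnorm_iqr(38.33, 31.27, 48.65),
         lnorm_iqr(42.38, 29.67, 52.49)),
    spec("Delta_LTV", "normal", norm_iqr(5.05, -7.35, 16.04),
         norm_iqr(5.24, -11.4, 14.04)),
    spec("Duration", "lognormal", lnorm_iqr(39, 27, 52), lnorm_iqr(47, 28, 68)),
    spec("Amplitude", "normal", norm_iqr(95, 81, 109), norm_iqr(103, 84, 118)),
    spec("Slope", "lognormal", lnorm_iqr(2.38, 1.77, 3.72),
         lnorm_iqr(2.08, 1.73, 3.71)),
    spec("AUCdec", "lognormal", lnorm_iqr(3812, 1958, 61433),
         lnorm_iqr(3030, 1728, 5476))
  )
}

#' Default latent correlation structure of the synthetic cohort
#'
#' Factor-block correlation targets mirroring the rotated-factor structure
#' of the real cohort: one block per factor (spectral family, STV/LTV
#' family, SDNN/RMSSD family, FSI family, FHR pair, deceleration
#' morphology, nadir/amplitude pair), with the FHRmin-Amplitude and
#' Duration-Slope pairs negatively correlated as their loadings indicate.
#' Cross-block correlations are zero.
#'
#' @return A named 23 x 23 positive-definite correlation matrix.
#' @export
cohort_default_correlation <- function() {
  v <- fhrv_feature_names()
  R <- diag(length(v))
  dimnames(R) <- list(v, v)
  set_block <- function(R, vars, r) {
    R[vars, vars] <- r
    diag(R[vars, vars]) <- 1
    R
  }
  R <- set_block(R, c("LF", "Delta_LF", "HF", "Delta_HF"), 0.9)
  R <- set_block(R, c("STV", "Delta_STV", "LTV", "Delta_LTV"), 0.9)
  R <- set_block(R, c("SDNN", "Delta_SDNN", "RMSSD", "Delta_RMSSD"), 0.9)
  R["FSI", "Delta_FSI"] <- R["Delta_FSI", "FSI"] <- 0.6
  R["Delta_HFnu", "FSI"] <- R["FSI", "Delta_HFnu"] <- 0.45
  R["Delta_HFnu", "Delta_FSI"] <- R["Delta_FSI", "Delta_HFnu"] <- 0.45
  R["HFnu", "Delta_HFnu"] <- R["Delta_HFnu", "HFnu"] <- 0.45
  R["HFnu", "FSI"] <- R["FSI", "HFnu"] <- 0.4
  R["HFnu", "Delta_FSI"] <- R["Delta_FSI", "HFnu"] <- 0.35
  R["FHRmean", "FHRmax"] <- R["FHRmax", "FHRmean"] <- 0.9
  R["Duration", "Slope"] <- R["Slope", "Duration"] <- -0.9
  R["Duration", "AUCdec"] <- R["AUCdec", "Duration"] <- -0.6
  R["Slope", "AUCdec"] <- R["AUCdec", "Slope"] <- 0.6
  R["FHRmin", "Amplitude"] <- R["Amplitude", "FHRmin"] <- -0.65
  R
}

#' Cohort generator parameters
#'
#' @param n_acidosis,n_non Group sizes (29 and 101).
#' @param copula Induce the factor-block correlation structure via a
#'   Gaussian copula (default `TRUE`); `FALSE` gives independent marginals.
#' @param correlation Target latent correlation matrix (23 x 23, named);
#'   default [cohort_default_correlation()].
#' @param specs Marginal distribution specs; default the published group
#'   summaries.
#' @param seed Optional RNG seed.
#' @return A `cohort_params` list.
#' @export
cohort_params <- function(n_acidosis = 29, n_non = 101, copula = TRUE,
                          correlation = cohort_default_correlation(),
                          specs = cohort_marginal_specs(), seed = NULL) {
  stopifnot(n_acidosis >= 0, n_non >= 0,
            setequal(specs$variable, fhrv_feature_names()))
  structure(list(n_acidosis = n_acidosis, n_non = n_non, copula = copula,
                 correlation = correlation, specs = specs, seed = seed),
            class = "cohort_params")
}

# u in (0,1) -> marginal quantile
marginal_quantile <- function(u, dist, p1, p2) {
  switch(dist,
    normal = stats::qnorm(u, p1, p2),
    lognormal = stats::qlnorm(u, p1, p2),
    stop(sprintf("unknown marginal distribution '%s'", dist))
  )
}

#' Generate a synthetic two-group cohort feature table
#'
#' Draws `n_non + n_acidosis` recordings with the 23 feature marginals
#' matched to the published group summaries, plus a group-consistent
#' arterial pH (truncated normal on the matching side of 7.10) and the
#' acidosis label `ph < 7.10`. With `copula = TRUE`, features within a
#' recording share the factor-block latent correlation structure, giving
#' the variable-reduction stage realistic redundancy.
#'
#' @param params A [cohort_params].
#' @return Data.frame with the 23 features, `ph`, `acidosis` (logical) and
#'   `group` (factor); attribute `seed` records the seed used.
#' @export
generate_cohort_table <- function(params = cohort_params()) {
  stopifnot(inherits(params, "cohort_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  vars <- fhrv_feature_names()
  specs <- params$specs[match(vars, params$specs$variable), ]
  gen_group <- function(n, acidosis) {
    if (n == 0L) return(NULL)
    if (params$copula) {
      R <- params$correlation[vars, vars]
      L <- chol(R)
      z <- matrix(stats::rnorm(n * length(vars)), n) %*% L
    } else {
      z <- matrix(stats::rnorm(n * length(vars)), n)
    }
    u <- stats::pnorm(z)
    x <- vapply(seq_along(vars), function(j) {
      p1 <- if (acidosis) specs$aci_p1[j] else specs$non_p1[j]
      p2 <- if (acidosis) specs$aci_p2[j] else specs$non_p2[j]
      marginal_quantile(u[, j], specs$dist[j], p1, p2)
    }, numeric(n))
    colnames(x) <- vars
    d <- as.data.frame(x)
    # group-consistent pH: truncated normal strictly on one side of 7.10
    up <- stats::runif(n)
    d$ph <- if (acidosis) {
      f <- stats::pnorm(7.10, 7.05, 0.074)
      stats::qnorm(up * f, 7.05, 0.074)
    } else {
      f <- stats::pnorm(7.10, 7.26, 0.096)
      stats::qnorm(f + up * (1 - f), 7.26, 0.096)
    }
    d$acidosis <- d$ph < 7.10
    d$group <- factor(if (acidosis) "acidosis" else "non_acidosis",
                      levels = c("non_acidosis", "acidosis"))
    d
  }
  out <- rbind(gen_group(params$n_non, FALSE),
               gen_group(params$n_acidosis, TRUE))
  rownames(out) <- NULL
  attr(out, "seed") <- params$seed
  out
}
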