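# Wavelet-based spectral HRV. The RR tachogram, resampled at 8 Hz, is
# decomposed with a Daubechies wavelet; detail level j covers the dyadic
# band (fs/2^(j+1), fs/2^j], so at 8 Hz levels 1-5 cover 0.125-4 Hz (the
# fetal HF band, nominally 0.15-4 Hz) and levels 6-7 cover 0.03125-0.125 Hz
# (the LF band, nominally 0.04-0.15 Hz). The dyadic grid is the closest
# wavelet-attainable cover of the nominal band edges.

# Daubechies scaling filters (orthonormal, sum = sqrt(2)).
daubechies_filter <- function(wavelet = c("d4", "d8")) {
  wavelet <- match.arg(wavelet)
  if (wavelet == "d4") {
    s3 <- sqrt(3)
    c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2))
  } else {
    # 8-tap Daubechies (4 vanishing moments)
    c(0.2303778133088552, 0.7148465705525415, 0.6308807679295904,
      -0.0279837694169839, -0.1870348117188811, 0.0308413818359870,
      0.0328830116669829, -0.0105974017849973)
  }
}

wavelet_pair <- function(wavelet) {
  h <- daubechies_filter(wavelet)
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1L)  # quadrature mirror
  list(h = h, g = g)
}

circular_filter <- function(x, taps, spacing) {
  n <- length(x)
  out <- numeric(n)
  idx <- seq_len(n)
  for (l in seq_along(taps)) {
    shift <- (l - 1L) * spacing
    out <- out + taps[l] * x[((idx - 1L - shift) %% n) + 1L]
  }
  out
}

#' Maximal-overlap discrete wavelet transform (MODWT)
#'
#' Undecimated (shift-invariant) wavelet decomposition with periodic
#' boundary handling. Energy is conserved exactly:
#' `sum(W^2) + sum(V^2) == sum(x^2)`.
#'
#' @param x Numeric vector, length at least `2^n_levels`.
#' @param n_levels Decomposition depth J.
#' @param wavelet `"d4"` (4-tap Daubechies, default) or `"d8"`.
#' @return List with `W` (n x J matrix of detail coefficients) and `V`
#'   (level-J approximation).
#' @export
modwt <- function(x, n_levels, wavelet = c("d4", "d8")) {
  wavelet <- match.arg(wavelet)
  n <- length(x)
  if (n < 2^n_levels) {
    stop(sprintf("modwt to level %d needs at least %d samples, got %d",
                 n_levels, 2^n_levels, n))
  }
  f <- wavelet_pair(wavelet)
  h <- f$h / sqrt(2)  # MODWT rescaling
  g <- f$g / sqrt(2)
  W <- matrix(0, n, n_levels)
  V <- x
  for (j in seq_len(n_levels)) {
    spacing <- 2^(j - 1L)
    W[, j] <- circular_filter(V, g, spacing)
    V <- circular_filter(V, h, spacing)
  }
  list(W = W, V = V, wavelet = wavelet)
}

#' Decimated discrete wavelet transform (pyramid algorithm)
#'
#' Orthonormal DWT with periodic boundary; requires the length to be a
#' multiple of `2^n_levels`. Conserves energy exactly.
#'
#' @inheritParams modwt
#' @return List with `W` (list of detail coefficient vectors per level) and
#'   `V` (final approximation).
#' @export
dwt <- function(x, n_levels, wavelet = c("d4", "d8")) {
  wavelet <- match.arg(wavelet)
  n <- length(x)
  if (n %% 2^n_levels != 0L || n < 2^n_levels) {
    stop(sprintf("dwt to level %d needs a multiple of %d samples, got %d",
                 n_levels, 2^n_levels, n))
  }
  f <- wavelet_pair(wavelet)
  W <- vector("list", n_levels)
  V <- x
  for (j in seq_len(n_levels)) {
    d <- circular_filter(V, f$g, 1L)
    a <- circular_filter(V, f$h, 1L)
    keep <- seq(2L, length(V), by = 2L)  # downsample by 2
    W[[j]] <- d[keep]
    V <- a[keep]
  }
  list(W = W, V = V, wavelet = wavelet)
}

#' LF and HF band powers of an RR series by wavelet decomposition
#'
#' Decomposes the mean-removed 8-Hz RR series to 7 wavelet levels and sums
#' the per-sample detail energy over the levels whose dyadic band lies in
#' the target band: HF (0.15-4 Hz) = levels 1-5, LF (0.04-0.15 Hz) =
#' levels 6-7. Power is total band coefficient energy divided by the number
#' of samples (ms^2 per sample); only ratios and between-window comparisons
#' are used downstream.
#'
#' @param series A `uniform_series` at 8 Hz.
#' @param wavelet Daubechies filter, `"d4"` default.
#' @param transform `"modwt"` (shift-invariant, default) or `"dwt"`.
#' @return List with `lf`, `hf` (ms^2), `hfnu`, and the `level_bands`
#'   mapping used.
#' @export
wavelet_band_powers <- function(series, wavelet = c("d4", "d8"),
                                transform = c("modwt", "dwt")) {
  stopifnot(inherits(series, "uniform_series"))
  wavelet <- match.arg(wavelet)
  transform <- match.arg(transform)
  if (series$rate != 8) stop("spectral analysis is defined on an 8-Hz series")
  J <- 7L
  n <- length(series$values)
  if (n < 2^J) {
    stop(sprintf("need at least %d samples (16 s at 8 Hz) for level-%d analysis",
                 2^J, J))
  }
  x <- series$values - mean(series$values)
  if (transform == "modwt") {
    dec <- modwt(x, J, wavelet)
    level_energy <- colSums(dec$W^2)
  } else {
    m <- n - n %% 2^J  # truncate to a multiple of 2^J
    dec <- dwt(x[seq_len(m)], J, wavelet)
    level_energy <- vapply(dec$W, function(w) sum(w^2), numeric(1))
    n <- m
  }
  hf_levels <- 1:5  # 0.125-4 Hz
  lf_levels <- 6:7  # 0.03125-0.125 Hz
  lf <- sum(level_energy[lf_levels]) / n
  hf <- sum(level_energy[hf_levels]) / n
  fs <- series$rate
  bands <- data.frame(
    level = seq_len(J),
    f_low = fs / 2^(seq_len(J) + 1L),
    f_high = fs / 2^seq_len(J),
    band = c(rep("HF", 5), rep("LF", 2))
  )
  list(lf = lf, hf = hf, hfnu = hfnu(lf, hf), level_bands = bands)
}

#' Normalised high-frequency index
#'
#' `HFnu = HF / (LF + HF)`, the proportion of spectral HRV power carried by
#' the parasympathetic (HF) band. Undefined (NA) when both powers are zero.
#'
#' @param lf,hf Non-negative band powers.
#' @return Value in `[0, 1]`, or `NA_real_` when `lf + hf == 0`.
#' @examples
#' hfnu(0.11, 0.05)  # 0.3125
#' @export
hfnu <- function(lf, hf) {
  if (any(c(lf, hf) < 0)) stop("band powers must be non-negative")
  if (lf + hf == 0) return(NA_real_)
  hf / (lf + hf)
}
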