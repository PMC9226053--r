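# Independent brute-force oracles used to pin down the implementations.

# direct-formula time-domain oracles
oracle_rmssd <- function(rr) {
  d <- rr[-1] - rr[-length(rr)]
  sqrt(sum(d^2) / length(d))
}

oracle_sdnn <- function(rr) {
  m <- sum(rr) / length(rr)
  sqrt(sum((rr - m)^2) / length(rr))
}

# epoch-by-epoch STV/LTV oracle on a 4-Hz vector (whole minutes only)
oracle_stv_ltv <- function(values) {
  n_min <- length(values) %/% 240
  stv <- ltv <- numeric(n_min)
  for (m in seq_len(n_min)) {
    em <- numeric(16)
    for (e in 1:16) {
      i0 <- (m - 1) * 240 + (e - 1) * 15
      em[e] <- mean(values[(i0 + 1):(i0 + 15)])
    }
    stv[m] <- mean(abs(em[-1] - em[-16]))
    ltv[m] <- max(em) - min(em)
  }
  list(stv = mean(stv), ltv = mean(ltv))
}

# per-sample spectral power in [f1, f2) Hz by discrete Fourier transform
fft_band_power <- function(x, fs, f1, f2) {
  x <- x - mean(x)
  n <- length(x)
  p <- Mod(stats::fft(x))^2 / n^2
  k <- 0:(n - 1)
  freq <- pmin(k, n - k) * fs / n
  sum(p[freq >= f1 & freq < f2])
}

# exhaustive pair-concordance AUC (ties count one half)
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# exhaustive midpoint scan for the best chi-square split
oracle_best_split <- function(x, y, min_child = 1) {
  xs <- sort(unique(x))
  best <- NULL
  for (i in seq_len(length(xs) - 1)) {
    thr <- (xs[i] + xs[i + 1]) / 2
    left <- x <= thr
    if (sum(left) < min_child || sum(!left) < min_child) next
    a <- sum(left & y == 1); b <- sum(left & y == 0)
    cc <- sum(!left & y == 1); d <- sum(!left & y == 0)
    n <- a + b + cc + d
    den <- (a + b) * (cc + d) * (a + cc) * (b + d)
    stat <- if (den > 0) n * (a * d - b * cc)^2 / den else 0
    if (is.null(best) || stat > best$chi2 + 1e-12) {
      best <- list(threshold = thr, chi2 = stat)
    }
  }
  best
}

# logistic log-likelihood maximised with a generic optimiser (reference
# solver independent of glm's IRLS)
oracle_logistic_coef <- function(x, y) {
  nll <- function(beta) {
    eta <- beta[1] + beta[2] * x
    sum(log1p(exp(eta))) - sum(y * eta)
  }
  stats::optim(c(0, 0), nll, method = "BFGS",
               control = list(reltol = 1e-12))$par
}

# quick deterministic sinusoid RR series builder: baseline ms plus one
# oscillation, beats placed by integrating instantaneous RR
make_sine_rr <- function(minutes, base_ms = 333.33, amp = 0, freq = 1) {
  t <- 0
  times <- numeric(ceiling(minutes * 60000 / base_ms * 1.5) + 2)
  n <- 1
  while (t < minutes * 60000) {
    rr <- base_ms + amp * sin(2 * pi * freq * t / 1000)
    t <- t + rr
    n <- n + 1
    times[n] <- t
  }
  rr_series(times[1:(n - 1)])
}
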