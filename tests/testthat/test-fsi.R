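test_that("normalisation centres on 100 and is scale-invariant", {
  u <- uniform_series(rep(420, 800), rate = 8)
  expect_equal(normalize_rr(u)$values, rep(100, 800), tolerance = 1e-12)
  t <- (0:1599) / 8
  x <- 500 + 10 * sin(2 * pi * 1 * t)
  n1 <- normalize_rr(uniform_series(x, rate = 8))
  n2 <- normalize_rr(uniform_series(2.7 * x, rate = 8))
  expect_equal(n1$values, n2$values, tolerance = 1e-12)
  # 10-ms oscillation on 500 ms: normalised amplitude 2 around 100
  tail_vals <- n1$values[800:1600]
  expect_equal(max(tail_vals) - min(tail_vals), 4, tolerance = 0.05)
  expect_equal(mean(tail_vals), 100, tolerance = 0.05)
})

test_that("the HF filter rejects DC and LF but passes the HF band", {
  t <- (0:2399) / 8
  dc <- hf_component(uniform_series(rep(500, 2400), rate = 8))
  expect_lt(max(abs(dc$values)), 1e-8)
  one_hz <- hf_component(uniform_series(500 + 10 * sin(2 * pi * 1 * t), rate = 8))
  mid <- one_hz$values[400:2000]
  expect_equal(max(mid), 10, tolerance = 0.02)
  slow <- hf_component(uniform_series(500 + 10 * sin(2 * pi * 0.05 * t), rate = 8))
  # >= 40 dB attenuation of a 0.05-Hz tone
  expect_lt(max(abs(slow$values[400:2000])), 10 / 100)
})

test_that("envelope magnitude recovers sinusoid amplitudes linearly", {
  z <- uniform_series(rep(0, 500), rate = 8)
  m0 <- envelope_magnitude(z)
  expect_equal(as.numeric(m0), 0)
  expect_true(attr(m0, "too_few_extrema"))
  t <- (0:799) / 8
  for (a in c(1, 2.5)) {
    u <- uniform_series(a * sin(2 * pi * 1 * t), rate = 8)
    expect_equal(as.numeric(envelope_magnitude(u)), 2 * a, tolerance = 0.02)
  }
  u1 <- uniform_series(sin(2 * pi * 0.7 * t), rate = 8)
  u2 <- uniform_series(2 * sin(2 * pi * 0.7 * t), rate = 8)
  expect_equal(2 * as.numeric(envelope_magnitude(u1)),
               as.numeric(envelope_magnitude(u2)), tolerance = 1e-9)
})

test_that("FSI is zero for constant RR and saturates at 100", {
  const <- rr_series(cumsum(c(0, rep(333.33, 1200))))
  expect_equal(fsi(const)$averaged, 0)
  big <- session_params(baseline_fhr = 120, hf_amp = 150, hf_freq = 0.8,
                        lf_amp = 0, noise_sd = 0, seed = 1)
  s <- generate_rr_segment(big, 3)
  expect_equal(fsi(s)$averaged, 100)
})

test_that("FSI responds monotonically to the HF amplitude ladder", {
  vals <- vapply(c(2, 5, 8), function(a) {
    p <- session_params(hf_amp = a, noise_sd = 0, seed = 2)
    fsi(generate_rr_segment(p, 4))$averaged
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("FSI is invariant to the absolute RR level", {
  base <- make_sine_rr(4, base_ms = 400, amp = 8, freq = 0.8)
  scaled <- rr_series(base$beat_times * 1.1)  # all RR scaled by 1.1
  f1 <- fsi(base)$averaged
  f2 <- fsi(scaled)$averaged
  expect_lt(abs(f1 - f2), 2)
  expect_gt(f1, 10)  # a real signal, not a trivial zero
})

test_that("FSI is insensitive to added pure-LF oscillation", {
  p0 <- session_params(hf_amp = 5, lf_amp = 0, noise_sd = 0, seed = 3)
  p1 <- session_params(hf_amp = 5, lf_amp = 20, lf_freq = 0.1,
                       noise_sd = 0, seed = 3)
  f0 <- fsi(generate_rr_segment(p0, 4))$averaged
  f1 <- fsi(generate_rr_segment(p1, 4))$averaged
  expect_lt(abs(f1 - f0), 5)
})

test_that("averaging window options behave as trailing means", {
  p <- session_params(seed = 4)
  s <- generate_rr_segment(p, 5)
  r4 <- fsi(s, averaging_minutes = 4)
  r3 <- fsi(s, averaging_minutes = 3)
  expect_equal(r4$averaged,
               mean(utils::tail(r4$instantaneous, 240)), tolerance = 1e-12)
  expect_equal(r3$averaged,
               mean(utils::tail(r3$instantaneous, 180)), tolerance = 1e-12)
  expect_true(all(r4$instantaneous >= 0 & r4$instantaneous <= 100))
})
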