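test_that("a noise-free, oscillation-free segment is a constant 180-bpm series", {
  p <- session_params(noise_sd = 0, lf_amp = 0, hf_amp = 0)
  s <- generate_rr_segment(p, 2)
  expect_equal(unique(round(s$rr, 6)), round(60000 / 180, 6))
})

test_that("segments are reproducible under a seed and reject impossible params", {
  a <- generate_rr_segment(session_params(seed = 9), 2)
  b <- generate_rr_segment(session_params(seed = 9), 2)
  expect_identical(a, b)
  expect_error(session_params(baseline_fhr = 50, decel_amplitude = 95),
               "non-positive RR")
  expect_error(session_params(noise_sd = 80), "non-positive RR")
})

test_that("an HF-dominated segment shows hf >> lf in the spectral module", {
  p <- session_params(hf_amp = 10, lf_amp = 0, noise_sd = 0, seed = 10)
  u <- resample_rr(generate_rr_segment(p, 3), 8)
  bp <- wavelet_band_powers(u)
  expect_gt(bp$hf, 10 * bp$lf)
})

test_that("the occlusion schedule matches the 5/3/2-min protocol arithmetic", {
  p <- session_params(ph_decline = 0, noise_sd = 0, seed = 1)
  sess <- generate_uco_session(params = p)
  counts <- table(sess$occlusions$phase)
  expect_equal(as.integer(counts[c("A", "B", "C")]), c(12L, 20L, 30L))
  # occlusions never overlap a stable period
  for (w in sess$windows) {
    del <- sess$occlusions[sess$occlusions$delivered, ]
    expect_false(any(del$onset_ms < w$end & del$end_ms > w$start))
  }
})

test_that("stable periods contain no decelerations", {
  sess <- generate_uco_session(params = session_params(seed = 12))
  for (w in sess$windows[-1]) {
    sub <- extract_window(sess$series, w)
    u4 <- resample_rr(sub, 4)
    fhr <- uniform_series(60000 / u4$values, rate = 4, t0 = u4$t0)
    dec <- detect_decelerations(fhr, baseline = sess$params$baseline_fhr)
    expect_equal(nrow(dec), 0L)
  }
})

test_that("pH truncation stops the session at the configured floor", {
  p <- session_params(ph_decline = 0.02, ph0 = 7.35, seed = 13)
  sess <- generate_uco_session(params = p)
  ph <- sess$occlusions$ph_after[sess$occlusions$delivered]
  expect_equal(sum(ph < 7.00), 1L)            # ends at the crossing occlusion
  expect_equal(min(ph), 7.35 - 0.02 * length(ph))
  expect_lt(max(sess$series$beat_times), 240 * 60000)
})

test_that("cohort marginals recover the configured group means", {
  tab <- generate_cohort_table(cohort_params(n_acidosis = 1e5, n_non = 1e5,
                                             copula = FALSE, seed = 14))
  expect_equal(mean(tab$FSI[!tab$acidosis]), 57.59, tolerance = 0.1 / 57.59)
  expect_equal(mean(tab$FSI[tab$acidosis]), 69.75, tolerance = 0.1 / 69.75)
  expect_equal(stats::sd(tab$FSI[!tab$acidosis]), 10.08, tolerance = 0.01)
  expect_equal(stats::median(tab$SDNN[!tab$acidosis]), 49.85, tolerance = 0.01)
})

test_that("cohort tables are reproducible, labelled consistently, and sized", {
  a <- generate_cohort_table(cohort_params(seed = 15))
  b <- generate_cohort_table(cohort_params(seed = 15))
  expect_identical(a, b)
  expect_equal(nrow(a), 130L)
  expect_equal(sum(a$group == "acidosis"), 29L)
  expect_equal(sum(a$group == "non_acidosis"), 101L)
  expect_identical(a$acidosis, a$ph < 7.10)
  expect_identical(a$acidosis, a$group == "acidosis")
  expect_true(all(fhrv_feature_names() %in% names(a)))
})

test_that("the copula hits its latent correlation targets on normal marginals", {
  tab <- generate_cohort_table(cohort_params(n_acidosis = 0, n_non = 1e4,
                                             seed = 16))
  expect_equal(cor(tab$FHRmean, tab$FHRmax), 0.9, tolerance = 0.02 / 0.9)
  expect_equal(cor(tab$FSI, tab$Delta_FSI), 0.6, tolerance = 0.04 / 0.6)
})

test_that("feature extraction sees the acidosis HF gain in the session", {
  sess <- generate_uco_session(params = session_params(seed = 3))
  feat <- extract_features(sess)
  expect_true(any(feat$acidosis))
  expect_gt(mean(feat$FSI[feat$acidosis]),
            mean(feat$FSI[!feat$acidosis]) + 3)
  expect_true(all(fhrv_feature_names() %in% names(feat)))
  expect_identical(feat$acidosis, feat$ph < 7.10)
})
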