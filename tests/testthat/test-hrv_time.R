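test_that("RMSSD and SDNN match their defining formulas", {
  const <- rr_series(cumsum(c(0, rep(500, 20))))
  expect_equal(as.numeric(rmssd(const)), 0)
  expect_equal(as.numeric(sdnn(const)), 0)

  alt <- rr_series(cumsum(c(0, rep(c(330, 340), 10))))
  expect_equal(as.numeric(rmssd(alt)), 10)

  two <- rr_series(c(0, 400, 1000))
  expect_equal(as.numeric(sdnn(two)), 100)  # population convention

  set.seed(21)
  for (i in 1:10) {
    rr <- runif(10, 300, 600)
    s <- rr_series(cumsum(c(0, rr)))
    expect_equal(as.numeric(rmssd(s)), oracle_rmssd(rr), tolerance = 1e-12)
    expect_equal(as.numeric(sdnn(s)), oracle_sdnn(rr), tolerance = 1e-12)
  }
  expect_error(rmssd(rr_series(c(0, 500))), "at least 2")
})

test_that("540-interval windowing takes the most recent intervals and flags short ones", {
  rr <- c(rep(400, 300), rep(500, 540))
  s <- rr_series(cumsum(c(0, rr)))
  v <- sdnn(s)
  expect_equal(as.numeric(v), 0)  # only the last 540 (constant) intervals
  expect_equal(attr(v, "n_intervals"), 540L)
  short <- rr_series(cumsum(c(0, runif(100, 400, 500))))
  expect_true(attr(rmssd(short), "short_window"))
})

test_that("RMSSD/SDNN are shift-invariant and amplitude-linear", {
  set.seed(5)
  rr <- 450 + 30 * sin(2 * pi * (1:600) / 40)
  s1 <- rr_series(cumsum(c(0, rr)))
  s2 <- rr_series(cumsum(c(0, rr + 100)))
  expect_equal(as.numeric(rmssd(s1)), as.numeric(rmssd(s2)), tolerance = 1e-12)
  expect_equal(as.numeric(sdnn(s1)), as.numeric(sdnn(s2)), tolerance = 1e-12)
  s3 <- rr_series(cumsum(c(0, 450 + 60 * sin(2 * pi * (1:600) / 40))))
  expect_equal(as.numeric(rmssd(s3)), 2 * as.numeric(rmssd(s1)), tolerance = 1e-9)
  expect_equal(as.numeric(sdnn(s3)), 2 * as.numeric(sdnn(s1)), tolerance = 1e-9)
})

test_that("STV/LTV follow the 16-epoch definition", {
  const <- uniform_series(rep(500, 480), rate = 4)
  sl <- stv_ltv(const)
  expect_equal(sl$stv, 0)
  expect_equal(sl$ltv, 0)

  # epoch means forming an arithmetic ramp with step d
  d <- 2.5
  ramp <- uniform_series(rep(d * (0:15), each = 15), rate = 4)
  sl2 <- stv_ltv(ramp)
  expect_equal(sl2$stv, d)
  expect_equal(sl2$ltv, 15 * d)

  # sinusoid against the brute-force epoch oracle, two full minutes
  vals <- 500 + 20 * sin(2 * pi * 0.02 * (0:479) / 4)
  u <- uniform_series(vals, rate = 4)
  o <- oracle_stv_ltv(vals)
  sl3 <- stv_ltv(u)
  expect_equal(sl3$stv, o$stv, tolerance = 1e-12)
  expect_equal(sl3$ltv, o$ltv, tolerance = 1e-12)
  expect_equal(sl3$n_minutes, 2)

  expect_warning(stv_ltv(uniform_series(rep(500, 250), rate = 4)), "incomplete")
  expect_error(stv_ltv(uniform_series(rep(500, 100), rate = 4)), "full minute")
  expect_error(stv_ltv(uniform_series(rep(500, 480), rate = 8)), "4-Hz")
})

test_that("STV/LTV scale linearly with oscillation amplitude", {
  base <- rep(500, 480)
  osc <- sin(2 * pi * 0.05 * (0:479) / 4)
  a <- stv_ltv(uniform_series(base + 10 * osc, rate = 4))
  b <- stv_ltv(uniform_series(base + 20 * osc, rate = 4))
  expect_equal(b$stv, 2 * a$stv, tolerance = 1e-9)
  expect_equal(b$ltv, 2 * a$ltv, tolerance = 1e-9)
})

test_that("delta_from_baseline handles both modes", {
  expect_equal(as.numeric(delta_from_baseline(50, 50)), 0)
  expect_equal(as.numeric(delta_from_baseline(50, 50, "absolute")), 0)
  expect_equal(as.numeric(delta_from_baseline(75, 50)), 50)
  expect_equal(as.numeric(delta_from_baseline(0.12, 0.11, "absolute")), 0.01)
  expect_error(delta_from_baseline(1, 0), "zero baseline")
  expect_equal(attr(delta_from_baseline(1, 2, "absolute"), "mode"), "absolute")
})
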