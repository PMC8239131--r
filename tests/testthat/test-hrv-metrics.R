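test_that("RMSSD and SDNN match hand arithmetic", {
  expect_equal(rmssd(c(800, 800, 800)), 0)
  expect_equal(rmssd(c(800, 810, 790)), sqrt(250))
  expect_equal(sdnn(c(800, 800, 800)), 0)
  expect_equal(sdnn(c(790, 800, 810)), 10)
  expect_error(rmssd(800), "at least 2")
  expect_error(sdnn(800), "at least 2")
})

test_that("time-domain metrics match brute-force recomputation on random input", {
  set.seed(55)
  for (rep in 1:100) {
    x <- runif(sample(2:400, 1), 300, 1700)
    n <- length(x)
    sq <- 0
    for (i in seq_len(n - 1)) sq <- sq + (x[i + 1] - x[i])^2
    r_oracle <- sqrt(sq / (n - 1))
    mu <- sum(x) / n
    ss <- 0
    for (i in seq_len(n)) ss <- ss + (x[i] - mu)^2
    s_oracle <- sqrt(ss / (n - 1))
    expect_lt(abs(rmssd(x) - r_oracle) / r_oracle, 1e-9)
    expect_lt(abs(sdnn(x) - s_oracle) / max(s_oracle, 1e-30), 1e-9)
  }
})

test_that("time-domain metrics are invariant under a constant BBI shift", {
  set.seed(56)
  x <- runif(200, 600, 1000)
  expect_equal(rmssd(x + 123.456), rmssd(x))
  expect_equal(sdnn(x + 123.456), sdnn(x))
})

test_that("IID Gaussian BBIs recover sigma and the sqrt(2) RMSSD/SDNN ratio", {
  set.seed(2026)
  x <- rnorm(5000, 850, 30)
  expect_lt(abs(sdnn(x) - 30) / 30, 0.05)
  expect_gt(rmssd(x) / sdnn(x), 1.3)
  expect_lt(rmssd(x) / sdnn(x), 1.5)
})

test_that("the tachogram reproduces a closed-form modulation on the grid", {
  # constant series: flat tachogram, exactly zero after mean removal
  seg <- rr_segment(constant_series(400, 800), 0, 300)
  tg <- tachogram(seg)
  expect_length(tg$bbi_ms, 1200L)
  expect_lt(max(abs(tg$bbi_ms)), 1e-9)
  expect_equal(attr(tg, "mean_ms"), 800)

  # sinusoidal modulation: grid values near the generator away from edges
  f <- function(ts) 800 + 50 * sin(2 * pi * 0.25 * ts)
  s <- series_from_bbi_fun(f, 320000)
  seg2 <- rr_segment(s, 0, 300)
  tg2 <- tachogram(seg2, detrend = "none")
  interior <- tg2$t_ms > 2000 & tg2$t_ms < 298000
  err <- abs(tg2$bbi_ms - f(tg2$t_ms / 1000))
  expect_lt(max(err[interior]), 2)

  expect_error(tachogram(rr_segment(constant_series(4, 1000), 0, 3)),
               "< 4")
})

test_that("pure in-band tones land their power in the right band for both estimators", {
  for (case in list(list(f = 0.25, band = "hf_ms2"),
                    list(f = 0.10, band = "lf_ms2"))) {
    s <- series_from_bbi_fun(
      function(ts) 800 + 50 * sin(2 * pi * case$f * ts), 320000)
    seg <- rr_segment(s, 0, 300)
    for (est in c("welch", "lomb_scargle")) {
      bp <- band_power(seg, spectral_config(estimator = est))
      expect_gt(bp[[case$band]] / sum(bp), 0.90)
      # a 50 ms amplitude tone carries ~ 50^2/2 ms^2
      expect_lt(abs(bp[[case$band]] - 1250) / 1250, 0.10)
    }
  }
})

test_that("constant input has (near) zero band power", {
  seg <- rr_segment(constant_series(400, 800), 0, 300)
  bp <- band_power(seg)
  expect_lt(bp[["lf_ms2"]], 1e-6)
  expect_lt(bp[["hf_ms2"]], 1e-6)
})

test_that("Welch and Lomb-Scargle agree on stationary two-tone signals", {
  s <- series_from_bbi_fun(
    function(ts) 850 + 40 * sin(2 * pi * 0.1 * ts) +
      30 * sin(2 * pi * 0.25 * ts + 1), 320000)
  seg <- rr_segment(s, 0, 300)
  w <- band_power(seg)
  l <- band_power(seg, spectral_config(estimator = "lomb_scargle"))
  expect_lt(abs(w[["lf_ms2"]] - l[["lf_ms2"]]) / w[["lf_ms2"]], 0.25)
  expect_lt(abs(w[["hf_ms2"]] - l[["hf_ms2"]]) / w[["hf_ms2"]], 0.25)
})

test_that("band power is insensitive to the mean interval level", {
  mk <- function(base) {
    series_from_bbi_fun(
      function(ts) base + 40 * sin(2 * pi * 0.25 * ts), 320000)
  }
  b1 <- band_power(rr_segment(mk(700), 0, 300))
  b2 <- band_power(rr_segment(mk(1100), 0, 300))
  expect_lt(abs(b1[["hf_ms2"]] - b2[["hf_ms2"]]) / b1[["hf_ms2"]], 0.10)
})

test_that("metric assembly shares one code path for 300 s and 60 s windows", {
  s <- generate_recording(synthetic_config(duration_h = 1, seed = 3))
  seg <- select_hourly(scan_clean_segments(s, build_mask(s)))[[1]]
  f1 <- extract_first_minute(seg)
  direct <- compute_metrics(rr_segment(s, seg$start_ms, 60),
                            warn_resolution = FALSE)
  via <- compute_metrics(f1, warn_resolution = FALSE)
  expect_identical(via, direct)

  m5 <- compute_metrics(seg)
  expect_true(all(c(m5$rmssd_ms, m5$sdnn_ms, m5$lf_ms2, m5$hf_ms2) >= 0))
  expect_equal(m5$duration_s, 300)
  expect_equal(m5$n_bbis, length(segment_bbis(seg)))
})

test_that("too few beats yields NA frequency metrics, never zeros", {
  s <- beat_series(bbis = c(1000, 1000, 1000))
  seg <- rr_segment(s, 0, 60)
  m <- compute_metrics(seg)
  expect_true(is.na(m$lf_ms2) && is.na(m$hf_ms2))
  expect_equal(m$rmssd_ms, 0)
})

test_that("a 60 s window under-resolves the LF band and says so", {
  s <- generate_recording(synthetic_config(duration_h = 0.2, seed = 8))
  seg <- rr_segment(s, 0, 60)
  expect_warning(band_power(seg), "under-resolved")
  expect_silent(bp <- band_power(seg, warn_resolution = FALSE))
  expect_true(all(bp >= 0))
})

test_that("LF period coverage matches the window arithmetic", {
  expect_equal(lf_period_coverage(60, 0.04), 2.4)
  expect_equal(lf_period_coverage(300, 0.04), 12)
  expect_equal(lf_period_coverage(25, 0.04), 1)
})

test_that("HF power grows monotonically with squared modulation amplitude", {
  hfp <- sapply(c(10, 30, 50), function(a) {
    s <- series_from_bbi_fun(
      function(ts) 850 + a * sin(2 * pi * 0.25 * ts), 320000)
    band_power(rr_segment(s, 0, 300))[["hf_ms2"]]
  })
  expect_true(all(diff(hfp) > 0))
  # roughly quadratic: a 5x amplitude -> ~25x power
  expect_gt(hfp[3] / hfp[1], 15)
})
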