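test_that("a modulation-free configuration has a closed form", {
  cfg <- synthetic_config(duration_h = 1, base_bbi_ms = 1000,
                          hf = list(amp_ms = 0), lf = list(amp_ms = 0),
                          slow_trend = list(amplitude_ms = 0),
                          jitter_sd_ms = 0)
  s <- generate_recording(cfg)
  expect_length(s$bbis, 3600L)
  expect_lt(max(abs(s$bbis - 1000)), 1e-9)
})

test_that("generated recordings have the configured mean interval and are seeded", {
  # without slow drift the mean settles within an hour
  s_flat <- generate_recording(tame_config(duration_h = 1, seed = 7))
  expect_lt(abs(mean(s_flat$bbis) - 850) / 850, 0.02)
  # beats oversample fast phases, so over a day the mean BBI converges to
  # the harmonic-mean prediction base - Var(m)/base, not to base itself
  s24 <- generate_recording(synthetic_config(duration_h = 24, seed = 7))
  v <- 250^2 / 2 + (45^2 * 1.125) / 2 + (30^2 * 1.125) / 2 + 10^2
  expect_lt(abs(mean(s24$bbis) - (850 - v / 850)) / 850, 0.01)

  cfg <- synthetic_config(duration_h = 1, seed = 7)
  s <- generate_recording(cfg)
  expect_true(all(diff(s$beat_times) > 0))

  s2 <- generate_recording(synthetic_config(duration_h = 1, seed = 7))
  expect_identical(s$beat_times, s2$beat_times)
  s3 <- generate_recording(synthetic_config(duration_h = 1, seed = 8))
  expect_false(identical(s$beat_times, s3$beat_times))
})

test_that("configurations that could produce non-positive intervals are rejected", {
  expect_error(synthetic_config(base_bbi_ms = 300),
               "exceed the base interval")
  expect_error(synthetic_config(hf = list(freq_hz = 0.5)), "HF band")
  expect_error(synthetic_config(lf = list(freq_hz = 0.2)), "LF band")
  # validation passes with zero amplitudes but huge jitter trips at run time
  cfg <- synthetic_config(duration_h = 1, hf = list(amp_ms = 0),
                          lf = list(amp_ms = 0),
                          slow_trend = list(amplitude_ms = 0),
                          jitter_sd_ms = 500, seed = 1)
  expect_error(generate_recording(cfg), "non-positive interval")
})

test_that("zero injection rates leave the series untouched", {
  s <- generate_recording(tame_config(duration_h = 1, seed = 2))
  out <- inject_artifacts(s, 0, 0, seed = 3)
  expect_identical(out$beat_times, s$beat_times)
  expect_equal(nrow(attr(out, "injections")), 0L)
})

test_that("injected ectopics preserve cumulative time and are detected", {
  s <- generate_recording(tame_config(duration_h = 3, seed = 13))
  inj <- inject_artifacts(s, ectopic_rate_per_h = 2, outlier_rate_per_h = 0,
                          seed = 17)
  log <- attr(inj, "injections")
  expect_gt(nrow(log), 2)            # ~6 expected on 3 h at 2/h
  expect_lt(nrow(log), 14)
  # premature beat + compensatory pause preserves later beat times
  expect_equal(duration_ms(inj), duration_ms(s), tolerance = 1e-12)
  expect_length(inj$bbis, length(s$bbis))
  # each injection detected by the default rule at or next to its index
  det <- detect_ectopic(inj)
  for (i in log$bbi_index) expect_true(any(c(i, i + 1L) %in% det))
})

test_that("injected outliers are exactly the out-of-range flags", {
  s <- generate_recording(tame_config(duration_h = 3, seed = 23))
  inj <- inject_artifacts(s, ectopic_rate_per_h = 0, outlier_rate_per_h = 2,
                          seed = 29)
  log <- attr(inj, "injections")
  expect_true(all(log$type == "outlier"))
  expect_true(all(log$injected_ms < 400 | log$injected_ms > 1500))
  flagged <- detect_outliers(inj)
  expect_setequal(flagged, log$bbi_index)   # all flagged, none untouched
})

test_that("most 5-minute oscillatory power sits in the LF and HF bands", {
  s <- generate_recording(synthetic_config(duration_h = 2, seed = 3))
  segs <- select_hourly(scan_clean_segments(s, build_mask(s)))
  for (seg in segs) {
    tg <- tachogram(seg)
    sp <- hrvconcord:::welch_psd(tg$bbi_ms, tg$fs_hz)
    inband <- hrvconcord:::band_integral(sp$freq, sp$psd, 0.04, 0.40)
    osc <- hrvconcord:::band_integral(sp$freq, sp$psd, 0.04, 2)
    expect_gt(inband / osc, 0.80)
  }
})

test_that("the recovery suite sees HF power rise with amplitude and RMSSD with jitter", {
  tab <- parameter_recovery_suite(hf_amp_grid = c(10, 30, 50),
                                  jitter_grid = c(5, 20), seeds = 1:2,
                                  duration_h = 1,
                                  base_config = tame_config())
  hf_means <- tapply(tab$hf_ms2[tab$sweep == "hf_amp"],
                     tab$hf_amp_ms[tab$sweep == "hf_amp"], mean)
  expect_true(all(diff(hf_means[order(as.numeric(names(hf_means)))]) > 0))

  # zero-modulation IID theory: RMSSD ~ sqrt(2) * sd, so 20 vs 5 ms -> 4x
  jit <- tab[tab$sweep == "jitter", ]
  r5 <- mean(jit$rmssd_ms[jit$jitter_sd_ms == 5])
  r20 <- mean(jit$rmssd_ms[jit$jitter_sd_ms == 20])
  expect_lt(abs(r20 / r5 - 4) / 4, 0.15)
  expect_lt(abs(r20 - sqrt(2) * 20) / (sqrt(2) * 20), 0.15)
})

test_that("an all-zero configuration yields near-zero metrics everywhere", {
  cfg <- synthetic_config(duration_h = 1, hf = list(amp_ms = 0),
                          lf = list(amp_ms = 0),
                          slow_trend = list(amplitude_ms = 0),
                          jitter_sd_ms = 0)
  s <- generate_recording(cfg)
  seg <- select_hourly(scan_clean_segments(s, build_mask(s)))[[1]]
  m <- compute_metrics(seg)
  expect_equal(m$rmssd_ms, 0)
  expect_equal(m$sdnn_ms, 0)
  expect_lt(m$lf_ms2 + m$hf_ms2, 1e-6)
})
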