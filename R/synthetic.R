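#' Configuration for the synthetic RR-interval generator
#'
#' Describes a multi-hour beat-to-beat recording as a slowly modulated point
#' process: the instantaneous interval is a base value plus a respiratory-band
#' (HF) sinusoid, a low-frequency (LF) sinusoid, a slow nonstationary drift,
#' and white beat-to-beat jitter.  The HF and LF amplitudes themselves wander
#' sinusoidally on a 10--30 minute scale, emulating autonomic drift: without
#' amplitude wander every hour of the recording would look alike and
#' between-segment correlation of HRV metrics would degenerate.
#'
#' Carrier defaults (0.25 Hz HF, 0.10 Hz LF) sit inside the conventional
#' 0.15--0.40 Hz and 0.04--0.15 Hz analysis bands.  All slow periods (the
#' amplitude wanders and the drift) are chosen incommensurate with the
#' one-hour segment spacing: a wander period that divides 3600 s would make
#' every hourly window sample the identical modulation state, collapsing the
#' between-segment variance the agreement analysis depends on.  The HF
#' amplitude wanders slowly (1700 s) so a 5-minute window and its first
#' minute see nearly the same respiratory amplitude, while the LF amplitude
#' wanders faster (911 s) and the drift (250 ms over 2390 s) contributes
#' variance mainly to 5-minute windows -- the structural reasons short-window
#' HF tracks well, LF moderately, and SDNN poorly.
#'
#' @param duration_h Recording length in hours.
#' @param base_bbi_ms Mean interval, ms (default 850, roughly 70 BPM).
#' @param hf List: `freq_hz` (default 0.25), `amp_ms`, `amp_wander_period_s`,
#'   `amp_wander_frac`.
#' @param lf List: same fields, `freq_hz` default 0.10.
#' @param slow_trend List: `amplitude_ms`, `period_s`.
#' @param jitter_sd_ms SD of white beat-to-beat noise, ms.
#' @param ectopic_rate_per_h,outlier_rate_per_h Expected artifact injections
#'   per hour (Poisson counts; 0 = clean recording).
#' @param seed Integer seed; fans out to independent substreams for phases,
#'   jitter and injections.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(duration_h = 8,
                             base_bbi_ms = 850,
                             hf = list(freq_hz = 0.25, amp_ms = 30,
                                       amp_wander_period_s = 1700,
                                       amp_wander_frac = 0.5),
                             lf = list(freq_hz = 0.10, amp_ms = 45,
                                       amp_wander_period_s = 911,
                                       amp_wander_frac = 0.5),
                             slow_trend = list(amplitude_ms = 250,
                                               period_s = 2390),
                             jitter_sd_ms = 10,
                             ectopic_rate_per_h = 0,
                             outlier_rate_per_h = 0,
                             seed = 1) {
  defaults <- eval(formals(synthetic_config)$hf)
  hf <- utils::modifyList(defaults, hf)
  defaults <- eval(formals(synthetic_config)$lf)
  lf <- utils::modifyList(defaults, lf)
  defaults <- eval(formals(synthetic_config)$slow_trend)
  slow_trend <- utils::modifyList(defaults, slow_trend)
  stopifnot(duration_h > 0, base_bbi_ms > 0, jitter_sd_ms >= 0,
            ectopic_rate_per_h >= 0, outlier_rate_per_h >= 0,
            hf$amp_ms >= 0, lf$amp_ms >= 0, slow_trend$amplitude_ms >= 0,
            hf$amp_wander_frac >= 0, hf$amp_wander_frac < 1,
            lf$amp_wander_frac >= 0, lf$amp_wander_frac < 1)
  if (!(hf$freq_hz > 0.15 && hf$freq_hz < 0.40)) {
    stop("hf$freq_hz must lie inside the HF band (0.15, 0.40) Hz")
  }
  if (!(lf$freq_hz > 0.04 && lf$freq_hz < 0.15)) {
    stop("lf$freq_hz must lie inside the LF band (0.04, 0.15) Hz")
  }
  peak <- hf$amp_ms * (1 + hf$amp_wander_frac) +
    lf$amp_ms * (1 + lf$amp_wander_frac) + slow_trend$amplitude_ms
  if (base_bbi_ms - peak <= 0) {
    stop("modulation amplitudes (peak ", peak,
         " ms) exceed the base interval; intervals could become <= 0")
  }
  structure(
    list(duration_h = duration_h, base_bbi_ms = base_bbi_ms, hf = hf,
         lf = lf, slow_trend = slow_trend, jitter_sd_ms = jitter_sd_ms,
         ectopic_rate_per_h = ectopic_rate_per_h,
         outlier_rate_per_h = outlier_rate_per_h,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' Generate a synthetic beat-to-beat recording
#'
#' Beats are produced by the recursion `t[k+1] = t[k] + m(t[k])` with
#' `m(t) = base + trend(t) + A_lf(t) sin(2 pi f_lf t + phi_lf) +
#' A_hf(t) sin(2 pi f_hf t + phi_hf) + jitter`, evaluating the modulation at
#' the previous beat time.  This beat-by-beat form is a good approximation
#' of a fully integrated pulse-modulation model while modulation amplitudes
#' are small relative to the base interval.  All phases and noise draw from
#' substreams of `config$seed`, so runs are exactly reproducible and
#' injection draws do not perturb the underlying rhythm.
#'
#' When `ectopic_rate_per_h` or `outlier_rate_per_h` is positive the clean
#' series is passed through [inject_artifacts()] and the injection log is
#' attached as the `"injections"` attribute.
#'
#' @param config A [synthetic_config()].
#' @param recording_id Label; default derives from the seed.
#' @return A [beat_series].
#' @export
generate_recording <- function(config = synthetic_config(),
                               recording_id = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(recording_id)) {
    recording_id <- sprintf("synthetic-seed%d", config$seed)
  }
  set.seed(config$seed)
  sub <- sample.int(2147483646L, 3L)

  set.seed(sub[1L])
  ph <- stats::runif(5L, 0, 2 * pi)  # trend, lf carrier, hf carrier, wanders

  dur_ms <- config$duration_h * 3.6e6
  b <- config$base_bbi_ms
  hf <- config$hf; lf <- config$lf; tr <- config$slow_trend
  min_det <- b - (hf$amp_ms * (1 + hf$amp_wander_frac) +
                  lf$amp_ms * (1 + lf$amp_wander_frac) + tr$amplitude_ms)
  n_max <- ceiling(dur_ms / max(min_det * 0.5, 1)) + 16L

  set.seed(sub[2L])
  eps <- if (config$jitter_sd_ms > 0) {
    stats::rnorm(n_max, 0, config$jitter_sd_ms)
  } else numeric(n_max)

  t <- numeric(n_max + 1L)
  tk <- 0
  k <- 0L
  w_tr <- 2 * pi / tr$period_s
  w_lfa <- 2 * pi / lf$amp_wander_period_s
  w_hfa <- 2 * pi / hf$amp_wander_period_s
  w_lf <- 2 * pi * lf$freq_hz
  w_hf <- 2 * pi * hf$freq_hz
  while (tk < dur_ms) {
    ts <- tk / 1000
    a_lf <- lf$amp_ms * (1 + lf$amp_wander_frac * sin(w_lfa * ts + ph[4L]))
    a_hf <- hf$amp_ms * (1 + hf$amp_wander_frac * sin(w_hfa * ts + ph[5L]))
    m <- b + tr$amplitude_ms * sin(w_tr * ts + ph[1L]) +
      a_lf * sin(w_lf * ts + ph[2L]) +
      a_hf * sin(w_hf * ts + ph[3L]) +
      eps[k + 1L]
    if (m <= 0) {
      stop("configuration produced a non-positive interval at t = ",
           round(ts), " s; reduce amplitudes or jitter")
    }
    k <- k + 1L
    tk <- tk + m
    t[k + 1L] <- tk
  }
  series <- beat_series(beat_times = t[seq_len(k + 1L)],
                        recording_id = recording_id)
  if (config$ectopic_rate_per_h > 0 || config$outlier_rate_per_h > 0) {
    series <- inject_artifacts(series, config$ectopic_rate_per_h,
                               config$outlier_rate_per_h, seed = sub[3L])
  }
  series
}

#' Inject ectopic beats and out-of-range outliers into a recording
#'
#' At seeded random BBI positions (Poisson counts given the per-hour rates,
#' positions at least 3 BBIs apart):
#' \itemize{
#'   \item an ectopic event replaces `bbi[i]` by `0.6 * bbi[i]` and adds the
#'     removed `0.4 * bbi[i]` to `bbi[i + 1]` -- a premature beat followed by
#'     a compensatory pause, preserving cumulative time so later beats (and
#'     segment grids) are unaffected;
#'   \item an outlier replaces `bbi[i]` by a draw from outside the 400--1500
#'     ms plausible range (uniform on 150--390 or 1600--2600 ms), shifting
#'     subsequent beat times.
#' }
#'
#' @param series A [beat_series].
#' @param ectopic_rate_per_h,outlier_rate_per_h Expected events per hour.
#' @param seed Integer seed for counts, positions and outlier values.
#' @param max_retries Re-draw budget for overlapping positions.
#' @return A [beat_series] with an `"injections"` attribute: a data frame
#'   with `type`, `bbi_index`, `original_ms`, `injected_ms`.
#' @export
inject_artifacts <- function(series, ectopic_rate_per_h = 0,
                             outlier_rate_per_h = 0, seed = 1,
                             max_retries = 1000L) {
  stopifnot(inherits(series, "beat_series"),
            ectopic_rate_per_h >= 0, outlier_rate_per_h >= 0)
  hours <- duration_ms(series) / 3.6e6
  set.seed(seed)
  n_ect <- stats::rpois(1L, ectopic_rate_per_h * hours)
  n_out <- stats::rpois(1L, outlier_rate_per_h * hours)
  if (n_ect + n_out == 0L) {
    attr(series, "injections") <- data.frame(
      type = character(0), bbi_index = integer(0),
      original_ms = numeric(0), injected_ms = numeric(0),
      stringsAsFactors = FALSE)
    return(series)
  }
  n <- length(series$bbis)
  if (n < 10L) stop("series too short for artifact injection")

  taken <- logical(n)
  draw_pos <- function(lo, hi) {
    for (r in seq_len(max_retries)) {
      i <- sample(lo:hi, 1L)
      win <- max(1L, i - 2L):min(n, i + 2L)
      if (!any(taken[win])) {
        taken[win] <<- TRUE
        return(i)
      }
    }
    stop("could not place injection without overlap after ",
         max_retries, " retries")
  }
  # ectopics need a reference before and a compensatory BBI after
  ect_pos <- if (n_ect > 0L) {
    vapply(seq_len(n_ect), function(...) draw_pos(2L, n - 1L), 1L)
  } else integer(0)
  out_pos <- if (n_out > 0L) {
    vapply(seq_len(n_out), function(...) draw_pos(2L, n - 1L), 1L)
  } else integer(0)

  bbis <- series$bbis
  log <- list()
  for (i in ect_pos) {
    b0 <- bbis[i]
    bbis[i] <- 0.6 * b0
    bbis[i + 1L] <- bbis[i + 1L] + 0.4 * b0
    log[[length(log) + 1L]] <- data.frame(
      type = "ectopic", bbi_index = i, original_ms = b0,
      injected_ms = 0.6 * b0, stringsAsFactors = FALSE)
  }
  for (i in out_pos) {
    b0 <- bbis[i]
    val <- if (stats::runif(1L) < 0.5) stats::runif(1L, 150, 390)
           else stats::runif(1L, 1600, 2600)
    bbis[i] <- val
    log[[length(log) + 1L]] <- data.frame(
      type = "outlier", bbi_index = i, original_ms = b0,
      injected_ms = val, stringsAsFactors = FALSE)
  }
  out <- beat_series(beat_times = series$beat_times[1L] + c(0, cumsum(bbis)),
                     recording_id = series$recording_id)
  log <- do.call(rbind, log)
  attr(out, "injections") <- log[order(log$bbi_index), , drop = FALSE]
  out
}

#' Parameter-recovery sweep for the synthetic generator
#'
#' Two sweeps validating that HRV metrics recover generator parameters:
#' (a) HF power as a function of HF modulation amplitude (everything else at
#' the base configuration), where estimated HF power should grow with the
#' squared amplitude; and (b) RMSSD as a function of white jitter SD with all
#' oscillatory modulation off, where IID theory predicts RMSSD close to
#' `sqrt(2) * sd`.  Each generated recording is screened and segmented and
#' the metric set averaged over the selected 5-minute windows.
#'
#' @param hf_amp_grid HF amplitudes (ms) for sweep (a); >= 3 values.
#' @param jitter_grid Jitter SDs (ms) for sweep (b).
#' @param seeds Integer seeds; each grid point runs once per seed.
#' @param duration_h Recording length per run (default 1).
#' @param base_config Template [synthetic_config()].
#' @return Data frame with `sweep` ("hf_amp" or "jitter"), `hf_amp_ms`,
#'   `jitter_sd_ms`, `seed`, `n_segments`, and mean `rmssd_ms`, `sdnn_ms`,
#'   `lf_ms2`, `hf_ms2` over selected segments.
#' @export
parameter_recovery_suite <- function(hf_amp_grid = c(10, 30, 50),
                                     jitter_grid = c(5, 20),
                                     seeds = 1:3,
                                     duration_h = 1,
                                     base_config = synthetic_config()) {
  stopifnot(length(hf_amp_grid) >= 3L)
  run_one <- function(cfg) {
    series <- generate_recording(cfg)
    mask <- build_mask(series)
    segs <- select_hourly(scan_clean_segments(series, mask))
    if (length(segs) == 0L) {
      return(c(n_segments = 0, rmssd_ms = NA, sdnn_ms = NA,
               lf_ms2 = NA, hf_ms2 = NA))
    }
    m <- lapply(segs, compute_metrics, warn_resolution = FALSE)
    c(n_segments = length(segs),
      rmssd_ms = mean(vapply(m, `[[`, 0, "rmssd_ms")),
      sdnn_ms = mean(vapply(m, `[[`, 0, "sdnn_ms")),
      lf_ms2 = mean(vapply(m, `[[`, 0, "lf_ms2")),
      hf_ms2 = mean(vapply(m, `[[`, 0, "hf_ms2")))
  }
  rows <- list()
  for (a in hf_amp_grid) {
    for (s in seeds) {
      cfg <- base_config
      cfg$hf$amp_ms <- a
      cfg$duration_h <- duration_h
      cfg$seed <- as.integer(s)
      cfg <- do.call(synthetic_config, unclass(cfg))
      rows[[length(rows) + 1L]] <- data.frame(
        sweep = "hf_amp", hf_amp_ms = a,
        jitter_sd_ms = cfg$jitter_sd_ms, seed = s,
        t(run_one(cfg)), stringsAsFactors = FALSE)
    }
  }
  for (j in jitter_grid) {
    for (s in seeds) {
      cfg <- base_config
      cfg$duration_h <- duration_h
      cfg$seed <- as.integer(s)
      cfg$jitter_sd_ms <- j
      cfg$hf$amp_ms <- 0
      cfg$lf$amp_ms <- 0
      cfg$slow_trend$amplitude_ms <- 0
      cfg <- do.call(synthetic_config, unclass(cfg))
      rows[[length(rows) + 1L]] <- data.frame(
        sweep = "jitter", hf_amp_ms = 0, jitter_sd_ms = j, seed = s,
        t(run_one(cfg)), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
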