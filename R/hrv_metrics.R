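#' Spectral estimation settings for LF/HF band power
#'
#' The LF band spans 0.04--0.15 Hz and the HF (respiratory) band
#' 0.15--0.40 Hz; band power is reported in absolute units (ms^2).  The
#' default estimator resamples the tachogram with a cubic spline at 4 Hz and
#' applies Welch's method (Hann window, 256-sample segments, 50% overlap,
#' mean detrend).  A Lomb-Scargle estimator operating directly on the uneven
#' (beat time, BBI) points is available as a robustness alternative.
#'
#' @param lf_band,hf_band Numeric length-2 band edges in Hz.
#' @param resample_hz Tachogram resampling rate for the Welch path.
#' @param estimator `"welch"` or `"lomb_scargle"`.
#' @param seg_len_samples Welch segment length (capped at the series length).
#' @param overlap_frac Welch segment overlap fraction in [0, 1).
#' @param detrend `"mean"` (subtract the window mean) or `"none"`.
#' @return An object of class `spectral_config`.
#' @export
spectral_config <- function(lf_band = c(0.04, 0.15),
                            hf_band = c(0.15, 0.40),
                            resample_hz = 4,
                            estimator = c("welch", "lomb_scargle"),
                            seg_len_samples = 256,
                            overlap_frac = 0.5,
                            detrend = c("mean", "none")) {
  estimator <- match.arg(estimator)
  detrend <- match.arg(detrend)
  stopifnot(length(lf_band) == 2L, length(hf_band) == 2L,
            all(lf_band > 0), all(hf_band > 0),
            lf_band[1] < lf_band[2], hf_band[1] < hf_band[2],
            resample_hz > 0, seg_len_samples >= 8,
            overlap_frac >= 0, overlap_frac < 1)
  if (lf_band[2] != hf_band[1]) {
    stop("LF upper edge must equal HF lower edge (contiguous bands)")
  }
  structure(
    list(lf_band = lf_band, hf_band = hf_band, resample_hz = resample_hz,
         estimator = estimator, seg_len_samples = seg_len_samples,
         overlap_frac = overlap_frac, detrend = detrend),
    class = "spectral_config"
  )
}

#' Root mean square of successive BBI differences
#'
#' Short-term, parasympathetically dominated time-domain HRV metric:
#' `sqrt(mean(diff(bbis)^2))` over the n - 1 successive differences.
#'
#' @param bbis Numeric vector of BBIs in ms, length >= 2.
#' @return RMSSD in ms.
#' @examples
#' rmssd(c(800, 810, 790))  # sqrt((10^2 + 20^2) / 2)
#' @export
rmssd <- function(bbis) {
  if (!is.numeric(bbis) || length(bbis) < 2L) {
    stop("RMSSD undefined: need at least 2 BBIs")
  }
  sqrt(mean(diff(bbis)^2))
}

#' Standard deviation of NN intervals
#'
#' Total-variability time-domain metric: the sample standard deviation of the
#' BBIs (n - 1 divisor), sensitive to slow trends as well as fast
#' oscillations.
#'
#' @param bbis Numeric vector of BBIs in ms, length >= 2.
#' @return SDNN in ms.
#' @export
sdnn <- function(bbis) {
  if (!is.numeric(bbis) || length(bbis) < 2L) {
    stop("SDNN undefined: need at least 2 BBIs")
  }
  stats::sd(bbis)
}

#' Evenly resampled tachogram of a segment
#'
#' Interpolates the (beat time, BBI) points of a segment -- each BBI placed
#' at the time of the beat that ends it -- onto a uniform grid with a cubic
#' spline.  The result is the signal whose power spectrum defines LF and HF.
#'
#' @param segment An [rr_segment()] with at least 4 BBIs inside the window.
#' @param resample_hz Grid rate in Hz (default 4).
#' @param detrend `"mean"` removes the grid mean (stored in the `"mean_ms"`
#'   attribute); `"none"` keeps raw values.
#' @return List with `t_ms` (grid times), `bbi_ms` (interpolated values) and
#'   `fs_hz`.
#' @export
tachogram <- function(segment, resample_hz = 4,
                      detrend = c("mean", "none")) {
  detrend <- match.arg(detrend)
  stopifnot(inherits(segment, "rr_segment"))
  bi <- segment_bbi_idx(segment)
  if (length(bi) < 4L) {
    stop("tachogram undefined: segment has ", length(bi), " BBIs (< 4)")
  }
  x <- segment$series$beat_times[bi + 1L]   # BBI anchored at its end beat
  y <- segment$series$bbis[bi]
  n <- round(segment$duration_s * resample_hz)
  grid <- segment$start_ms + (seq_len(n) - 1) * (1000 / resample_hz)
  vals <- stats::spline(x, y, xout = grid, method = "fmm")$y
  # constant extension outside the anchor range: cubic extrapolation over
  # the fraction of a beat at the window edges can ring wildly
  vals[grid < x[1L]] <- y[1L]
  vals[grid > x[length(x)]] <- y[length(y)]
  m <- mean(vals)
  if (detrend == "mean") vals <- vals - m
  structure(list(t_ms = grid, bbi_ms = vals, fs_hz = resample_hz),
            mean_ms = m)
}

# Welch one-sided PSD: Hann window, per-segment mean detrend, densities in
# ms^2/Hz so that sum(psd) * df recovers the signal variance.
welch_psd <- function(x, fs, seg_len = 256, overlap_frac = 0.5) {
  n <- length(x)
  L <- min(seg_len, n)
  step <- max(1L, floor(L * (1 - overlap_frac)))
  starts <- seq(1L, n - L + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(L - 1)) / L)   # periodic Hann
  u <- sum(w^2)
  nf <- floor(L / 2) + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + L - 1L)]
    seg <- (seg - mean(seg)) * w
    p <- Mod(stats::fft(seg))^2
    acc <- acc + p[seq_len(nf)]
  }
  psd <- acc / (length(starts) * fs * u)
  scale2 <- rep(2, nf)
  scale2[1L] <- 1
  if (L %% 2 == 0) scale2[nf] <- 1
  list(freq = (seq_len(nf) - 1) * fs / L, psd = psd * scale2)
}

# Classical Lomb-Scargle periodogram on uneven samples (t in seconds, y
# demeaned internally), evaluated on an oversampled grid and rescaled so its
# integral over the grid equals the sample variance -- giving a density
# comparable, band-by-band, to the Welch estimate.
lomb_scargle_psd <- function(t_s, y, oversample = 4, f_max = NULL) {
  y <- y - mean(y)
  T <- diff(range(t_s))
  n <- length(y)
  if (is.null(f_max)) f_max <- min(2, n / (2 * T))  # mean-rate Nyquist cap
  df <- 1 / (oversample * T)
  freq <- seq(df, f_max, by = df)
  p <- numeric(length(freq))
  for (k in seq_along(freq)) {
    w <- 2 * pi * freq[k]
    tau <- atan2(sum(sin(2 * w * t_s)), sum(cos(2 * w * t_s))) / (2 * w)
    ct <- cos(w * (t_s - tau))
    st <- sin(w * (t_s - tau))
    p[k] <- 0.5 * (sum(y * ct)^2 / sum(ct^2) + sum(y * st)^2 / sum(st^2))
  }
  v <- sum(y^2) / n
  tot <- sum(p) * df
  psd <- if (tot > 0) p * (v / tot) else p
  list(freq = freq, psd = psd)
}

# trapezoidal band integral with linear interpolation at the band edges
band_integral <- function(freq, psd, lo, hi) {
  if (hi <= freq[1L] || lo >= freq[length(freq)]) return(0)
  lo <- max(lo, freq[1L])
  hi <- min(hi, freq[length(freq)])
  inside <- freq > lo & freq < hi
  f <- c(lo, freq[inside], hi)
  v <- c(stats::approx(freq, psd, xout = lo)$y, psd[inside],
         stats::approx(freq, psd, xout = hi)$y)
  sum(diff(f) * (utils::head(v, -1) + utils::tail(v, -1)) / 2)
}

#' LF and HF band power of a segment
#'
#' Estimates the power spectral density of the segment's tachogram and
#' integrates it over the LF and HF bands (trapezoid rule, ms^2).  With the
#' Welch estimator the tachogram is spline-resampled first; the Lomb-Scargle
#' estimator works on the uneven (beat time, BBI) points directly.
#'
#' A 60 s window covers only 2.4 periods of the 0.04 Hz LF lower edge, too
#' few for a stable estimate of the full band; the value is still computed
#' (the convention in ultra-short-term HRV work) and a warning is emitted
#' whenever the window covers fewer than 5 lower-edge periods, unless
#' `warn_resolution = FALSE`.
#'
#' @param segment An [rr_segment()].
#' @param config A [spectral_config()].
#' @param warn_resolution Warn when the window is too short to resolve the
#'   LF lower edge.
#' @return Named numeric vector `c(lf_ms2 = , hf_ms2 = )`.
#' @export
band_power <- function(segment, config = spectral_config(),
                       warn_resolution = TRUE) {
  stopifnot(inherits(segment, "rr_segment"),
            inherits(config, "spectral_config"))
  if (warn_resolution &&
      lf_period_coverage(segment$duration_s, config$lf_band[1]) < 5) {
    warning(sprintf(
      "window of %g s covers only %.2f periods of the %g Hz LF lower edge; LF is reported but under-resolved",
      segment$duration_s, segment$duration_s * config$lf_band[1],
      config$lf_band[1]))
  }
  if (config$estimator == "welch") {
    tg <- tachogram(segment, config$resample_hz, detrend = config$detrend)
    sp <- welch_psd(tg$bbi_ms, tg$fs_hz, config$seg_len_samples,
                    config$overlap_frac)
  } else {
    bi <- segment_bbi_idx(segment)
    if (length(bi) < 4L) stop("band power undefined: fewer than 4 BBIs")
    t_s <- segment$series$beat_times[bi + 1L] / 1000
    y <- segment$series$bbis[bi]
    sp <- lomb_scargle_psd(t_s, y)
  }
  c(lf_ms2 = band_integral(sp$freq, sp$psd, config$lf_band[1],
                           config$lf_band[2]),
    hf_ms2 = band_integral(sp$freq, sp$psd, config$hf_band[1],
                           config$hf_band[2]))
}

#' Compute the HRV metric set for one segment
#'
#' Assembles RMSSD, SDNN, LF and HF with window metadata.  The identical code
#' path serves 300 s and 60 s windows, so a first-minute window analysed via
#' [extract_first_minute()] yields exactly what direct analysis of that 60 s
#' window yields.  Frequency-domain metrics are `NA` (never zero) when the
#' window holds fewer than 4 BBIs.
#'
#' @param segment An [rr_segment()].
#' @param config A [spectral_config()].
#' @param warn_resolution Passed to [band_power()].
#' @return An object of class `hrv_metrics`: a list with `recording_id`,
#'   `start_ms`, `duration_s`, `n_bbis`, `rmssd_ms`, `sdnn_ms`, `lf_ms2`,
#'   `hf_ms2`.
#' @export
compute_metrics <- function(segment, config = spectral_config(),
                            warn_resolution = TRUE) {
  stopifnot(inherits(segment, "rr_segment"))
  bbis <- segment_bbis(segment)
  bp <- if (length(bbis) >= 4L) {
    band_power(segment, config, warn_resolution)
  } else {
    c(lf_ms2 = NA_real_, hf_ms2 = NA_real_)
  }
  structure(
    list(recording_id = segment$series$recording_id,
         start_ms = segment$start_ms,
         duration_s = segment$duration_s,
         n_bbis = length(bbis),
         rmssd_ms = rmssd(bbis),
         sdnn_ms = sdnn(bbis),
         lf_ms2 = unname(bp["lf_ms2"]),
         hf_ms2 = unname(bp["hf_ms2"])),
    class = "hrv_metrics"
  )
}

#' @export
as.data.frame.hrv_metrics <- function(x, ...) {
  data.frame(recording_id = x$recording_id, start_ms = x$start_ms,
             duration_s = x$duration_s, n_bbis = x$n_bbis,
             rmssd_ms = x$rmssd_ms, sdnn_ms = x$sdnn_ms,
             lf_ms2 = x$lf_ms2, hf_ms2 = x$hf_ms2,
             stringsAsFactors = FALSE)
}

#' @export
print.hrv_metrics <- function(x, ...) {
  cat(sprintf("<hrv_metrics> %s @ %g ms (%g s, %d BBIs)\n",
              x$recording_id, x$start_ms, x$duration_s, x$n_bbis))
  cat(sprintf("  RMSSD %.2f ms, SDNN %.2f ms, LF %.1f ms^2, HF %.1f ms^2\n",
              x$rmssd_ms, x$sdnn_ms, x$lf_ms2, x$hf_ms2))
  invisible(x)
}

#' How many LF periods fit in a window
#'
#' The lower LF band edge (0.04 Hz) has a 25 s period, so a 60 s window
#' covers only 2.4 periods -- the structural reason ultra-short LF estimates
#' are noisy.  Returns `window_s * lf_low_hz`.
#'
#' @param window_s Window length in seconds.
#' @param lf_low_hz Lower band edge in Hz (default 0.04).
#' @return Dimensionless period count.
#' @examples
#' lf_period_coverage(60)    # 2.4
#' lf_period_coverage(300)   # 12
#' @export
lf_period_coverage <- function(window_s, lf_low_hz = 0.04) {
  stopifnot(window_s > 0, lf_low_hz > 0)
  window_s * lf_low_hz
}
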