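#' Pearson product-moment correlation
#'
#' Thin validated wrapper used for 1-min vs 5-min metric agreement.  Constant
#' input is an error (agreement is undefined), never silently zero.
#'
#' @param x,y Equal-length numeric vectors, length >= 3, both nonconstant.
#' @return Correlation coefficient in [-1, 1].
#' @export
pearson_r <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y)) stop("inputs must be numeric")
  if (length(x) != length(y)) {
    stop("length mismatch: ", length(x), " vs ", length(y))
  }
  if (length(x) < 3L) stop("need at least 3 pairs")
  if (anyNA(x) || anyNA(y)) stop("missing values in correlation input")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for constant input")
  }
  stats::cor(x, y)
}

#' Categorise a correlation coefficient
#'
#' Agreement categories for method-comparison correlations: `excellent` for
#' r >= 0.9, `good` for 0.7 <= r < 0.9, `moderate` for 0.4 <= r < 0.7 and
#' `low` for r < 0.4.  Bins are half-open and exhaustive; negative r falls in
#' `low` (no absolute value is taken).
#'
#' @param r Numeric vector of correlations in [-1, 1].
#' @return Character vector of categories.
#' @export
categorize_correlation <- function(r) {
  if (!is.numeric(r) || anyNA(r)) stop("r must be numeric without NA")
  if (any(r < -1 | r > 1)) stop("r outside [-1, 1]")
  out <- character(length(r))
  out[r < 0.4] <- "low"
  out[r >= 0.4 & r < 0.7] <- "moderate"
  out[r >= 0.7 & r < 0.9] <- "good"
  out[r >= 0.9] <- "excellent"
  out
}

#' Pipeline configuration
#'
#' Bundles the artifact rules, segmentation settings and spectral settings
#' consumed by [run_concordance_study()].
#'
#' @param outlier An [outlier_rule()].
#' @param ectopic An [ectopic_rule()].
#' @param duration_s Long window length, seconds (default 300).
#' @param short_duration_s Short window length, seconds (default 60; must
#'   currently be 60, the first minute).
#' @param step_ms Candidate grid step for [scan_clean_segments()].
#' @param spacing_min Start-to-start spacing for [select_hourly()].
#' @param spectral A [spectral_config()].
#' @return An object of class `concord_config`.
#' @export
concord_config <- function(outlier = outlier_rule(),
                           ectopic = ectopic_rule(),
                           duration_s = 300,
                           short_duration_s = 60,
                           step_ms = 60000,
                           spacing_min = 60,
                           spectral = spectral_config()) {
  stopifnot(inherits(outlier, "outlier_rule"),
            inherits(ectopic, "ectopic_rule"),
            inherits(spectral, "spectral_config"),
            duration_s > 0, step_ms > 0, spacing_min > 0)
  if (short_duration_s != 60 || duration_s != 300) {
    # the agreement design is 1 min vs 5 min; other pairs are untested
    warning("non-standard window pair (", short_duration_s, " s vs ",
            duration_s, " s)")
  }
  structure(
    list(outlier = outlier, ectopic = ectopic, duration_s = duration_s,
         short_duration_s = short_duration_s, step_ms = step_ms,
         spacing_min = spacing_min, spectral = spectral),
    class = "concord_config"
  )
}

hrv_metric_names <- c("rmssd_ms", "sdnn_ms", "lf_ms2", "hf_ms2")

#' Run the 1-min vs 5-min HRV concordance study
#'
#' End-to-end pipeline over one or more recordings: build the artifact mask,
#' scan for artifact-free 5-minute windows, greedily select at most one per
#' hour, compute the HRV metric set on each selected window and on its first
#' minute, then pool all pairs and compute one Pearson correlation (with
#' agreement category) per metric.  Pairing is structural: each 1-minute
#' value shares its window start with its 5-minute partner.
#'
#' @param recordings A [beat_series] or list of them.
#' @param config A [concord_config()].
#' @return An object of class `concordance_study` with components:
#'   \describe{
#'     \item{pairs}{Data frame, one row per (segment, metric):
#'       `recording_id`, `start_ms`, `metric`, `value_5min`, `value_1min`.}
#'     \item{results}{Data frame, one row per metric: `metric`, `pearson_r`,
#'       `category`, `n_pairs` (`NA` correlation when fewer than 3 pairs).}
#'     \item{report}{Per-recording segment counts, rules used, and notes.}
#'     \item{config}{The configuration used.}
#'   }
#' @seealso [coef.concordance_study()], [plot.concordance_study()]
#' @export
run_concordance_study <- function(recordings, config = concord_config()) {
  if (inherits(recordings, "beat_series")) recordings <- list(recordings)
  stopifnot(length(recordings) >= 1L,
            all(vapply(recordings, inherits, TRUE, "beat_series")),
            inherits(config, "concord_config"))

  pair_rows <- list()
  rec_report <- list()
  for (series in recordings) {
    mask <- build_mask(series, config$outlier, config$ectopic)
    candidates <- withCallingHandlers(
      scan_clean_segments(series, mask, config$duration_s, config$step_ms),
      warning = function(w) invokeRestart("muffleWarning"))
    selected <- select_hourly(candidates, config$spacing_min)
    for (seg in selected) {
      m5 <- compute_metrics(seg, config$spectral, warn_resolution = FALSE)
      m1 <- compute_metrics(extract_first_minute(seg), config$spectral,
                            warn_resolution = FALSE)
      pair_rows[[length(pair_rows) + 1L]] <- data.frame(
        recording_id = series$recording_id,
        start_ms = seg$start_ms,
        metric = hrv_metric_names,
        value_5min = unlist(m5[hrv_metric_names], use.names = FALSE),
        value_1min = unlist(m1[hrv_metric_names], use.names = FALSE),
        stringsAsFactors = FALSE)
    }
    rec_report[[series$recording_id]] <- list(
      recording_id = series$recording_id,
      duration_h = duration_ms(series) / 3.6e6,
      n_bbis = length(series$bbis),
      n_not_clean = sum(mask$labels != "clean"),
      n_candidates = length(candidates),
      n_selected = length(selected))
  }

  pairs <- if (length(pair_rows)) {
    do.call(rbind, pair_rows)
  } else {
    data.frame(recording_id = character(0), start_ms = numeric(0),
               metric = character(0), value_5min = numeric(0),
               value_1min = numeric(0), stringsAsFactors = FALSE)
  }

  results <- do.call(rbind, lapply(hrv_metric_names, function(mn) {
    sub <- pairs[pairs$metric == mn, , drop = FALSE]
    ok <- stats::complete.cases(sub[c("value_5min", "value_1min")])
    sub <- sub[ok, , drop = FALSE]
    r <- if (nrow(sub) >= 3L &&
             stats::sd(sub$value_5min) > 0 && stats::sd(sub$value_1min) > 0) {
      pearson_r(sub$value_5min, sub$value_1min)
    } else NA_real_
    data.frame(metric = mn, pearson_r = r,
               category = if (is.na(r)) NA_character_
                          else categorize_correlation(r),
               n_pairs = nrow(sub), stringsAsFactors = FALSE)
  }))

  structure(
    list(pairs = pairs, results = results,
         report = list(recordings = rec_report,
                       n_recordings = length(recordings),
                       n_segments = nrow(pairs) / length(hrv_metric_names),
                       config_digest = config_digest(config)),
         config = config),
    class = "concordance_study"
  )
}

# small stable digest of the configuration for run reports
config_digest <- function(config) {
  flat <- unlist(config, use.names = TRUE)
  txt <- paste(names(flat), as.character(flat), sep = "=", collapse = ";")
  sum(utf8ToInt(txt) * (seq_along(utf8ToInt(txt)) %% 251 + 1)) %% 1e9
}

#' @export
print.concordance_study <- function(x, digits = 3, ...) {
  cat("1-min vs 5-min HRV concordance study\n")
  cat(sprintf("  recordings: %d; selected 5-min segments: %d\n",
              x$report$n_recordings, x$report$n_segments))
  if (nrow(x$pairs) == 0L) {
    cat("  no artifact-free segments selected; no correlations computed\n")
    return(invisible(x))
  }
  res <- x$results
  res$pearson_r <- round(res$pearson_r, digits)
  print(res, row.names = FALSE)
  invisible(x)
}

#' @export
summary.concordance_study <- function(object, ...) {
  rec <- do.call(rbind, lapply(object$report$recordings, as.data.frame))
  structure(list(results = object$results, per_recording = rec),
            class = "summary.concordance_study")
}

#' @export
print.summary.concordance_study <- function(x, ...) {
  cat("Per-metric agreement (pooled pairs):\n")
  print(x$results, row.names = FALSE)
  cat("\nPer-recording segment yield:\n")
  print(x$per_recording, row.names = FALSE)
  invisible(x)
}

#' Extract the per-metric correlation coefficients
#' @param object A `concordance_study`.
#' @param ... Unused.
#' @return Named numeric vector of Pearson r, one per metric.
#' @export
coef.concordance_study <- function(object, ...) {
  stats::setNames(object$results$pearson_r, object$results$metric)
}

#' Scatter plots of 1-min vs 5-min metric values
#'
#' One panel per metric with the identity line; tight clustering around the
#' line indicates that the 1-minute window preserves the 5-minute value.
#'
#' @param x A `concordance_study`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.concordance_study <- function(x, ...) {
  if (nrow(x$pairs) == 0L) stop("nothing to plot: no pairs")
  old <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2.5, 1))
  on.exit(graphics::par(old))
  for (mn in hrv_metric_names) {
    sub <- x$pairs[x$pairs$metric == mn, , drop = FALSE]
    r <- x$results$pearson_r[x$results$metric == mn]
    graphics::plot(sub$value_5min, sub$value_1min,
                   xlab = paste(mn, "(5 min)"), ylab = paste(mn, "(1 min)"),
                   main = sprintf("%s  r = %.2f", mn, r), ...)
    graphics::abline(0, 1, lty = 2, col = "grey40")
  }
  invisible(x)
}
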