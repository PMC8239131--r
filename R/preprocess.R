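#' Outlier rule: physiologically plausible BBI range
#'
#' BBIs outside `[low_ms, high_ms]` are classified as outliers.  The default
#' range 400--1500 ms corresponds to heart rates above 150 or below 40 beats
#' per minute; the bounds themselves are inclusive-clean (a 400 ms or 1500 ms
#' BBI is not an outlier).
#'
#' @param low_ms,high_ms Range bounds in ms, `0 < low_ms < high_ms`.
#' @return An object of class `outlier_rule`.
#' @export
outlier_rule <- function(low_ms = 400, high_ms = 1500) {
  stopifnot(is.numeric(low_ms), is.numeric(high_ms), length(low_ms) == 1L,
            length(high_ms) == 1L)
  if (!(low_ms > 0 && low_ms < high_ms)) {
    stop("need 0 < low_ms < high_ms")
  }
  structure(list(low_ms = low_ms, high_ms = high_ms), class = "outlier_rule")
}

#' Ectopic rule: Malik-style relative-difference criterion
#'
#' A BBI is flagged as ectopic when it differs from the most recent accepted
#' (non-ectopic, non-outlier) BBI by more than `rel_threshold` of that
#' reference value.  This is the de facto default criterion for NN-interval
#' screening; the threshold is configurable.
#'
#' @param method Currently only `"malik_relative"`.
#' @param rel_threshold Relative-difference threshold, in (0, 1).
#' @return An object of class `ectopic_rule`.
#' @export
ectopic_rule <- function(method = "malik_relative", rel_threshold = 0.20) {
  method <- match.arg(method)
  if (!(is.numeric(rel_threshold) && length(rel_threshold) == 1L &&
        rel_threshold > 0 && rel_threshold < 1)) {
    stop("rel_threshold must be a single value in (0, 1)")
  }
  structure(list(method = method, rel_threshold = rel_threshold),
            class = "ectopic_rule")
}

#' Detect out-of-range BBIs
#'
#' @param series A [beat_series].
#' @param rule An [outlier_rule()].
#' @return Sorted integer vector of BBI indices with `bbi < low_ms` or
#'   `bbi > high_ms`.
#' @examples
#' detect_outliers(beat_series(bbis = c(800, 390, 800)))  # 2
#' @export
detect_outliers <- function(series, rule = outlier_rule()) {
  stopifnot(inherits(series, "beat_series"), inherits(rule, "outlier_rule"))
  which(series$bbis < rule$low_ms | series$bbis > rule$high_ms)
}

#' Convert a BBI to an instantaneous heart rate
#'
#' @param bbi_ms Beat-to-beat interval(s) in ms, all > 0.
#' @return Heart rate in beats per minute, `60000 / bbi_ms`.  The default
#'   outlier bounds map to the round figures 400 ms -> 150 BPM and
#'   1500 ms -> 40 BPM.
#' @export
bbi_to_heart_rate <- function(bbi_ms) {
  if (!is.numeric(bbi_ms) || any(!is.finite(bbi_ms)) || any(bbi_ms <= 0)) {
    stop("bbi_ms must be positive and finite")
  }
  60000 / bbi_ms
}

#' Detect ectopic BBIs
#'
#' Applies the Malik-style relative criterion: scanning left to right,
#' `bbi[i]` is ectopic when it deviates from the most recent accepted BBI by
#' more than the rule's threshold.  Accepted means neither ectopic nor an
#' outlier under `out_rule`; outliers never serve as the reference and are
#' never themselves labelled ectopic (outlier classification takes
#' precedence).  The first in-range BBI seeds the reference and is never
#' ectopic.
#'
#' @param series A [beat_series] with at least 2 BBIs.
#' @param rule An [ectopic_rule()].
#' @param out_rule The [outlier_rule()] identifying BBIs to skip, both as
#'   candidates and as references.
#' @return Sorted integer vector of ectopic BBI indices.
#' @examples
#' detect_ectopic(beat_series(bbis = c(800, 1000, 800)))  # 2
#' @export
detect_ectopic <- function(series, rule = ectopic_rule(),
                           out_rule = outlier_rule()) {
  stopifnot(inherits(series, "beat_series"), inherits(rule, "ectopic_rule"))
  bbis <- series$bbis
  if (length(bbis) < 2L) {
    warning("fewer than 2 BBIs; no ectopic detection possible")
    return(integer(0))
  }
  is_outlier <- bbis < out_rule$low_ms | bbis > out_rule$high_ms
  thr <- rule$rel_threshold
  ect <- logical(length(bbis))
  ref <- NA_real_
  for (i in seq_along(bbis)) {
    if (is_outlier[i]) next
    if (is.na(ref)) {           # first in-range BBI seeds the reference
      ref <- bbis[i]
      next
    }
    if (abs(bbis[i] - ref) > thr * ref) {
      ect[i] <- TRUE
    } else {
      ref <- bbis[i]
    }
  }
  which(ect)
}

#' Build the artifact mask for a beat series
#'
#' Labels every BBI as `clean`, `outlier`, or `ectopic`.  Outlier
#' classification takes precedence when both rules would fire on the same
#' BBI.  The mask only labels; BBIs are never removed, because deleting beats
#' would change the statistics of any window containing them -- clean
#' analysis windows are instead selected downstream.
#'
#' @param series A [beat_series].
#' @param out_rule An [outlier_rule()].
#' @param ect_rule An [ectopic_rule()].
#' @return An object of class `artifact_mask` with fields `labels` (character
#'   vector aligned to `series$bbis`), `outlier_rule` and `ectopic_rule`.
#' @export
build_mask <- function(series, out_rule = outlier_rule(),
                       ect_rule = ectopic_rule()) {
  stopifnot(inherits(series, "beat_series"))
  labels <- rep("clean", length(series$bbis))
  labels[detect_ectopic(series, ect_rule, out_rule)] <- "ectopic"
  labels[detect_outliers(series, out_rule)] <- "outlier"
  structure(
    list(labels = labels, outlier_rule = out_rule, ectopic_rule = ect_rule,
         recording_id = series$recording_id),
    class = "artifact_mask"
  )
}

#' @export
print.artifact_mask <- function(x, ...) {
  tab <- table(factor(x$labels, levels = c("clean", "outlier", "ectopic")))
  cat("<artifact_mask> ", x$recording_id, "\n", sep = "")
  cat(sprintf("  %d BBIs: %d clean, %d outlier, %d ectopic\n",
              length(x$labels), tab[["clean"]], tab[["outlier"]],
              tab[["ectopic"]]))
  cat(sprintf("  outlier bounds [%g, %g] ms; ectopic %s @ %.2f\n",
              x$outlier_rule$low_ms, x$outlier_rule$high_ms,
              x$ectopic_rule$method, x$ectopic_rule$rel_threshold))
  invisible(x)
}
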