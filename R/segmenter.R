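#' Construct an analysis window over a beat series
#'
#' A segment is a half-open time window `[start_ms, start_ms + 1000 *
#' duration_s)` into a parent [beat_series].  A BBI "falls inside" the window
#' iff both of its beat endpoints do; only those BBIs enter metric
#' computations, so windows are unambiguous even when a BBI straddles an
#' edge.
#'
#' @param series Parent [beat_series].
#' @param start_ms Window start, ms from recording start.
#' @param duration_s Window length in seconds (300 for the standard window,
#'   60 for its first minute).
#' @return An object of class `rr_segment` with fields `series`, `start_ms`,
#'   `end_ms`, `duration_s` and `beat_idx` (indices of beats inside the
#'   window).
#' @export
rr_segment <- function(series, start_ms, duration_s) {
  stopifnot(inherits(series, "beat_series"),
            is.numeric(start_ms), length(start_ms) == 1L, start_ms >= 0,
            is.numeric(duration_s), length(duration_s) == 1L, duration_s > 0)
  end_ms <- start_ms + duration_s * 1000
  idx <- beats_in_window(series$beat_times, start_ms, end_ms)
  if (length(idx) < 2L) {
    stop("window [", start_ms, ", ", end_ms,
         ") contains fewer than 2 beats; no BBI exists")
  }
  structure(
    list(series = series, start_ms = start_ms, end_ms = end_ms,
         duration_s = duration_s, beat_idx = idx),
    class = "rr_segment"
  )
}

# indices i with start <= t[i] < end (t sorted ascending)
beats_in_window <- function(t, start_ms, end_ms) {
  i1 <- findInterval(start_ms, t, left.open = TRUE) + 1L
  i2 <- findInterval(end_ms, t, left.open = TRUE)
  if (i2 < i1) integer(0) else i1:i2
}

#' Indices of the BBIs fully inside a segment
#'
#' @param segment An [rr_segment()].
#' @return Integer indices into `segment$series$bbis`; BBI `i` is included
#'   iff beats `i` and `i + 1` both lie in the window.
#' @export
segment_bbi_idx <- function(segment) {
  stopifnot(inherits(segment, "rr_segment"))
  idx <- segment$beat_idx
  idx[-length(idx)]
}

#' BBI values fully inside a segment
#' @param segment An [rr_segment()].
#' @return Numeric vector of BBIs, ms.
#' @export
segment_bbis <- function(segment) {
  segment$series$bbis[segment_bbi_idx(segment)]
}

#' @export
print.rr_segment <- function(x, ...) {
  cat(sprintf("<rr_segment> %s [%g, %g) ms (%g s, %d beats)\n",
              x$series$recording_id, x$start_ms, x$end_ms, x$duration_s,
              length(x$beat_idx)))
  invisible(x)
}

#' Scan a recording for artifact-free windows
#'
#' Slides a window of `duration_s` seconds over the recording on a start-time
#' grid of `step_ms` (anchored at 0) and keeps every window in which all
#' fully contained BBIs are labelled clean in `mask` and whose clean BBI
#' count reaches `min_beats`.  Windows are clipped to the recording extent:
#' no partial windows are emitted.
#'
#' @param series A [beat_series].
#' @param mask An [build_mask()] result aligned to `series`.
#' @param duration_s Window length, seconds (default 300).
#' @param step_ms Grid step between candidate window starts (default 60000).
#' @param min_beats Minimum number of BBIs inside a qualifying window.  The
#'   default, `floor(0.4 * duration_s)` (120 for a 5-minute window), is a
#'   guard against malformed masks: any truly clean window already holds at
#'   least one beat per 1.5 s under the 1500 ms clean upper bound.
#' @return List of [rr_segment()] in increasing start order (possibly empty).
#' @export
scan_clean_segments <- function(series, mask, duration_s = 300,
                                step_ms = 60000,
                                min_beats = floor(0.4 * duration_s)) {
  stopifnot(inherits(series, "beat_series"), inherits(mask, "artifact_mask"))
  if (length(mask$labels) != length(series$bbis)) {
    stop("mask is not aligned to the series (",
         length(mask$labels), " labels vs ", length(series$bbis), " BBIs)")
  }
  dur_ms <- duration_s * 1000
  total <- duration_ms(series)
  if (dur_ms > total) {
    warning("window (", duration_s, " s) longer than recording (",
            round(total / 1000), " s); no candidates")
    return(list())
  }
  t <- series$beat_times
  bad_cum <- c(0, cumsum(mask$labels != "clean"))  # bad BBIs among 1..i
  starts <- seq(0, total - dur_ms, by = step_ms)
  out <- vector("list", length(starts))
  kept <- 0L
  for (s in starts) {
    idx <- beats_in_window(t, s, s + dur_ms)
    nb <- length(idx) - 1L                         # fully contained BBIs
    if (nb < min_beats) next
    i1 <- idx[1L]
    if (bad_cum[i1 + nb] - bad_cum[i1] > 0) next   # any bad BBI in i1..i1+nb-1
    kept <- kept + 1L
    out[[kept]] <- structure(
      list(series = series, start_ms = s, end_ms = s + dur_ms,
           duration_s = duration_s, beat_idx = idx),
      class = "rr_segment"
    )
  }
  out[seq_len(kept)]
}

#' Greedy one-segment-per-hour selection
#'
#' Keeps the first candidate, then repeatedly takes the earliest candidate
#' whose start is at least `spacing_min` minutes (inclusive) after the start
#' of the most recently selected one.
#'
#' @param candidates List of [rr_segment()] sorted by `start_ms`.
#' @param spacing_min Minimum start-to-start spacing in minutes (default 60).
#' @return Sub-list of `candidates`; empty input yields an empty list.
#' @examples
#' # candidate starts at minutes 0, 30, 70, 100, 135 -> selected 0, 70, 135
#' @export
select_hourly <- function(candidates, spacing_min = 60) {
  if (length(candidates) == 0L) return(list())
  starts <- vapply(candidates, function(s) s$start_ms, 0)
  if (is.unsorted(starts)) stop("candidates must be sorted by start_ms")
  spacing_ms <- spacing_min * 60000
  sel <- logical(length(candidates))
  last <- -Inf
  for (i in seq_along(candidates)) {
    if (starts[i] >= last + spacing_ms || is.infinite(last)) {
      sel[i] <- TRUE
      last <- starts[i]
    }
  }
  candidates[sel]
}

#' Extract the first minute of a 5-minute segment
#'
#' Returns the sub-window `[start_ms, start_ms + 60000)` over the same parent
#' series.  A sub-window of a clean window is clean, so the result inherits
#' the parent's artifact-free status.  Under the 1500 ms clean upper bound a
#' clean first minute contains at least one beat per 1.5 s, i.e. about 40
#' BBIs; fewer than 2 beats is an error.
#'
#' @param segment An [rr_segment()] with `duration_s = 300`.
#' @return An [rr_segment()] with `duration_s = 60` sharing `start_ms`.
#' @export
extract_first_minute <- function(segment) {
  stopifnot(inherits(segment, "rr_segment"))
  if (segment$duration_s != 300) {
    stop("first-minute extraction is defined for 300 s segments, got ",
         segment$duration_s, " s")
  }
  rr_segment(segment$series, segment$start_ms, 60)
}
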