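#' Beat series: beat times and beat-to-beat intervals
#'
#' A `beat_series` holds one continuous heart-beat recording as a strictly
#' increasing vector of beat times (milliseconds from recording start) together
#' with the derived beat-to-beat intervals (BBIs), `bbis[i] =
#' beat_times[i + 1] - beat_times[i]`.  All downstream screening, segmentation
#' and HRV computation operates on this container.
#'
#' Either `beat_times` or `bbis` must be supplied.  When only intervals are
#' given, beat times are reconstructed on an absolute axis starting at 0.
#'
#' @param beat_times Numeric vector of beat times in ms, strictly increasing,
#'   all values >= 0.
#' @param bbis Numeric vector of beat-to-beat intervals in ms, all > 0.  Used
#'   only when `beat_times` is `NULL`.
#' @param recording_id Opaque label carried through metric tables and reports.
#'
#' @return An object of class `beat_series` with fields `beat_times`, `bbis`
#'   and `recording_id`.
#' @examples
#' s <- beat_series(bbis = c(800, 810, 790))
#' s$beat_times   # 0 800 1610 2400
#' @export
beat_series <- function(beat_times = NULL, bbis = NULL,
                        recording_id = "recording") {
  if (is.null(beat_times)) {
    if (is.null(bbis)) stop("supply either 'beat_times' or 'bbis'")
    bbis <- as.numeric(bbis)
    if (length(bbis) < 1L) stop("no beats: empty interval vector")
    if (anyNA(bbis) || any(!is.finite(bbis))) {
      stop("BBIs must be finite numbers")
    }
    if (any(bbis <= 0)) {
      stop("non-positive BBI at position ",
           which(bbis <= 0)[1L], " (", bbis[bbis <= 0][1L], " ms)")
    }
    beat_times <- c(0, cumsum(bbis))
  } else {
    beat_times <- as.numeric(beat_times)
    if (length(beat_times) < 2L) stop("no beats: need at least 2 beat times")
    if (anyNA(beat_times) || any(!is.finite(beat_times))) {
      stop("beat times must be finite numbers")
    }
    if (any(beat_times < 0)) stop("beat times must be >= 0")
    d <- diff(beat_times)
    if (any(d <= 0)) {
      stop("beat times not strictly increasing at position ",
           which(d <= 0)[1L] + 1L)
    }
    bbis <- d
  }
  structure(
    list(beat_times = beat_times, bbis = bbis,
         recording_id = as.character(recording_id)[1L]),
    class = "beat_series"
  )
}

#' @export
print.beat_series <- function(x, ...) {
  cat("<beat_series> ", x$recording_id, "\n", sep = "")
  cat("  beats:    ", length(x$beat_times), "\n", sep = "")
  cat(sprintf("  duration: %.1f min\n", duration_ms(x) / 60000))
  cat(sprintf("  BBI range: %.0f-%.0f ms (mean %.0f)\n",
              min(x$bbis), max(x$bbis), mean(x$bbis)))
  invisible(x)
}

#' @export
length.beat_series <- function(x) length(x$beat_times)

#' Recording duration in milliseconds
#' @param series A [beat_series].
#' @return Time of the last beat, ms.
#' @export
duration_ms <- function(series) {
  stopifnot(inherits(series, "beat_series"))
  series$beat_times[length(series$beat_times)]
}

#' Read an RR-interval or beat-time text file
#'
#' Two plain-text layouts are supported.  `intervals_only`: one BBI in ms per
#' line; beat times are reconstructed starting at 0.  `time_interval_pairs`:
#' whitespace-separated `time_ms interval_ms` per line, where the time column
#' is the beat time from recording start and the interval column is the BBI
#' ending at that beat (the first line's interval has no preceding beat and is
#' ignored).  `#` starts a comment; blank lines are skipped.
#'
#' In `time_interval_pairs` mode the time column is authoritative: BBIs are
#' recomputed as successive time differences, and a warning reports any line
#' whose stated interval disagrees with the derived one by more than
#' `tol_ms`.
#'
#' @param path Path to the text file.
#' @param mode `"intervals_only"` or `"time_interval_pairs"`.
#' @param recording_id Label for the resulting series; defaults to the file
#'   name without extension.
#' @param tol_ms Tolerance (ms) for the stated-vs-derived interval consistency
#'   check in `time_interval_pairs` mode.
#' @return A [beat_series].
#' @export
read_rr_text <- function(path,
                         mode = c("intervals_only", "time_interval_pairs"),
                         recording_id = NULL, tol_ms = 0.5) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(recording_id)) {
    recording_id <- sub("\\.[^.]*$", "", basename(path))
  }
  raw <- readLines(path, warn = FALSE)
  stripped <- sub("#.*$", "", raw)
  stripped <- trimws(stripped)
  keep <- which(nzchar(stripped))
  if (length(keep) == 0L) stop("no beats: file '", path, "' has no data lines")
  lines <- stripped[keep]

  parse_field <- function(txt, lineno, what) {
    v <- suppressWarnings(as.numeric(txt))
    bad <- which(is.na(v))
    if (length(bad)) {
      stop("cannot parse ", what, " on line ", lineno[bad[1L]],
           ": '", txt[bad[1L]], "'")
    }
    v
  }

  if (mode == "intervals_only") {
    if (any(grepl("[[:space:]]", lines))) {
      stop("line ", keep[grep("[[:space:]]", lines)[1L]],
           " has multiple fields; use mode = 'time_interval_pairs'")
    }
    vals <- parse_field(lines, keep, "interval")
    if (any(vals <= 0)) {
      i <- which(vals <= 0)[1L]
      stop("non-positive interval (", vals[i], " ms) on line ", keep[i])
    }
    return(beat_series(bbis = vals, recording_id = recording_id))
  }

  fields <- strsplit(lines, "[[:space:],]+")
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    stop("line ", keep[which(nf < 2L)[1L]],
         " needs two fields 'time_ms interval_ms'")
  }
  times  <- parse_field(vapply(fields, `[`, "", 1L), keep, "time")
  stated <- parse_field(vapply(fields, `[`, "", 2L), keep, "interval")
  if (any(diff(times) <= 0)) {
    i <- which(diff(times) <= 0)[1L] + 1L
    stop("time column not strictly increasing on line ", keep[i])
  }
  derived <- diff(times)
  # stated interval on line i is the BBI ending at that line's beat time;
  # the first line has no preceding beat, so compare lines 2..n only
  mism <- which(abs(stated[-1L] - derived) > tol_ms)
  if (length(mism)) {
    warning("stated intervals disagree with the time column on line",
            if (length(mism) > 1L) "s " else " ",
            paste(keep[mism + 1L], collapse = ", "),
            " (e.g. stated ", stated[mism[1L] + 1L], " ms vs derived ",
            derived[mism[1L]],
            " ms); using intervals derived from beat times")
  }
  beat_series(beat_times = times, recording_id = recording_id)
}

metrics_columns <- c("recording_id", "start_ms", "duration_s", "n_bbis",
                     "rmssd_ms", "sdnn_ms", "lf_ms2", "hf_ms2")

#' Write an HRV metrics table to CSV
#'
#' Writes one row per segment-window with the standard metric schema
#' (`recording_id, start_ms, duration_s, n_bbis, rmssd_ms, sdnn_ms, lf_ms2,
#' hf_ms2`).  Numbers are written with full double precision so the table
#' round-trips losslessly through [read_metrics_table()].  Missing metrics
#' (e.g. frequency-domain values on windows with too few beats) are written
#' as empty cells, never as zeros.
#'
#' @param rows A data frame with the schema above, or a list of
#'   `hrv_metrics` objects (see [compute_metrics()]).
#' @param path Output file path.
#' @return Invisibly, the number of data rows written.
#' @export
write_metrics_table <- function(rows, path) {
  if (is.list(rows) && !is.data.frame(rows)) {
    rows <- do.call(rbind, lapply(rows, as.data.frame))
  }
  if (is.null(rows)) {
    rows <- as.data.frame(stats::setNames(rep(list(numeric(0)),
                                       length(metrics_columns)),
                                   metrics_columns))
  }
  stopifnot(is.data.frame(rows))
  missing_cols <- setdiff(metrics_columns, names(rows))
  if (length(missing_cols)) {
    stop("rows lack metric columns: ", paste(missing_cols, collapse = ", "))
  }
  rows <- rows[metrics_columns]
  fmt <- function(v) {
    if (length(v) == 0L) return(character(0))
    if (is.numeric(v)) ifelse(is.na(v), "", sprintf("%.17g", v))
    else ifelse(is.na(v), "", as.character(v))
  }
  out <- vapply(rows, fmt, character(nrow(rows)))
  if (nrow(rows) == 1L) out <- matrix(out, nrow = 1L)
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot open '", path, "' for writing: ", conditionMessage(e))
  })
  on.exit(close(con))
  writeLines(paste(metrics_columns, collapse = ","), con)
  if (nrow(rows) > 0L) {
    writeLines(apply(out, 1L, paste, collapse = ","), con)
  }
  invisible(nrow(rows))
}

#' Read an HRV metrics table written by [write_metrics_table()]
#'
#' @param path CSV path.
#' @return A data frame with the metric schema; empty cells become `NA`.
#' @export
read_metrics_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, colClasses = c(recording_id = "character"),
                        na.strings = "")
  missing_cols <- setdiff(metrics_columns, names(df))
  if (length(missing_cols)) {
    stop("not a metrics table; missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  for (cl in setdiff(metrics_columns, "recording_id")) {
    df[[cl]] <- as.numeric(df[[cl]])
  }
  df
}
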