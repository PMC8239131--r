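# shared fixture builders (all fixtures are generated in code)

# constant-interval recording: n BBIs of bbi_ms each
constant_series <- function(n, bbi_ms = 1000, id = "const") {
  beat_series(bbis = rep(bbi_ms, n), recording_id = id)
}

# beats whose BBI *ending* at each beat follows bbi_fun(t_seconds); solved
# beat-by-beat by fixed-point iteration so the end-anchored tachogram has an
# exact closed-form reference
series_from_bbi_fun <- function(bbi_fun, duration_ms, id = "fun") {
  t <- 0
  out <- numeric(ceiling(duration_ms / 200) + 2L)
  k <- 1L
  while (t < duration_ms) {
    nxt <- t + bbi_fun(t / 1000)
    for (i in 1:8) nxt <- t + bbi_fun(nxt / 1000)
    k <- k + 1L
    out[k] <- nxt
    t <- nxt
  }
  beat_series(beat_times = out[seq_len(k)], recording_id = id)
}

# tamed generator settings: modulation small enough that injected premature
# beats (0.6 x local BBI) always stay inside the 400-1500 ms clean range
tame_config <- function(duration_h = 3, seed = 1, ...) {
  synthetic_config(
    duration_h = duration_h, seed = seed,
    hf = list(amp_ms = 20), lf = list(amp_ms = 20),
    slow_trend = list(amplitude_ms = 0), jitter_sd_ms = 5, ...)
}

write_tmp_lines <- function(lines) {
  f <- tempfile(fileext = ".rr")
  writeLines(lines, f)
  f
}
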