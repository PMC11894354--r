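# In-code fixtures used across the suite.

# one participant/device stream from explicit beat times (seconds) and IBI
# values (ms)
make_series <- function(times_s, ibis_ms, participant = "P01", device = "ppg") {
  tibble::tibble(
    participant_id = participant, device = device,
    timestamp_ms = times_s * 1000, ibi_ms = ibis_ms
  )
}

# evenly spaced 1-Hz beats filling [0, 300) s: 300 points, one window
beats_1hz <- function(ibi = 1000, t0_s = 0) {
  make_series(t0_s + 0:299, rep(ibi, 300))
}

# a window tibble whose single window holds a pure sinusoidal tachogram:
# IBI(t) = base + amp * sin(2*pi*freq*t), sampled at beat times spaced
# `spacing_s` apart across the full window
tone_window <- function(freq_hz, amp_ms, base_ms = 800, spacing_s = 0.8,
                        noise_sd = 0, seed = 1) {
  t <- seq(0, 300 - spacing_s / 2, by = spacing_s)
  set.seed(seed)
  ibi <- base_ms + amp_ms * sin(2 * pi * freq_hz * t) + rnorm(length(t), 0, noise_sd)
  segment_windows(make_series(t, ibi))
}

# noise-free generator config for spectral tests
tone_config <- function(lf_amp, hf_amp, duration_h = 1, seed = 11, ...) {
  synth_config(
    participant_count = 1, duration_days = duration_h / 24,
    lf_amp = lf_amp, hf_amp = hf_amp,
    beat_noise_sd = 0, artifact_rate = 0,
    device_noise_sd_ppg = 0, ppg_bias = 0,
    activity_blocks = list(), seed = seed, ...
  )
}

# long-format fixture with known random-intercept structure: one metric,
# reference plus one degraded level with a known additive effect
sim_long <- function(n_part = 8, n_win = 30, effect = -0.5, sd_part = 1,
                     sd_res = 1, seed = 1, level = "10") {
  set.seed(seed)
  purrr::map_dfr(seq_len(n_part), function(p) {
    u <- rnorm(1, 0, sd_part)
    base <- 5 + u + rnorm(n_win, 0, sd_res)
    deg <- 5 + u + effect + rnorm(n_win, 0, sd_res)
    tibble::tibble(
      participant_id = sprintf("P%02d", p),
      window_start_ms = rep(300000 * (seq_len(n_win) - 1), 2),
      activity = "rest",
      level = rep(c("ref", level), each = n_win),
      metric = "hf",
      value = c(base, deg)
    )
  })
}

# full single-stream pipeline to gap-annotated windows
windows_of <- function(series, steps = NULL) {
  w <- find_gaps(segment_windows(filter_artifacts(series)))
  if (!is.null(steps)) w <- classify_activity(w, steps)
  w
}
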