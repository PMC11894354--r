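#' Configuration for the synthetic IBI cohort generator
#'
#' Builds a validated configuration describing a synthetic cohort of paired
#' wrist-PPG and chest-ECG interbeat-interval (IBI) streams with known
#' oscillatory structure. The defaults describe a free-living cohort of the
#' kind the package's analyses are aimed at: 16 participants wearing a watch
#' day and night for two weeks, resting mean IBI near 889 ms, light-activity
#' mean IBI near 691 ms, a low-frequency (Mayer-wave) oscillation at 0.10 Hz
#' and a respiratory high-frequency oscillation at 0.25 Hz, beat-level noise,
#' occasional artifact beats outside the physiological 300--1500 ms range,
#' and one daily two-hour light-activity block at 60 steps/min.
#'
#' Amplitudes are chosen so that clean-window band powers (median censored
#' ln-variance, see [compute_hrv()]) land near 6.5 (LF) and 5.5 (HF), typical
#' resting values on that scale.
#'
#' @param participant_count Number of participants (>= 1).
#' @param duration_days Length of the recording per participant, days.
#' @param mean_ibi_rest,mean_ibi_active Mean IBI (ms) at rest / during
#'   activity; both must lie in (300, 1500).
#' @param lf_freq,lf_amp Low-frequency oscillation: frequency (Hz, in
#'   \[0.04, 0.15)) and amplitude (ms).
#' @param hf_freq,hf_amp High-frequency oscillation: frequency (Hz, in
#'   \[0.15, 1.0\]) and amplitude (ms).
#' @param beat_noise_sd SD of white beat-to-beat noise (ms).
#' @param artifact_rate Per-beat probability that the emitted IBI value is
#'   replaced by an artifact outside \[300, 1500\] ms.
#' @param device_noise_sd_ppg SD of additional PPG measurement noise (ms).
#' @param ppg_bias Fixed additive PPG bias (ms).
#' @param wear_schedule List of `c(start, end)` worn intervals, seconds from
#'   recording start; `NULL` means worn throughout.
#' @param activity_blocks List of `c(start, end, steps_per_min)` activity
#'   blocks, seconds from recording start; `NULL` installs one daily 2-hour
#'   block (17:00--19:00) at 60 steps/min; `list()` means no activity.
#' @param seed Integer seed; all generator output is deterministic given
#'   `(seed, participant_index, device)`.
#'
#' @return An object of class `synth_config` (a validated named list).
#' @export
#' @examples
#' cfg <- synth_config(participant_count = 2, duration_days = 0.05)
#' ibi <- generate_ibi_series(cfg, 1, "ppg")
#' head(ibi)
synth_config <- function(participant_count = 16,
                         duration_days = 14,
                         mean_ibi_rest = 889,
                         mean_ibi_active = 691,
                         lf_freq = 0.10,
                         lf_amp = 35,
                         hf_freq = 0.25,
                         hf_amp = 25,
                         beat_noise_sd = 10,
                         artifact_rate = 0.001,
                         device_noise_sd_ppg = 10,
                         ppg_bias = 5,
                         wear_schedule = NULL,
                         activity_blocks = NULL,
                         seed = 1L) {
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
      abort(sprintf("`%s` must be a single finite number.", nm))
    }
    as.numeric(x)
  }
  participant_count <- num1(participant_count, "participant_count")
  duration_days <- num1(duration_days, "duration_days")
  for (nm in c("mean_ibi_rest", "mean_ibi_active", "lf_freq", "lf_amp",
               "hf_freq", "hf_amp", "beat_noise_sd", "artifact_rate",
               "device_noise_sd_ppg", "ppg_bias", "seed")) {
    assign(nm, num1(get(nm), nm))
  }
  if (participant_count < 1) abort("`participant_count` must be >= 1.")
  if (duration_days <= 0) abort("`duration_days` must be positive.")
  if (lf_freq < 0.04 || lf_freq >= 0.15) abort("`lf_freq` must lie in [0.04, 0.15).")
  if (hf_freq < 0.15 || hf_freq > 1.0) abort("`hf_freq` must lie in [0.15, 1.0].")
  if (lf_amp < 0 || hf_amp < 0 || beat_noise_sd < 0 || device_noise_sd_ppg < 0) {
    abort("Amplitudes and noise SDs must be non-negative.")
  }
  if (artifact_rate < 0 || artifact_rate > 1) abort("`artifact_rate` must lie in [0, 1].")
  for (m in c(mean_ibi_rest, mean_ibi_active)) {
    if (m <= 300 || m >= 1500) abort("Mean IBI values must lie in (300, 1500) ms.")
  }

  duration_s <- duration_days * 86400
  if (is.null(wear_schedule)) wear_schedule <- list(c(0, duration_s))
  wear_schedule <- lapply(wear_schedule, function(iv) {
    if (length(iv) != 2L || !all(is.finite(iv)) || iv[2] <= iv[1]) {
      abort("Each wear interval must be c(start, end) with end > start.")
    }
    as.numeric(iv)
  })
  if (is.null(activity_blocks)) {
    starts <- seq(0, by = 86400, length.out = ceiling(duration_days))
    activity_blocks <- lapply(starts[starts + 17 * 3600 < duration_s], function(d0) {
      c(d0 + 17 * 3600, min(d0 + 19 * 3600, duration_s), 60)
    })
  }
  activity_blocks <- lapply(activity_blocks, function(b) {
    if (length(b) != 3L || !all(is.finite(b)) || b[2] <= b[1] || b[3] < 0) {
      abort("Each activity block must be c(start, end, steps_per_min).")
    }
    as.numeric(b)
  })

  structure(
    list(
      participant_count = as.integer(participant_count),
      duration_days = duration_days,
      duration_s = duration_s,
      mean_ibi_rest = mean_ibi_rest,
      mean_ibi_active = mean_ibi_active,
      lf_freq = lf_freq, lf_amp = lf_amp,
      hf_freq = hf_freq, hf_amp = hf_amp,
      beat_noise_sd = beat_noise_sd,
      artifact_rate = artifact_rate,
      device_noise_sd_ppg = device_noise_sd_ppg,
      ppg_bias = ppg_bias,
      wear_schedule = wear_schedule,
      activity_blocks = activity_blocks,
      seed = as.integer(seed)
    ),
    class = "synth_config"
  )
}

# derived seed for one participant's beat process / one device's noise,
# kept inside 32-bit integer range
synth_seed <- function(config, participant_index, stream = 0L) {
  as.integer((abs(config$seed) * 100003 + participant_index * 7919 +
                stream * 611953) %% 2147483647)
}

# activity weight in [0,1] at time t (seconds): 1 inside an activity block
# after a 30-s linear ramp-in, ramping back to 0 over 30 s after block end
activity_weight <- function(t, blocks) {
  w <- rep(0, length(t))
  for (b in blocks) {
    up <- pmin(1, pmax(0, (t - b[1]) / 30))
    dn <- pmin(1, pmax(0, (b[2] + 30 - t) / 30))
    w <- pmax(w, pmin(up, dn) * (t >= b[1] & t <= b[2] + 30))
  }
  w
}

in_wear <- function(t, schedule) {
  keep <- rep(FALSE, length(t))
  for (iv in schedule) keep <- keep | (t >= iv[1] & t < iv[2])
  keep
}

#' Generate one synthetic IBI stream
#'
#' Emits beats iteratively: each beat time is the previous beat time plus the
#' instantaneous IBI, where the instantaneous IBI is the activity-dependent
#' base level plus the LF and HF sinusoids plus Gaussian beat noise. With
#' probability `artifact_rate` the *emitted* IBI value (not the beat timing)
#' is replaced by an artifact drawn uniformly from
#' \[100, 300) or (1500, 3000\] ms. For `device = "ppg"` independent Gaussian
#' measurement noise and a fixed additive bias are applied; the underlying
#' beat process is identical between the two devices of a participant.
#' Samples falling outside the wear schedule are dropped.
#'
#' @param config A [synth_config()].
#' @param participant_index Positive integer.
#' @param device `"ppg"` or `"ecg"`.
#' @return A tibble with columns `participant_id`, `device`, `timestamp_ms`
#'   (strictly increasing), `ibi_ms`.
#' @export
generate_ibi_series <- function(config, participant_index, device = c("ppg", "ecg")) {
  stopifnot(inherits(config, "synth_config"))
  device <- match.arg(device)
  if (participant_index < 1 || participant_index != round(participant_index)) {
    abort("`participant_index` must be a positive integer.")
  }

  dur <- config$duration_s
  # upper bound on beat count: shortest plausible clean IBI, floored at 250 ms
  min_ibi <- max(250, min(config$mean_ibi_rest, config$mean_ibi_active) -
                   config$lf_amp - config$hf_amp - 6 * config$beat_noise_sd)
  n_max <- ceiling(dur * 1000 / min_ibi) + 16L

  base_lo <- config$mean_ibi_rest
  base_hi <- config$mean_ibi_active

  noise <- withr::with_seed(synth_seed(config, participant_index), {
    list(
      beat = rnorm(n_max, 0, config$beat_noise_sd),
      art_flag = runif(n_max) < config$artifact_rate,
      art_side = runif(n_max) < 0.5,
      art_val = runif(n_max)
    )
  })

  t_ms <- numeric(n_max)
  ibi <- numeric(n_max)
  t_cur <- 0
  i <- 0L
  end_ms <- dur * 1000
  blocks <- config$activity_blocks
  while (t_cur < end_ms && i < n_max) {
    i <- i + 1L
    w <- if (length(blocks)) activity_weight(t_cur / 1000, blocks) else 0
    clean <- base_lo + (base_hi - base_lo) * w +
      config$lf_amp * sin(2 * pi * config$lf_freq * t_cur / 1000) +
      config$hf_amp * sin(2 * pi * config$hf_freq * t_cur / 1000) +
      noise$beat[i]
    clean <- max(clean, 1)  # guard against degenerate configs
    t_cur <- t_cur + clean
    t_ms[i] <- t_cur
    ibi[i] <- clean
  }
  n <- i
  t_ms <- t_ms[seq_len(n)]
  ibi <- ibi[seq_len(n)]

  # artifact injection replaces the recorded value, leaving timing untouched
  if (config$artifact_rate > 0) {
    flag <- noise$art_flag[seq_len(n)]
    lowv <- 100 + noise$art_val[seq_len(n)] * 200    # [100, 300)
    highv <- 1500 + noise$art_val[seq_len(n)] * 1500 # (1500, 3000]
    ibi[flag] <- ifelse(noise$art_side[seq_len(n)], lowv, highv)[flag]
  }

  if (device == "ppg" && (config$device_noise_sd_ppg > 0 || config$ppg_bias != 0)) {
    dev_noise <- withr::with_seed(
      synth_seed(config, participant_index, 1L),
      rnorm(n, 0, config$device_noise_sd_ppg)
    )
    ibi <- ibi + dev_noise + config$ppg_bias
  }

  keep <- t_ms <= end_ms & in_wear(t_ms / 1000, config$wear_schedule)
  tibble::tibble(
    participant_id = sprintf("P%02d", participant_index),
    device = device,
    timestamp_ms = t_ms[keep],
    ibi_ms = ibi[keep]
  )
}

#' Generate per-minute step counts for one participant
#'
#' One integer per worn minute: 0 at rest and the block's `steps_per_min`
#' when the minute start falls inside an activity block. Minutes whose start
#' lies outside the wear schedule are absent.
#'
#' @inheritParams generate_ibi_series
#' @return A tibble with columns `participant_id`, `minute_start_ms`, `steps`.
#' @export
generate_steps <- function(config, participant_index) {
  stopifnot(inherits(config, "synth_config"))
  minute_start_s <- seq(0, config$duration_s - 60, by = 60)
  steps <- rep(0L, length(minute_start_s))
  for (b in config$activity_blocks) {
    steps[minute_start_s >= b[1] & minute_start_s < b[2]] <- as.integer(b[3])
  }
  keep <- in_wear(minute_start_s, config$wear_schedule)
  tibble::tibble(
    participant_id = sprintf("P%02d", participant_index),
    minute_start_ms = minute_start_s[keep] * 1000,
    steps = steps[keep]
  )
}

#' Generate a full synthetic cohort with ground truth
#'
#' For each participant, paired PPG and ECG streams sharing the same
#' underlying beat process (differing only by device noise and bias), a step
#' series, and a per-5-minute-window ground-truth table holding the true mean
#' IBI, the configured band-power proxies `ln(amp^2 / 2)` and the activity
#' class implied by the activity blocks.
#'
#' @param config A [synth_config()].
#' @return A list with tibbles `ibi` (all participants and devices stacked),
#'   `steps`, and `truth`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  idx <- seq_len(config$participant_count)
  ibi <- purrr::map_dfr(idx, function(i) {
    dplyr::bind_rows(
      generate_ibi_series(config, i, "ppg"),
      generate_ibi_series(config, i, "ecg")
    )
  })
  steps <- purrr::map_dfr(idx, generate_steps, config = config)

  win_starts <- seq(0, config$duration_s * 1000 - 1, by = WINDOW_MS)
  truth_one <- tibble::tibble(
    window_start_ms = win_starts,
    true_mean_ibi = purrr::map_dbl(win_starts, function(w0) {
      tt <- seq(w0, w0 + WINDOW_MS - 1000, by = 1000) / 1000
      w <- if (length(config$activity_blocks)) {
        activity_weight(tt, config$activity_blocks)
      } else 0
      mean(config$mean_ibi_rest + (config$mean_ibi_active - config$mean_ibi_rest) * w)
    }),
    true_lf = if (config$lf_amp > 0) log(config$lf_amp^2 / 2) else NA_real_,
    true_hf = if (config$hf_amp > 0) log(config$hf_amp^2 / 2) else NA_real_
  )
  truth <- purrr::map_dfr(idx, function(i) {
    st <- generate_steps(config, i)
    dplyr::mutate(
      truth_one,
      participant_id = sprintf("P%02d", i),
      activity = purrr::map_chr(.data$window_start_ms, function(w0) {
        s <- st$steps[st$minute_start_ms >= w0 & st$minute_start_ms < w0 + WINDOW_MS]
        if (length(s) < 2) return("unknown")
        m <- mean(s)
        if (m == 0) "rest" else if (m < 100) "light" else "high"
      }),
      .before = 1
    )
  })
  list(ibi = ibi, steps = steps, truth = truth)
}
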