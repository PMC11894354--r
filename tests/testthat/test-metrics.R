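test_that("time-domain metrics match hand arithmetic on tiny windows", {
  expect_equal(
    as.data.frame(time_domain(c(800, 800, 800))),
    data.frame(median_ibi = 800, stdrr = 0, rmsdrr = 0, time_valid = TRUE)
  )
  td <- time_domain(c(790, 810))
  expect_equal(td$median_ibi, 800)
  expect_equal(td$rmsdrr, 20)
  expect_false(time_domain(c(800))$time_valid)
})

test_that("stdrr/rmsdrr are shift-invariant; median shifts with the data", {
  set.seed(7)
  x <- runif(200, 600, 1000)
  a <- time_domain(x)
  b <- time_domain(x + 123.4)
  expect_equal(b$stdrr, a$stdrr)
  expect_equal(b$rmsdrr, a$rmsdrr)
  expect_equal(b$median_ibi, a$median_ibi + 123.4)
})

test_that("pchip resampling reproduces knots, preserves constants and monotonicity", {
  # constant series -> constant resample
  w <- find_gaps(segment_windows(beats_1hz(ibi = 800)))
  rs <- resample_pchip(w$samples[[1]], w$usable_start_ms, w$usable_end_ms)
  expect_true(all(abs(rs$value - 800) < 1e-9))
  expect_identical(nrow(rs), 1500L)
  expect_equal(diff(rs$time_ms)[1], 200)

  # interpolant passes through original samples
  set.seed(3)
  t <- sort(runif(50, 0, 290))
  y <- 800 + cumsum(rnorm(50, 0, 5))
  s <- make_series(t, y)
  at_knots <- pracma::pchip(t * 1000, y, t * 1000)
  expect_equal(at_knots, y, tolerance = 1e-12)

  # monotone input -> monotone output, no overshoot beyond data range
  ym <- sort(y)
  wm <- find_gaps(segment_windows(make_series(seq(0, 299, length.out = 50), ym)))
  rsm <- resample_pchip(wm$samples[[1]], wm$usable_start_ms, wm$usable_end_ms)
  expect_true(all(diff(rsm$value) >= -1e-9))
  expect_true(all(rsm$value >= min(ym) - 1e-9 & rsm$value <= max(ym) + 1e-9))
})

test_that("too-short or too-sparse segments are refused", {
  w <- find_gaps(segment_windows(make_series(c(0, 10, 20), c(800, 810, 805))))
  expect_null(resample_pchip(w$samples[[1]], w$usable_start_ms, w$usable_end_ms))
  w2 <- find_gaps(segment_windows(make_series(seq(0, 40, 2), rep(800, 21))))
  # 21 samples but segment only reaches 40 s + trailing gap -> usable segment
  # is the leading [0, 41] s run, under the 60-s minimum
  expect_null(resample_pchip(w2$samples[[1]], w2$usable_start_ms, w2$usable_end_ms))
})

test_that("band filters pass in-band tones and attenuate out-of-band tones per their own response", {
  fs <- 5
  t <- seq(0, 299.8, by = 0.2)
  # analytic two-pass amplitude gain of the realized filter at frequency f:
  # |H(e^{iw})|^2 evaluated directly from the transfer-function polynomials
  gain2 <- function(edges, f) {
    flt <- signal::butter(2, edges / (fs / 2), type = "pass")
    z <- exp(-1i * 2 * pi * f / fs)
    h <- sum(flt$b * z^(seq_along(flt$b) - 1)) /
      sum(flt$a * z^(seq_along(flt$a) - 1))
    Mod(h)^2
  }
  mid <- 500:1000  # interior stretch, away from filtfilt edge transients
  for (f0 in c(0.10, 0.25)) {
    tone <- sin(2 * pi * f0 * t)
    for (band in list(c(0.04, 0.15), c(0.15, 1.0))) {
      out <- band_filter(tone, band, fs)
      measured <- sqrt(mean(out[mid]^2) / mean(tone[mid]^2))
      expect_equal(measured, gain2(band, f0), tolerance = 0.05)
    }
  }
  # in-band gains are near unity, cross-band leakage is heavily attenuated
  expect_gt(gain2(c(0.04, 0.15), 0.10), 0.9)
  expect_gt(gain2(c(0.15, 1.0), 0.25), 0.9)
  expect_lt(gain2(c(0.15, 1.0), 0.10), 0.2)
  expect_lt(gain2(c(0.04, 0.15), 0.25), 0.1)
  # zero in, zero out
  expect_true(all(band_filter(rep(0, 1500), "lf") == 0))
})

test_that("ln-variance sub-windows tile 60 s (LF) and 30 s (HF), dropping partial tails", {
  x <- rnorm(1500)
  expect_length(ln_variance_candidates(x, 60, 5), 5)
  expect_length(ln_variance_candidates(x, 30, 5), 10)
  expect_length(ln_variance_candidates(x[1:1499], 60, 5), 4)
  expect_length(ln_variance_candidates(numeric(0), 60, 5), 0)
  # candidate equals ln of the population variance of its sub-window
  v1 <- ln_variance_candidates(x, 60, 5)[1]
  seg <- x[1:300]
  expect_equal(v1, log(mean((seg - mean(seg))^2)), tolerance = 1e-12)
})

test_that("censored median eliminates values outside [2.5, 9.0]", {
  expect_equal(censored_median(c(3.0, 4.0, 10.0, 5.0, 2.0)), 4.0)
  expect_equal(censored_median(c(2.5, 9.0)), 5.75)   # bounds survive
  expect_true(is.na(censored_median(c(1, 10))))
  expect_true(is.na(censored_median(rep(-Inf, 5))))  # zero-variance windows
})

test_that("a pure in-band tone recovers ln(amp^2/2) after gain correction", {
  # HF tone with variance e^6: amp = sqrt(2 * e^6)
  amp <- sqrt(2 * exp(6))
  w <- tone_window(0.25, amp)
  m <- compute_hrv(w)
  gain <- local({
    flt <- signal::butter(2, c(0.15, 1.0) / 2.5, type = "pass")
    z <- exp(-1i * 2 * pi * 0.25 / 5)
    Mod(sum(flt$b * z^(seq_along(flt$b) - 1)) /
          sum(flt$a * z^(seq_along(flt$a) - 1)))^2
  })
  expect_equal(m$hf, 6 + log(gain^2), tolerance = 0.05)
  # LF leakage of a pure HF tone falls below the censoring floor
  expect_true(is.na(m$lf))
})

test_that("hf-dominant windows give hf > lf and lf_hf < 1; gap-failed windows keep time metrics", {
  cfg <- tone_config(lf_amp = 15, hf_amp = 30, duration_h = 0.25)
  m <- compute_hrv(windows_of(generate_ibi_series(cfg, 1, "ecg")))
  expect_true(all(m$hf > m$lf))
  expect_true(all(m$lf_hf < 1))

  keep <- !(0:299 %in% c(20:40, 90:110, 160:180, 230:250))
  w <- find_gaps(segment_windows(make_series((0:299)[keep], 800 + sin((0:299)[keep]))))
  mf <- compute_hrv(w)
  expect_false(mf$freq_valid)
  expect_true(mf$time_valid)
  expect_equal(mf$median_ibi, median(w$samples[[1]]$ibi_ms))
})

test_that("generated rest windows recover the configured mean at zero noise", {
  cfg <- tone_config(lf_amp = 0, hf_amp = 0, duration_h = 0.5)
  m <- compute_hrv(windows_of(generate_ibi_series(cfg, 1, "ecg")))
  expect_true(all(abs(m$median_ibi - cfg$mean_ibi_rest) < 5))
})

test_that("metrics_table drops list columns and keeps the metric record", {
  m <- compute_hrv(tone_window(0.25, 30))
  tbl <- metrics_table(m)
  expect_false(any(purrr::map_lgl(tbl, is.list)))
  expect_true(all(c("median_ibi", "stdrr", "rmsdrr", "lf", "hf", "lf_hf") %in%
                    names(tbl)))
})
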