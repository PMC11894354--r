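#' Intraclass correlation ICC(2,k): agreement and consistency
#'
#' Two-way random-effects, mean-of-k-raters intraclass correlations computed
#' from the two-way ANOVA mean squares (McGraw--Wong): consistency
#' `(MS_R - MS_E) / MS_R` and absolute agreement
#' `(MS_R - MS_E) / (MS_R + (MS_C - MS_E) / n)`, with F-distribution 95%
#' confidence intervals. Magnitudes above 0.5, 0.75 and 0.9 are labelled
#' moderate, good and excellent; below 0.5, poor.
#'
#' @param ratings Matrix or data frame of n subjects x k raters (k >= 2);
#'   rows containing missing values are dropped.
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `hrv_icc`; `tidy()` gives one row per ICC type
#'   with estimate, CI and interpretation label.
#' @export
#' @examples
#' m <- cbind(a = rnorm(20), b = rnorm(20))
#' tidy(icc2k(m))
icc2k <- function(ratings, conf_level = 0.95) {
  x <- as.matrix(ratings)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  n <- nrow(x)
  k <- ncol(x)
  if (k < 2) abort("ICC needs at least 2 raters (columns).")
  if (n < 5) abort("ICC needs at least 5 complete paired observations.")

  gm <- mean(x)
  rm_ <- rowMeans(x)
  cm <- colMeans(x)
  ss_total <- sum((x - gm)^2)
  ss_rows <- k * sum((rm_ - gm)^2)
  ss_cols <- n * sum((cm - gm)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))

  if (msr <= .Machine$double.eps * abs(gm + 1)) {
    warn("Zero between-subject variance: ICC undefined.")
    est <- tibble::tibble(
      type = c("agreement", "consistency"), estimate = NA_real_,
      ci_low = NA_real_, ci_high = NA_real_, interpretation = NA_character_
    )
    return(structure(list(results = est, n = n, k = k,
                          ms = c(msr = msr, msc = msc, mse = mse)),
                     class = "hrv_icc"))
  }

  alpha <- 1 - conf_level
  icc_c <- (msr - mse) / msr
  icc_a <- (msr - mse) / (msr + (msc - mse) / n)

  # consistency CI: F = MSR/MSE with (n-1), (n-1)(k-1) df
  f_c <- msr / mse
  df2 <- (n - 1) * (k - 1)
  fl <- f_c / qf(1 - alpha / 2, n - 1, df2)
  fu <- f_c * qf(1 - alpha / 2, df2, n - 1)
  ci_c <- c(1 - 1 / fl, 1 - 1 / fu)

  # agreement CI: Satterthwaite df on the single-rater ICC, then
  # Spearman-Brown step-up to k raters
  icc_a1 <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  fj <- msc / mse
  vn <- df2 * (k * icc_a1 * fj + n * (1 + (k - 1) * icc_a1) - k * icc_a1)^2 /
    ((n - 1) * k^2 * icc_a1^2 * fj^2 +
       (n * (1 + (k - 1) * icc_a1) - k * icc_a1)^2)
  fl_a <- qf(1 - alpha / 2, n - 1, vn)
  fu_a <- qf(1 - alpha / 2, vn, n - 1)
  l1 <- n * (msr - fl_a * mse) /
    (fl_a * (k * msc + (k * n - k - n) * mse) + n * msr)
  u1 <- n * (fu_a * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * fu_a * msr)
  ci_a <- c(l1 * k / (1 + l1 * (k - 1)), u1 * k / (1 + u1 * (k - 1)))

  label <- function(v) {
    dplyr::case_when(v > 0.9 ~ "excellent", v > 0.75 ~ "good",
                     v > 0.5 ~ "moderate", TRUE ~ "poor")
  }
  est <- tibble::tibble(
    type = c("agreement", "consistency"),
    estimate = c(icc_a, icc_c),
    ci_low = c(ci_a[1], ci_c[1]),
    ci_high = c(ci_a[2], ci_c[2]),
    interpretation = label(c(icc_a, icc_c))
  )
  structure(list(results = est, n = n, k = k,
                 ms = c(msr = msr, msc = msc, mse = mse)),
            class = "hrv_icc")
}

#' @export
print.hrv_icc <- function(x, ...) {
  cat(sprintf("ICC(2,k): %d subjects x %d raters\n", x$n, x$k))
  print(x$results)
  invisible(x)
}

#' @rdname icc2k
#' @param x An `hrv_icc` object.
#' @param ... Unused.
#' @method tidy hrv_icc
#' @export
tidy.hrv_icc <- function(x, ...) x$results

#' @rdname icc2k
#' @method glance hrv_icc
#' @export
glance.hrv_icc <- function(x, ...) {
  tibble::tibble(n_subjects = x$n, n_raters = x$k,
                 ms_rows = x$ms[["msr"]], ms_cols = x$ms[["msc"]],
                 ms_error = x$ms[["mse"]])
}

#' Bland-Altman agreement analysis
#'
#' Differences `a - b` against per-pair means, with the mean difference and
#' 95% limits of agreement `mean +- 1.96 * sd` (sample SD).
#'
#' @param data Data frame holding the paired measurements.
#' @param a,b Unquoted column names of the two devices' values.
#' @return An object of class `hrv_bland_altman`: `tidy()` gives the
#'   per-pair points, `glance()` the mean difference and limits.
#' @export
#' @examples
#' d <- data.frame(g = c(800, 850, 900), p = c(795, 860, 905))
#' glance(bland_altman(d, g, p))
bland_altman <- function(data, a, b) {
  av <- dplyr::pull(data, {{ a }})
  bv <- dplyr::pull(data, {{ b }})
  ok <- is.finite(av) & is.finite(bv)
  av <- av[ok]
  bv <- bv[ok]
  if (length(av) < 2) abort("Bland-Altman needs at least 2 complete pairs.")
  diffs <- av - bv
  md <- mean(diffs)
  s <- sd(diffs)
  structure(
    list(
      points = tibble::tibble(mean = (av + bv) / 2, diff = diffs),
      summary = tibble::tibble(
        n = length(diffs), mean_diff = md,
        loa_low = md - 1.96 * s, loa_high = md + 1.96 * s
      )
    ),
    class = "hrv_bland_altman"
  )
}

#' @export
print.hrv_bland_altman <- function(x, ...) {
  cat("Bland-Altman agreement\n")
  print(x$summary)
  invisible(x)
}

#' @rdname bland_altman
#' @param x An `hrv_bland_altman` object.
#' @param ... Unused.
#' @method tidy hrv_bland_altman
#' @export
tidy.hrv_bland_altman <- function(x, ...) x$points

#' @rdname bland_altman
#' @method glance hrv_bland_altman
#' @export
glance.hrv_bland_altman <- function(x, ...) x$summary

#' Root-mean-square error between paired measurements
#'
#' @param a,b Numeric vectors of equal length.
#' @return Scalar `sqrt(mean((a - b)^2))` over complete pairs.
#' @export
rmse_pairs <- function(a, b) {
  stopifnot(length(a) == length(b))
  ok <- is.finite(a) & is.finite(b)
  if (!any(ok)) abort("No complete pairs.")
  sqrt(mean((a[ok] - b[ok])^2))
}

#' Pair per-window metrics between two devices
#'
#' Inner join of two flattened metric tables (see [metrics_table()]) on
#' `(participant_id, window_start_ms)`; only windows present and time-valid
#' in both devices are retained. Device columns are suffixed `_ppg`/`_ecg`.
#'
#' @param ppg_metrics,ecg_metrics Metric tibbles for the two devices.
#' @return Paired tibble keyed by participant and window start.
#' @export
align_devices <- function(ppg_metrics, ecg_metrics) {
  p <- metrics_table(ppg_metrics) |> dplyr::select(-dplyr::any_of("device"))
  e <- metrics_table(ecg_metrics) |> dplyr::select(-dplyr::any_of("device"))
  out <- dplyr::inner_join(p, e, by = c("participant_id", "window_start_ms"),
                           suffix = c("_ppg", "_ecg"))
  if (nrow(out) == 0) abort("No overlapping windows between the two devices.")
  dplyr::filter(out, .data$time_valid_ppg & .data$time_valid_ecg)
}

#' Between-device agreement table for all six HRV metrics
#'
#' For each metric, ICC(2,k) agreement and consistency with 95% CIs,
#' Bland-Altman mean difference and limits of agreement, and RMSE, computed
#' over the windows where both devices yield a valid value.
#'
#' @param paired Paired tibble from [align_devices()].
#' @param metrics Metrics to summarise (default all six).
#' @return Tibble with one row per metric.
#' @export
agreement_analysis <- function(paired,
                               metrics = c("median_ibi", "stdrr", "rmsdrr",
                                           "lf", "hf", "lf_hf")) {
  purrr::map_dfr(metrics, function(m) {
    a <- paired[[paste0(m, "_ppg")]]
    b <- paired[[paste0(m, "_ecg")]]
    ok <- is.finite(a) & is.finite(b)
    icc <- tidy(icc2k(cbind(a[ok], b[ok])))
    ba <- glance(bland_altman(tibble::tibble(a = a[ok], b = b[ok]), a, b))
    tibble::tibble(
      metric = m,
      n_windows = sum(ok),
      icc_agreement = icc$estimate[icc$type == "agreement"],
      icc_agreement_low = icc$ci_low[icc$type == "agreement"],
      icc_agreement_high = icc$ci_high[icc$type == "agreement"],
      icc_consistency = icc$estimate[icc$type == "consistency"],
      icc_consistency_low = icc$ci_low[icc$type == "consistency"],
      icc_consistency_high = icc$ci_high[icc$type == "consistency"],
      mean_diff = ba$mean_diff,
      loa_low = ba$loa_low,
      loa_high = ba$loa_high,
      rmse = rmse_pairs(a[ok], b[ok])
    )
  })
}
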