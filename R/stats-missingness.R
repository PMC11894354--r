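#' Box-Cox transformation with profile-likelihood lambda
#'
#' Chooses lambda by maximum profile log-likelihood over a fine grid
#' (refined around the optimum) and applies
#' `y -> (y^lambda - 1)/lambda` (`ln y` at `lambda = 0`).
#'
#' @param values Positive numeric vector.
#' @return List with `values` (transformed) and `lambda`.
#' @export
boxcox_transform <- function(values) {
  if (any(!is.finite(values))) abort("Box-Cox input must be finite.")
  if (any(values <= 0)) {
    abort("Box-Cox requires strictly positive values; shift or exclude non-positive observations first.")
  }
  fit <- MASS::boxcox(values ~ 1, lambda = seq(-3, 3, 0.05), plotit = FALSE)
  l0 <- fit$x[which.max(fit$y)]
  fine <- MASS::boxcox(values ~ 1, lambda = seq(l0 - 0.05, l0 + 0.05, 0.001),
                       plotit = FALSE)
  lambda <- fine$x[which.max(fine$y)]
  tf <- if (abs(lambda) < 1e-8) log(values) else (values^lambda - 1) / lambda
  list(values = tf, lambda = lambda)
}

#' Normal Q-Q points
#'
#' Ordered pairs of theoretical standard-normal quantiles against sample
#' quantiles, for visual normality assessment of a metric distribution.
#'
#' @param values Numeric vector, `n >= 3`.
#' @return Tibble with `theoretical` and `sample` columns; a `degenerate`
#'   attribute flags constant input.
#' @export
qq_points <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 3) abort("Q-Q points require at least 3 finite values.")
  out <- tibble::tibble(
    theoretical = qnorm(ppoints(length(values))),
    sample = sort(values)
  )
  attr(out, "degenerate") <- sd(values) == 0
  out
}

# sample skewness (m3 / m2^1.5)
sample_skewness <- function(x) {
  x <- x[is.finite(x)]
  m <- mean(x)
  mean((x - m)^3) / mean((x - m)^2)^1.5
}

#' Stack reference and degraded metric tables into long format
#'
#' One row per window x missingness level x metric, the layout the
#' mixed-model stage consumes. The reference table is labelled
#' `level = "ref"`; degraded tables carry their numeric level.
#'
#' @param reference Metric tibble from [compute_hrv()] (reference windows).
#' @param degraded Metric tibble for degraded windows (must carry a `level`
#'   column, e.g. from [degrade_dataset()] followed by [compute_hrv()]).
#' @return Long tibble with columns `participant_id`, `window_start_ms`,
#'   `activity`, `level`, `metric`, `value`.
#' @export
metrics_long <- function(reference, degraded) {
  prep <- function(tbl, lvl) {
    tbl <- metrics_table(tbl)
    if (!"level" %in% names(tbl)) tbl$level <- lvl
    tbl |>
      dplyr::mutate(level = as.character(.data$level)) |>
      tidyr::pivot_longer(
        cols = dplyr::all_of(c("median_ibi", "stdrr", "rmsdrr", "lf", "hf", "lf_hf")),
        names_to = "metric", values_to = "value"
      ) |>
      dplyr::select(dplyr::any_of(c("participant_id", "window_start_ms",
                                    "activity", "level", "metric", "value")))
  }
  dplyr::bind_rows(prep(reference, "ref"), prep(degraded, NA_character_)) |>
    dplyr::filter(is.finite(.data$value))
}

#' Default per-metric Box-Cox choices
#'
#' The transform bookkeeping used for free-living smartwatch HRV: at rest,
#' STDRR and RMSDRR are right-skewed and Box-Cox transformed; during light
#' activity, RMSDRR and LF/HF are. All other metric/activity combinations
#' are analysed untransformed.
#'
#' @return Tibble with `activity`, `metric`, `transform` columns.
#' @export
default_transform_map <- function() {
  tibble::tribble(
    ~activity, ~metric,   ~transform,
    "rest",    "stdrr",   "boxcox",
    "rest",    "rmsdrr",  "boxcox",
    "light",   "rmsdrr",  "boxcox",
    "light",   "lf_hf",   "boxcox"
  )
}

#' Mixed-model contrasts of HRV metrics by missingness level
#'
#' Fits `value ~ level + (1 | participant_id)` by REML to the long metric
#' table restricted to one metric and one activity class, with the reference
#' level as baseline, and reports one contrast per missingness level: the
#' estimated difference from reference, its SE, a two-sided p-value with
#' Satterthwaite-approximated denominator degrees of freedom, and a
#' percentile 95% CI from a parametric bootstrap (simulate from the fitted
#' model, refit; `n_boot` replicates).
#'
#' The metric can be Box-Cox transformed first: `transform = "auto"` applies
#' the transform when the map from `transform_map` requests it (falling back
#' to a |skewness| > 0.5 rule for metric/activity pairs absent from the
#' map), `"boxcox"` forces it, `"none"` disables it. Estimates for
#' transformed metrics are on the transformed scale.
#'
#' @param table Long tibble from [metrics_long()].
#' @param metric One of `"median_ibi"`, `"stdrr"`, `"rmsdrr"`, `"lf"`,
#'   `"hf"`, `"lf_hf"`.
#' @param activity `"rest"` or `"light"`.
#' @param n_boot Parametric-bootstrap replicates (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @param transform `"auto"`, `"none"` or `"boxcox"`.
#' @param transform_map Tibble like [default_transform_map()].
#' @return An object of class `hrv_contrasts`; see [tidy.hrv_contrasts()].
#' @export
fit_missingness_contrasts <- function(table, metric, activity = c("rest", "light"),
                                      n_boot = 1000, seed = 1L,
                                      transform = c("auto", "none", "boxcox"),
                                      transform_map = default_transform_map()) {
  activity <- match.arg(activity)
  transform <- match.arg(transform)
  dat <- table |>
    dplyr::filter(.data$metric == !!metric, .data$activity == !!activity,
                  is.finite(.data$value))
  if (nrow(dat) == 0) abort("No rows for this metric/activity combination.")
  lvls <- unique(dat$level)
  if (!"ref" %in% lvls || length(lvls) < 2) {
    abort("Need a reference level and at least one degraded level.")
  }
  if (dplyr::n_distinct(dat$participant_id) < 2) {
    abort("Random intercept unidentifiable with a single participant.")
  }

  use_boxcox <- switch(
    transform,
    none = FALSE,
    boxcox = TRUE,
    auto = {
      hit <- transform_map$transform[transform_map$metric == metric &
                                       transform_map$activity == activity]
      if (length(hit)) hit[1] == "boxcox" else
        abs(sample_skewness(dat$value[dat$level == "ref"])) > 0.5
    }
  )
  lambda <- NA_real_
  if (use_boxcox) {
    bc <- boxcox_transform(dat$value)
    dat$value <- bc$values
    lambda <- bc$lambda
  }

  num_lvls <- sort(as.numeric(setdiff(lvls, "ref")))
  dat$level <- factor(dat$level, levels = c("ref", as.character(num_lvls)))
  fit <- lmerTest::lmer(value ~ level + (1 | participant_id), data = dat,
                        REML = TRUE)
  coefs <- summary(fit)$coefficients
  rows <- paste0("level", num_lvls)

  boot <- withr::with_seed(as.integer(seed), suppressMessages(
    lme4::bootMer(fit, FUN = lme4::fixef, nsim = n_boot, type = "parametric",
                  use.u = FALSE)
  ))
  ci <- apply(boot$t, 2, quantile, probs = c(0.025, 0.975), names = FALSE)

  results <- tibble::tibble(
    metric = metric,
    activity = activity,
    level = num_lvls,
    estimate = coefs[rows, "Estimate"],
    se = coefs[rows, "Std. Error"],
    df = coefs[rows, "df"],
    ci_low = ci[1, rows],
    ci_high = ci[2, rows],
    p_value = coefs[rows, "Pr(>|t|)"],
    transform = if (use_boxcox) sprintf("boxcox(%.3f)", lambda) else "none"
  )
  structure(
    list(results = results, model = fit, metric = metric, activity = activity,
         lambda = lambda, n_boot = n_boot, seed = seed),
    class = "hrv_contrasts"
  )
}

#' @export
print.hrv_contrasts <- function(x, ...) {
  cat(sprintf("Missingness contrasts for %s (%s), %d bootstrap reps\n",
              x$metric, x$activity, x$n_boot))
  print(x$results)
  invisible(x)
}

#' Tidy missingness contrasts
#'
#' @param x An `hrv_contrasts` object.
#' @param ... Unused.
#' @return Tibble with one row per missingness level: estimate, SE,
#'   Satterthwaite df, bootstrap CI, p-value, transform tag.
#' @method tidy hrv_contrasts
#' @export
tidy.hrv_contrasts <- function(x, ...) x$results

#' Model-level summary of a contrast fit
#'
#' @param x An `hrv_contrasts` object.
#' @param ... Unused.
#' @return One-row tibble with variance components and fit size.
#' @method glance hrv_contrasts
#' @export
glance.hrv_contrasts <- function(x, ...) {
  vc <- as.data.frame(lme4::VarCorr(x$model))
  tibble::tibble(
    metric = x$metric,
    activity = x$activity,
    n_obs = stats::nobs(x$model),
    n_participants = lme4::ngrps(x$model)[["participant_id"]],
    sd_participant = vc$sdcor[vc$grp == "participant_id"],
    sd_residual = vc$sdcor[vc$grp == "Residual"],
    reml_criterion = lme4::REMLcrit(x$model)
  )
}
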