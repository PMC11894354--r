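test_that("Box-Cox lambda lands near 0 for log-normal and near 1 for normal data", {
  set.seed(11)
  ln <- exp(rnorm(10000, 0, 0.5))
  bc <- boxcox_transform(ln)
  expect_lt(abs(bc$lambda), 0.2)

  nm <- rnorm(10000, 50, 5)
  expect_lt(abs(boxcox_transform(nm)$lambda - 1), 0.2)

  expect_error(boxcox_transform(c(1, 0, 2)), "positive")
  expect_error(boxcox_transform(c(1, NA, 2)), "finite")
})

test_that("Box-Cox lambda maximises an independently coded profile likelihood", {
  set.seed(12)
  y <- exp(rnorm(500, 1, 0.4))
  # direct grid-search oracle for the profile log-likelihood
  loglik <- function(lam) {
    z <- if (abs(lam) < 1e-12) log(y) else (y^lam - 1) / lam
    n <- length(y)
    -n / 2 * log(mean((z - mean(z))^2)) + (lam - 1) * sum(log(y))
  }
  grid <- seq(-2, 2, 0.001)
  lam_oracle <- grid[which.max(vapply(grid, loglik, numeric(1)))]
  expect_equal(boxcox_transform(y)$lambda, lam_oracle, tolerance = 0.01)
  # transform applies (y^l - 1)/l
  bc <- boxcox_transform(y)
  expect_equal(bc$values, (y^bc$lambda - 1) / bc$lambda, tolerance = 1e-12)
})

test_that("Q-Q points pair theoretical and sample quantiles", {
  set.seed(4)
  x <- rnorm(2000)
  q <- qq_points(x)
  expect_identical(nrow(q), 2000L)
  expect_lt(max(abs(q$theoretical - q$sample)), 0.35)
  expect_false(attr(q, "degenerate"))
  expect_true(attr(qq_points(rep(1, 10)), "degenerate"))
  expect_identical(nrow(qq_points(c(1, 2, 3))), 3L)
  expect_error(qq_points(c(1, 2)), "at least 3")
})

test_that("identical raters give ICC agreement = consistency = 1", {
  x <- rnorm(20, 800, 50)
  r <- tidy(icc2k(cbind(x, x)))
  expect_equal(r$estimate, c(1, 1), tolerance = 1e-12)
})

test_that("an additive rater offset leaves consistency at 1 but lowers agreement", {
  x <- rnorm(20, 800, 50)
  r <- tidy(icc2k(cbind(x, x + 30)))
  expect_equal(r$estimate[r$type == "consistency"], 1, tolerance = 1e-12)
  expect_lt(r$estimate[r$type == "agreement"], 1)
})

test_that("ICC point estimates match an aov mean-squares oracle to 1e-9", {
  set.seed(21)
  for (i in 1:5) {
    x <- matrix(rnorm(40, 700, 60), ncol = 2)
    x[, 2] <- 0.7 * x[, 1] + rnorm(20, 100, 30)
    r <- tidy(icc2k(x))
    # independent route: mean squares from a two-way aov fit
    d <- data.frame(y = as.vector(x),
                    subj = factor(rep(seq_len(nrow(x)), 2)),
                    rater = factor(rep(1:2, each = nrow(x))))
    ms <- summary(stats::aov(y ~ subj + rater, data = d))[[1]][["Mean Sq"]]
    msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
    n <- nrow(x)
    expect_equal(r$estimate[r$type == "consistency"], (msr - mse) / msr,
                 tolerance = 1e-9)
    expect_equal(r$estimate[r$type == "agreement"],
                 (msr - mse) / (msr + (msc - mse) / n), tolerance = 1e-9)
  }
})

test_that("ICC is invariant to shifting both raters; degenerate input is flagged", {
  set.seed(5)
  x <- matrix(rnorm(30, 5, 2), ncol = 2)
  a <- tidy(icc2k(x))
  b <- tidy(icc2k(x + 1000))
  expect_equal(a$estimate, b$estimate, tolerance = 1e-8)
  expect_warning(r <- icc2k(matrix(c(rep(1, 5), rep(2, 5)), ncol = 2)),
                 "Zero between-subject")
  expect_true(all(is.na(tidy(r)$estimate)))
  expect_error(icc2k(matrix(1:6, ncol = 2)), "at least 5")
})

test_that("Bland-Altman statistics match the direct formulas", {
  d <- data.frame(a = c(1, 2, 3), b = c(1, 2, 3))
  g <- glance(bland_altman(d, a, b))
  expect_equal(g$mean_diff, 0)
  expect_equal(g$loa_high - g$loa_low, 0)

  d2 <- data.frame(a = c(10, 20, 30), b = c(5, 15, 25))
  g2 <- glance(bland_altman(d2, a, b))
  expect_equal(g2$mean_diff, 5)
  expect_equal(g2$loa_high - g2$loa_low, 0)

  set.seed(9)
  d3 <- data.frame(a = rnorm(50, 800, 60), b = rnorm(50, 790, 55))
  g3 <- glance(bland_altman(d3, a, b))
  diffs <- d3$a - d3$b
  expect_equal(g3$mean_diff, mean(diffs), tolerance = 1e-12)
  expect_equal(g3$loa_low, mean(diffs) - 1.96 * sd(diffs), tolerance = 1e-12)
  expect_equal(g3$loa_high, mean(diffs) + 1.96 * sd(diffs), tolerance = 1e-12)
  # swapping raters negates the mean difference
  g3r <- glance(bland_altman(d3, b, a))
  expect_equal(g3r$mean_diff, -g3$mean_diff)
  expect_identical(nrow(tidy(bland_altman(d3, a, b))), 50L)
})

test_that("rmse matches brute force", {
  expect_equal(rmse_pairs(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse_pairs(c(10, 20), c(5, 15)), 5)
  set.seed(2)
  a <- rnorm(100); b <- rnorm(100)
  expect_equal(rmse_pairs(a, b), sqrt(sum((a - b)^2) / 100), tolerance = 1e-12)
})

test_that("device alignment inner-joins on participant and window", {
  mk <- function(starts, device, ids = "P01") {
    tibble::tibble(participant_id = ids, device = device,
                   window_start_ms = starts,
                   median_ibi = 800 + starts / 1e5, stdrr = 50, rmsdrr = 40,
                   lf = 6, hf = 5.5, lf_hf = 6 / 5.5,
                   time_valid = TRUE, freq_valid = TRUE)
  }
  p <- mk(c(0, 300000, 600000), "ppg")
  e <- mk(c(300000, 600000, 900000), "ecg")
  paired <- align_devices(p, e)
  expect_equal(paired$window_start_ms, c(300000, 600000))
  expect_true(all(c("median_ibi_ppg", "median_ibi_ecg") %in% names(paired)))
  expect_error(align_devices(p, mk(c(2e6, 3e6), "ecg")), "No overlapping")
})

test_that("agreement table reports near-perfect ICC and zero RMSE for identical devices", {
  set.seed(14)
  p <- tibble::tibble(
    participant_id = "P01", device = "ppg",
    window_start_ms = 300000 * (0:19),
    median_ibi = rnorm(20, 890, 40), stdrr = runif(20, 30, 70),
    rmsdrr = runif(20, 20, 60), lf = rnorm(20, 6.5, 0.5),
    hf = rnorm(20, 5.5, 0.5), lf_hf = rnorm(20, 1.2, 0.1),
    time_valid = TRUE, freq_valid = TRUE
  )
  e <- dplyr::mutate(p, device = "ecg")
  tab <- agreement_analysis(align_devices(p, e))
  expect_identical(nrow(tab), 6L)
  expect_true(all(abs(tab$icc_agreement - 1) < 1e-9))
  expect_true(all(tab$rmse == 0))
})

test_that("duplicated level data gives a zero contrast with p near 1", {
  tab <- sim_long(n_part = 6, n_win = 20, effect = 0, seed = 3)
  # make degraded rows exact copies of reference
  tab$value[tab$level == "10"] <- tab$value[tab$level == "ref"]
  fit <- fit_missingness_contrasts(tab, "hf", "rest", n_boot = 30, seed = 1,
                                   transform = "none")
  res <- tidy(fit)
  expect_equal(res$estimate, 0, tolerance = 1e-10)
  expect_gt(res$p_value, 0.99)
})

test_that("a known level effect is recovered with a covering bootstrap CI", {
  tab <- sim_long(n_part = 10, n_win = 40, effect = -0.5, seed = 7)
  fit <- fit_missingness_contrasts(tab, "hf", "rest", n_boot = 60, seed = 2,
                                   transform = "none")
  res <- tidy(fit)
  expect_equal(res$estimate, -0.5, tolerance = 0.15)
  expect_lt(res$ci_low, -0.5 + 0.2)
  expect_gt(res$ci_high, -0.5 - 0.2)
  expect_lt(res$p_value, 0.001)
  expect_true(res$ci_low <= res$estimate & res$estimate <= res$ci_high)
  g <- glance(fit)
  expect_equal(g$n_participants, 10)
  expect_equal(g$sd_residual, 1, tolerance = 0.15)
})

test_that("bootstrap CIs are reproducible under the seed", {
  tab <- sim_long(n_part = 6, n_win = 15, effect = -0.3, seed = 5)
  a <- tidy(fit_missingness_contrasts(tab, "hf", "rest", n_boot = 25, seed = 9,
                                      transform = "none"))
  b <- tidy(fit_missingness_contrasts(tab, "hf", "rest", n_boot = 25, seed = 9,
                                      transform = "none"))
  expect_equal(a, b)
})

test_that("contrast fitting validates its inputs and transform bookkeeping", {
  tab <- sim_long(n_part = 6, n_win = 10, seed = 8)
  expect_error(fit_missingness_contrasts(tab, "stdrr", "rest"), "No rows")
  one <- dplyr::filter(tab, participant_id == "P01")
  expect_error(fit_missingness_contrasts(one, "hf", "rest"),
               "single participant")
  noref <- dplyr::filter(tab, level != "ref")
  expect_error(fit_missingness_contrasts(noref, "hf", "rest"), "reference")

  # the default map requests Box-Cox for rest stdrr and records lambda
  tab_pos <- dplyr::mutate(tab, metric = "stdrr", value = exp(value / 2))
  fit <- fit_missingness_contrasts(tab_pos, "stdrr", "rest", n_boot = 20,
                                   seed = 1, transform = "auto")
  expect_match(tidy(fit)$transform[1], "^boxcox\\(")
  fit_none <- fit_missingness_contrasts(tab_pos, "stdrr", "rest", n_boot = 20,
                                        seed = 1, transform = "none")
  expect_identical(tidy(fit_none)$transform[1], "none")
})
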