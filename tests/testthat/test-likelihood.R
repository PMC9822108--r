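mod <- metabolism_model()

make_toy_data <- function(times = c(600, 900), obs = c("Lac", "Gluc"),
                          sem = 2, experiment = "lin_single",
                          zero_noise = TRUE, seed = 1) {
  generate_dataset(mod, paradigm_name = experiment, observables = obs,
                   sample_times = times,
                   noise = noise_model(Lac = sem, Gluc = sem,
                                       Glut = sem, Asp = sem),
                   seed = seed) -> d
  if (zero_noise) {
    pred <- neurometab:::model_predictions(numeric(0), d, mod)
    d$mean_pct <- pred$yhat
  }
  d
}

test_that("zero residuals leave only the Gaussian normalization term", {
  d <- make_toy_data()
  J <- negative_log_likelihood(numeric(0), d, mod)
  expect_equal(J, 0.5 * sum(log(2 * pi * d$sem_pct^2)), tolerance = 1e-12)
  expect_lt(chi2_statistic(numeric(0), d, mod), 1e-10)
})

test_that("a unit residual with unit sigma has the closed-form value", {
  # one pre-stimulus sample where the model predicts exactly 0%
  d <- make_toy_data(times = 100, obs = "Lac", sem = 1)
  d$mean_pct <- 1
  J <- negative_log_likelihood(numeric(0), d, mod)
  expect_equal(J, 0.5 * (log(2 * pi) + 1), tolerance = 1e-9)
})

test_that("doubling sigma with zero residuals adds N log 2", {
  d <- make_toy_data()
  J1 <- negative_log_likelihood(numeric(0), d, mod)
  d2 <- d
  d2$sem_pct <- 2 * d2$sem_pct
  J2 <- negative_log_likelihood(numeric(0), d2, mod)
  expect_equal(J2 - J1, nrow(d) * log(2), tolerance = 1e-10)
})

test_that("the likelihood decomposes over datasets", {
  d1 <- make_toy_data(zero_noise = FALSE, seed = 5)
  d2 <- generate_dataset(mod, paradigm_name = "lin_double",
                         observables = c("Glut", "Asp"),
                         sample_times = c(700, 1400), seed = 6)
  th <- c(reference_parameters(), default_scalings())
  expect_equal(negative_log_likelihood(th, list(d1, d2), mod),
               negative_log_likelihood(th, d1, mod) +
                 negative_log_likelihood(th, d2, mod),
               tolerance = 1e-10)
  expect_equal(chi2_statistic(th, list(d1, d2), mod),
               chi2_statistic(th, d1, mod) + chi2_statistic(th, d2, mod),
               tolerance = 1e-10)
})

test_that("simulation failures give an optimizer-safe infinite objective", {
  d <- make_toy_data()
  bad <- c(reference_parameters(), default_scalings())
  bad[["k_o2in"]] <- 1  # irrelevant for this model; break steady state instead
  bad[["kmaxGln"]] <- -1
  expect_warning(J <- negative_log_likelihood(bad, d, mod))
  expect_identical(J, Inf)
})

test_that("chi-squared thresholds match the reference quantiles", {
  expect_equal(round(chi2_threshold(0.05, 191), 2), 224.24)
  expect_equal(round(chi2_threshold(0.05, 1), 3), 3.841)
  dofs <- c(1, 5, 20, 100, 191)
  expect_true(all(diff(vapply(dofs, chi2_threshold, 1, alpha = 0.05)) > 0))
  expect_error(chi2_threshold(0, 10))
  expect_error(chi2_threshold(0.05, 0))
})

test_that("the rejection test is boundary-inclusive", {
  expect_true(chi2_test(213.44, 0.05, 191)$pass)
  thr <- chi2_threshold(0.05, 191)
  expect_true(chi2_test(thr, 0.05, 191)$pass)
  expect_false(chi2_test(thr + 1, 0.05, 191)$pass)
})

test_that("residual statistics at truth are chi-squared distributed", {
  # data simulated exactly at the true parameters: the weighted residual
  # sum over repeated noise draws follows a chi-squared with one dof per
  # residual (reduced-scale: one experiment, 200 replicates)
  d0 <- make_toy_data(times = seq(200, 2200, by = 200),
                      obs = c("Lac", "Glut", "Gluc", "Asp"))
  pred <- d0$mean_pct  # noise-free model values
  n <- nrow(d0)
  set.seed(99)
  stats <- replicate(200, {
    y <- pred + rnorm(n, 0, d0$sem_pct)
    sum(((y - pred) / d0$sem_pct)^2)
  })
  ks <- stats::ks.test(stats, "pchisq", df = n)
  expect_gt(ks$p.value, 0.01)
})

test_that("datasets round-trip through the CSV schema", {
  d <- make_toy_data(zero_noise = FALSE, seed = 3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_dataset(d, f)
  back <- read_dataset(f)
  expect_equal(as.data.frame(back), as.data.frame(d), tolerance = 1e-12)
  expect_equal(attr(back, "paradigms")$lin_single$on,
               attr(d, "paradigms")$lin_single$on)
  # validation: sigma must be positive, times within horizon
  d_bad <- as.data.frame(d); d_bad$sem_pct[1] <- 0
  expect_error(nmc_dataset(d_bad, attr(d, "paradigms")), "positive")
  d_bad2 <- as.data.frame(d); d_bad2$time_s[1] <- 1e6
  expect_error(nmc_dataset(d_bad2, attr(d, "paradigms")), "horizon")
})
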