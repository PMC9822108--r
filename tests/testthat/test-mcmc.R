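test_that("retained set of a quadratic objective matches the level set", {
  # J = (theta - 2)^2 / 2: with threshold Delta the acceptable set is
  # theta in 2 +/- sqrt(2 * Delta). alpha = 0.5 keeps the set inside the
  # positive axis sampled in log space.
  obj <- function(th) (th[["x"]] - 2)^2 / 2
  delta <- chi2_threshold(0.5, 1)
  post <- mcmc_sample(obj, n_samples = 20000, seed = 4,
                      start = c(x = 2), alpha = 0.5, dof = 1,
                      init_step = 0.1)
  expect_true(all(post$stat[post$retained] <= post$best + delta + 1e-12))
  xs <- post$draws[post$retained, "x"]
  lo <- 2 - sqrt(2 * delta); hi <- 2 + sqrt(2 * delta)
  expect_gt(min(xs), lo - 0.05)
  expect_lt(max(xs), hi + 0.05)
  # the sampled set approaches the analytic bounds
  expect_lt(min(xs), lo + 0.25)
  expect_gt(max(xs), hi - 0.25)
  expect_true(min(xs) < 2 && max(xs) > 2)  # brackets the optimum
})

test_that("zero draws give an empty set without error", {
  obj <- function(th) (th[["x"]] - 2)^2
  post <- mcmc_sample(obj, n_samples = 0, seed = 1, start = c(x = 2))
  expect_equal(nrow(post$draws), 0)
  expect_equal(sum(post$retained), 0)
})

# a small real fit shared by the envelope tests
mod <- metabolism_model()
env_data <- generate_dataset(
  mod, paradigm_name = "lin_single", observables = c("Lac", "Gluc"),
  sample_times = seq(300, 2100, by = 300), seed = 31)
env_fit <- nmc_fit(env_data, mod,
                   config = fit_config(n_starts = 1, maxiter = 15),
                   seed = 31)
env_post <- suppressWarnings(
  mcmc_sample(env_fit, n_samples = 800, seed = 32))

test_that("every retained draw satisfies the acceptable-set criterion", {
  delta <- chi2_threshold(0.05, length(env_fit$theta))
  expect_equal(env_post$delta, delta)
  expect_true(all(env_post$stat[env_post$retained] <=
                    env_post$best + delta + 1e-9))
})

test_that("envelopes contain the best fit and behave under set size", {
  tt <- seq(0, 2376, 60)
  env <- prediction_envelope(env_post, "lin_single", "Lac", times = tt,
                             max_draws = 60)
  expect_true(all(env$lower <= env$best + 1e-9))
  expect_true(all(env$upper >= env$best - 1e-9))
  # enlarging the retained set (nested subsets) can only widen the band
  idx <- which(env_post$retained)
  post_a <- env_post; post_a$retained[] <- FALSE
  post_a$retained[idx[1:15]] <- TRUE
  post_b <- env_post; post_b$retained[] <- FALSE
  post_b$retained[idx[1:30]] <- TRUE
  env_a <- prediction_envelope(post_a, "lin_single", "Lac", times = tt,
                               max_draws = 50)
  env_b <- prediction_envelope(post_b, "lin_single", "Lac", times = tt,
                               max_draws = 50)
  expect_true(all(env_b$upper >= env_a$upper - 1e-9))
  expect_true(all(env_b$lower <= env_a$lower + 1e-9))
  # degenerate single-draw set: zero-width band at the best draw
  post1 <- env_post
  keep <- which(post1$retained)[1]
  post1$draws <- post1$draws[keep, , drop = FALSE]
  post1$stat <- post1$stat[keep]
  post1$retained <- TRUE
  env1 <- prediction_envelope(post1, "lin_single", "Lac", times = tt)
  expect_equal(env1$lower, env1$upper, tolerance = 1e-10)
  # empty retained set errors
  post0 <- env_post
  post0$retained[] <- FALSE
  expect_error(prediction_envelope(post0, "lin_single", "Lac"),
               "empty")
})
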