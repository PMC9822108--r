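test_that("model documents round-trip through JSON", {
  mod <- metabolism_model()
  f <- withr::local_tempfile(fileext = ".json")
  write_model_json(mod, f)
  back <- read_model_json(f, quiet = TRUE)
  expect_equal(back$states, mod$states)
  expect_equal(unlist(back$parameters), unlist(mod$parameters))
  expect_equal(back$rates, mod$rates)
  expect_equal(back$odes, mod$odes)
  # a structurally identical import regains the compiled fast path
  expect_false(is.null(back$compiled))
  # and simulates identically
  ss <- steady_state(mod)
  pp <- make_paradigm("witt_bold")
  a <- simulate_model(mod, paradigm = pp, times = seq(0, 20, 1), init = ss)
  b <- simulate_model(back, paradigm = pp, times = seq(0, 20, 1), init = ss)
  expect_equal(a$values, b$values)
})

test_that("symbol resolution is validated with the offending name", {
  bad <- metabolism_model()
  bad$rates$V_LDH <- "kmaxPyr * Pyruvate"
  expect_error(neurometab:::validate_model(bad), "Pyruvate")
  bad2 <- metabolism_model()
  bad2$odes$Lac <- "V_LDH - V_nope"
  expect_error(neurometab:::validate_model(bad2), "V_nope")
})

test_that("parameter counts are reported with a scaling breakdown", {
  cnt <- model_parameter_count(metabolism_model())
  expect_equal(cnt$kinetic, 19)
  expect_equal(cnt$scalings, 4)
  expect_equal(cnt$total, 23)
  cmb <- combine_models(metabolism_model(), nvc_model())
  cnt2 <- model_parameter_count(cmb)
  expect_equal(cnt2$total, cnt2$kinetic + cnt2$scalings)
  # 35 ODE-level constants + the BOLD exponent ky + 6 scalings
  expect_equal(cnt2$kinetic, 36)
  expect_equal(cnt2$scalings, 6)
  expect_equal(cnt2$total, 42)
})

test_that("rate expressions expand recursively into state equations", {
  mod <- metabolism_model()
  f <- neurometab:::model_field(mod)
  vars <- all.vars(f$Pyr)
  expect_true(all(c("Gluc_t", "Stimulus", "Pyr", "OAA", "kmaxPO",
                    "KM_Pyr", "KM_OAA") %in% vars))
  expect_false(any(grepl("^V_", vars)))
})

test_that("series and reports export to the stated text formats", {
  mod <- metabolism_model()
  ss <- steady_state(mod)
  tr <- simulate_model(mod, paradigm = make_paradigm("witt_bold"),
                       times = seq(0, 20, 5), init = ss)
  f <- withr::local_tempfile(fileext = ".csv")
  write_series_csv(tr, f)
  tab <- read.csv(f)
  expect_equal(names(tab), c("time_s", mod$states))
  obs <- observe(tr, mod, ss = ss)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_series_csv(obs, f2)
  expect_equal(names(read.csv(f2)), c("time_s", names(mod$observables)))

  d <- generate_dataset(mod, paradigm_name = "lin_single",
                        observables = "Lac", sample_times = c(600, 900),
                        seed = 2)
  fit <- nmc_fit(d, mod, fit_params = c("kmaxPyr", "k1", "ky_Lac"),
                 config = fit_config(n_starts = 1, maxiter = 5), seed = 2)
  fj <- withr::local_tempfile(fileext = ".json")
  write_fit_json(fit, fj)
  back <- jsonlite::read_json(fj, simplifyVector = TRUE)
  expect_equal(back$objective, fit$objective)
  expect_equal(back$theta_hash, neurometab:::param_hash(fit$theta))
  post <- suppressWarnings(mcmc_sample(fit, n_samples = 100, seed = 3))
  pc <- withr::local_tempfile(fileext = ".csv")
  write_posterior_csv(post, pc)
  draws <- read.csv(pc, check.names = FALSE)
  expect_equal(nrow(draws), nrow(post$draws))
  expect_true(all(c("stat", "retained", "kmaxPyr") %in% names(draws)))
})
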