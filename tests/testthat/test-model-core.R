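mod <- metabolism_model()

test_that("right-hand side matches the independent flux-table oracle", {
  set.seed(42)
  for (i in 1:100) {
    st <- random_metab_state()
    p <- random_metab_params()
    u <- sample(0:1, 1)
    want <- metab_flux_oracle(st, c(p, u = u))$derivs
    got <- package_rhs_at(mod, st, p, u = u)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("compiled and interpreted right-hand sides agree along a simulation", {
  ss <- steady_state(mod)
  par1 <- make_paradigm("lin_single")
  tt <- seq(0, 2376, by = 120)
  tr_c <- simulate_model(mod, paradigm = par1, times = tt, init = ss)
  mod_r <- mod
  mod_r$compiled <- NULL
  tr_r <- simulate_model(mod_r, paradigm = par1, times = tt, init = ss)
  expect_equal(tr_c$values, tr_r$values, tolerance = 1e-7)
})

test_that("steady state satisfies the closed-form balances", {
  p <- reference_parameters()
  ss <- steady_state(mod, p)
  expect_equal(ss[["Gluc_c"]], p[["Glucose_blood"]] / p[["kmax_glucc"]])
  expect_equal(ss[["Gln"]],
               p[["kmaxGlut1"]] / p[["kmaxGln"]] * ss[["Glut"]])
  f <- package_rhs_at(mod, ss, p, u = 0)
  expect_lt(max(abs(f)), 1e-9)
  # turnover balances at rest
  fl <- metab_flux_oracle(ss, c(p, u = 0))$fluxes
  expect_lt(abs(fl[["V_GS"]] - fl[["V_PAG"]]), 1e-9)
  expect_lt(abs(fl[["V_Gluc"]] - fl[["V_glycolysis"]]), 1e-9)
  expect_true(all(ss >= 0))
})

test_that("steady state holds for perturbed parameter sets", {
  set.seed(7)
  for (i in 1:20) {
    p <- random_metab_params()
    ss <- steady_state(mod, p)
    expect_lt(max(abs(package_rhs_at(mod, ss, p, u = 0))), 1e-9)
  }
})

test_that("without stimulation every observable stays flat at zero", {
  ss <- steady_state(mod)
  quiet <- stimulus_paradigm(numeric(0), numeric(0), horizon = 3000)
  tr <- simulate_model(mod, paradigm = quiet, times = seq(0, 3000, 30),
                       init = ss)
  obs <- observe(tr, mod, ss = ss)
  for (o in obs) expect_lt(max(abs(o$values)), 0.01)
  # state-level constancy
  expect_lt(max(abs(sweep(tr$values, 2, ss, "-"))), 1e-6)
})

test_that("halving solver tolerances barely changes the trajectory", {
  ss <- steady_state(mod)
  par1 <- make_paradigm("lin_single")
  tt <- seq(0, 2376, by = 120)
  a <- simulate_model(mod, paradigm = par1, times = tt, init = ss,
                      rtol = 1e-8, atol = 1e-10)
  b <- simulate_model(mod, paradigm = par1, times = tt, init = ss,
                      rtol = 5e-9, atol = 5e-11)
  expect_lt(max(abs(a$values - b$values)), 1e-6)
})

test_that("sustained stimulation drives the reported response pattern", {
  ss <- steady_state(mod)
  par1 <- make_paradigm("lin_single")
  tr <- simulate_model(mod, paradigm = par1, times = seq(0, 2376, 4),
                       init = ss)
  obs <- observe(tr, mod, ss = ss)
  instim <- tr$times >= 396 & tr$times <= 1188
  expect_gt(max(obs$Lac$values[instim]), 5)
  expect_gt(max(obs$Glut$values[instim]), 1)
  expect_lt(min(obs$Gluc$values[instim]), -5)
  expect_lt(min(obs$Asp$values[instim]), -1)
  # glycolysis flux with the stimulus off equals its basal form
  p <- reference_parameters()
  st <- random_metab_state(); st[["Stimulus"]] <- 0
  fl <- metab_flux_oracle(st, c(p, u = 0))$fluxes
  expect_equal(fl[["V_glycolysis"]], p[["kmax_gluct"]] * st[["Gluc_t"]])
})

test_that("simulated concentrations stay non-negative across random models", {
  set.seed(11)
  par1 <- make_paradigm("lin_single")
  par2 <- make_paradigm("lin_double")
  for (i in 1:100) {
    p <- random_metab_params()
    ss <- steady_state(mod, p)
    pp <- if (i %% 2 == 0) par1 else par2
    tr <- simulate_model(mod, p, pp,
                         times = seq(0, pp$horizon, length.out = 60),
                         init = ss)
    # never below baseline by more than the solver error scale
    # (rtol * |state| + atol)
    expect_gt(min(tr$values), -1e-8)
  }
})

test_that("percent-change observables follow the scaling definition", {
  p <- reference_parameters()
  ss <- steady_state(mod, p)
  fake <- structure(list(times = c(0, 1, 2),
                         values = rbind(ss, ss * 1.1, ss * 0.9),
                         init = ss, model = mod$name,
                         diagnostics = list()),
                    class = "nmc_trajectory")
  rownames(fake$values) <- NULL
  o1 <- observe(fake, mod, p, ss = ss)
  expect_equal(o1$Lac$values, c(0, 10, -10), tolerance = 1e-12)
  o2 <- observe(fake, mod, p, scalings = c(ky_Lac = 2), ss = ss)
  expect_equal(o2$Lac$values, c(0, 20, -20), tolerance = 1e-12)
  expect_error(observe(fake, mod, p, names = "Pyruvate"), "unknown")
})
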