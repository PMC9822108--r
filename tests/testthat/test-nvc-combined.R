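cmb <- combine_models(metabolism_model(), nvc_model())

test_that("assembly removes the standalone stimulus/glucose equations", {
  expect_false(any(c("Gluc_c", "Gluc_t", "Stimulus") %in% cmb$states))
  expect_true(all(c("Glucose_A", "O2_A", "Delay_M", "dHb") %in% cmb$states))
  # pyruvate production references the NVC quantities after expansion
  pyr <- all.vars(neurometab:::expand_expression(cmb$odes$Pyr, cmb))
  expect_true(all(c("Glucose_A", "O2_A", "Delay_M") %in% pyr))
  # the retained metabolite equations are verbatim
  met <- metabolism_model()
  for (s in c("Lac", "OAA", "OG", "Asp", "Glut", "Gln"))
    expect_identical(cmb$odes[[s]], met$odes[[s]])
})

test_that("assembly fails loudly when the NVC submodel lacks a contract symbol", {
  broken <- nvc_model()
  broken$states <- setdiff(broken$states, "Delay_M")
  broken$odes$Delay_M <- NULL
  expect_error(combine_models(metabolism_model(), broken), "Delay_M")
  broken2 <- nvc_model()
  broken2$rates$V_stimMet <- NULL
  expect_error(combine_models(metabolism_model(), broken2), "V_stimMet")
})

test_that("BOLD signal is exp(-ky * dHb) with the expected properties", {
  expect_equal(bold_signal(0, 0.15), 1)
  d <- seq(0, 5, by = 0.5)
  v <- bold_signal(d, 0.15)
  expect_true(all(diff(v) < 0))
  expect_error(bold_signal(-1, 0.15))
  # percent-change BOLD observable is 0 at steady state
  ss <- steady_state(cmb)
  quiet <- stimulus_paradigm(numeric(0), numeric(0), horizon = 60)
  tr <- simulate_model(cmb, paradigm = quiet, times = seq(0, 60, 1),
                       init = ss)
  ob <- observe(tr, cmb, ss = ss)
  for (o in ob) expect_lt(max(abs(o$values)), 1e-6)
})

test_that("a pass-through NVC document reproduces the standalone model", {
  # Surrogate whose hemodynamic states are inert and whose metabolic
  # rates equal the standalone glycolysis split into basal + stimulated
  # parts; assembling it must reproduce the standalone metabolite
  # trajectories exactly (up to solver tolerance).
  met <- metabolism_model()
  p <- reference_parameters()
  passthrough <- structure(list(
    name = "nvc_passthrough",
    states = c("Delay_M", "Glucose_A", "Gluc_c", "O2_A", "dHb"),
    parameters = as.list(c(kstim1 = p[["kstim1"]], kstim2 = p[["kstim2"]],
                           kmax_glucc = p[["kmax_glucc"]],
                           kmax_gluct = p[["kmax_gluct"]],
                           Glucose_blood = p[["Glucose_blood"]],
                           ky = 0.1)),
    inputs = "u",
    rates = list(
      V_baseMet = "kmax_gluct * Glucose_A",
      V_stimMet = "kmax_gluct * Glucose_A * Delay_M"),
    odes = list(
      Delay_M = "kstim1 * u - kstim2 * Delay_M",
      Glucose_A = "kmax_glucc * Gluc_c - (V_baseMet + V_stimMet)",
      Gluc_c = "Glucose_blood - kmax_glucc * Gluc_c",
      O2_A = "0 * O2_A",
      dHb = "0 * dHb"),
    observables = list(BOLD = list(expr = "exp(-ky * dHb)",
                                   scaling = "ky_BOLD")),
    compiled = NULL), class = "nmc_model")

  joined <- combine_models(met, passthrough)
  expect_null(joined$compiled)  # custom structure runs interpreted

  ss_met <- steady_state(met)
  ss_join <- stats::setNames(rep(NA_real_, length(joined$states)),
                             joined$states)
  ss_join[c("Delay_M", "Glucose_A", "Gluc_c", "O2_A", "dHb")] <-
    c(0, ss_met[["Gluc_t"]], ss_met[["Gluc_c"]], 1, 1)
  mets <- c("Pyr", "Lac", "OAA", "OG", "Asp", "Glut", "Gln")
  ss_join[mets] <- ss_met[mets]

  par1 <- make_paradigm("lin_single")
  tt <- seq(0, 2376, by = 60)
  tr_met <- simulate_model(met, paradigm = par1, times = tt, init = ss_met)
  tr_join <- simulate_model(joined, paradigm = par1, times = tt,
                            init = ss_join)
  for (s in mets) {
    rel <- max(abs(tr_join$values[, s] - tr_met$values[, s]) /
                 pmax(abs(tr_met$values[, s]), 1e-12))
    expect_lt(rel, 1e-8)
  }
})

test_that("a short stimulus yields dip, peak and undershoot in order", {
  sim <- simulate_combined(paradigm = make_paradigm("witt_bold"))
  b <- sim$observables$BOLD
  v <- b$values; tt <- b$times
  imax <- which.max(v)
  pre <- tt < tt[imax]; post <- tt > tt[imax]
  t_dip <- tt[pre][which.min(v[pre])]
  t_peak <- tt[imax]
  t_und <- tt[post][which.min(v[post])]
  expect_lt(v[pre][which.min(v[pre])], -0.01)        # a real dip
  expect_gt(v[imax], 0.2)                            # a real main peak
  expect_lt(min(v[post]), -0.01)                     # a real undershoot
  expect_true(t_dip < t_peak && t_peak < t_und)      # temporal order
  expect_true(t_dip >= 1 && t_dip <= 3.5)
  expect_true(t_peak >= 5 && t_peak <= 7)
  expect_true(t_und >= 10 && t_und <= 16)
})

test_that("metabolism outlasts the BOLD response for double short stimuli", {
  sim <- simulate_combined(paradigm = make_paradigm("lundengard_double"))
  b <- sim$observables$BOLD
  expect_lt(max(abs(b$values[b$times >= 20])), 0.05)
  late_dev <- vapply(sim$observables[c("Lac", "Glut", "Gluc", "Asp")],
                     function(o) {
                       pk <- max(abs(o$values))
                       abs(o$values[which.min(abs(o$times - 20))]) / pk
                     }, numeric(1))
  expect_gt(max(late_dev), 0.10)
})
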