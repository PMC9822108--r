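# Shared helpers: toy model documents and an independent flux-table
# evaluation of the metabolism right-hand side.

toy_decay_model <- function(k = 0.5) {
  structure(list(
    name = "toy_decay", states = "x", parameters = list(k = k),
    inputs = character(0), rates = list(),
    odes = list(x = "0 - k * x"),
    observables = list(y = list(expr = "x", scaling = "ky_y")),
    compiled = NULL), class = "nmc_model")
}

toy_scaled_model <- function(k = 0.5, cc = 2) {
  structure(list(
    name = "toy_scaled", states = "x",
    parameters = list(k = k, cc = cc),
    inputs = character(0), rates = list(),
    odes = list(x = "0 - k * x"),
    observables = list(y = list(expr = "cc * x", scaling = "ky_y")),
    compiled = NULL), class = "nmc_model")
}

# Independent term-by-term flux table for the metabolism model, written
# directly from the rate laws (kept deliberately separate from the
# package's model document so it can serve as an oracle).
metab_flux_oracle <- function(state, p) {
  with(as.list(c(state, p)), {
    fl <- c(
      V_Gluc = kmax_glucc * Gluc_c,
      V_glycolysis = kmax_gluct * Gluc_t * (1 + Stimulus),
      V_LDH = kmaxPyr * Pyr,
      V_PC = kmaxPyr2 * Pyr / (KM_Pyr2 + Pyr),
      V_TCA1 = kmaxPO * (Pyr / (KM_Pyr + Pyr)) * (OAA / (KM_OAA + OAA)),
      V_TCA2 = kmaxOG1 * OG,
      V_GOT = kmaxOAA * OAA,
      V_xm = kmaxOG2 * OG,
      V_GS = kmaxGln * Gln,
      V_PAG = kmaxGlut1 * Glut,
      V_clear1 = k1 * Lac,
      V_clear2 = kmaxAsp * Asp,
      V_clear3 = kmaxGlut2 * Glut)
    u <- if ("u" %in% names(p)) p[["u"]] else 0
    derivs <- c(
      Stimulus = kstim1 * u - kstim2 * Stimulus,
      Gluc_c = Glucose_blood - fl[["V_Gluc"]],
      Gluc_t = fl[["V_Gluc"]] - fl[["V_glycolysis"]],
      Pyr = fl[["V_glycolysis"]] - fl[["V_TCA1"]] - fl[["V_LDH"]] -
        fl[["V_PC"]],
      Lac = fl[["V_LDH"]] - fl[["V_clear1"]],
      OAA = fl[["V_TCA2"]] + fl[["V_PC"]] - fl[["V_TCA1"]] -
        fl[["V_GOT"]],
      OG = fl[["V_TCA1"]] - fl[["V_TCA2"]] - fl[["V_xm"]],
      Asp = fl[["V_GOT"]] - fl[["V_clear2"]],
      Glut = fl[["V_xm"]] + fl[["V_GS"]] - fl[["V_PAG"]] -
        fl[["V_clear3"]],
      Gln = fl[["V_PAG"]] - fl[["V_GS"]])
    list(fluxes = fl, derivs = derivs)
  })
}

# Evaluate the package's interpreted right-hand side at a point.
package_rhs_at <- function(model, state, p, u = 0) {
  rhs <- neurometab:::build_rhs(model)
  stats::setNames(unlist(rhs(0, state, c(p, u = u))), model$states)
}

random_metab_state <- function() {
  stats::setNames(10^stats::runif(10, -1, 1),
                  c("Stimulus", "Gluc_c", "Gluc_t", "Pyr", "Lac", "OAA",
                    "OG", "Asp", "Glut", "Gln"))
}

random_metab_params <- function() {
  p <- reference_parameters()
  p * 10^stats::runif(length(p), -0.5, 0.5)
}
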