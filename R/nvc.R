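## Surrogate neurovascular submodel and assembly of the combined
## metabolism + NVC model.

.combined_par_names <- c(
  "tau_n", "kdm1", "kdm2", "tau_f1", "tau_f2", "tau_f3", "a_F", "a_V",
  "tau_v",
  "k_o2in", "k_o2leak", "a_O", "k_o2use", "k_glcin", "a_G", "k_dhb",
  "k_wash", "k_basalMet", "k_prop1", "k_prop2", "k_dip",
  "kmaxPO", "KM_Pyr", "KM_OAA", "kmaxPyr", "kmaxPyr2", "KM_Pyr2", "k1",
  "kmaxOG1", "kmaxOAA", "kmaxOG2", "kmaxAsp", "kmaxGln", "kmaxGlut1",
  "kmaxGlut2")

#' Reference parameters for the surrogate neurovascular submodel
#'
#' Defaults are calibrated so that a 0.5 s stimulus produces an
#' archetypical BOLD response: an initial dip near 2 s (early rise in
#' oxygen consumption before the flow response arrives), a positive peak
#' near 5-7 s (flow-driven washout of deoxyhaemoglobin), and a post-peak
#' undershoot spanning roughly 10-16 s (venous volume relaxing more slowly
#' than flow). Time constants `tau_*` are in seconds; rate constants per
#' second.
#'
#' @return named numeric vector of the NVC and coupling parameters.
#' @export
nvc_reference_parameters <- function() {
  c(tau_n = 0.8, kdm1 = 1.2, kdm2 = 0.35,
    tau_f1 = 1.65, tau_f2 = 1.65, tau_f3 = 1.65, a_F = 7, a_V = 3.6,
    tau_v = 1.5,
    k_o2in = 0.02, k_o2leak = 0.01, a_O = 0.1, k_o2use = 1.0,
    k_glcin = 0.01, a_G = 0.1, k_dhb = 60, k_wash = 0.7,
    k_basalMet = 0.1, k_prop1 = 0.1, k_prop2 = 0.00052, k_dip = 0.004,
    ky = 0.06)
}

#' The surrogate neurovascular model document
#'
#' A minimal feed-forward hemodynamic model standing in for a full
#' neurovascular submodel. It exposes the quantities required by the
#' coupling contract: tissue glucose `Glucose_A`, tissue oxygen `O2_A`,
#' the stimulus-to-metabolism intermediate `Delay_M`, deoxyhaemoglobin
#' `dHb`, and the metabolic rates `V_baseMet` and `V_stimMet`. A fast
#' neural drive feeds (i) the metabolic intermediate, (ii) a three-stage
#' flow cascade controlling blood flow `CBF = 1 + a_F * Fl`, and (iii) a
#' slower venous volume `Vv`; deoxyhaemoglobin is produced in proportion
#' to metabolism and washed out at rate proportional to flow over volume.
#'
#' @param params optional named overrides of [nvc_reference_parameters()].
#' @return A model document of class `"nmc_model"`.
#' @export
nvc_model <- function(params = NULL) {
  p <- nvc_reference_parameters()
  if (!is.null(params)) p[names(params)] <- params
  doc <- list(
    name = "nvc_surrogate",
    states = c("N", "Delay_M", "A1", "A2", "Fl", "Vv", "O2_A",
               "Glucose_A", "dHb"),
    parameters = as.list(p),
    inputs = "u",
    rates = list(
      CBF = "1 + a_F * Fl",
      V_baseMet = "Glucose_A * k_basalMet * O2_A * k_prop1",
      V_stimMet = "Glucose_A * Delay_M * O2_A * k_prop2"),
    odes = list(
      N = "(u - N) / tau_n",
      Delay_M = "kdm1 * N - kdm2 * Delay_M",
      A1 = "(N - A1) / tau_f1",
      A2 = "(A1 - A2) / tau_f2",
      Fl = "(A2 - Fl) / tau_f3",
      Vv = "((1 + a_V * Fl) - Vv) / tau_v",
      O2_A = "k_o2in * (1 + a_O * Fl) - k_o2leak * O2_A - k_o2use * (V_baseMet + V_stimMet)",
      Glucose_A = "k_glcin * (1 + a_G * Fl) - (V_baseMet + V_stimMet)",
      dHb = "k_dhb * (k_basalMet * k_prop1 + k_dip * Delay_M) - k_wash * (CBF / Vv) * dHb"),
    observables = list(
      BOLD = list(expr = "exp(-ky * dHb)", scaling = "ky_BOLD")),
    compiled = NULL
  )
  structure(doc, class = "nmc_model")
}

#' BOLD signal from the deoxyhaemoglobin amount
#'
#' The BOLD signal is modelled as `exp(-ky * dHb)`; its percent-change
#' observable is then computed against the steady-state BOLD value like
#' any other observable.
#'
#' @param dHb amount of deoxyhaemoglobin (non-negative).
#' @param ky positive scale parameter.
#' @return the BOLD signal value(s).
#' @examples
#' bold_signal(0, 0.15)  # 1 at zero deoxyhaemoglobin
#' @export
bold_signal <- function(dHb, ky) {
  stopifnot(all(dHb >= 0))
  exp(-ky * dHb)
}

#' Assemble the combined metabolism + NVC model
#'
#' Connects a neurovascular submodel to the metabolism model: the
#' standalone stimulus and glucose equations (`Stimulus`, `Gluc_t`,
#' `Gluc_c`) are removed, tissue glucose is identified with the NVC state
#' `Glucose_A`, and glycolysis in the pyruvate equation is replaced by the
#' NVC metabolic rates `V_baseMet + V_stimMet`. All remaining metabolite
#' equations are retained verbatim. The BOLD observable and the four
#' metabolite observables (with `Gluc` mapped to `Glucose_A`) are exposed.
#'
#' @param metab the metabolism model document.
#' @param nvc a neurovascular model document exposing at least the states
#'   `Glucose_A`, `O2_A`, `Delay_M`, `dHb` and rates `V_baseMet`,
#'   `V_stimMet`.
#' @param negative_bold also expose a sign-inverted, separately scaled
#'   BOLD observable (`BOLDneg`), a surrogate for the negative BOLD
#'   response recorded in a different cortical region.
#' @return A combined model document of class `"nmc_model"`.
#' @examples
#' cmb <- combine_models(metabolism_model(), nvc_model())
#' setdiff(metabolism_model()$states, cmb$states)  # dropped equations
#' @export
combine_models <- function(metab = metabolism_model(), nvc = nvc_model(),
                           negative_bold = TRUE) {
  required <- c("Glucose_A", "O2_A", "Delay_M", "dHb")
  missing_states <- setdiff(required, nvc$states)
  if (length(missing_states))
    stop("NVC model lacks required state(s): ",
         paste(missing_states, collapse = ", "))
  for (r in c("V_baseMet", "V_stimMet"))
    if (is.null(nvc$rates[[r]]))
      stop("NVC model lacks required rate: ", r)

  drop_states <- c("Stimulus", "Gluc_t", "Gluc_c")
  keep_states <- setdiff(metab$states, drop_states)
  drop_pars <- c("kstim1", "kstim2", "kmax_glucc", "kmax_gluct",
                 "Glucose_blood")
  keep_rates <- metab$rates[
    !names(metab$rates) %in% c("V_stim_on", "V_stim_off", "V_Gluc",
                               "V_glycolysis")]

  odes <- metab$odes[keep_states]
  odes$Pyr <- "V_baseMet + V_stimMet - V_TCA1 - V_LDH - V_PC"

  doc <- list(
    name = "combined",
    states = c(nvc$states, keep_states),
    parameters = c(nvc$parameters,
                   metab$parameters[setdiff(names(metab$parameters),
                                            drop_pars)]),
    inputs = "u",
    rates = c(nvc$rates, keep_rates),
    odes = c(nvc$odes, odes),
    observables = list(
      Lac = list(expr = "Lac", scaling = "ky_Lac"),
      Glut = list(expr = "Glut", scaling = "ky_Glut"),
      Gluc = list(expr = "Glucose_A", scaling = "ky_Gluc"),
      Asp = list(expr = "Asp", scaling = "ky_Asp"),
      BOLD = list(expr = "exp(-ky * dHb)", scaling = "ky_BOLD")),
    compiled = NULL
  )
  if (negative_bold)
    doc$observables$BOLDneg <- list(expr = "exp(-ky * dHb)",
                                    scaling = "ky_BOLDneg", sign = -1)
  ## fast path applies only to the packaged surrogate structure
  ref_nvc <- nvc_model()
  if (identical(nvc$name, "nvc_surrogate") &&
      identical(nvc$rates, ref_nvc$rates) &&
      identical(nvc$odes, ref_nvc$odes) &&
      identical(names(doc$odes),
                c("N", "Delay_M", "A1", "A2", "Fl", "Vv", "O2_A",
                  "Glucose_A", "dHb", "Pyr", "Lac", "OAA", "OG", "Asp",
                  "Glut", "Gln")))
    doc$compiled <- list(derivs = "derivs_cmb", init = "initmod_cmb",
                         par_order = .combined_par_names)
  structure(doc, class = "nmc_model")
}
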