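## Declarative model documents.
##
## A model document is a plain list describing an input-driven kinetic ODE
## model: state names, parameter defaults, named rate expressions, ODEs
## written as signed sums of rate names, and percent-change observables.
## Documents are serializable as JSON (see read_model_json/write_model_json)
## so that submodels can be swapped and models inspected as text.

.metab_par_names <- c(
  "kstim1", "kstim2", "kmax_glucc", "kmax_gluct", "Glucose_blood",
  "kmaxPO", "KM_Pyr", "KM_OAA", "kmaxPyr", "kmaxPyr2", "KM_Pyr2", "k1",
  "kmaxOG1", "kmaxOAA", "kmaxOG2", "kmaxAsp", "kmaxGln", "kmaxGlut1",
  "kmaxGlut2")

.metab_state_names <- c("Stimulus", "Gluc_c", "Gluc_t", "Pyr", "Lac",
                        "OAA", "OG", "Asp", "Glut", "Gln")

#' Reference kinetic parameters for the metabolism model
#'
#' The packaged plausible parameter set for the standalone metabolism model.
#' Rate constants are per second (or per second per unit concentration as
#' dimensional analysis of each term requires); concentrations are in
#' arbitrary units. The set is calibrated so that sustained visual
#' stimulation reproduces the reported qualitative response pattern
#' (lactate and glutamate rise, tissue glucose and aspartate fall, with
#' response amplitudes saturating for stimulations of a few hundred
#' seconds).
#'
#' @return named numeric vector of the 19 kinetic parameters.
#' @seealso [metabolism_model()], [default_scalings()]
#' @export
reference_parameters <- function() {
  c(kstim1 = 0.009, kstim2 = 0.05,
    kmax_glucc = 0.01, kmax_gluct = 1 / 130, Glucose_blood = 0.01,
    kmaxPO = 0.018, KM_Pyr = 0.2, KM_OAA = 0.1,
    kmaxPyr = 0.01, kmaxPyr2 = 0.0022, KM_Pyr2 = 0.02,
    k1 = 0.02,
    kmaxOG1 = 0.025, kmaxOAA = 0.005, kmaxOG2 = 0.005,
    kmaxAsp = 0.02, kmaxGln = 0.005, kmaxGlut1 = 0.005, kmaxGlut2 = 0.012)
}

#' Default observable scaling factors
#'
#' Dimensionless scale factors applied to each percent-change observable.
#' @param model "metabolism" or "combined".
#' @return named numeric vector of scalings.
#' @export
default_scalings <- function(model = c("metabolism", "combined")) {
  model <- match.arg(model)
  s <- c(ky_Lac = 1, ky_Glut = 1, ky_Gluc = 1, ky_Asp = 1)
  if (model == "combined")
    s <- c(s, ky_BOLD = 1, ky_BOLDneg = 0.4)
  s
}

#' The standalone metabolism model document
#'
#' Kinetic model of stimulated central metabolism in the visual cortex:
#' a step stimulus drives a first-order stimulus state, which accelerates
#' glycolysis; pyruvate feeds lactate (LDH), the condensed TCA cycle
#' (PDH/TCA1 and pyruvate carboxylase), and the cycle states OAA and OG
#' exchange with aspartate (GOT) and glutamate/glutamine (XM, GS/PAG).
#' The TCA1 rate uses a single maximal-rate prefactor multiplying both
#' Michaelis factors.
#'
#' @param params optional named numeric vector overriding
#'   [reference_parameters()] entries.
#' @return A model document of class `"nmc_model"`.
#' @examples
#' mod <- metabolism_model()
#' mod$odes$Pyr
#' @export
metabolism_model <- function(params = NULL) {
  p <- reference_parameters()
  if (!is.null(params)) p[names(params)] <- params
  doc <- list(
    name = "metabolism",
    states = .metab_state_names,
    parameters = as.list(p),
    inputs = "u",
    rates = list(
      V_stim_on  = "kstim1 * u",
      V_stim_off = "kstim2 * Stimulus",
      V_Gluc = "kmax_glucc * Gluc_c",
      V_glycolysis = "kmax_gluct * Gluc_t * (1 + Stimulus)",
      V_LDH = "kmaxPyr * Pyr",
      V_PC = "kmaxPyr2 * Pyr / (KM_Pyr2 + Pyr)",
      V_TCA1 = "kmaxPO * Pyr / (KM_Pyr + Pyr) * OAA / (KM_OAA + OAA)",
      V_TCA2 = "kmaxOG1 * OG",
      V_GOT = "kmaxOAA * OAA",
      V_xm = "kmaxOG2 * OG",
      V_GS = "kmaxGln * Gln",
      V_PAG = "kmaxGlut1 * Glut",
      V_clear1 = "k1 * Lac",
      V_clear2 = "kmaxAsp * Asp",
      V_clear3 = "kmaxGlut2 * Glut"),
    odes = list(
      Stimulus = "V_stim_on - V_stim_off",
      Gluc_c = "Glucose_blood - V_Gluc",
      Gluc_t = "V_Gluc - V_glycolysis",
      Pyr = "V_glycolysis - V_TCA1 - V_LDH - V_PC",
      Lac = "V_LDH - V_clear1",
      OAA = "V_TCA2 + V_PC - V_TCA1 - V_GOT",
      OG = "V_TCA1 - V_TCA2 - V_xm",
      Asp = "V_GOT - V_clear2",
      Glut = "V_xm + V_GS - V_PAG - V_clear3",
      Gln = "V_PAG - V_GS"),
    observables = list(
      Lac = list(expr = "Lac", scaling = "ky_Lac"),
      Glut = list(expr = "Glut", scaling = "ky_Glut"),
      Gluc = list(expr = "Gluc_t", scaling = "ky_Gluc"),
      Asp = list(expr = "Asp", scaling = "ky_Asp")),
    compiled = list(derivs = "derivs_met", init = "initmod_met",
                    par_order = .metab_par_names)
  )
  structure(doc, class = "nmc_model")
}

#' @export
print.nmc_model <- function(x, ...) {
  cnt <- model_parameter_count(x)
  cat(sprintf("Model document '%s': %d states, %d kinetic parameters, %d rates\n",
              x$name, length(x$states), cnt$kinetic, length(x$rates)))
  cat("  observables:", paste(names(x$observables), collapse = ", "), "\n")
  cat(sprintf("  total parameters incl. %d observable scalings: %d\n",
              cnt$scalings, cnt$total))
  invisible(x)
}

#' Report the parameter count of a model document
#'
#' @param model a model document.
#' @return list with elements `kinetic`, `scalings` (observable scale
#'   factors, including any parameters appearing only in observable
#'   expressions) and `total`.
#' @export
model_parameter_count <- function(model) {
  kin <- length(model$parameters)
  scal <- length(unique(vapply(model$observables, `[[`, "", "scaling")))
  obs_extra <- setdiff(
    unlist(lapply(model$observables,
                  function(o) all.vars(str2lang(o$expr)))),
    c(model$states, names(model$parameters), model$inputs))
  list(kinetic = kin, scalings = scal + length(obs_extra),
       total = kin + scal + length(obs_extra))
}

## Validate internal symbol resolution; returns TRUE or stops naming the
## offending symbol.
validate_model <- function(model) {
  known <- c(model$states, names(model$parameters), model$inputs,
             names(model$rates))
  for (nm in names(model$rates)) {
    vars <- all.vars(str2lang(model$rates[[nm]]))
    bad <- setdiff(vars, known)
    if (length(bad))
      stop("rate '", nm, "' references unknown symbol(s): ",
           paste(bad, collapse = ", "))
  }
  for (nm in names(model$odes)) {
    if (!nm %in% model$states) stop("ODE for non-state '", nm, "'")
    vars <- all.vars(str2lang(model$odes[[nm]]))
    bad <- setdiff(vars, known)
    if (length(bad))
      stop("ODE for '", nm, "' references unknown symbol(s): ",
           paste(bad, collapse = ", "))
  }
  if (!setequal(names(model$odes), model$states))
    stop("states and ODEs do not match")
  TRUE
}

## Substitute rate definitions into an expression until only states,
## parameters and inputs remain. Used by the identifiability machinery and
## the generic (non-compiled) simulation path.
expand_expression <- function(expr_chr, model, max_depth = 20L) {
  e <- str2lang(expr_chr)
  rates <- lapply(model$rates, str2lang)
  for (i in seq_len(max_depth)) {
    vars <- all.vars(e)
    hit <- intersect(vars, names(rates))
    if (!length(hit)) return(e)
    e <- eval(call("substitute", e, rates))
  }
  stop("rate definitions appear to be cyclic")
}

## Full symbolic right-hand side: named list of expressions per state.
model_field <- function(model) {
  lapply(model$odes, expand_expression, model = model)
}

## Build an R-level RHS closure f(t, y, parms_with_u) -> list(dy) suitable
## for deSolve. The compiled path in simulate_model() bypasses this.
build_rhs <- function(model) {
  validate_model(model)
  field <- model_field(model)
  body_expr <- as.call(c(as.name("c"), field))
  snames <- model$states
  function(t, y, parms) {
    env <- list2env(as.list(parms))
    for (i in seq_along(snames)) assign(snames[i], y[[i]], envir = env)
    list(eval(body_expr, env))
  }
}

#' Write a model document as JSON
#'
#' The JSON schema mirrors the document structure: `name`, `states`,
#' `parameters` (name/value map), `inputs`, `rates` (name/expression map),
#' `odes` (state/expression map, signed sums of rate names), and
#' `observables` (name to expression + scaling). The `compiled` hint is
#' dropped on export; imported documents run through the generic
#' interpreter unless they match a packaged model.
#'
#' @param model a model document.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  x <- unclass(model)
  x$compiled <- NULL
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a model document from JSON
#'
#' Validates that every symbol referenced by a rate or ODE resolves to a
#' state, parameter, input, or rate, and reports the parameter count.
#' If the document is structurally identical to a packaged model, the
#' packaged compiled right-hand side is re-attached.
#'
#' @param path JSON file path.
#' @param quiet suppress the parameter-count message.
#' @return A model document of class `"nmc_model"`.
#' @export
read_model_json <- function(path, quiet = FALSE) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$parameters <- as.list(x$parameters)
  x$rates <- as.list(x$rates)
  x$odes <- as.list(x$odes)
  x$observables <- lapply(x$observables, as.list)
  model <- structure(x, class = "nmc_model")
  validate_model(model)
  for (builder in list(metabolism_model,
                       function() combine_models(metabolism_model(),
                                                 nvc_model()))) {
    ref <- builder()
    if (identical(model$name, ref$name) &&
        identical(model$states, ref$states) &&
        identical(unname(unlist(model$rates[names(ref$rates)])),
                  unname(unlist(ref$rates))) &&
        identical(unname(unlist(model$odes[ref$states])),
                  unname(unlist(ref$odes))))
      model$compiled <- ref$compiled
  }
  if (!quiet) {
    cnt <- model_parameter_count(model)
    message(sprintf("model '%s': %d states, %d parameters (%d kinetic + %d observable scalings)",
                    model$name, length(model$states), cnt$total,
                    cnt$kinetic, cnt$scalings))
  }
  model
}
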