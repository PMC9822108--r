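## Synthetic datasets with the statistical structure of the study's
## functional MRS / fMRI designs.

#' Noise model for synthetic datasets
#'
#' Per-observable Gaussian noise standard deviations, in percent-change
#' units. Defaults approximate the error-bar scales of published visual
#' stimulation MRS/fMRI time courses: 2 percentage points for lactate and
#' glutamate, 3 for glucose, 1.5 for aspartate and 0.1 for BOLD.
#'
#' @param ... named overrides, e.g. `Lac = 1`.
#' @return named numeric vector of standard deviations.
#' @export
noise_model <- function(...) {
  sd <- c(Lac = 2, Glut = 2, Gluc = 3, Asp = 1.5, BOLD = 0.1,
          BOLDneg = 0.1)
  over <- c(...)
  if (length(over)) sd[names(over)] <- over
  if (any(sd <= 0)) stop("noise standard deviations must be positive")
  sd
}

#' Default sample times of the emulated designs
#'
#' * metabolite designs are sampled uniformly within the paradigm unless
#'   the design states a resolution;
#' * `bednarik` uses the stated 2.7-minute resolution (9 samples);
#' * `schaller` uses the stated 75 samples over 25 minutes;
#' * BOLD designs are sampled every 0.5 s.
#'
#' @param name a [make_paradigm()] catalog name.
#' @return numeric vector of sample times (seconds).
#' @export
design_sample_times <- function(name) {
  switch(name,
    lin_single = seq(120, 2376, by = 120),
    lin_double = seq(150, 2970, by = 150),
    witt_bold = seq(0.5, 20, by = 0.5),
    schaller = seq(20, 1500, length.out = 75),
    bednarik = 60 * (1.35 + 2.7 * (0:8)),
    lundengard_double = seq(0.5, 60, by = 0.5),
    stop("no default sample times for paradigm '", name, "'"))
}

#' Generate a synthetic dataset from the model
#'
#' Simulates the requested observables at the sample times and adds
#' independent Gaussian noise with the supplied standard deviations,
#' which are also recorded as the per-sample SEM. Fully reproducible from
#' the seed.
#'
#' @param model a model document.
#' @param true_params named parameter vector (kinetic + scalings) used as
#'   ground truth; defaults to the document values.
#' @param paradigm_name a catalog name (used for both the paradigm and
#'   the experiment label).
#' @param observables which observables to include.
#' @param sample_times sampling grid; defaults to
#'   [design_sample_times()].
#' @param noise a [noise_model()] vector.
#' @param seed integer seed.
#' @param experiment experiment label; defaults to `paradigm_name`.
#' @return An `"nmc_dataset"`.
#' @export
generate_dataset <- function(model, true_params = NULL, paradigm_name,
                             observables, sample_times = NULL,
                             noise = noise_model(), seed = 1L,
                             experiment = paradigm_name) {
  paradigm <- make_paradigm(paradigm_name)
  if (is.null(sample_times)) sample_times <- design_sample_times(paradigm_name)
  sp <- split_parameters(if (is.null(true_params)) numeric(0) else
    true_params, model)
  p <- resolve_params(model, sp$kinetic)
  ss <- steady_state(model, p)
  tt <- sort(unique(sample_times))
  traj <- simulate_model(model, p, paradigm,
                         times = if (tt[1] > 0) c(0, tt) else tt,
                         init = ss)
  obs <- observe(traj, model, p, scalings = sp$scalings,
                 names = observables, ss = ss)
  set.seed(seed)
  rows <- lapply(obs, function(o) {
    v <- o$values[match(tt, o$times)]
    sd_o <- noise[[o$name]]
    data.frame(experiment = experiment, observable = o$name,
               time_s = tt, mean_pct = v + stats::rnorm(length(tt), 0, sd_o),
               sem_pct = sd_o, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  nmc_dataset(df, stats::setNames(list(paradigm), experiment))
}

#' Write the packaged synthetic fixture bundle
#'
#' Generates the estimation bundle (metabolites under the single and
#' double long-stimulation designs; positive and negative BOLD under the
#' short-stimulus design) and the validation bundle (lactate/glutamate
#' under the 5-minute block design; four metabolites under the
#' 5.3-minute block design) at the packaged reference parameters of the
#' combined model, and writes them in the dataset CSV schema together
#' with a JSON manifest recording the seed and parameter values.
#'
#' @param dir output directory (created if needed).
#' @param seed integer master seed; per-file seeds are derived from it.
#' @param model combined model document; default packaged combined model.
#' @param true_params optional named overrides of the generating truth.
#' @param noise a [noise_model()] vector.
#' @return named character vector of the files written, invisibly.
#' @export
package_fixtures <- function(dir, seed = 1L, model = NULL,
                             true_params = NULL, noise = noise_model()) {
  if (is.null(model)) model <- combine_models(metabolism_model(),
                                              nvc_model())
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mets <- c("Lac", "Glut", "Gluc", "Asp")
  spec <- list(
    estimation_lin_single = list(par = "lin_single", obs = mets),
    estimation_lin_double = list(par = "lin_double", obs = mets),
    estimation_witt_bold = list(par = "witt_bold",
                                obs = c("BOLD", "BOLDneg")),
    validation_schaller = list(par = "schaller", obs = c("Lac", "Glut")),
    validation_bednarik = list(par = "bednarik", obs = mets))
  files <- character(0)
  for (i in seq_along(spec)) {
    s <- spec[[i]]
    d <- generate_dataset(model, true_params, s$par, s$obs,
                          noise = noise, seed = seed * 1000L + i,
                          experiment = s$par)
    f <- file.path(dir, paste0(names(spec)[i], ".csv"))
    write_dataset(d, f)
    files[names(spec)[i]] <- f
  }
  manifest <- list(
    seed = seed,
    noise = as.list(noise),
    model = model$name,
    parameters = as.list(resolve_params(
      model, split_parameters(if (is.null(true_params)) numeric(0)
                              else true_params, model)$kinetic)),
    files = as.list(files))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(files)
}

#' Load a fixture bundle written by [package_fixtures()]
#'
#' @param dir the fixture directory.
#' @return list with `estimation` (list of datasets), `validation` (list
#'   of datasets) and `manifest`.
#' @export
load_fixtures <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  est <- grep("^estimation", names(manifest$files), value = TRUE)
  val <- grep("^validation", names(manifest$files), value = TRUE)
  rd <- function(nm) read_dataset(file.path(dir, paste0(nm, ".csv")))
  list(estimation = stats::setNames(lapply(est, rd), est),
       validation = stats::setNames(lapply(val, rd), val),
       manifest = manifest)
}
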