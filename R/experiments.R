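## End-to-end experiment drivers: joint estimation, validation
## prediction, amplitude-versus-duration sweep, and short-stimulus
## prediction.

#' Joint estimation on the packaged designs
#'
#' Fits the combined model simultaneously to the estimation datasets
#' (single- and double-stimulation metabolite time courses and the
#' short-stimulus BOLD responses), reports the chi-squared rejection test
#' at one degree of freedom per residual, and optionally samples the
#' posterior for uncertainty envelopes.
#'
#' @param fixtures list of estimation datasets (e.g. the `estimation`
#'   element of [load_fixtures()]), or a directory containing a fixture
#'   bundle.
#' @param model combined model document; default packaged combined model.
#' @param config a [fit_config()].
#' @param seed integer seed.
#' @param n_mcmc posterior draws for the envelopes (0 to skip MCMC).
#' @return list of class `"nmc_estimation"` with elements `fit`,
#'   `posterior` (or NULL) and `threshold`.
#' @export
run_estimation <- function(fixtures, model = NULL,
                           config = fit_config(), seed = 1L,
                           n_mcmc = 0) {
  if (is.character(fixtures)) fixtures <- load_fixtures(fixtures)$estimation
  if (is.null(model)) model <- combine_models(metabolism_model(),
                                              nvc_model())
  fit <- nmc_fit(fixtures, model, config = config, seed = seed)
  post <- NULL
  if (n_mcmc > 0)
    post <- mcmc_sample(fit, n_samples = n_mcmc, seed = seed + 1L)
  structure(list(fit = fit, posterior = post,
                 threshold = fit$test$threshold),
            class = "nmc_estimation")
}

#' @export
print.nmc_estimation <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$posterior)) print(x$posterior)
  invisible(x)
}

#' Pure-prediction validation against independent designs
#'
#' Simulates the fitted model, with the optimal parameters unchanged,
#' under the validation paradigms and overlays the predictions on the
#' validation datasets. No refitting takes place; the parameter vector
#' hash is recorded so downstream reports can assert it.
#'
#' @param fit an `"nmc_fit"` from [run_estimation()].
#' @param validation list of validation datasets (or fixture directory).
#' @return list of class `"nmc_validation"`: per-dataset data frames with
#'   columns of the dataset plus `yhat`, the chi-squared statistic of the
#'   predictions, and `theta_hash`.
#' @export
run_validation <- function(fit, validation) {
  if (is.character(validation))
    validation <- load_fixtures(validation)$validation
  theta_hash <- param_hash(fit$theta)
  out <- lapply(validation, function(d)
    model_predictions(fit$theta, d, fit$model))
  stat <- sum(vapply(out, function(o)
    sum(((o$mean_pct - o$yhat) / o$sem_pct)^2), numeric(1)))
  n <- sum(vapply(out, nrow, integer(1)))
  structure(list(predictions = out, stat = stat, n_samples = n,
                 theta_hash = theta_hash, theta = fit$theta),
            class = "nmc_validation")
}

#' @export
print.nmc_validation <- function(x, ...) {
  cat(sprintf("Validation predictions (no refitting; parameter hash %s)\n",
              x$theta_hash))
  cat(sprintf("  %d samples, prediction chi-squared statistic %.2f\n",
              x$n_samples, x$stat))
  invisible(x)
}

## Order-independent hash of a named parameter vector.
param_hash <- function(theta) {
  s <- paste(sprintf("%s=%.15g", names(theta)[order(names(theta))],
                     theta[order(names(theta))]), collapse = ";")
  ## small stable polynomial hash (exact in double precision); avoids
  ## external digest dependencies
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}

#' Metabolic response amplitude versus stimulation duration
#'
#' For each stimulation duration, simulates a single-epoch paradigm with a
#' recovery period of at least twice the duration and records each
#' metabolite observable's peak absolute percent change during the
#' stimulation epoch (the driven response; the post-stimulus rebound is
#' excluded so that the amplitude is a saturating, non-decreasing
#' function of duration). The plateau onset per metabolite is the first
#' duration whose amplitude reaches 99% of the asymptotic
#' (longest-duration) amplitude.
#'
#' @param params named parameter overrides for the metabolism model.
#' @param durations stimulation lengths in seconds (default 25 log-spaced
#'   values from 0.5 to 10000).
#' @param model model document; default the standalone metabolism model.
#' @param observables metabolite observables to track.
#' @return An object of class `"nmc_sweep"`: list with `durations`,
#'   `amplitude` (duration-by-observable matrix, %), and `plateau` (named
#'   vector of plateau-onset durations, s).
#' @export
amplitude_vs_duration <- function(params = NULL,
                                  durations = 10^seq(log10(0.5), 4,
                                                     length.out = 25),
                                  model = metabolism_model(),
                                  observables = c("Lac", "Glut", "Gluc",
                                                  "Asp")) {
  if (any(durations < 0.5 | durations > 10000))
    stop("durations must lie within [0.5, 10000] s")
  p <- resolve_params(model, split_parameters(
    if (is.null(params)) numeric(0) else params, model)$kinetic)
  ss <- steady_state(model, p)
  amp <- matrix(NA_real_, length(durations), length(observables),
                dimnames = list(NULL, observables))
  onset <- 60
  for (i in seq_along(durations)) {
    d <- durations[i]
    horizon <- onset + 3 * max(d, 60)
    par_i <- stimulus_paradigm(onset, onset + d, horizon = horizon)
    ## keep the output grid fine enough to resolve the response peak at
    ## every duration (coarse grids bias the sampled maximum downwards)
    dt <- max(min(d / 20, 2), 0.1)
    traj <- simulate_model(model, p, par_i,
                           times = seq(0, horizon, by = dt), init = ss)
    obs <- observe(traj, model, p, names = observables, ss = ss)
    instim <- traj$times >= onset & traj$times <= onset + d + dt
    for (o in obs) amp[i, o$name] <- max(abs(o$values[instim]))
  }
  plateau <- apply(amp, 2, function(a) {
    asymptote <- a[length(a)]
    durations[which(a >= 0.99 * asymptote)[1]]
  })
  structure(list(durations = durations, amplitude = amp,
                 plateau = plateau),
            class = "nmc_sweep")
}

#' @export
print.nmc_sweep <- function(x, ...) {
  cat("Amplitude-versus-duration sweep\n")
  for (nm in colnames(x$amplitude))
    cat(sprintf("  %-5s max amplitude %6.2f %%, plateau onset ~%g s\n",
                nm, max(x$amplitude[, nm]), x$plateau[nm]))
  invisible(x)
}

#' @export
plot.nmc_sweep <- function(x, ...) {
  graphics::matplot(x$durations, x$amplitude, type = "b", log = "x",
                    pch = 16, lty = 1, xlab = "stimulation duration (s)",
                    ylab = "peak |response| (%)", ...)
  graphics::legend("topleft", colnames(x$amplitude), col = 1:4, pch = 16,
                   bty = "n")
  invisible(x)
}

#' Predicted responses to two short stimuli
#'
#' Simulates the combined model under the two-0.5-second-stimulus
#' paradigm and returns the BOLD and four metabolite percent-change
#' series together with the peak metabolite amplitudes.
#'
#' @param params named parameter overrides for the combined model.
#' @param model combined model document; default packaged combined model.
#' @param horizon simulated horizon in seconds (>= 60).
#' @return list of class `"nmc_short_prediction"` with `observables`
#'   (an `"nmc_observables"`) and `peaks` (named vector, %).
#' @export
short_stimulus_prediction <- function(params = NULL, model = NULL,
                                      horizon = 600) {
  if (is.null(model)) model <- combine_models(metabolism_model(),
                                              nvc_model())
  paradigm <- make_paradigm("lundengard_double")
  if (horizon > paradigm$horizon)
    paradigm <- stimulus_paradigm(paradigm$on, paradigm$off,
                                  horizon = horizon)
  times <- sort(unique(c(seq(0, min(60, horizon), by = 0.1),
                         seq(60, horizon, by = 1))))
  sim <- simulate_combined(params, paradigm, times = times, model = model)
  peaks <- vapply(sim$observables[c("Lac", "Glut", "Gluc", "Asp")],
                  function(o) max(abs(o$values)), numeric(1))
  structure(list(observables = sim$observables, peaks = peaks),
            class = "nmc_short_prediction")
}

#' @export
print.nmc_short_prediction <- function(x, ...) {
  cat("Short double-stimulus prediction; peak metabolite responses (%):\n")
  print(signif(x$peaks, 3))
  bold <- x$observables$BOLD
  cat(sprintf("  BOLD range [%+.3f, %+.3f] %%\n", min(bold$values),
              max(bold$values)))
  invisible(x)
}
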