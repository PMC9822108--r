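## Multi-start maximum-likelihood fitting.

#' Configuration for model fitting
#'
#' Fitting works on log10-transformed parameters inside box bounds, using
#' multi-start Levenberg-Marquardt on the weighted residual vector. Starts
#' are drawn uniformly in log10 space, either across the whole box or in a
#' window of `start_spread` decades around a supplied center.
#'
#' @param lower,upper default box bounds on the natural scale (applied to
#'   every fitted parameter unless overridden by a named entry).
#' @param n_starts number of optimizer starts.
#' @param start_spread half-width, in decades, of the start window around
#'   the center point (when one is supplied).
#' @param maxiter per-start iteration budget for the optimizer.
#' @return list of class `"nmc_fit_config"`.
#' @export
fit_config <- function(lower = 1e-6, upper = 1e6, n_starts = 5,
                       start_spread = 0.5, maxiter = 100) {
  structure(list(lower = lower, upper = upper, n_starts = n_starts,
                 start_spread = start_spread, maxiter = maxiter),
            class = "nmc_fit_config")
}

fit_bounds <- function(config, par_names) {
  expand <- function(b, default) {
    out <- stats::setNames(rep(default, length(par_names)), par_names)
    if (!is.null(names(b))) out[names(b)[names(b) %in% par_names]] <-
        b[names(b) %in% par_names]
    else out[] <- b[1]
    out
  }
  list(lower = expand(config$lower, 1e-6), upper = expand(config$upper, 1e6))
}

#' Fit the model to percent-change datasets by maximum likelihood
#'
#' Minimizes the weighted residual sum of squares (equivalently the
#' negative log-likelihood, whose data-noise term does not depend on the
#' parameters) simultaneously across all experiments of all supplied
#' datasets. The search runs in log10 parameter space with multi-start
#' Levenberg-Marquardt; the best start is refined and returned together
#' with a chi-squared rejection test at one degree of freedom per
#' residual.
#'
#' @param data an `"nmc_dataset"` or list of datasets (fitted jointly).
#' @param model the model document.
#' @param fit_params names of the parameters to estimate; default all
#'   kinetic parameters plus the scalings of the observables present in
#'   the data.
#' @param start optional named center for the start window (natural
#'   scale); defaults to the model document's parameter values.
#' @param config a [fit_config()].
#' @param seed integer seed controlling the random starts.
#' @param alpha significance level of the rejection test.
#' @return An object of class `"nmc_fit"`.
#' @seealso [mcmc_sample()], [prediction_envelope()]
#' @export
nmc_fit <- function(data, model, fit_params = NULL, start = NULL,
                    config = fit_config(), seed = 1L, alpha = 0.05) {
  datasets <- if (inherits(data, "nmc_dataset")) list(data) else data
  if (!length(datasets)) stop("at least one dataset is required")
  all_df <- do.call(rbind, lapply(datasets, as.data.frame))

  sc_names <- unique(vapply(model$observables, `[[`, "", "scaling"))
  obs_in_data <- unique(all_df$observable)
  sc_used <- unique(vapply(model$observables[obs_in_data], `[[`, "",
                           "scaling"))
  if (is.null(fit_params))
    fit_params <- c(names(model$parameters), sc_used)

  defaults <- c(unlist(model$parameters),
                default_obs_scalings(model)[sc_names])
  center <- defaults[fit_params]
  if (!is.null(start)) center[names(start)[names(start) %in% fit_params]] <-
      start[names(start) %in% fit_params]

  b <- fit_bounds(config, fit_params)
  llo <- log10(b$lower); lup <- log10(b$upper)
  lcenter <- pmin(pmax(log10(center), llo), lup)

  resid_fun <- function(ltheta) {
    theta <- stats::setNames(10^ltheta, fit_params)
    r <- tryCatch(suppressWarnings({
      rr <- numeric(0)
      for (d in datasets) {
        pred <- model_predictions(theta, d, model)
        rr <- c(rr, (pred$mean_pct - pred$yhat) / pred$sem_pct)
      }
      rr
    }), error = function(e) NULL)
    if (is.null(r) || any(!is.finite(r)))
      r <- rep(1e4, nrow(all_df))
    r
  }

  set.seed(seed)
  ## rejection-sample feasible starts: wide random draws can violate the
  ## positivity constraints of the steady state, where the objective is
  ## flat and the local search cannot recover
  draw_start <- function() {
    for (i in 1:20) {
      s <- stats::runif(length(fit_params),
                        pmax(llo, lcenter - config$start_spread),
                        pmin(lup, lcenter + config$start_spread))
      if (all(is.finite(resid_fun(s))) &&
          sum(resid_fun(s)^2) < 1e7) return(s)
    }
    lcenter
  }
  starts <- matrix(NA_real_, config$n_starts, length(fit_params))
  starts[1, ] <- lcenter  # first start at the center point
  for (i in seq_len(config$n_starts)[-1]) starts[i, ] <- draw_start()

  runs <- vector("list", config$n_starts)
  for (i in seq_len(config$n_starts)) {
    fitres <- tryCatch(
      suppressWarnings(minpack.lm::nls.lm(par = starts[i, ], fn = resid_fun,
                         lower = llo, upper = lup,
                         control = minpack.lm::nls.lm.control(
                           maxiter = config$maxiter,
                           ## forward-difference step must exceed the
                           ## solver tolerance or the Jacobian is noise
                           epsfcn = 1e-6))),
      error = function(e) NULL)
    if (!is.null(fitres))
      runs[[i]] <- list(par = fitres$par, value = fitres$deviance,
                        niter = fitres$niter,
                        message = fitres$message)
  }
  ok <- !vapply(runs, is.null, logical(1))
  if (!any(ok)) stop("all optimizer starts failed")
  vals <- vapply(runs[ok], `[[`, numeric(1), "value")
  best <- runs[ok][[which.min(vals)]]
  theta <- stats::setNames(10^best$par, fit_params)

  breakdown <- vapply(seq_along(datasets), function(j) {
    chi2_statistic(theta, datasets[[j]], model)
  }, numeric(1))
  names(breakdown) <- if (!is.null(names(datasets))) names(datasets)
    else paste0("dataset", seq_along(datasets))
  stat <- sum(breakdown)
  n_res <- nrow(all_df)
  test <- chi2_test(stat, alpha, dof = n_res)

  structure(list(
    theta = theta, objective = stat,
    nll = negative_log_likelihood(theta, datasets, model),
    breakdown = breakdown, n_residuals = n_res, test = test,
    model = model, data = datasets, fit_params = fit_params,
    bounds = b, config = config, seed = seed, resid_fun = resid_fun,
    trace = list(start_values = vals, n_ok = sum(ok),
                 niter = best$niter, message = best$message)),
    class = "nmc_fit")
}

#' @export
print.nmc_fit <- function(x, ...) {
  cat(sprintf("Maximum-likelihood fit of model '%s'\n", x$model$name))
  cat(sprintf("  %d parameters fitted to %d residuals across %d dataset(s)\n",
              length(x$theta), x$n_residuals, length(x$data)))
  cat(sprintf("  J(theta*) = %.2f, ", x$objective))
  print(x$test)
  invisible(x)
}

#' @export
summary.nmc_fit <- function(object, ...) {
  cat(sprintf("Maximum-likelihood fit of model '%s' (seed %d)\n",
              object$model$name, object$seed))
  cat(sprintf("  residuals: %d, J(theta*) = %.4f, -logL = %.4f\n",
              object$n_residuals, object$objective, object$nll))
  cat("  per-dataset residual breakdown:\n")
  for (nm in names(object$breakdown))
    cat(sprintf("    %-12s %.2f\n", nm, object$breakdown[nm]))
  print(object$test)
  cat("  estimates (natural scale):\n")
  print(signif(object$theta, 4))
  invisible(object)
}

#' @export
coef.nmc_fit <- function(object, ...) object$theta

#' @export
deviance.nmc_fit <- function(object, ...) object$objective

#' @export
logLik.nmc_fit <- function(object, ...) {
  structure(-object$nll, df = length(object$theta), class = "logLik")
}

#' @export
residuals.nmc_fit <- function(object, type = c("weighted", "raw"), ...) {
  type <- match.arg(type)
  out <- do.call(rbind, lapply(object$data, function(d)
    model_predictions(object$theta, d, object$model)))
  r <- out$mean_pct - out$yhat
  if (type == "weighted") r <- r / out$sem_pct
  stats::setNames(r, paste(out$experiment, out$observable, out$time_s,
                           sep = ":"))
}

#' Predict observable time courses from a fitted model
#'
#' Pure prediction at the fitted parameters: simulates the model under a
#' (possibly new) stimulation paradigm and returns percent-change
#' observables. No refitting takes place.
#'
#' @param object an `"nmc_fit"`.
#' @param paradigm a [stimulus_paradigm()] (or catalog name).
#' @param times output grid; see [simulate_model()].
#' @param observables which observables to return; default all.
#' @param ... unused.
#' @return An `"nmc_observables"` object.
#' @export
predict.nmc_fit <- function(object, paradigm, times = NULL,
                            observables = NULL, ...) {
  if (is.character(paradigm)) paradigm <- make_paradigm(paradigm)
  sp <- split_parameters(object$theta, object$model)
  p <- resolve_params(object$model, sp$kinetic)
  ss <- steady_state(object$model, p)
  traj <- simulate_model(object$model, p, paradigm, times, init = ss)
  observe(traj, object$model, p, scalings = sp$scalings,
          names = observables, ss = ss)
}

#' @export
plot.nmc_fit <- function(x, experiment = NULL, ...) {
  df <- do.call(rbind, lapply(x$data, function(d)
    model_predictions(x$theta, d, x$model)))
  if (is.null(experiment)) experiment <- unique(df$experiment)[1]
  df <- df[df$experiment == experiment, ]
  obs <- unique(df$observable)
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(obs)),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (o in obs) {
    d <- df[df$observable == o, ]
    ylim <- range(d$mean_pct - d$sem_pct, d$mean_pct + d$sem_pct, d$yhat)
    plot(d$time_s, d$mean_pct, ylim = ylim, pch = 16, col = "red3",
         xlab = "time (s)", ylab = "% change", main = o, ...)
    graphics::arrows(d$time_s, d$mean_pct - d$sem_pct, d$time_s,
                     d$mean_pct + d$sem_pct, angle = 90, code = 3,
                     length = 0.02, col = "red3")
    graphics::lines(d$time_s, d$yhat, col = "blue3", lwd = 2)
  }
  invisible(x)
}

#' Simulate replicate datasets from a fitted model
#'
#' Draws new noisy datasets at the fitted parameters, using each sample's
#' SEM as the noise standard deviation (parametric bootstrap).
#'
#' @param object an `"nmc_fit"`.
#' @param nsim number of replicate dataset lists.
#' @param seed integer seed.
#' @param ... unused.
#' @return list of length `nsim`; each element is a list of datasets
#'   matching the fitted ones.
#' @export
simulate.nmc_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nsim), function(i) {
    lapply(object$data, function(d) {
      pred <- model_predictions(object$theta, d, object$model)
      d$mean_pct <- pred$yhat + stats::rnorm(nrow(pred), 0, pred$sem_pct)
      d
    })
  })
}
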