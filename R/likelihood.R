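## Datasets, likelihood, and chi-squared goodness of fit.

#' Construct a dataset of percent-change time courses
#'
#' A dataset is a data frame with columns `experiment`, `observable`,
#' `time_s`, `mean_pct` and `sem_pct` (one row per sample), together with
#' a named list of stimulation paradigms keyed by experiment name. The
#' per-sample SEM is used as the standard deviation in the likelihood.
#'
#' @param df data frame with the five columns above.
#' @param paradigms named list of [stimulus_paradigm()] objects, one per
#'   experiment appearing in `df`.
#' @return An object of class `"nmc_dataset"` (a data frame).
#' @export
nmc_dataset <- function(df, paradigms) {
  need <- c("experiment", "observable", "time_s", "mean_pct", "sem_pct")
  if (!all(need %in% names(df)))
    stop("dataset needs columns: ", paste(need, collapse = ", "))
  if (any(df$sem_pct <= 0)) stop("sem_pct must be strictly positive")
  exps <- unique(df$experiment)
  missing_par <- setdiff(exps, names(paradigms))
  if (length(missing_par))
    stop("no paradigm supplied for experiment(s): ",
         paste(missing_par, collapse = ", "))
  for (e in exps) {
    h <- paradigms[[e]]$horizon
    if (any(df$time_s[df$experiment == e] > h))
      stop("sample times exceed the paradigm horizon in experiment '",
           e, "'")
  }
  structure(as.data.frame(df), paradigms = paradigms[exps],
            class = c("nmc_dataset", "data.frame"))
}

#' @export
print.nmc_dataset <- function(x, ...) {
  cat(sprintf("Dataset: %d samples, %d experiment(s), %d observable(s)\n",
              nrow(x), length(unique(x$experiment)),
              length(unique(x$observable))))
  print(stats::aggregate(mean_pct ~ experiment + observable,
                         as.data.frame(x), length))
  invisible(x)
}

#' Read / write datasets in the shared CSV schema
#'
#' CSV columns: `experiment, observable, time_s, mean_pct, sem_pct`.
#' Paradigms are attached from the catalog by matching experiment names
#' to [make_paradigm()] names (prefix before any `:` suffix), or can be
#' supplied explicitly.
#'
#' @param path CSV file path.
#' @param paradigms optional named list of paradigms keyed by experiment.
#' @return An `"nmc_dataset"`.
#' @export
read_dataset <- function(path, paradigms = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(paradigms)) {
    exps <- unique(df$experiment)
    paradigms <- stats::setNames(
      lapply(exps, function(e) make_paradigm(sub(":.*$", "", e))), exps)
  }
  nmc_dataset(df, paradigms)
}

#' @rdname read_dataset
#' @param data an `"nmc_dataset"`.
#' @export
write_dataset <- function(data, path) {
  utils::write.csv(as.data.frame(data)[, c("experiment", "observable",
                                           "time_s", "mean_pct",
                                           "sem_pct")],
                   path, row.names = FALSE)
  invisible(path)
}

## Simulate the model for every experiment of a dataset and return the
## dataset with a fitted-value column `yhat`. `params` may contain both
## kinetic parameters and observable scalings (ky_*).
model_predictions <- function(params, data, model,
                              paradigms = attr(data, "paradigms"),
                              rtol = 1e-8, atol = 1e-10) {
  split_par <- split_parameters(params, model)
  p <- resolve_params(model, split_par$kinetic)
  ss <- steady_state(model, p)
  out <- as.data.frame(data)
  out$yhat <- NA_real_
  for (e in unique(out$experiment)) {
    rows <- which(out$experiment == e)
    tt <- sort(unique(out$time_s[rows]))
    tt_sim <- if (tt[1] > 0) c(0, tt) else tt
    traj <- simulate_model(model, p, paradigms[[e]], times = tt_sim,
                           init = ss, rtol = rtol, atol = atol)
    obs <- observe(traj, model, p, scalings = split_par$scalings,
                   names = unique(out$observable[rows]), ss = ss)
    for (o in obs) {
      sel <- rows[out$observable[rows] == o$name]
      out$yhat[sel] <- o$values[match(out$time_s[sel], traj$times)]
    }
  }
  out
}

split_parameters <- function(params, model) {
  kin <- params[names(params) %in% names(model$parameters)]
  sc_names <- unique(vapply(model$observables, `[[`, "", "scaling"))
  sc <- params[names(params) %in% sc_names]
  list(kinetic = kin, scalings = if (length(sc)) sc else NULL)
}

#' Negative log-likelihood of a dataset under the model
#'
#' `J = 1/2 * sum over samples [ log(2 pi sigma^2) + ((y - yhat)/sigma)^2 ]`
#' with independent Gaussian errors whose standard deviations are the
#' per-sample SEMs. Simulation failures return `+Inf` with a warning so
#' that global searches can continue.
#'
#' @param params named parameter vector (kinetic parameters and observable
#'   scalings; unnamed entries fall back to model defaults).
#' @param data an `"nmc_dataset"` or list of them.
#' @param model the model document.
#' @param paradigms optional named paradigm list overriding the dataset's.
#' @return the scalar J.
#' @seealso [chi2_statistic()] for the weighted residual sum of squares
#'   used by the chi-squared test.
#' @export
negative_log_likelihood <- function(params, data, model,
                                    paradigms = NULL) {
  r <- likelihood_parts(params, data, model, paradigms)
  if (!is.finite(r$stat)) return(Inf)
  0.5 * (r$logconst + r$stat)
}

#' Chi-squared statistic of a dataset under the model
#'
#' The weighted residual sum of squares
#' `sum(((y - yhat)/sigma)^2)`, i.e. the parameter-dependent part of twice
#' the negative log-likelihood. At the true parameters this statistic is
#' chi-squared distributed with one degree of freedom per residual, which
#' is the basis of the model rejection test.
#'
#' @inheritParams negative_log_likelihood
#' @return the scalar statistic (`+Inf` on simulation failure).
#' @export
chi2_statistic <- function(params, data, model, paradigms = NULL) {
  likelihood_parts(params, data, model, paradigms)$stat
}

likelihood_parts <- function(params, data, model, paradigms = NULL) {
  datasets <- if (inherits(data, "nmc_dataset")) list(data) else data
  stat <- 0; logconst <- 0; n <- 0L
  for (d in datasets) {
    pr <- if (is.null(paradigms)) attr(d, "paradigms") else paradigms
    pred <- tryCatch(model_predictions(params, d, model, pr),
                     error = function(e) {
                       warning("simulation failed: ", conditionMessage(e),
                               call. = FALSE)
                       NULL
                     })
    if (is.null(pred)) return(list(stat = Inf, logconst = Inf, n = n))
    r <- (pred$mean_pct - pred$yhat) / pred$sem_pct
    stat <- stat + sum(r^2)
    logconst <- logconst + sum(log(2 * pi * pred$sem_pct^2))
    n <- n + nrow(pred)
  }
  list(stat = stat, logconst = logconst, n = n)
}

#' Chi-squared rejection threshold
#'
#' The `(1 - alpha)` quantile of the chi-squared distribution.
#'
#' @param alpha significance level in (0, 1).
#' @param dof degrees of freedom (>= 1).
#' @return the threshold value.
#' @examples
#' chi2_threshold(0.05, 191)  # 224.24
#' @export
chi2_threshold <- function(alpha, dof) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  if (dof < 1) stop("dof must be >= 1")
  stats::qchisq(1 - alpha, df = dof)
}

#' Chi-squared model rejection test
#'
#' The model is rejected when the test statistic exceeds the chi-squared
#' threshold at significance `alpha` with one degree of freedom per
#' residual in the fitted datasets. A statistic exactly at the threshold
#' counts as a pass (boundary inclusive).
#'
#' @param stat the chi-squared statistic (see [chi2_statistic()]).
#' @param alpha significance level.
#' @param dof degrees of freedom (total residual count).
#' @return list of class `"nmc_chi2_test"` with elements `pass`, `stat`,
#'   `threshold`, `alpha`, `dof`.
#' @export
chi2_test <- function(stat, alpha = 0.05, dof) {
  stopifnot(is.finite(stat))
  thr <- chi2_threshold(alpha, dof)
  structure(list(pass = stat <= thr, stat = stat, threshold = thr,
                 alpha = alpha, dof = dof),
            class = "nmc_chi2_test")
}

#' @export
print.nmc_chi2_test <- function(x, ...) {
  cat(sprintf("chi-squared test: stat = %.2f, threshold chi2(alpha = %g, DoF = %d) = %.2f -> %s\n",
              x$stat, x$alpha, x$dof, x$threshold,
              if (x$pass) "not rejected" else "REJECTED"))
  invisible(x)
}
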