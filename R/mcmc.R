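## MCMC posterior sampling and prediction uncertainty envelopes.

#' Sample the parameter posterior by adaptive Metropolis MCMC
#'
#' Random-walk Metropolis in log10 parameter space targeting the
#' likelihood `exp(-stat/2)`, where `stat` is the chi-squared statistic
#' (weighted residual sum of squares). The proposal covariance adapts to
#' the running sample covariance after an initial phase, with the global
#' scale tuned toward an acceptance rate near 0.23. Draws whose statistic
#' lies within `chi2_threshold(alpha, dof)` of the best value are retained
#' as the acceptable set used for uncertainty envelopes, with the degrees
#' of freedom equal to the number of sampled parameters.
#'
#' @param x an `"nmc_fit"` (sampling starts at its optimum), or a function
#'   `f(theta)` returning the chi-squared statistic for a named parameter
#'   vector on the natural scale.
#' @param n_samples total number of MCMC draws (default 1e4; use 1e5 for
#'   final analyses).
#' @param seed integer seed.
#' @param ... passed to methods.
#' @return An object of class `"nmc_posterior"`: draws (natural scale),
#'   their statistics, the retained-set indicator, acceptance rate and
#'   seed.
#' @export
mcmc_sample <- function(x, n_samples = 10000, seed = 1L, ...) {
  UseMethod("mcmc_sample")
}

#' @rdname mcmc_sample
#' @param start named start vector (natural scale); required for the
#'   function method.
#' @param alpha significance level of the acceptable-set criterion.
#' @param dof degrees of freedom of the criterion; defaults to the number
#'   of sampled parameters.
#' @param lower,upper box bounds (natural scale).
#' @param init_step initial proposal standard deviation in decades.
#' @export
#' @param proposal_cov optional proposal covariance on the log10 scale
#'   (e.g. a Gauss-Newton approximation at the optimum); used as the
#'   initial proposal shape and refined adaptively.
#' @param temp sampling temperature: the chain targets
#'   `exp(-stat / (2 * temp))`. Values above 1 flatten the target so the
#'   chain maps the chi-squared acceptable region (the retained set)
#'   faster; the retained-set criterion itself is always evaluated at
#'   temperature 1.
#' @export
mcmc_sample.function <- function(x, n_samples = 10000, seed = 1L,
                                 start, alpha = 0.05, dof = NULL,
                                 lower = NULL, upper = NULL,
                                 init_step = 0.05, proposal_cov = NULL,
                                 temp = 1, ...) {
  objective <- x
  npar <- length(start)
  if (is.null(dof)) dof <- npar
  delta <- chi2_threshold(alpha, dof)
  lo <- if (is.null(lower)) rep(-Inf, npar) else log10(lower)
  hi <- if (is.null(upper)) rep(Inf, npar) else log10(upper)

  set.seed(seed)
  lth <- log10(unname(start))
  nms <- names(start)
  f_of <- function(l) {
    v <- tryCatch(suppressWarnings(objective(stats::setNames(10^l, nms))),
                  error = function(e) Inf)
    if (!is.finite(v)) Inf else v
  }
  cur <- f_of(lth)
  if (!is.finite(cur)) stop("objective not finite at the start point")

  draws <- matrix(NA_real_, n_samples, npar)
  stats_v <- numeric(n_samples)
  if (n_samples == 0)
    return(new_posterior(draws, stats_v, nms, cur, delta, 0, seed,
                         alpha, dof))

  scale <- init_step
  chol_l <- diag(npar)
  if (!is.null(proposal_cov)) {
    md <- mean(diag(proposal_cov))
    ch <- tryCatch(chol(proposal_cov / md + 1e-6 * diag(npar)),
                   error = function(e) NULL)
    if (!is.null(ch)) {
      chol_l <- t(ch)
      scale <- 2.38 / sqrt(npar) * sqrt(md)
    }
  }
  n_acc <- 0L; n_acc_win <- 0L
  mean_l <- lth; m2 <- matrix(0, npar, npar); n_seen <- 1L
  best <- cur
  window <- 200L

  for (i in seq_len(n_samples)) {
    prop <- lth + scale * as.numeric(chol_l %*% stats::rnorm(npar))
    if (all(prop >= lo & prop <= hi)) {
      v <- f_of(prop)
      if (is.finite(v) && log(stats::runif(1)) < (cur - v) / (2 * temp)) {
        lth <- prop; cur <- v
        n_acc <- n_acc + 1L; n_acc_win <- n_acc_win + 1L
        if (cur < best) best <- cur
      }
    }
    draws[i, ] <- lth
    stats_v[i] <- cur
    ## running moments for the adaptive covariance
    n_seen <- n_seen + 1L
    d <- lth - mean_l
    mean_l <- mean_l + d / n_seen
    m2 <- m2 + outer(d, lth - mean_l)
    if (i %% window == 0) {
      rate_win <- n_acc_win / window
      n_acc_win <- 0L
      scale <- scale * exp(rate_win - 0.23)
      if (i >= max(1000, npar * 20)) {
        ## correlation-shaped proposal: normalize the running covariance
        ## to unit mean diagonal (the global magnitude lives in `scale`)
        ## and regularize so no direction collapses entirely
        cv <- m2 / (n_seen - 1)
        md <- mean(diag(cv))
        if (md > 0) {
          cvn <- cv / md + 0.05 * diag(npar)
          ch <- tryCatch(chol(cvn), error = function(e) NULL)
          if (!is.null(ch)) chol_l <- t(ch)
        }
      }
    }
  }
  rate <- n_acc / n_samples
  if (rate < 0.01)
    warning(sprintf("MCMC acceptance rate %.2f%% is very low; consider re-tuning the proposal scale", 100 * rate))
  new_posterior(draws, stats_v, nms, best, delta, rate, seed, alpha, dof)
}

new_posterior <- function(draws_log10, stats_v, nms, best, delta, rate,
                          seed, alpha, dof) {
  draws <- 10^draws_log10
  colnames(draws) <- nms
  retained <- is.finite(stats_v) & stats_v <= best + delta
  structure(list(draws = draws, stat = stats_v, retained = retained,
                 best = best, delta = delta, acceptance = rate,
                 seed = seed, alpha = alpha, dof = dof),
            class = "nmc_posterior")
}

#' @rdname mcmc_sample
#' @param burn_in fraction of initial draws discarded before the retained
#'   set is formed (default 0.1).
#' @param thin keep every `thin`-th draw.
#' @export
mcmc_sample.nmc_fit <- function(x, n_samples = 10000, seed = 1L,
                                alpha = 0.05, burn_in = 0.1, thin = 1L,
                                temp = 2, ...) {
  fit <- x
  objective <- function(theta)
    chi2_statistic(theta, fit$data, fit$model)
  post <- mcmc_sample.function(
    objective, n_samples = n_samples, seed = seed, start = fit$theta,
    alpha = alpha, dof = length(fit$theta),
    lower = fit$bounds$lower[fit$fit_params],
    upper = fit$bounds$upper[fit$fit_params],
    proposal_cov = gauss_newton_cov(fit), temp = temp, ...)
  keep <- seq_len(n_samples)
  if (burn_in > 0) keep <- keep[-seq_len(floor(burn_in * n_samples))]
  if (thin > 1L) keep <- keep[seq(1L, length(keep), by = thin)]
  post$draws <- post$draws[keep, , drop = FALSE]
  post$stat <- post$stat[keep]
  post$best <- min(post$best, fit$objective)
  post$retained <- is.finite(post$stat) & post$stat <= post$best + post$delta
  post$fit <- fit
  post
}

## Gauss-Newton posterior covariance approximation at the optimum, on
## the log10 scale, from a forward-difference Jacobian of the weighted
## residual vector. Flat (sloppy) directions are floored at 1e-6 of the
## leading curvature so the covariance stays finite.
gauss_newton_cov <- function(fit, step = 1e-3) {
  l0 <- log10(fit$theta)
  r0 <- fit$resid_fun(l0)
  J <- matrix(0, length(r0), length(l0))
  for (j in seq_along(l0)) {
    lp <- l0; lp[j] <- lp[j] + step
    J[, j] <- (fit$resid_fun(lp) - r0) / step
  }
  H <- crossprod(J)
  e <- eigen(H, symmetric = TRUE)
  lam <- pmax(e$values, max(e$values) * 1e-6)
  e$vectors %*% (t(e$vectors) / lam)
}

#' @export
print.nmc_posterior <- function(x, ...) {
  cat(sprintf("Posterior sample: %d draws, %d retained (stat <= best %.2f + %.2f), acceptance %.1f%%\n",
              nrow(x$draws), sum(x$retained), x$best, x$delta,
              100 * x$acceptance))
  invisible(x)
}

#' Pointwise prediction uncertainty envelope
#'
#' Simulates the model observable for draws of the retained (acceptable)
#' parameter set and returns the pointwise band (min/max, plus optional
#' quantiles). The optimal-fit draw is always included, so the band always
#' contains the best-fit trajectory.
#'
#' @param samples an `"nmc_posterior"` produced from a fit.
#' @param paradigm a [stimulus_paradigm()] or catalog name.
#' @param observable observable name (e.g. `"Lac"`).
#' @param times output grid; see [simulate_model()].
#' @param max_draws number of retained draws to propagate (uniformly
#'   subsampled; all retained draws if fewer).
#' @param probs optional quantile levels to add to the band.
#' @return data frame of class `"nmc_envelope"` with columns `time_s`,
#'   `lower`, `upper`, `best`, and any requested quantiles.
#' @export
prediction_envelope <- function(samples, paradigm, observable,
                                times = NULL, max_draws = 200,
                                probs = NULL) {
  if (is.null(samples$fit))
    stop("prediction_envelope needs a posterior produced from a fit")
  if (!any(samples$retained)) stop("the retained set is empty")
  if (is.character(paradigm)) paradigm <- make_paradigm(paradigm)
  fit <- samples$fit
  idx <- which(samples$retained)
  if (length(idx) > max_draws)
    idx <- idx[unique(round(seq(1, length(idx), length.out = max_draws)))]

  sim_one <- function(theta) {
    sp <- split_parameters(theta, fit$model)
    p <- resolve_params(fit$model, sp$kinetic)
    ss <- steady_state(fit$model, p)
    traj <- simulate_model(fit$model, p, paradigm, times, init = ss)
    o <- observe(traj, fit$model, p, scalings = sp$scalings,
                 names = observable, ss = ss)[[1]]
    list(times = o$times, values = o$values)
  }
  best <- sim_one(fit$theta)
  mat <- matrix(NA_real_, length(idx) + 1L, length(best$values))
  mat[1L, ] <- best$values
  for (j in seq_along(idx)) {
    theta <- stats::setNames(samples$draws[idx[j], ], colnames(samples$draws))
    v <- tryCatch(sim_one(theta)$values, error = function(e) NULL)
    mat[j + 1L, ] <- if (is.null(v)) best$values else v
  }
  out <- data.frame(time_s = best$times,
                    lower = apply(mat, 2, min),
                    upper = apply(mat, 2, max),
                    best = best$values)
  if (!is.null(probs))
    for (pq in probs)
      out[[sprintf("q%g", 100 * pq)]] <- apply(mat, 2, stats::quantile,
                                               probs = pq)
  attr(out, "observable") <- observable
  attr(out, "n_draws") <- length(idx) + 1L
  class(out) <- c("nmc_envelope", "data.frame")
  out
}

#' @export
plot.nmc_envelope <- function(x, add_data = NULL, ...) {
  plot(x$time_s, x$best, type = "n",
       ylim = range(x$lower, x$upper,
                    if (!is.null(add_data)) add_data$mean_pct),
       xlab = "time (s)",
       ylab = sprintf("%s (%% change)", attr(x, "observable")), ...)
  graphics::polygon(c(x$time_s, rev(x$time_s)), c(x$lower, rev(x$upper)),
                    col = grDevices::adjustcolor("steelblue", 0.4),
                    border = NA)
  graphics::lines(x$time_s, x$best, col = "blue3", lwd = 2)
  if (!is.null(add_data))
    graphics::points(add_data$time_s, add_data$mean_pct, pch = 16,
                     col = "red3")
  invisible(x)
}

#' Serialize fit results and posterior draws
#'
#' `write_fit_json()` writes the optimum, objective, per-dataset residual
#' breakdown, chi-squared test, seed and a hash of the parameter vector;
#' `write_posterior_csv()` writes one row per draw (parameters on the
#' natural scale, the chi-squared statistic, and the retained-set flag).
#'
#' @param fit an `"nmc_fit"`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(list(
    model = fit$model$name,
    seed = fit$seed,
    n_residuals = fit$n_residuals,
    objective = fit$objective,
    nll = fit$nll,
    breakdown = as.list(fit$breakdown),
    test = list(pass = fit$test$pass, stat = fit$test$stat,
                threshold = fit$test$threshold, alpha = fit$test$alpha,
                dof = fit$test$dof),
    theta = as.list(fit$theta),
    theta_hash = param_hash(fit$theta)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_fit_json
#' @param posterior an `"nmc_posterior"`.
#' @export
write_posterior_csv <- function(posterior, path) {
  utils::write.csv(data.frame(posterior$draws,
                              stat = posterior$stat,
                              retained = posterior$retained,
                              check.names = FALSE),
                   path, row.names = FALSE)
  invisible(path)
}
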