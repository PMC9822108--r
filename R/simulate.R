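## Steady states, trajectory simulation and percent-change observables.

## Newton solve (in log space, damped) for the steady-state pyruvate/OAA
## pair shared by both packaged models: total glycolytic influx G is split
## between TCA1, LDH and PC, and the OAA/OG loop balances PC against the
## transamination drains.
solve_pyr_oaa <- function(G, p) {
  fn <- function(z) {
    Pyr <- exp(z[1]); OAA <- exp(z[2])
    VT <- p[["kmaxPO"]] * Pyr / (p[["KM_Pyr"]] + Pyr) *
      OAA / (p[["KM_OAA"]] + OAA)
    VPC <- p[["kmaxPyr2"]] * Pyr / (p[["KM_Pyr2"]] + Pyr)
    c(G - VT - p[["kmaxPyr"]] * Pyr - VPC,
      VPC - p[["kmaxOG2"]] / (p[["kmaxOG1"]] + p[["kmaxOG2"]]) * VT -
        p[["kmaxOAA"]] * OAA)
  }
  z <- log(c(G / (2 * p[["kmaxPyr"]]), p[["KM_OAA"]]))
  f <- fn(z)
  for (it in 1:200) {
    J <- matrix(0, 2, 2)
    h <- 1e-7
    for (j in 1:2) {
      zp <- z; zp[j] <- zp[j] + h
      J[, j] <- (fn(zp) - f) / h
    }
    step <- tryCatch(solve(J, f), error = function(e) f * 0)
    lam <- 1
    repeat {
      zn <- z - lam * step
      fn2 <- fn(zn)
      if (sum(fn2^2) < sum(f^2) || lam < 1e-6) break
      lam <- lam / 2
    }
    z <- zn; f <- fn2
    if (max(abs(f)) < 1e-15) break
  }
  c(Pyr = exp(z[1]), OAA = exp(z[2]))
}

metab_tail_ss <- function(G, p) {
  po <- solve_pyr_oaa(G, p)
  VT <- p[["kmaxPO"]] * po[["Pyr"]] / (p[["KM_Pyr"]] + po[["Pyr"]]) *
    po[["OAA"]] / (p[["KM_OAA"]] + po[["OAA"]])
  OG <- VT / (p[["kmaxOG1"]] + p[["kmaxOG2"]])
  Glut <- p[["kmaxOG2"]] * OG / p[["kmaxGlut2"]]
  c(Pyr = po[["Pyr"]],
    Lac = p[["kmaxPyr"]] * po[["Pyr"]] / p[["k1"]],
    OAA = po[["OAA"]], OG = OG,
    Asp = p[["kmaxOAA"]] * po[["OAA"]] / p[["kmaxAsp"]],
    Glut = Glut,
    Gln = p[["kmaxGlut1"]] * Glut / p[["kmaxGln"]])
}

#' Steady state of a model with the stimulus off
#'
#' For the packaged metabolism and combined models the balance equations
#' are reduced analytically to a two-variable root-finding problem in
#' pyruvate and OAA; for arbitrary model documents the state is obtained
#' by a long pre-simulation (1e5 s) followed by damped Newton iteration on
#' the right-hand side. In all cases the returned state is verified to
#' satisfy `max |dx/dt| < tol` coordinate-wise and to be non-negative;
#' otherwise an error naming the failing state is raised.
#'
#' @param model a model document.
#' @param params optional named parameter overrides.
#' @param tol acceptance residual on the infinity norm of the derivatives.
#' @return named numeric steady-state vector (one entry per model state).
#' @export
steady_state <- function(model, params = NULL, tol = 1e-9) {
  p <- resolve_params(model, params)
  nm <- model$name
  if (identical(nm, "metabolism") && !is.null(model$compiled)) {
    G <- p[["Glucose_blood"]]
    tail <- metab_tail_ss(G, p)
    ss <- c(Stimulus = 0,
            Gluc_c = G / p[["kmax_glucc"]],
            Gluc_t = G / p[["kmax_gluct"]],
            tail)[model$states]
  } else if (identical(nm, "combined") && !is.null(model$compiled)) {
    O2 <- (p[["k_o2in"]] - p[["k_o2use"]] * p[["k_glcin"]]) / p[["k_o2leak"]]
    if (!is.finite(O2) || O2 <= 0)
      stop("no non-negative steady state: O2_A")
    GA <- p[["k_glcin"]] / (p[["k_basalMet"]] * p[["k_prop1"]] * O2)
    tail <- metab_tail_ss(p[["k_glcin"]], p)
    ss <- c(N = 0, Delay_M = 0, A1 = 0, A2 = 0, Fl = 0, Vv = 1,
            O2_A = O2, Glucose_A = GA,
            dHb = p[["k_dhb"]] * p[["k_basalMet"]] * p[["k_prop1"]] /
              p[["k_wash"]],
            tail)[model$states]
  } else {
    ss <- steady_state_generic(model, p, tol)
  }
  names(ss) <- model$states
  check_steady(model, p, ss, tol)
  ss
}

steady_state_generic <- function(model, p, tol) {
  rhs <- build_rhs(model)
  parms <- c(p, u = 0)
  y0 <- stats::setNames(rep(1, length(model$states)), model$states)
  pre <- deSolve::ode(y0, c(0, 1e5), rhs, parms, method = "lsoda",
                      rtol = 1e-8, atol = 1e-10)
  y <- pre[nrow(pre), -1]
  f <- unlist(rhs(0, y, parms))
  for (it in 1:100) {
    if (max(abs(f)) < tol * 1e-3) break
    J <- matrix(0, length(y), length(y))
    for (j in seq_along(y)) {
      h <- 1e-7 * max(abs(y[j]), 1e-4)
      yp <- y; yp[j] <- yp[j] + h
      J[, j] <- (unlist(rhs(0, yp, parms)) - f) / h
    }
    step <- tryCatch(solve(J, f), error = function(e) f * 0)
    lam <- 1
    repeat {
      yn <- y - lam * step
      f2 <- unlist(rhs(0, yn, parms))
      if (sum(f2^2) < sum(f^2) || lam < 1e-8) break
      lam <- lam / 2
    }
    y <- yn; f <- f2
  }
  y
}

## Interpreted right-hand sides are cached for the packaged (compiled)
## models, whose document structure is fixed; arbitrary documents are
## rebuilt on each call.
.rhs_cache <- new.env(parent = emptyenv())

rhs_for <- function(model) {
  if (is.null(model$compiled)) return(build_rhs(model))
  key <- model$name
  if (is.null(.rhs_cache[[key]]))
    .rhs_cache[[key]] <- build_rhs(model)
  .rhs_cache[[key]]
}

check_steady <- function(model, p, ss, tol) {
  rhs <- rhs_for(model)
  f <- unlist(rhs(0, ss, c(p, u = 0)))
  bad <- which(abs(f) >= tol)
  if (length(bad))
    stop("steady-state residual above tolerance for state(s): ",
         paste(model$states[bad], collapse = ", "))
  neg <- which(ss < 0)
  if (length(neg))
    stop("no non-negative steady state: ",
         paste(model$states[neg], collapse = ", "))
  invisible(TRUE)
}

resolve_params <- function(model, params = NULL) {
  p <- unlist(model$parameters)
  if (!is.null(params)) {
    if (is.null(names(params)) && length(params) == length(p)) {
      names(params) <- names(p)
      p <- params
    } else {
      p[names(params)] <- params
    }
  }
  p
}

#' Simulate a model over a stimulation paradigm
#'
#' Integrates the model ODEs with a stiff-capable solver (lsoda), default
#' relative tolerance 1e-8 and absolute tolerance 1e-10. Because the step
#' input breaks the solver's smoothness assumptions, integration is
#' restarted at every epoch boundary with the input held constant within
#' each segment. The packaged models use compiled right-hand sides; other
#' documents run through a generic interpreter.
#'
#' @param model a model document.
#' @param params optional named parameter overrides.
#' @param paradigm a [stimulus_paradigm()].
#' @param times strictly increasing output grid (seconds); defaults to a
#'   1 s grid over the horizon (0.1 s when the horizon is short).
#' @param init initial state; defaults to [steady_state()].
#' @param rtol,atol solver tolerances.
#' @return An object of class `"nmc_trajectory"`: list with `times`,
#'   `values` (time-by-state matrix), `init` and solver diagnostics.
#' @export
simulate_model <- function(model, params = NULL, paradigm, times = NULL,
                           init = NULL, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(paradigm, "stimulus_paradigm"))
  p <- resolve_params(model, params)
  if (is.null(times)) {
    dt <- if (paradigm$horizon <= 120) 0.1 else 1
    times <- seq(0, paradigm$horizon, by = dt)
  }
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (max(times) > paradigm$horizon) stop("times exceed the horizon")
  if (is.null(init)) init <- steady_state(model, p)
  y <- stats::setNames(as.numeric(init), model$states)

  bounds <- sort(unique(c(0, paradigm$on, paradigm$off, max(times))))
  bounds <- bounds[bounds <= max(times)]
  use_c <- !is.null(model$compiled)
  rhs <- if (use_c) NULL else build_rhs(model)

  out <- matrix(NA_real_, length(times), length(y),
                dimnames = list(NULL, model$states))
  idx_done <- logical(length(times))
  for (i in seq_len(length(bounds) - 1L)) {
    t0 <- bounds[i]; t1 <- bounds[i + 1L]
    if (t1 <= t0) next
    u <- as.numeric(any(t0 >= paradigm$on & t0 < paradigm$off))
    sel <- which(times > t0 & times <= t1)
    tt <- c(t0, times[sel], t1)
    ## collapse output times within solver resolution of a boundary
    tt <- tt[c(TRUE, diff(tt) > 1e-9)]
    o <- if (use_c) {
      deSolve::ode(y, tt, func = model$compiled$derivs,
                   parms = c(unname(p[model$compiled$par_order]), u),
                   dllname = "neurometab", initfunc = model$compiled$init,
                   method = "lsoda", rtol = rtol, atol = atol)
    } else {
      deSolve::ode(y, tt, rhs, c(p, u = u), method = "lsoda",
                   rtol = rtol, atol = atol)
    }
    istate <- attr(o, "istate")
    if (!is.null(istate) && istate[1] < 0)
      stop(sprintf("solver failure in [%g, %g] s; last successful time %g s",
                   t0, t1, o[nrow(o), 1]))
    if (length(sel)) {
      rows <- vapply(times[sel], function(x) which.min(abs(o[, 1] - x)),
                     integer(1))
      out[sel, ] <- o[rows, -1, drop = FALSE]
      idx_done[sel] <- TRUE
    }
    y <- o[nrow(o), -1]
  }
  sel0 <- which(times <= bounds[1L])
  if (length(sel0)) {
    out[sel0, ] <- matrix(init, length(sel0), length(y), byrow = TRUE)
    idx_done[sel0] <- TRUE
  }
  if (!all(idx_done) || any(!is.finite(out)))
    stop("simulation produced missing or non-finite values")
  structure(list(times = times, values = out, init = y0_named(init, model),
                 model = model$name,
                 diagnostics = list(rtol = rtol, atol = atol,
                                    success = TRUE)),
            class = "nmc_trajectory")
}

y0_named <- function(init, model) stats::setNames(as.numeric(init),
                                                  model$states)

#' @export
print.nmc_trajectory <- function(x, ...) {
  cat(sprintf("Trajectory of '%s': %d states, %d time points over [%g, %g] s\n",
              x$model, ncol(x$values), length(x$times), min(x$times),
              max(x$times)))
  invisible(x)
}

#' @export
as.data.frame.nmc_trajectory <- function(x, ...) {
  data.frame(time_s = x$times, x$values, check.names = FALSE)
}

#' Write a trajectory or observable set as CSV
#'
#' Header row is `time_s` followed by one column per state or observable.
#' @param x an `"nmc_trajectory"` or `"nmc_observables"` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Percent-change observables of a trajectory
#'
#' Each observable is the percentage difference of a (possibly
#' transformed) state from its steady-state baseline, scaled by its
#' dimensionless scale factor: `ky_i * (X_i(t) / ssX_i - 1) * 100`. The
#' glucose observable maps to tissue glucose.
#'
#' @param trajectory an `"nmc_trajectory"` simulated from the steady state
#'   of `params`.
#' @param model the model document used for the simulation.
#' @param params optional named parameter overrides (must match the
#'   simulation).
#' @param scalings named scale factors; defaults to 1 for every observable
#'   (with the packaged negative-BOLD surrogate scaling for `BOLDneg`).
#' @param names observables to return; default all.
#' @param ss optional precomputed steady state.
#' @return An object of class `"nmc_observables"`: named list of series,
#'   each with `name`, `times` and `values` (percent).
#' @export
observe <- function(trajectory, model, params = NULL, scalings = NULL,
                    names = NULL, ss = NULL) {
  p <- resolve_params(model, params)
  if (is.null(ss)) ss <- steady_state(model, p)
  obs <- model$observables
  if (!is.null(names)) {
    missing_obs <- setdiff(names, base::names(obs))
    if (length(missing_obs))
      stop("unknown observable(s): ", paste(missing_obs, collapse = ", "))
    obs <- obs[names]
  }
  sc <- default_obs_scalings(model)
  if (!is.null(scalings)) sc[base::names(scalings)] <- scalings

  penv <- as.list(p)
  res <- lapply(base::names(obs), function(nm) {
    o <- obs[[nm]]
    ex <- str2lang(o$expr)
    ssX <- eval(ex, c(as.list(ss), penv))
    if (ssX == 0) stop("degenerate baseline: steady-state value of '",
                       nm, "' is zero")
    vals <- trajectory$values
    cols <- stats::setNames(lapply(seq_len(ncol(vals)),
                                   function(j) vals[, j]),
                            colnames(vals))
    X <- eval(ex, c(cols, penv))
    sgn <- if (is.null(o$sign)) 1 else o$sign
    ky <- sc[[o$scaling]]
    list(name = nm, times = trajectory$times,
         values = sgn * ky * (X / ssX - 1) * 100)
  })
  structure(stats::setNames(res, base::names(obs)),
            class = "nmc_observables")
}

default_obs_scalings <- function(model) {
  sc <- lapply(model$observables, function(o) 1)
  nm <- unique(vapply(model$observables, `[[`, "", "scaling"))
  out <- stats::setNames(rep(1, length(nm)), nm)
  if ("ky_BOLDneg" %in% nm) out[["ky_BOLDneg"]] <- 0.4
  out
}

#' @export
as.data.frame.nmc_observables <- function(x, ...) {
  wide <- data.frame(time_s = x[[1]]$times)
  for (o in x) wide[[o$name]] <- o$values
  wide
}

#' @export
print.nmc_observables <- function(x, ...) {
  cat("Percent-change observables:",
      paste(names(x), collapse = ", "), "\n")
  for (o in x)
    cat(sprintf("  %-8s range [%+.3f, %+.3f] %%\n", o$name,
                min(o$values), max(o$values)))
  invisible(x)
}

#' Simulate the combined model and return all observables
#'
#' Convenience wrapper: assembles (or accepts) the combined model,
#' simulates from its steady state and returns the trajectory together
#' with the five percent-change observables (four metabolites and BOLD).
#'
#' @param params optional named parameter overrides.
#' @param paradigm a [stimulus_paradigm()].
#' @param times output grid; see [simulate_model()].
#' @param model a combined model document; defaults to
#'   `combine_models(metabolism_model(), nvc_model())`.
#' @param scalings observable scale factors (see [observe()]).
#' @return list with elements `trajectory` and `observables`.
#' @export
simulate_combined <- function(params = NULL, paradigm, times = NULL,
                              model = NULL, scalings = NULL) {
  if (is.null(model)) model <- combine_models(metabolism_model(),
                                              nvc_model())
  p <- resolve_params(model, params)
  ss <- steady_state(model, p)
  traj <- simulate_model(model, p, paradigm, times, init = ss)
  obs <- observe(traj, model, p, scalings = scalings, ss = ss,
                 names = c("Lac", "Glut", "Gluc", "Asp", "BOLD"))
  list(trajectory = traj, observables = obs)
}
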