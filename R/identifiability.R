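## Local structural identifiability via the rank of the Jacobian of
## successive output derivatives with respect to initial states and
## parameters.
##
## Output derivatives y, y', ..., y^(k) at t = 0 are Lie derivatives of
## the output maps along the vector field. They are computed here through
## the Taylor coefficients of the ODE solution: truncated power-series
## arithmetic propagates the state series through the right-hand side
## (the standard Taylor recurrence c_{m+1} = f_m / (m+1)), and the output
## expressions are evaluated on the state series. Differentiation with
## respect to each initial state and parameter uses the complex-step
## method (exact to machine precision for the rational/analytic rate
## expressions used here).

## ---- truncated power-series arithmetic (complex coefficients) ----

ps_const <- function(v, K) c(v, rep(0+0i, K))

ps_mul <- function(a, b) {
  K <- length(a) - 1L
  out <- rep(0+0i, K + 1L)
  for (m in 0:K)
    out[m + 1L] <- sum(a[1:(m + 1L)] * b[(m + 1L):1L])
  out
}

ps_div <- function(a, b) {
  K <- length(a) - 1L
  out <- rep(0+0i, K + 1L)
  out[1L] <- a[1L] / b[1L]
  if (K > 0) for (m in 1:K)
    out[m + 1L] <- (a[m + 1L] -
                      sum(out[1:m] * b[(m + 1L):2L])) / b[1L]
  out
}

ps_exp <- function(a) {
  K <- length(a) - 1L
  out <- rep(0+0i, K + 1L)
  out[1L] <- exp(a[1L])
  if (K > 0) for (m in 1:K)
    out[m + 1L] <- sum((1:m) * a[2:(m + 1L)] * out[m:1L]) / m
  out
}

ps_log <- function(a) {
  K <- length(a) - 1L
  out <- rep(0+0i, K + 1L)
  out[1L] <- log(a[1L])
  if (K > 0) for (m in 1:K) {
    conv <- if (m > 1L)
      sum((1:(m - 1L)) * out[2:m] * a[m:2L]) / m else 0+0i
    out[m + 1L] <- (a[m + 1L] - conv) / a[1L]
  }
  out
}

## Evaluate an R expression under power-series semantics. `env` maps
## symbols to series (states) or scalars (parameters, input).
ps_eval <- function(e, env, K) {
  if (is.numeric(e) || is.complex(e)) return(ps_const(e, K))
  if (is.symbol(e)) {
    v <- env[[as.character(e)]]
    if (is.null(v)) stop("unknown symbol: ", as.character(e))
    if (length(v) == 1L) return(ps_const(v, K))
    return(v)
  }
  if (!is.call(e)) stop("cannot evaluate term of class ", class(e)[1])
  op <- as.character(e[[1L]])
  if (op == "(") return(ps_eval(e[[2L]], env, K))
  if (op == "-" && length(e) == 2L) return(-ps_eval(e[[2L]], env, K))
  if (op == "+" && length(e) == 2L) return(ps_eval(e[[2L]], env, K))
  if (op == "exp") return(ps_exp(ps_eval(e[[2L]], env, K)))
  if (op == "log") return(ps_log(ps_eval(e[[2L]], env, K)))
  a <- ps_eval(e[[2L]], env, K)
  b <- ps_eval(e[[3L]], env, K)
  switch(op,
    "+" = a + b,
    "-" = a - b,
    "*" = ps_mul(a, b),
    "/" = ps_div(a, b),
    "^" = {
      pw <- e[[3L]]
      if (is.numeric(pw) && pw == round(pw) && pw >= 1) {
        out <- a
        for (i in seq_len(pw - 1L)) out <- ps_mul(out, a)
        out
      } else ps_exp(ps_mul(ps_const(b[1L], length(a) - 1L), ps_log(a)))
    },
    stop("operator not supported in model expressions: ", op))
}

## Taylor coefficients (orders 0..K) of the states and outputs at t = 0.
## `point` is a named list holding initial states and parameters
## (scalars) and, for each input, either a scalar (input held constant)
## or a vector of Taylor coefficients (a generic input signal).
taylor_outputs <- function(field, outputs, states, point, K) {
  env <- lapply(point, function(v)
    if (length(v) > 1L) {
      s <- rep(0+0i, K + 1L)
      s[seq_len(min(length(v), K + 1L))] <- v[seq_len(min(length(v), K + 1L))]
      s
    } else v)
  series <- lapply(states, function(s) ps_const(point[[s]][1L], K))
  names(series) <- states
  is_series <- vapply(env, function(v) length(v) > 1L, logical(1))
  for (m in 0:max(K - 1L, 0L)) {
    if (K == 0L) break
    envm <- env
    for (nm in names(env)[is_series]) envm[[nm]] <- env[[nm]][1:(m + 1L)]
    for (s in states) envm[[s]] <- series[[s]][1:(m + 1L)]
    for (s in states) {
      fm <- ps_eval(field[[s]], envm, m)[m + 1L]
      series[[s]][m + 2L] <- fm / (m + 1L)
    }
  }
  envK <- env
  for (s in states) envK[[s]] <- series[[s]]
  vapply(outputs, function(g) ps_eval(g, envK, K), complex(K + 1L))
}

#' Jacobian of successive output derivatives
#'
#' Computes the matrix of partial derivatives of the stacked output
#' derivatives `(y, y', ..., y^(k))` at `t = 0` with respect to the
#' initial states and parameters, evaluated at a given point with the
#' stimulus input held at a constant value.
#'
#' @param model a model document.
#' @param outputs named character vector of output expressions (in states
#'   and parameters); defaults to the model's observables in
#'   arbitrary-units form (`scaling * expression`), with the scalings as
#'   additional unknown parameters.
#' @param k highest derivative order (>= 0).
#' @param point named numeric vector of values for all states, parameters
#'   and `u`; missing entries default to the model document values (with
#'   `u = 1` and states at 1).
#' @param input_series optional named list giving Taylor coefficients of
#'   the input signal(s), e.g. `list(u = c(1, 0.3, -0.2))`; treats the
#'   input as a generic differentiable signal rather than a constant.
#' @param unknowns names of the quantities to differentiate with respect
#'   to; defaults to all initial states followed by all parameters
#'   appearing in the model or outputs.
#' @return matrix with `length(outputs) * (k + 1)` rows (outputs ordered
#'   within derivative order) and one column per unknown; row `i` of
#'   block `j` is the gradient of the j-th derivative of output i.
#' @export
output_derivative_jacobian <- function(model, outputs = NULL, k,
                                       point = NULL, unknowns = NULL,
                                       input_series = NULL) {
  stopifnot(k >= 0)
  field <- model_field(model)
  if (is.null(outputs)) outputs <- scaled_outputs(model)
  out_exprs <- lapply(outputs, str2lang)

  par_syms <- setdiff(
    unique(unlist(c(lapply(field, all.vars),
                    lapply(out_exprs, all.vars)))),
    c(model$states, model$inputs))
  full <- c(stats::setNames(rep(1, length(model$states)), model$states),
            stats::setNames(rep(1, length(par_syms)), par_syms), u = 1)
  defaults <- unlist(model$parameters)
  full[names(defaults)[names(defaults) %in% par_syms]] <-
    defaults[names(defaults) %in% par_syms]
  if (!is.null(point)) full[names(point)] <- point
  if (is.null(unknowns)) unknowns <- c(model$states, par_syms)

  h <- 1e-100
  base <- as.list(full)
  if (!is.null(input_series))
    for (nm in names(input_series)) base[[nm]] <- input_series[[nm]]
  J <- matrix(0, length(outputs) * (k + 1L), length(unknowns),
              dimnames = list(NULL, unknowns))
  fac <- factorial(0:k)
  for (j in seq_along(unknowns)) {
    pt <- base
    pt[[unknowns[j]]][1L] <- pt[[unknowns[j]]][1L] + h * 1i
    co <- taylor_outputs(field, out_exprs, model$states, pt, k)
    ## co is (k+1) x n_out; stack derivative-order-major (all outputs at
    ## order 0, then order 1, ...), converting coefficients to derivatives
    J[, j] <- rep(fac, each = length(outputs)) *
      as.vector(t(Im(co) / h))
  }
  rownames(J) <- paste0(rep(names(outputs), k + 1L), "^(",
                        rep(0:k, each = length(outputs)), ")")
  J
}

scaled_outputs <- function(model) {
  obs <- model$observables
  stats::setNames(vapply(obs, function(o)
    sprintf("%s * (%s)", o$scaling, o$expr), ""), names(obs))
}

#' Local structural identifiability at a derivative order
#'
#' At several random generic points (log-uniform in [0.1, 10] per
#' quantity), computes the Jacobian of the output derivatives up to order
#' `k` and its numerical rank; a quantity is locally identifiable at
#' order `k` when its column does not participate in the Jacobian's null
#' space (equivalently, removing it reduces the rank) at all points.
#' Classification is by majority vote across trials, with discordant
#' quantities flagged as indeterminate.
#'
#' @inheritParams output_derivative_jacobian
#' @param trials number of random evaluation points.
#' @param seed integer seed for the evaluation points.
#' @param generic_input treat the stimulus input as a generic
#'   differentiable signal (random Taylor coefficients per trial), the
#'   convention of differential-algebra identifiability analysis; with
#'   `FALSE` the input is held at the constant 1, which can hide
#'   information carried by input switching and merge quantities into
#'   spurious symmetries.
#' @param rank_tol singular values below `max(dim) * rank_tol * max(sv)`
#'   count as zero (default machine epsilon).
#' @return An object of class `"nmc_identifiability"`: data frame with
#'   one row per quantity (`quantity`, `type`, `identifiable`, `votes`),
#'   plus attributes `rank`, `n_unknowns`, `k`, `seed`.
#' @export
local_identifiability <- function(model, outputs = NULL, k, trials = 5,
                                  seed = 1L, rank_tol = .Machine$double.eps,
                                  unknowns = NULL, generic_input = TRUE) {
  stopifnot(trials >= 1)
  field <- model_field(model)
  if (is.null(outputs)) outputs <- scaled_outputs(model)
  par_syms <- setdiff(
    unique(unlist(c(lapply(field, all.vars),
                    lapply(outputs, function(o) all.vars(str2lang(o)))))),
    c(model$states, model$inputs))
  if (is.null(unknowns)) unknowns <- c(model$states, par_syms)

  set.seed(seed)
  votes <- matrix(FALSE, length(unknowns), trials,
                  dimnames = list(unknowns, NULL))
  ranks <- integer(trials)
  for (tr in seq_len(trials)) {
    qty <- c(model$states, par_syms)
    point <- stats::setNames(10^stats::runif(length(qty), -1, 1), qty)
    inp <- if (generic_input && length(model$inputs))
      stats::setNames(lapply(model$inputs, function(i)
        c(1, stats::rnorm(k + 1L))), model$inputs) else NULL
    J <- output_derivative_jacobian(model, outputs, k, point = point,
                                    unknowns = unknowns,
                                    input_series = inp)
    res <- jacobian_rank_analysis(J, point[unknowns], rank_tol)
    ranks[tr] <- res$rank
    votes[, tr] <- res$identifiable
  }
  n_yes <- rowSums(votes)
  status <- ifelse(n_yes == trials, "identifiable",
                   ifelse(n_yes == 0L, "unidentifiable",
                          ifelse(n_yes > trials / 2, "identifiable",
                                 "unidentifiable")))
  indeterminate <- n_yes > 0L & n_yes < trials
  df <- data.frame(
    quantity = unknowns,
    type = ifelse(unknowns %in% model$states, "state", "parameter"),
    identifiable = status == "identifiable",
    indeterminate = indeterminate,
    votes = n_yes, stringsAsFactors = FALSE)
  structure(df, rank = ranks, n_unknowns = length(unknowns), k = k,
            trials = trials, seed = seed,
            class = c("nmc_identifiability", "data.frame"))
}

## Rank and per-column null-space participation of a (row/column scaled)
## Jacobian. Columns are scaled by the point values (log-derivative
## scaling) and rows normalized, which changes neither the rank nor the
## null-space support.
jacobian_rank_analysis <- function(J, colscale, rank_tol) {
  Js <- J %*% diag(as.numeric(colscale), ncol(J))
  rn <- sqrt(rowSums(Js^2))
  keep <- rn > 0
  Js[keep, ] <- Js[keep, , drop = FALSE] / rn[keep]
  sv <- svd(Js, nu = 0, nv = ncol(Js))
  tol <- max(dim(Js)) * rank_tol * max(sv$d, 0)
  r <- sum(sv$d > tol)
  if (r == ncol(Js)) {
    ident <- rep(TRUE, ncol(Js))
  } else {
    null_basis <- sv$v[, seq(r + 1L, ncol(Js)), drop = FALSE]
    part <- sqrt(rowSums(null_basis^2))
    ident <- part < 1e-7
  }
  list(rank = r, identifiable = stats::setNames(ident, colnames(J)))
}

#' @export
print.nmc_identifiability <- function(x, ...) {
  cat(sprintf("Local identifiability at derivative order k = %d (%d unknowns, ranks: %s)\n",
              attr(x, "k"), attr(x, "n_unknowns"),
              paste(attr(x, "rank"), collapse = "/")))
  n_un <- sum(!x$identifiable)
  if (n_un == 0) cat("  all states and parameters locally identifiable\n")
  else cat("  unidentifiable:",
           paste(x$quantity[!x$identifiable], collapse = ", "), "\n")
  if (any(x$indeterminate))
    cat("  indeterminate (discordant trials):",
        paste(x$quantity[x$indeterminate], collapse = ", "), "\n")
  invisible(x)
}

#' Smallest derivative order giving full local identifiability
#'
#' Scans derivative orders 0..`k_max` and returns the first at which all
#' states and parameters are locally identifiable, or `NA` (with the
#' unidentifiable quantities listed) if none is.
#'
#' @inheritParams local_identifiability
#' @param k_max largest derivative order scanned.
#' @return list of class `"nmc_minimal_order"` with elements `order`
#'   (integer or NA), `reports` (per-order identifiability reports) and
#'   `unidentifiable` (quantities still unidentifiable at `k_max`).
#' @export
minimal_order <- function(model, outputs = NULL, k_max = 10, trials = 5,
                          seed = 1L, unknowns = NULL,
                          generic_input = TRUE) {
  stopifnot(k_max >= 1)
  reports <- list()
  for (k in 0:k_max) {
    rep_k <- local_identifiability(model, outputs, k, trials = trials,
                                   seed = seed, unknowns = unknowns,
                                   generic_input = generic_input)
    reports[[as.character(k)]] <- rep_k
    if (all(rep_k$identifiable))
      return(structure(list(order = k, reports = reports,
                            unidentifiable = character(0)),
                       class = "nmc_minimal_order"))
  }
  last <- reports[[length(reports)]]
  structure(list(order = NA_integer_, reports = reports,
                 unidentifiable = last$quantity[!last$identifiable]),
            class = "nmc_minimal_order")
}

#' @export
print.nmc_minimal_order <- function(x, ...) {
  if (is.na(x$order)) {
    cat("No derivative order up to the scanned maximum identifies all quantities.\n")
    cat("  unidentifiable:", paste(x$unidentifiable, collapse = ", "),
        "\n")
  } else {
    cat(sprintf("All states and parameters locally identifiable from %d output derivatives.\n",
                x$order))
  }
  invisible(x)
}

#' Write an identifiability report as CSV
#'
#' One row per quantity: name, type, the smallest sufficient derivative
#' order observed (or NA) and the final status.
#'
#' @param x an `"nmc_minimal_order"` result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_identifiability_csv <- function(x, path) {
  ords <- as.integer(names(x$reports))
  qty <- x$reports[[1]]$quantity
  first_ok <- vapply(qty, function(q) {
    ok <- vapply(x$reports, function(r)
      r$identifiable[r$quantity == q], logical(1))
    if (any(ok)) ords[which(ok)[1]] else NA_integer_
  }, integer(1))
  last <- x$reports[[length(x$reports)]]
  utils::write.csv(data.frame(
    quantity = qty, type = last$type,
    sufficient_order = first_ok,
    status = ifelse(last$identifiable, "locally identifiable",
                    "unidentifiable")), path, row.names = FALSE)
  invisible(path)
}
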