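#' Define a stimulation paradigm
#'
#' A paradigm is an ordered set of non-overlapping stimulus epochs (on/off
#' times in seconds) over a finite simulation horizon, together with the end
#' of the pre-stimulus baseline period. All model input is a binary step
#' function that is 1 inside an epoch and 0 elsewhere.
#'
#' Zero-length epochs are accepted and act as no-ops; an epoch starting at
#' t = 0 means immediate onset.
#'
#' @param on numeric vector of epoch onset times (seconds).
#' @param off numeric vector of epoch offset times (seconds), same length as
#'   `on`, with `on[i] < off[i] <= horizon` (equality `on == off` is allowed
#'   and gives a zero-length epoch).
#' @param horizon total simulated time (seconds).
#' @param baseline_end time of the last pre-stimulus sample (seconds);
#'   defaults to the first onset (or `horizon` if there are no epochs).
#' @return An object of class `"stimulus_paradigm"`.
#' @examples
#' p <- stimulus_paradigm(on = 396, off = 1188, horizon = 2376)
#' stimulus_input(c(0, 500, 2000), p)
#' @export
stimulus_paradigm <- function(on, off, horizon, baseline_end = NULL) {
  stopifnot(length(on) == length(off), is.numeric(horizon), horizon > 0)
  if (length(on)) {
    ord <- order(on)
    on <- on[ord]; off <- off[ord]
    if (any(off < on)) stop("each epoch needs t_on <= t_off")
    if (any(off > horizon)) stop("epochs must end within the horizon")
    if (any(on < 0)) stop("epochs must start at t >= 0")
    if (length(on) > 1L && any(on[-1L] < off[-length(off)]))
      stop("epochs must not overlap")
  }
  if (is.null(baseline_end))
    baseline_end <- if (length(on)) on[1L] else horizon
  if (length(on) && baseline_end > on[1L])
    stop("baseline_end must not exceed the first epoch onset")
  structure(list(on = as.numeric(on), off = as.numeric(off),
                 horizon = as.numeric(horizon),
                 baseline_end = as.numeric(baseline_end)),
            class = "stimulus_paradigm")
}

#' @export
print.stimulus_paradigm <- function(x, ...) {
  cat(sprintf("Stimulation paradigm: %d epoch(s), horizon %.1f s\n",
              length(x$on), x$horizon))
  if (length(x$on))
    cat(paste(sprintf("  [%g, %g] s", x$on, x$off), collapse = "\n"), "\n")
  invisible(x)
}

#' Evaluate the binary stimulus input
#'
#' Step-function input: 1 when `t` lies within any stimulus epoch (inclusive
#' at both boundaries), 0 otherwise.
#'
#' @param t time(s) in seconds, within `[0, horizon]`.
#' @param paradigm a [stimulus_paradigm()].
#' @return numeric vector of 0/1 values, one per element of `t`.
#' @export
stimulus_input <- function(t, paradigm) {
  stopifnot(inherits(paradigm, "stimulus_paradigm"))
  if (any(t < 0 | t > paradigm$horizon))
    stop("t outside [0, horizon]")
  if (!length(paradigm$on)) return(rep(0, length(t)))
  vapply(t, function(ti)
    as.numeric(any(ti >= paradigm$on & ti <= paradigm$off)), numeric(1))
}

#' Named paradigms of the visual-stimulation study designs
#'
#' Catalog of the block designs emulated by the synthetic-data generator.
#' All block lengths stated in minutes in the source designs are converted
#' to seconds exactly (minutes times 60).
#'
#' * `lin_single`: 6.6 min baseline, 13.2 min stimulus, 19.8 min recovery.
#'   A 13.6 min stimulus variant of the same design is available via
#'   `lin_single_13.6`.
#' * `lin_double`: 9.9 min baseline, then stimulus/rest/stimulus blocks of
#'   9.9 min each, plus 9.9 min recovery.
#' * `witt_bold`: a 0.5 s stimulus at t = 0.1 s, 20 s horizon.
#' * `schaller`: 5 min baseline, 5 min stimulus, 5 min rest, 5 min
#'   stimulus, 5 min recovery (25 min total).
#' * `bednarik`: 5.3 min baseline then stimulus/rest/stimulus/rest blocks
#'   of 5.3 min each.
#' * `lundengard_double`: two 0.5 s stimuli with onsets 4 s apart, 60 s
#'   horizon.
#'
#' @param name one of the catalog names above.
#' @return A [stimulus_paradigm()].
#' @examples
#' make_paradigm("lin_single")
#' @export
make_paradigm <- function(name) {
  m <- 60
  ## block arithmetic in minutes leaves floating-point dust; snap to the
  ## nearest nanosecond so that e.g. 6.6 + 13.2 + 19.8 minutes is 2376 s
  sp <- function(on, off, horizon)
    stimulus_paradigm(round(on, 9), round(off, 9), round(horizon, 9))
  switch(name,
    lin_single = sp(6.6 * m, (6.6 + 13.2) * m, (6.6 + 13.2 + 19.8) * m),
    `lin_single_13.6` = sp(6.6 * m, (6.6 + 13.6) * m,
                           (6.6 + 13.6 + 19.8) * m),
    lin_double = sp(c(9.9, 29.7) * m, c(19.8, 39.6) * m, 49.5 * m),
    witt_bold = sp(0.1, 0.6, 20),
    schaller = sp(c(5, 15) * m, c(10, 20) * m, 25 * m),
    bednarik = sp(c(5.3, 15.9) * m, c(10.6, 21.2) * m, 26.5 * m),
    lundengard_double = sp(c(0.1, 4.1), c(0.6, 4.6), 60),
    stop("unknown paradigm '", name, "'; available: lin_single, ",
         "lin_single_13.6, lin_double, witt_bold, schaller, bednarik, ",
         "lundengard_double")
  )
}
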