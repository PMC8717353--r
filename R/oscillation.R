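# Oscillation detection: classify a trajectory as non-oscillatory, damped
# (shrinking peaks toward a stable spiral), or sustained (peak amplitude
# stabilising above a floor, e.g. a limit cycle or neutral orbit family).

#' Detect oscillations along a trajectory
#'
#' Integrates from `x0`, discards the transient (first half of the horizon),
#' and inspects the sequence of local maxima of `N1`.  Monotonically
#' shrinking peaks combined with complex eigenvalues at the attractor give
#' `"damped"`; a peak amplitude stabilising above the amplitude floor gives
#' `"sustained"` (with an estimated period); anything else is `"none"`.
#'
#' @inheritParams findEquilibria
#' @param x0 initial state.
#' @param t_max integration horizon.
#' @param transient_frac fraction of the horizon discarded as transient.
#' @param amp_floor relative amplitude floor for sustained oscillation.
#' @return list of class `oscillation_report`: `status` (`"none"`,
#'   `"damped"`, `"sustained"`), `period` (for sustained), `n_peaks`,
#'   `terminal_event`.
#' @export
detectOscillation <- function(model, params = list(), x0, t_max = 400,
                              box = NULL, settings = analysisSettings(),
                              transient_frac = 0.5, amp_floor = 1e-3) {
  model <- as_model(model)
  params <- validateParams(model, params)
  if (is.null(box)) box <- defaultBox(model, params)
  tr <- integrateModel(model, params, x0, t_max = t_max, box = box,
                       settings = settings, n_out = 4000)
  res <- list(status = "none", period = NA_real_, n_peaks = 0L,
              terminal_event = tr$terminal_event)
  class(res) <- "oscillation_report"
  if (tr$terminal_event %in% c("extinct", "unbounded", "domain")) return(res)
  s <- tr$series
  s <- s[s$time >= transient_frac * max(s$time), ]
  if (nrow(s) < 10) return(res)
  y <- s$N1
  pk <- which(diff(sign(diff(y))) == -2) + 1L
  # ignore numerically flat ripples
  scale <- max(abs(y), 1e-12)
  if (length(pk) >= 2) {
    amp <- y[pk]
    tt <- s$time[pk]
    trough <- min(y)
    rel_amp <- (amp - trough) / scale
    pk <- pk[rel_amp > 1e-9]
    amp <- y[pk]; tt <- s$time[pk]
  }
  res$n_peaks <- length(pk)
  if (length(pk) < 2) return(res)
  amp_span <- function(v) (max(v) - min(v))
  last_q <- amp[tt >= stats::quantile(tt, 0.5)]
  swing <- (max(y) - min(y)) / scale
  if (swing < amp_floor) return(res)
  shrinking <- all(diff(amp) < 0)
  if (length(last_q) >= 2 &&
      amp_span(last_q) < 0.05 * max(abs(last_q)) &&
      (max(last_q) - min(y)) / scale > amp_floor) {
    res$status <- "sustained"
    res$period <- mean(diff(tt))
    return(res)
  }
  if (shrinking || all(diff(amp) <= 0)) {
    # damped if the attractor is a spiral
    eq <- tryCatch(findEquilibria(model, params, box, settings),
                   error = function(e) NULL)
    spiral <- !is.null(eq) && any(eq$type == "stable_spiral")
    res$status <- if (spiral) "damped" else "none"
    return(res)
  }
  res$status <- "none"
  res
}

#' @export
print.oscillation_report <- function(x, ...) {
  cat("<oscillation_report> ", x$status,
      if (x$status == "sustained") paste0(" (period ~ ",
                                          format(x$period, digits = 4), ")"),
      "; peaks after transient: ", x$n_peaks,
      "; terminal event: ", x$terminal_event, "\n", sep = "")
  invisible(x)
}
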