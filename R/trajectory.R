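# Time integration with ecological event detection.  Uses lsodar (adaptive
# step, automatic stiff switching, root finding) with three terminal events:
# unbounded growth (a density exceeds blowup_factor * L), extinction (a
# density falls below eps_ext with negative per-capita growth at the
# crossing), and convergence (the derivative norm stays small over a
# confirmation window, so slow passages near saddles are not mistaken for
# convergence).

#' Integrate a model trajectory
#'
#' @inheritParams findEquilibria
#' @param x0 initial state `(N1, N2)`.
#' @param t_max integration horizon.
#' @param n_out number of stored output points.
#' @param keep_series if `FALSE` only the endpoints are stored (used by the
#'   basin mapper).
#' @return object of class `trajectory`: list with `series`
#'   (`data.frame(time, N1, N2)`), `terminal_event` (`"converged"`,
#'   `"extinct"`, `"unbounded"`, `"horizon"` or `"domain"`), `event_time`,
#'   `final` state, and `extinct_species` (integer vector, possibly empty).
#' @examples
#' tr <- integrateModel("case_1_1_1",
#'                      list(r1 = 1, r2 = 1, b12 = 0.5, b21 = 0.5),
#'                      x0 = c(0.1, 0.1), t_max = 100)
#' tr$terminal_event
#' @export
integrateModel <- function(model, params = list(), x0, t_max = NULL,
                           box = NULL, settings = analysisSettings(),
                           n_out = 400, keep_series = TRUE) {
  model <- as_model(model)
  params <- validateParams(model, params)
  if (is.null(box)) box <- defaultBox(model, params)
  if (is.null(t_max)) t_max <- settings$t_max
  L <- box[2]
  checkState(model, params, x0)
  blow <- settings$blowup_factor * L
  eps_ext <- settings$eps_ext_frac * L
  ctol <- settings$conv_tol * max(1, L)
  atol <- max(settings$atol_frac * L, 1e-14)

  func <- function(t, y, parms) list(rhsRaw(model, params, pmax(y, 0)))
  rootfunc <- function(t, y, parms) {
    y <- pmax(y, 0)
    d <- rhsRaw(model, params, y)
    c(max(y) - blow, y[1] - eps_ext, y[2] - eps_ext,
      sqrt(sum(d^2)) - ctol)
  }

  runChunk <- function(y0, t0, t1, nout, roots = TRUE) {
    times <- seq(t0, t1, length.out = max(2L, nout))
    out <- tryCatch(suppressWarnings(
      deSolve::lsodar(y = y0, times = times, func = func,
                      rootfunc = if (roots) rootfunc else NULL,
                      rtol = settings$rtol, atol = atol)),
      error = function(e) NULL)
    out
  }

  series <- list(data.frame(time = 0, N1 = x0[1], N2 = x0[2]))
  state <- x0; t0 <- 0
  event <- "horizon"; ext <- integer(0)
  restarts <- 0L
  repeat {
    out <- runChunk(state, t0, t_max, n_out)
    if (is.null(out) || nrow(out) < 2) {
      # integrator failure: overflow counts as unbounded, otherwise a
      # validity-domain exit
      d <- tryCatch(rhsRaw(model, params, pmax(state, 0)),
                    error = function(e) rep(NA_real_, 2))
      event <- if (any(!is.finite(d)) || any(!is.finite(state))) "domain"
               else if (max(state) > 0.5 * blow) "unbounded" else "domain"
      if (event == "domain")
        warning("integration left the validity domain; trajectory truncated")
      break
    }
    dat <- as.data.frame(out)
    names(dat) <- c("time", "N1", "N2")
    if (keep_series) series[[length(series) + 1L]] <- dat[-1, , drop = FALSE]
    tEnd <- dat$time[nrow(dat)]
    state <- pmax(c(dat$N1[nrow(dat)], dat$N2[nrow(dat)]), 0)
    if (any(!is.finite(state))) { event <- "unbounded"; t0 <- tEnd; break }
    rootHit <- !is.null(attr(out, "iroot")) || tEnd < t_max - 1e-9
    if (!rootHit || tEnd >= t_max - 1e-9) { event <- "horizon"; t0 <- tEnd; break }
    t0 <- tEnd
    # which event fired?
    if (max(state) >= blow * (1 - 1e-9)) { event <- "unbounded"; break }
    d <- rhsRaw(model, params, state)
    low <- which(state <= eps_ext * (1 + 1e-6))
    if (length(low)) {
      neg <- low[d[low] < 0]
      if (length(neg)) { ext <- neg; event <- "extinct"; break }
      # benign dip: nudge away from the root and continue
      state[low] <- eps_ext * 1.5
      restarts <- restarts + 1L
      if (restarts > 50L) { event <- "horizon"; break }
      next
    }
    if (sqrt(sum(d^2)) <= ctol * (1 + 1e-6)) {
      # confirmation window: still quiescent after a short continuation?
      win <- runChunk(state, t0, min(t0 + max(5, 0.05 * t_max), t_max), 5,
                      roots = FALSE)
      if (is.null(win)) { event <- "domain"; break }
      wEnd <- pmax(as.numeric(win[nrow(win), 2:3]), 0)
      t0 <- win[nrow(win), 1]
      dw <- rhsRaw(model, params, wEnd)
      state <- wEnd
      if (keep_series) {
        wdat <- as.data.frame(win); names(wdat) <- c("time", "N1", "N2")
        series[[length(series) + 1L]] <- wdat[-1, , drop = FALSE]
      }
      if (sqrt(sum(dw^2)) <= ctol * 2) { event <- "converged"; break }
      restarts <- restarts + 1L
      if (restarts > 50L || t0 >= t_max - 1e-9) { event <- "horizon"; break }
      next
    }
    # root reported but no condition holds (numerical grazing): continue
    restarts <- restarts + 1L
    if (restarts > 50L || t0 >= t_max - 1e-9) { event <- "horizon"; break }
  }
  if (event == "horizon") {
    # classify the endpoint in case no root ever fired (e.g. start already
    # quiescent, or on an invariant axis)
    d <- tryCatch(rhsRaw(model, params, state), error = function(e) NA)
    if (max(state) >= blow) event <- "unbounded"
    else if (all(is.finite(d)) && sqrt(sum(d^2)) <= ctol) event <- "converged"
  }
  ser <- if (keep_series) do.call(rbind, series) else
    data.frame(time = c(0, t0), N1 = c(x0[1], state[1]),
               N2 = c(x0[2], state[2]))
  rownames(ser) <- NULL
  structure(list(series = ser, terminal_event = event, event_time = t0,
                 final = state, extinct_species = ext,
                 model = model$id, box = box),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> model ", x$model, ": ", x$terminal_event,
      " at t = ", format(x$event_time, digits = 4),
      ", final state (", format(x$final[1], digits = 4), ", ",
      format(x$final[2], digits = 4), ")\n", sep = "")
  invisible(x)
}
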