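# Separatrix tracing: the stable manifold of a saddle, obtained by
# integrating backward in time from small offsets along the stable
# eigenvector.  The separatrix divides basins of attraction (e.g. collapse
# from coexistence in threshold regimes).

#' Trace the separatrix through a saddle
#'
#' Offsets the saddle by `+/- sep_delta_frac * L` along the stable
#' eigenvector and integrates the flow in reversed time until the trajectory
#' leaves the box or the horizon is reached.
#'
#' @inheritParams findEquilibria
#' @param saddle one row of an [findEquilibria()] result with
#'   `type == "saddle"`, or a numeric state at a saddle.
#' @param t_max backward-time horizon.
#' @return object of class `separatrix`: list with `saddle`, `branches`
#'   (two `data.frame(N1, N2)` polylines), and `truncation` (per branch:
#'   `"box_exit"`, `"origin"` or `"horizon"`).
#' @export
separatrix <- function(model, params = list(), saddle, box = NULL,
                       t_max = 80, settings = analysisSettings()) {
  model <- as_model(model)
  params <- validateParams(model, params)
  if (is.null(box)) box <- defaultBox(model, params)
  L <- box[2]
  if (is.data.frame(saddle)) {
    if (nrow(saddle) != 1L) stop("'saddle' must be a single equilibrium")
    if (saddle$type != "saddle")
      stop("separatrix requires a saddle; got type '", saddle$type, "'")
    sp <- c(saddle$N1, saddle$N2)
  } else {
    sp <- as.numeric(saddle)
    J0 <- evalJacobian(model, params, sp)
    ev0 <- eigen(J0, only.values = TRUE)$values
    if (classifyEigenvalues(ev0, settings$tol_hyp) != "saddle")
      stop("separatrix requires a saddle equilibrium")
  }
  J <- evalJacobian(model, params, sp)
  ed <- eigen(J)
  stable_idx <- which(Re(ed$values) < 0)
  if (length(stable_idx) != 1L)
    stop("separatrix requires a saddle equilibrium")
  v <- Re(ed$vectors[, stable_idx])
  v <- v / sqrt(sum(v^2))
  delta <- settings$sep_delta_frac * L

  back <- function(t, y, parms) list(-rhsRaw(model, params, pmax(y, 0)))
  traceBranch <- function(dir) {
    y0 <- sp + dir * delta * v
    y0 <- pmax(y0, 0)
    times <- seq(0, t_max, length.out = 2000)
    rootf <- function(t, y, parms)
      c(min(y) + 1e-12, box[2] - max(y))  # leave quadrant or leave box
    out <- tryCatch(suppressWarnings(
      deSolve::lsodar(y = y0, times = times, func = back, rootfunc = rootf,
                      rtol = settings$rtol,
                      atol = max(settings$atol_frac * L, 1e-14))),
      error = function(e) NULL)
    if (is.null(out) || nrow(out) < 2)
      return(list(poly = data.frame(N1 = y0[1], N2 = y0[2]),
                  why = "horizon"))
    d <- as.data.frame(out); names(d) <- c("time", "N1", "N2")
    inside <- d$N1 >= -1e-9 & d$N2 >= -1e-9 & d$N1 <= L & d$N2 <= L
    cut <- if (all(inside)) nrow(d) else max(1L, which(!inside)[1] - 1L)
    poly <- d[seq_len(cut), c("N1", "N2")]
    endt <- d$time[nrow(d)]
    final <- as.numeric(d[nrow(d), c("N1", "N2")])
    why <- if (endt >= t_max - 1e-9) "horizon"
      else if (max(final) > L * (1 - 1e-6)) "box_exit"
      else if (sqrt(sum(final^2)) < 1e-3 * L) "origin"
      else "box_exit"
    list(poly = poly, why = why)
  }
  b1 <- traceBranch(+1); b2 <- traceBranch(-1)
  structure(list(saddle = sp,
                 branches = list(b1$poly, b2$poly),
                 truncation = c(b1$why, b2$why),
                 eigenvector = v, box = box, model = model$id),
            class = "separatrix")
}

#' Consistency of a separatrix with a basin map
#'
#' Samples probe pairs straddling the separatrix polyline and checks that
#' opposite sides carry different basin labels.
#'
#' @param sep a [separatrix()] object.
#' @param bm a [basinMap()] for the same model and parameters.
#' @param n_probes number of probe pairs.
#' @return fraction of probes whose two sides carry different labels.
#' @export
separatrixConsistency <- function(sep, bm, n_probes = 20) {
  poly <- do.call(rbind, sep$branches)
  poly <- poly[poly$N1 > 0 & poly$N2 > 0, ]
  if (nrow(poly) < 3) return(NA_real_)
  idx <- unique(round(seq(2, nrow(poly) - 1, length.out = n_probes)))
  L <- sep$box[2]
  # nearest-cell basin lookup
  lookupLabel <- function(pt) {
    d2 <- (bm$grid$N1_0 - pt[1])^2 + (bm$grid$N2_0 - pt[2])^2
    bm$grid$label[which.min(d2)]
  }
  agree <- 0; used <- 0
  for (i in idx) {
    tang <- as.numeric(poly[min(i + 1, nrow(poly)), ]) -
      as.numeric(poly[max(i - 1, 1), ])
    nt <- sqrt(sum(tang^2)); if (nt == 0) next
    nrm <- c(-tang[2], tang[1]) / nt
    off <- 0.08 * L
    a <- as.numeric(poly[i, ]) + off * nrm
    b <- as.numeric(poly[i, ]) - off * nrm
    if (any(a < 0) || any(b < 0) || any(a > L) || any(b > L)) next
    la <- lookupLabel(a); lb <- lookupLabel(b)
    used <- used + 1
    if (la != lb) agree <- agree + 1
  }
  if (used == 0) return(NA_real_)
  agree / used
}

#' @export
print.separatrix <- function(x, ...) {
  cat("<separatrix> model ", x$model, ", saddle (",
      format(x$saddle[1], digits = 4), ", ", format(x$saddle[2], digits = 4),
      "); branches truncated by: ", paste(x$truncation, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
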