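# Nullcline extraction and geometry summaries.  Nontrivial nullclines are the
# zero contours of the per-capita growth functions g_i (dNi/dt = Ni * g_i);
# the axes are the trivial nullclines of axis-invariant models.

#' Extract nullclines of a model in a box
#'
#' Nontrivial curves are extracted as zero contours of the per-capita growth
#' of each species on a regular grid (via [grDevices::contourLines()]);
#' invalid regions of the state space are masked, clipping curves with a
#' warning flag.  Each curve carries a geometry summary
#' (`increasing`/`decreasing`/`non-monotonic` and
#' `linear`/`concave_up`/`concave_down`/`lobe`) computed from finite-
#' difference slope and curvature signs along the polyline with a 95%
#' sign-consistency vote.
#'
#' @inheritParams findEquilibria
#' @param resolution per-axis grid resolution (minimum 50).
#' @return list of class `nullcline_set`: per species a list of polylines
#'   (`data.frame(N1, N2)`) with attributes `kind` (`"trivial"`/
#'   `"nontrivial"`) and `geometry` (`c(monotonicity, shape)`), plus the
#'   clipping flag.
#' @examples
#' nc <- nullclines("case_1_1_1", list(r1 = 1, r2 = 1, b12 = 0.5, b21 = 0.5),
#'                  box = c(0, 5), resolution = 101)
#' attr(nc$N1[[1]], "geometry")
#' @export
nullclines <- function(model, params = list(), box = NULL, resolution = NULL,
                       settings = analysisSettings()) {
  model <- as_model(model)
  params <- validateParams(model, params)
  if (is.null(box)) box <- defaultBox(model, params)
  if (is.null(resolution)) resolution <- settings$nullcline_res
  stopifnot(resolution >= 50)
  L <- box[2]
  xs <- seq(box[1], L, length.out = resolution)
  interiorF <- interiorField(model, params)
  clipped <- FALSE
  out <- list()
  ai <- model$axis_invariant(params)
  for (i in 1:2) {
    f <- if (i == 1) interiorF$f1 else interiorF$f2
    Z <- outer(xs, xs, f)
    if (any(is.na(Z))) clipped <- TRUE
    curves <- grDevices::contourLines(xs, xs, Z, levels = 0)
    polys <- lapply(curves, function(cv) {
      d <- data.frame(N1 = cv$x, N2 = cv$y)
      attr(d, "kind") <- "nontrivial"
      attr(d, "geometry") <- curveGeometry(d)
      d
    })
    if (ai[i]) {
      axis_poly <- if (i == 1)
        data.frame(N1 = c(0, 0), N2 = c(box[1], L))
      else data.frame(N1 = c(box[1], L), N2 = c(0, 0))
      attr(axis_poly, "kind") <- "trivial"
      attr(axis_poly, "geometry") <- c("n/a", "axis")
      polys <- c(list(axis_poly), polys)
    }
    out[[model$species[i]]] <- polys
  }
  if (clipped)
    warning("validity-domain violation inside box; nullclines clipped to the valid region")
  names(out) <- c("N1", "N2")
  structure(list(N1 = out[[1]], N2 = out[[2]], box = box,
                 model = model$id, clipped = clipped),
            class = "nullcline_set")
}

# geometry of a polyline: monotonicity of N2 along N1 and curvature class,
# by sign votes along the curve (>= 95% consistency required for a label)
curveGeometry <- function(d, vote = 0.95) {
  if (nrow(d) < 5) return(c("non-monotonic", "lobe"))
  dx <- diff(d$N1); dy <- diff(d$N2)
  seg <- sqrt(dx^2 + dy^2)
  use <- seg > 0
  dx <- dx[use]; dy <- dy[use]
  if (!length(dx)) return(c("non-monotonic", "lobe"))
  closed <- sqrt(sum((d[1, ] - d[nrow(d), ])^2)) < 1e-8 * sum(seg)
  fx <- mean(sign(dx) == sign(dx[which.max(abs(dx))]))
  xr <- max(d$N1) - min(d$N1)
  yr0 <- max(d$N2) - min(d$N2)
  if (xr < 1e-9 * max(yr0, 1)) return(c("n/a", "linear"))     # vertical line
  if (yr0 < 1e-9 * max(xr, 1)) return(c("n/a", "linear"))     # horizontal line
  # back-bending or closed curve: N1 not a monotone coordinate along the curve
  if (closed || (xr > 0 && fx < vote && mean(abs(dx)) > 1e-10 * xr) || xr == 0) {
    if (closed || fx < vote) return(c("non-monotonic", "lobe"))
  }
  slope <- dy / dx
  up <- mean(slope > 0); down <- mean(slope < 0)
  mono <- if (up >= vote) "increasing" else if (down >= vote) "decreasing"
          else "non-monotonic"
  # shape from least-squares fits: contour polylines carry jitter at the
  # grid scale, so pointwise second differences are pure noise; global
  # linear and quadratic fits average the jitter out
  o <- order(d$N1)
  x <- d$N1[o]; y <- d$N2[o]
  keep <- c(TRUE, diff(x) > 1e-12)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 5) return(c(mono, "linear"))
  yr <- max(max(y) - min(y), xr)
  fit1 <- stats::lm(y ~ x)
  r1 <- sqrt(mean(stats::residuals(fit1)^2))
  if (r1 < 2e-3 * max(yr, 1)) return(c(mono, "linear"))
  fit2 <- stats::lm(y ~ x + I(x^2))
  r2 <- sqrt(mean(stats::residuals(fit2)^2))
  # single-signed curvature is captured by the quadratic term; an
  # S-shaped or otherwise mixed-curvature curve is not
  if (r2 < 0.5 * r1) {
    co <- stats::coef(fit2)[[3]]
    return(c(mono, if (co > 0) "concave_up" else "concave_down"))
  }
  c(mono, "lobe")
}

#' @export
print.nullcline_set <- function(x, ...) {
  cat("<nullcline_set> model ", x$model, ", box [0, ",
      format(x$box[2], digits = 4), "]^2\n", sep = "")
  for (sp in c("N1", "N2")) {
    for (k in seq_along(x[[sp]])) {
      g <- attr(x[[sp]][[k]], "geometry")
      cat("  ", sp, " curve ", k, " (", attr(x[[sp]][[k]], "kind"), "): ",
          paste(g, collapse = ", "), " [", nrow(x[[sp]][[k]]), " pts]\n",
          sep = "")
    }
  }
  invisible(x)
}
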