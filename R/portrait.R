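# Phase-portrait rendering: vector field (arrow angle = direction, color =
# magnitude), nullclines, equilibrium markers (filled black = stable, filled
# red = unstable, hollow = saddle), dashed red separatrices.

#' Portrait style settings
#'
#' The equilibrium marker convention (filled black = stable, filled red =
#' unstable, hollow = saddle) and the dashed separatrix style are fixed;
#' only field density and colors of the auxiliary elements are adjustable.
#'
#' @param arrow_n arrows per axis of the vector field.
#' @param field_palette function `n -> colors`, magnitude ramp from weak to
#'   strong flow.
#' @param nullcline_cols length-2 colors for the N1 and N2 nullclines.
#' @return list of class `portrait_style`.
#' @export
portraitStyle <- function(arrow_n = 15,
                          field_palette = function(n)
                            grDevices::hcl.colors(n, "Blues 3", rev = TRUE),
                          nullcline_cols = c("darkgreen", "darkorange3")) {
  stopifnot(arrow_n >= 4, length(nullcline_cols) == 2)
  structure(list(arrow_n = arrow_n, field_palette = field_palette,
                 nullcline_cols = nullcline_cols,
                 # fixed conventions
                 stable_col = "black", unstable_col = "red2",
                 separatrix_col = "red", separatrix_lty = 2),
            class = "portrait_style")
}

#' Render a phase portrait
#'
#' Draws the vector field (arrow angle gives the direction of change,
#' arrow color its magnitude), both species' nullclines, equilibrium
#' markers (filled black = stable, filled red = unstable, hollow = saddle),
#' and dashed separatrices through every interior saddle.  With `file`
#' given, writes an SVG or PNG (chosen by extension) and returns the path;
#' otherwise draws on the active device.
#'
#' @inheritParams findEquilibria
#' @param file optional output path ending in `.svg` or `.png`.
#' @param style a [portraitStyle()].
#' @param equilibria optional precomputed [findEquilibria()] result.
#' @param draw_separatrix draw stable manifolds through interior saddles.
#' @param main plot title (defaults to the model id).
#' @return the output path (invisibly `NULL` when drawing on screen).
#' @examples
#' \donttest{
#' f <- tempfile(fileext = ".svg")
#' renderPortrait("case_1_1_1", canonicalParams("case_1_1_1", "SC"),
#'                box = c(0, 5), file = f)
#' }
#' @export
renderPortrait <- function(model, params = list(), box = NULL, file = NULL,
                           style = portraitStyle(),
                           settings = analysisSettings(), equilibria = NULL,
                           draw_separatrix = TRUE, main = NULL) {
  model <- as_model(model)
  params <- validateParams(model, params)
  if (is.null(box)) box <- defaultBox(model, params)
  if (diff(box) <= 0) stop("box has zero or negative area", call. = FALSE)
  L <- box[2]
  if (is.null(equilibria))
    equilibria <- findEquilibria(model, params, box, settings)
  nc <- nullclines(model, params, box, settings = settings)

  dev_open <- FALSE
  if (!is.null(file)) {
    ext <- tolower(tools::file_ext(file))
    if (ext == "svg") grDevices::svg(file, width = 7, height = 7)
    else if (ext == "png") grDevices::png(file, width = 900, height = 900,
                                          res = 130)
    else stop("unsupported figure format '.", ext, "' (use .svg or .png)",
              call. = FALSE)
    dev_open <- TRUE
    on.exit(grDevices::dev.off(), add = TRUE)
  }

  graphics::plot(NA, xlim = box, ylim = box, xlab = expression(N[1]),
                 ylab = expression(N[2]), asp = 1,
                 main = if (is.null(main)) model$id else main)

  # vector field
  n <- style$arrow_n
  xs <- seq(box[1] + L / (2 * n), L - L / (2 * n), length.out = n)
  g <- expand.grid(x = xs, y = xs)
  vel <- t(apply(g, 1, function(r) {
    v <- tryCatch(rhsRaw(model, params, c(r[[1]], r[[2]])),
                  error = function(e) c(NA_real_, NA_real_))
    v
  }))
  mag <- sqrt(rowSums(vel^2))
  ok <- is.finite(mag) & mag > 0
  if (any(ok)) {
    cols <- style$field_palette(64)
    q <- pmin(mag[ok] / stats::quantile(mag[ok], 0.95, na.rm = TRUE), 1)
    ci <- pmax(1L, ceiling(q * 64))
    len <- 0.8 * L / n
    ux <- vel[ok, 1] / mag[ok] * len / 2
    uy <- vel[ok, 2] / mag[ok] * len / 2
    suppressWarnings(graphics::arrows(
      g$x[ok] - ux, g$y[ok] - uy, g$x[ok] + ux, g$y[ok] + uy,
      length = 0.04, col = cols[ci]))
  }

  # nullclines
  for (sp in 1:2) {
    for (curve in nc[[c("N1", "N2")[sp]]]) {
      graphics::lines(curve$N1, curve$N2, lwd = 2,
                      col = style$nullcline_cols[sp])
    }
  }

  # separatrices through interior saddles
  if (draw_separatrix) {
    sad <- equilibria[equilibria$type == "saddle" &
                        equilibria$class == "interior", , drop = FALSE]
    for (k in seq_len(nrow(sad))) {
      sep <- tryCatch(
        separatrix(model, params, sad[k, , drop = FALSE], box, settings = settings),
        error = function(e) NULL)
      if (is.null(sep)) next
      for (br in sep$branches)
        graphics::lines(br$N1, br$N2, col = style$separatrix_col,
                        lty = style$separatrix_lty, lwd = 1.6)
    }
  }

  # equilibrium markers: filled black = stable, filled red = unstable,
  # hollow = saddle
  for (k in seq_len(nrow(equilibria))) {
    ty <- equilibria$type[k]
    if (ty == "saddle") {
      graphics::points(equilibria$N1[k], equilibria$N2[k], pch = 21,
                       bg = "white", col = "black", cex = 1.6, lwd = 1.6)
    } else if (grepl("^stable", ty)) {
      graphics::points(equilibria$N1[k], equilibria$N2[k], pch = 21,
                       bg = style$stable_col, col = style$stable_col,
                       cex = 1.6)
    } else {
      graphics::points(equilibria$N1[k], equilibria$N2[k], pch = 21,
                       bg = style$unstable_col, col = style$unstable_col,
                       cex = 1.6)
    }
  }

  invisible(if (dev_open) file else NULL)
}
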