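# Basin-of-attraction mapping: integrate a grid of initial conditions to
# their terminal events and label each cell by the attractor (equilibrium or
# recurrent cycle) it reaches, or by extinction / unbounded growth / horizon.

#' Map basins of attraction over a grid of initial conditions
#'
#' Each grid cell is integrated to its terminal event.  Converged endpoints
#' are matched to known equilibria within `match_frac * L`; bounded orbits
#' that neither converge nor collapse but revisit their neighbourhood are
#' registered as cycle attractors.
#'
#' @inheritParams findEquilibria
#' @param grid_n per-axis grid resolution (inclusive endpoints, origin at
#'   `(0, 0)`, row-major).
#' @param t_max integration horizon per cell.
#' @param equilibria optional precomputed [findEquilibria()] result.
#' @param low_refine number of extra geometric low-density levels
#'   (`L/4, L/8, ...`) added to each axis of the grid.
#' @return object of class `basin_map`: list with `grid`
#'   (`data.frame(N1_0, N2_0, label)`), `attractors` (named list of states),
#'   `counts` (label table), `grid_n`, `t_max`, `box`.
#' @examples
#' bm <- basinMap("case_1_1_1", list(r1 = 1, r2 = 1, b12 = 0.5, b21 = 0.5),
#'                box = c(0, 5), grid_n = 11, t_max = 100)
#' bm$counts
#' @export
basinMap <- function(model, params = list(), box = NULL, grid_n = NULL,
                     t_max = NULL, settings = analysisSettings(),
                     equilibria = NULL, low_refine = 6) {
  model <- as_model(model)
  params <- validateParams(model, params)
  if (is.null(box)) box <- defaultBox(model, params)
  if (is.null(grid_n)) grid_n <- settings$basin_n
  if (is.null(t_max)) t_max <- settings$t_max
  stopifnot(grid_n >= 11)
  L <- box[2]
  if (is.null(equilibria))
    equilibria <- findEquilibria(model, params, box, settings)
  attractors <- list()
  for (k in seq_len(nrow(equilibria))) {
    nm <- paste0("eq_", equilibria$class[k], "_", k)
    attractors[[nm]] <- c(equilibria$N1[k], equilibria$N2[k])
  }
  eq_mat <- do.call(rbind, attractors)
  match_r <- settings$match_frac * L

  xs <- seq(box[1], L, length.out = grid_n)
  # geometric refinement near the origin so that small collapse basins
  # below a low-lying saddle are sampled regardless of grid resolution
  xs <- sort(unique(c(xs, L * 0.5^seq(2, 2 + low_refine - 1))))
  grid <- expand.grid(N2_0 = xs, N1_0 = xs)[, c("N1_0", "N2_0")]
  labels <- character(nrow(grid))
  cycles <- list()
  extras <- list()
  for (k in seq_len(nrow(grid))) {
    x0 <- c(grid$N1_0[k], grid$N2_0[k])
    tr <- tryCatch(
      integrateModel(model, params, x0, t_max = t_max, box = box,
                     settings = settings, keep_series = FALSE),
      error = function(e) NULL)
    if (is.null(tr)) { labels[k] <- "domain"; next }
    labels[k] <- switch(tr$terminal_event,
      unbounded = "unbounded",
      extinct = "extinct",
      domain = "domain",
      converged = {
        dists <- if (!is.null(eq_mat) && nrow(eq_mat))
          sqrt(rowSums((eq_mat -
            matrix(tr$final, nrow(eq_mat), 2, byrow = TRUE))^2))
        else numeric(0)
        if (length(dists) && min(dists) <= match_r)
          rownames(eq_mat)[which.min(dists)]
        else if (min(tr$final) < 1e-3 * L)
          # quiescent endpoint on/near an axis with no matching registered
          # equilibrium (e.g. decay toward a singular origin): extinction
          "extinct"
        else matchCycle(extras, tr$final, match_r, prefix = "eq_extra_",
                        register = function(st) {
                          extras[[length(extras) + 1L]] <<- st
                          length(extras)
                        })
      },
      horizon = {
        # bounded, non-convergent orbit: recurrence check for a cycle
        rec <- recurrentOrbit(model, params, tr$final, box, settings)
        if (rec) matchCycle(cycles, tr$final, 0.05 * L, prefix = "cycle_",
                            register = function(st) {
                              cycles[[length(cycles) + 1L]] <<- st
                              length(cycles)
                            })
        else "horizon"
      })
  }
  for (j in seq_along(cycles))
    attractors[[paste0("cycle_", j)]] <- cycles[[j]]
  for (j in seq_along(extras))
    attractors[[paste0("eq_extra_", j)]] <- extras[[j]]
  grid$label <- labels
  counts <- table(labels)
  structure(list(grid = grid, attractors = attractors,
                 counts = counts, grid_n = grid_n, t_max = t_max,
                 box = box, model = model$id),
            class = "basin_map")
}

# label an endpoint as an existing or newly registered extra attractor
matchCycle <- function(cycles, state, radius, register, prefix = "cycle_") {
  for (j in seq_along(cycles)) {
    if (sqrt(sum((cycles[[j]] - state)^2)) <= radius)
      return(paste0(prefix, j))
  }
  paste0(prefix, register(state))
}

# Poincare-style recurrence: does the orbit return within 1e-3 * L of a
# sampled point while remaining bounded?
recurrentOrbit <- function(model, params, x0, box, settings,
                           t_probe = 60, n_out = 600) {
  L <- box[2]
  tr <- tryCatch(
    integrateModel(model, params, pmax(x0, 0), t_max = t_probe, box = box,
                   settings = settings, n_out = n_out, keep_series = TRUE),
    error = function(e) NULL)
  if (is.null(tr) || tr$terminal_event %in% c("unbounded", "extinct", "domain"))
    return(FALSE)
  s <- tr$series
  if (nrow(s) < 50) return(FALSE)
  ref <- as.numeric(s[round(nrow(s) * 0.25), c("N1", "N2")])
  later <- s[s$time > s$time[round(nrow(s) * 0.35)], c("N1", "N2")]
  d <- sqrt((later$N1 - ref[1])^2 + (later$N2 - ref[2])^2)
  # require the orbit to both leave and re-enter the neighbourhood
  far <- max(d) > 1e-2 * L
  near <- min(d) < 1e-3 * L
  far && near
}

#' @export
print.basin_map <- function(x, ...) {
  cat("<basin_map> model ", x$model, ", ", x$grid_n, "x", x$grid_n,
      " grid over [0, ", format(x$box[2], digits = 4), "]^2, t_max = ",
      x$t_max, "\n", sep = "")
  print(x$counts)
  invisible(x)
}
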