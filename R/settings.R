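#' Analysis settings
#'
#' Numerical tolerances and grid sizes used across the phase-plane machinery.
#' All length scales are expressed as fractions of the analysis box side
#' \eqn{L}, so a single settings object is meaningful across models.
#'
#' @param grid_equilibria per-axis resolution of the sign-change grid used to
#'   seed interior equilibrium candidates.
#' @param nullcline_res per-axis resolution of the nullcline contour grid
#'   (minimum 50).
#' @param basin_n per-axis resolution of the basin-of-attraction grid.
#' @param t_max integration horizon for trajectories and basin cells.
#' @param newton_tol relative Newton residual tolerance for equilibrium
#'   polishing.
#' @param dedupe_frac equilibria closer than `dedupe_frac * L` are merged.
#' @param tol_hyp hyperbolicity tolerance: an eigenvalue with
#'   `|Re| < tol_hyp * max(1, |lambda|)` is treated as nonhyperbolic.
#' @param blowup_factor a trajectory is labelled unbounded once any density
#'   exceeds `blowup_factor * L` (finite-time surrogate for divergence).
#' @param eps_ext_frac extinction threshold as a fraction of `L`; extinction
#'   additionally requires negative per-capita growth at the crossing.
#' @param conv_tol derivative norm under which a trajectory is considered
#'   converged (scaled by `max(1, L)`).
#' @param match_frac converged endpoints are matched to known equilibria
#'   within `match_frac * L`.
#' @param sep_delta_frac separatrix seeding offset along the stable
#'   eigenvector, as a fraction of `L`.
#' @param rtol,atol_frac integrator tolerances (`atol = atol_frac * L`).
#' @return a list with class `mutdyn_settings`.
#' @export
analysisSettings <- function(grid_equilibria = 64,
                             nullcline_res = 301,
                             basin_n = 41,
                             t_max = 200,
                             newton_tol = 1e-10,
                             dedupe_frac = 1e-5,
                             tol_hyp = 1e-6,
                             blowup_factor = 1e3,
                             eps_ext_frac = 1e-6,
                             conv_tol = 1e-6,
                             match_frac = 0.02,
                             sep_delta_frac = 1e-6,
                             rtol = 1e-8,
                             atol_frac = 1e-10) {
  stopifnot(nullcline_res >= 50, basin_n >= 11, grid_equilibria >= 8)
  structure(list(grid_equilibria = grid_equilibria,
                 nullcline_res = nullcline_res, basin_n = basin_n,
                 t_max = t_max, newton_tol = newton_tol,
                 dedupe_frac = dedupe_frac, tol_hyp = tol_hyp,
                 blowup_factor = blowup_factor, eps_ext_frac = eps_ext_frac,
                 conv_tol = conv_tol, match_frac = match_frac,
                 sep_delta_frac = sep_delta_frac, rtol = rtol,
                 atol_frac = atol_frac),
            class = "mutdyn_settings")
}

#' Default analysis box for a model
#'
#' The box is \eqn{[0, L]^2} with
#' `L = 10 * max(single-species equilibria, half-saturation constants, 1)`:
#' per-capita benefits in the saturating models are bounded, so all finite
#' equilibria fall well inside.
#'
#' @inheritParams evalRhs
#' @return numeric length-2 vector `c(0, L)` giving the per-axis range.
#' @export
defaultBox <- function(model, params = list()) {
  model <- as_model(model)
  params <- validateParams(model, params)
  K <- c(singleSpeciesEquilibrium(model, params, 1),
         singleSpeciesEquilibrium(model, params, 2))
  sat <- grep("^(h[0-9]*|e[12]|D|d)$", model$schema$name, value = TRUE)
  satv <- if (length(sat)) unlist(params[sat]) else 0
  L <- 10 * max(c(1, K, satv))
  c(0, L)
}
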