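# Qualitative outcome classification: map (model, parameters) to the
# outcome taxonomy (stable coexistence, unbounded growth, extinction,
# threshold regimes, multi-attractor), the threshold-type vocabulary
# (partner threshold / own-density Allee / overexploitation), the
# mutualistic-vs-parasitic character of coexistence, and the critical
# benefit strength separating regimes.

.outcome_labels <- c("SC", "UC", "E", "UC/E threshold", "SC/E threshold",
                     "HD SC & SC/E threshold", "HD UC & UC/SC threshold",
                     "multi-attractor")

# Map a basin label (attractor name from basinMap) to an outcome category.
# "coexist": interior equilibrium or cycle; "extinction": origin or axis
# equilibrium, or an extinction event; "unbounded"; "horizon"; "domain".
.basinCategory <- function(lbl, equilibria) {
  if (lbl %in% c("unbounded", "extinct", "horizon", "domain")) {
    return(switch(lbl, extinct = "extinction", lbl))
  }
  if (startsWith(lbl, "cycle_")) return("coexist")
  if (startsWith(lbl, "eq_extra_")) return("coexist")
  if (startsWith(lbl, "eq_")) {
    k <- as.integer(sub(".*_", "", lbl))
    cl <- equilibria$class[k]
    if (cl != "interior") return("extinction")
    # a cell can hit an interior saddle only by starting on its stable
    # manifold (a measure-zero separatrix): indeterminate, not an attractor
    ty <- equilibria$type[k]
    return(if (grepl("^stable", ty)) "coexist" else "horizon")
  }
  "horizon"
}

#' Classify the qualitative dynamics of a parameterized model
#'
#' Runs the full pipeline: equilibria with stability types, basin map over a
#' grid of initial conditions, and synthesis of the outcome label from the
#' basin structure.  The label vocabulary is `"SC"` (stable coexistence),
#' `"UC"` (unbounded growth), `"E"` (extinction), the threshold regimes
#' `"UC/E threshold"`, `"SC/E threshold"`, `"HD SC & SC/E threshold"`,
#' `"HD UC & UC/SC threshold"` (`HD` = high density), and
#' `"multi-attractor"` (two or more distinct coexistence attractors).
#'
#' Synthesis rules, applied over the interior initial-condition cells:
#' two or more coexistence attractors give `"multi-attractor"`;
#' coexistence plus an unbounded basin gives `"HD UC & UC/SC threshold"`;
#' coexistence plus an extinction basin gives `"SC/E threshold"`, upgraded
#' to `"HD SC & SC/E threshold"` when the attractor lies componentwise
#' above both single-species equilibria; coexistence alone is `"SC"`;
#' unbounded plus extinction is `"UC/E threshold"`; unbounded alone is
#' `"UC"`; extinction alone is `"E"`.
#'
#' @inheritParams findEquilibria
#' @param grid_n basin grid resolution (default `settings$basin_n`).
#' @param t_max basin integration horizon (default `settings$t_max`).
#' @param equilibria optional precomputed [findEquilibria()] result.
#' @param basin optional precomputed [basinMap()] result.
#' @param probe_thresholds if `FALSE`, skip the threshold-type probes
#'   (`threshold_type` is then `NA`); used by sweeps for speed.
#' @param detect_oscillation if `FALSE`, skip oscillation detection.
#' @return object of class `outcome_report`: list with `outcome_label`,
#'   `threshold_type`, `coexistence_character` (`"mutualistic"`,
#'   `"parasitic"` or `"n/a"`), `oscillation`, `low_confidence` (`TRUE`
#'   when more than 10% of basin cells hit the horizon), and `evidence`
#'   (equilibria table, basin fractions, attractor states, probe outcomes).
#' @examples
#' rep <- classifyDynamics("case_1_1_1",
#'                         list(r1 = 1, r2 = 1, b12 = 0.5, b21 = 0.5),
#'                         grid_n = 11)
#' rep$outcome_label
#' @export
classifyDynamics <- function(model, params = list(), box = NULL,
                             settings = analysisSettings(), grid_n = NULL,
                             t_max = NULL, equilibria = NULL, basin = NULL,
                             probe_thresholds = TRUE,
                             detect_oscillation = TRUE) {
  model <- as_model(model)
  params <- validateParams(model, params)
  user_box <- box
  if (is.null(box)) box <- defaultBox(model, params)
  if (is.null(grid_n)) grid_n <- settings$basin_n
  if (is.null(t_max)) t_max <- settings$t_max
  L <- box[2]
  if (is.null(equilibria))
    equilibria <- findEquilibria(model, params, box, settings)
  if (is.null(basin)) {
    # scale the sampling grid to the equilibrium structure so that basins
    # below a low-lying saddle are actually sampled
    if (is.null(user_box)) {
      S <- suppressWarnings(max(c(equilibria$N1, equilibria$N2, 0),
                                na.rm = TRUE))
      bb <- c(0, min(L, max(3 * S, 0.1 * L)))
    } else bb <- box
    basin <- basinMap(model, params, bb, grid_n = grid_n, t_max = t_max,
                      settings = settings, equilibria = equilibria)
  }

  g <- basin$grid
  interior_ic <- g$N1_0 > 0 & g$N2_0 > 0
  lbl <- g$label[interior_ic]
  n_cells <- length(lbl)
  cat_of <- vapply(lbl, .basinCategory, character(1),
                   equilibria = equilibria, USE.NAMES = FALSE)
  frac <- function(cc) sum(cat_of == cc) / n_cells
  fr <- c(coexist = frac("coexist"), extinction = frac("extinction"),
          unbounded = frac("unbounded"),
          horizon = frac("horizon") + frac("domain"))
  low_confidence <- fr[["horizon"]] > 0.10

  # distinct coexistence attractors actually reached
  coexist_lbls <- unique(lbl[cat_of == "coexist"])
  coexist_states <- lapply(coexist_lbls, function(nm) basin$attractors[[nm]])
  names(coexist_states) <- coexist_lbls
  has_coexist <- fr[["coexist"]] > 0
  has_unb <- fr[["unbounded"]] > 0
  has_ext <- fr[["extinction"]] > 0

  k_alone <- c(singleSpeciesEquilibrium(model, params, 1),
               singleSpeciesEquilibrium(model, params, 2))
  k_alone[is.na(k_alone)] <- 0

  outcome_label <-
    if (length(coexist_lbls) >= 2) "multi-attractor"
    else if (has_coexist && has_unb) "HD UC & UC/SC threshold"
    else if (has_coexist && has_ext) {
      st <- coexist_states[[1]]
      if (all(st > k_alone + 1e-9)) "HD SC & SC/E threshold"
      else "SC/E threshold"
    }
    else if (has_coexist) "SC"
    else if (has_unb && has_ext) "UC/E threshold"
    else if (has_unb) "UC"
    else if (has_ext) "E"
    else "E"  # horizon-only: fall back, flagged low-confidence

  # coexistence character for a single interior-equilibrium attractor
  coexistence_character <- "n/a"
  if (length(coexist_lbls) == 1 && startsWith(coexist_lbls[1], "eq_")) {
    coexistence_character <- tryCatch(
      coexistenceCharacter(model, params, coexist_states[[1]],
                           k_alone = k_alone)$character,
      error = function(e) "n/a")
  }

  # oscillation: probe from a coexistence-basin cell if one exists
  oscillation <- "none"
  if (detect_oscillation && (has_coexist || fr[["horizon"]] > 0)) {
    pick <- which(interior_ic)[which(cat_of %in% c("coexist", "horizon"))[1]]
    x0 <- if (is.na(pick)) c(0.3 * L, 0.3 * L) else
      c(g$N1_0[pick], g$N2_0[pick])
    osc <- tryCatch(
      detectOscillation(model, params, x0 = x0, box = box,
                        t_max = max(400, 2 * t_max), settings = settings),
      error = function(e) NULL)
    if (!is.null(osc)) oscillation <- osc$status
  }

  report <- structure(list(
    outcome_label = outcome_label,
    threshold_type = NA_character_,
    coexistence_character = coexistence_character,
    oscillation = oscillation,
    low_confidence = low_confidence,
    evidence = list(
      equilibria = equilibria,
      basin_fractions = fr,
      basin_counts = basin$counts,
      coexistence_attractors = coexist_states,
      k_alone = k_alone,
      saddle_present = any(equilibria$type == "saddle"),
      probes = NULL),
    model = model$id, params = params, box = box,
    grid_n = basin$grid_n, t_max = basin$t_max), class = "outcome_report")

  report$threshold_type <- if (probe_thresholds) {
    tt <- thresholdType(model, params, report, box = basin$box,
                        settings = settings)
    report$evidence$probes <- tt$evidence
    tt$type
  } else NA_character_
  report
}

#' @export
print.outcome_report <- function(x, ...) {
  cat("<outcome_report> model ", x$model, "\n",
      "  outcome:     ", x$outcome_label,
      if (isTRUE(x$low_confidence)) "  [low confidence]", "\n",
      "  threshold:   ", x$threshold_type, "\n",
      "  coexistence: ", x$coexistence_character, "\n",
      "  oscillation: ", x$oscillation, "\n", sep = "")
  fr <- x$evidence$basin_fractions
  cat("  basins: ", paste(sprintf("%s %.2f", names(fr), fr),
                          collapse = ", "), "\n", sep = "")
  invisible(x)
}

# integrate from x0 and decide whether the focal species collapses
.collapses <- function(model, params, x0, focal, box, settings, t_max) {
  tr <- tryCatch(
    integrateModel(model, params, x0, t_max = t_max, box = box,
                   settings = settings, keep_series = FALSE),
    error = function(e) NULL)
  if (is.null(tr)) return(NA)
  if (tr$terminal_event == "extinct") return(focal %in% tr$extinct_species ||
                                               length(tr$extinct_species) == 0)
  if (tr$terminal_event == "unbounded") return(FALSE)
  tr$final[focal] < 1e-4 * box[2]
}

# a collapse pattern over an increasing anchor grid: "below" when collapse
# happens only at the low end, "above" when only at the high end
.flipDirection <- function(collapse) {
  collapse <- collapse[!is.na(collapse)]
  if (length(collapse) < 3 || all(collapse) || !any(collapse)) return("none")
  if (collapse[1] && !collapse[length(collapse)]) return("below")
  if (!collapse[1] && collapse[length(collapse)]) return("above")
  "mixed"
}

#' Identify the threshold type behind a threshold regime
#'
#' Distinguishes the three threshold mechanisms by integration probes:
#' \describe{
#'   \item{partner_threshold}{with the focal species anchored at high
#'     density (`0.8 * L`), the focal collapses when the partner starts
#'     below a critical density.}
#'   \item{overexploitation}{the focal collapses when the partner starts
#'     \emph{above} a critical density (consumer over-exploits the
#'     resource).}
#'   \item{own_density_allee}{with the partner anchored near its own
#'     nullcline, the focal collapses when its own initial density is below
#'     a critical value.}
#' }
#' Several probes can fire at once (a partner threshold induces an Allee
#' effect in both species); precedence is overexploitation, then
#' own-density Allee, then partner threshold, and every fired probe is
#' listed in the evidence.  Returns `"none"` when the report has no
#' saddle-split basin structure.
#'
#' @inheritParams findEquilibria
#' @param report an [classifyDynamics()] outcome report (used for the
#'   saddle/basin precondition and the attractor anchor).
#' @param n_anchor number of anchor densities per probe.
#' @param t_max probe integration horizon.
#' @return list with `type` (one of `"none"`, `"partner_threshold"`,
#'   `"own_density_allee"`, `"overexploitation"`) and `evidence`
#'   (data.frame of all probes with their flip direction).
#' @export
thresholdType <- function(model, params = list(), report, box = NULL,
                          settings = analysisSettings(), n_anchor = 9,
                          t_max = NULL) {
  model <- as_model(model)
  params <- validateParams(model, params)
  if (is.null(box)) box <- defaultBox(model, params)
  if (is.null(t_max)) t_max <- settings$t_max
  L <- box[2]

  fr <- report$evidence$basin_fractions
  multi_basin <- sum(fr[c("coexist", "extinction", "unbounded")] > 0) >= 2
  if (!isTRUE(report$evidence$saddle_present) || !multi_basin)
    return(list(type = "none", evidence = NULL))

  ev <- list()
  fired <- character(0)
  for (focal in 1:2) {
    partner <- 3L - focal
    # geometric anchor grid: thresholds often sit near the origin
    anchors <- sort(0.9 * L * 0.5^seq(0, n_anchor - 1))

    # high-focal probe: sweep the partner's initial density
    cl <- vapply(anchors, function(a) {
      x0 <- c(0, 0); x0[focal] <- 0.8 * L; x0[partner] <- a
      .collapses(model, params, x0, focal, box, settings, t_max)
    }, logical(1))
    dir <- .flipDirection(cl)
    ev[[length(ev) + 1L]] <- data.frame(
      probe = "partner_sweep", focal = focal, direction = dir)
    if (dir == "below") fired <- c(fired, "partner_threshold")
    if (dir == "above") fired <- c(fired, "overexploitation")

    # Allee probe: anchor the partner near its nullcline, sweep own density
    anchor_p <- .partnerNullclineAnchor(model, params, partner, box, report)
    if (!is.na(anchor_p)) {
      cl2 <- vapply(anchors, function(a) {
        x0 <- c(0, 0); x0[focal] <- a; x0[partner] <- anchor_p
        .collapses(model, params, x0, focal, box, settings, t_max)
      }, logical(1))
      dir2 <- .flipDirection(cl2)
      ev[[length(ev) + 1L]] <- data.frame(
        probe = "own_density_sweep", focal = focal, direction = dir2)
      if (dir2 == "below") fired <- c(fired, "own_density_allee")
    }
  }
  fired <- unique(fired)
  type <- if ("overexploitation" %in% fired) "overexploitation"
    else if ("own_density_allee" %in% fired) "own_density_allee"
    else if ("partner_threshold" %in% fired) "partner_threshold"
    else "none"
  list(type = type, fired = fired, evidence = do.call(rbind, ev))
}

# anchor value for the Allee probe: the partner's component at the
# coexistence attractor when one exists, otherwise a zero of the partner's
# per-capita growth along its own axis direction at mid-box focal density
.partnerNullclineAnchor <- function(model, params, partner, box, report) {
  st <- report$evidence$coexistence_attractors
  if (length(st) >= 1) return(st[[1]][partner])
  eq <- report$evidence$equilibria
  sad <- eq[eq$type == "saddle" & eq$class == "interior", ]
  if (nrow(sad)) return(as.numeric(sad[1, c("N1", "N2")])[partner] * 1.5)
  L <- box[2]
  gfun <- function(v) {
    x <- c(0, 0); x[partner] <- v; x[3L - partner] <- 0.5 * L
    model$growth[[partner]](params, x[1], x[2])
  }
  xs <- seq(L * 1e-4, 0.95 * L, length.out = 101)
  gv <- vapply(xs, function(v) tryCatch(gfun(v), error = function(e) NA_real_),
               numeric(1))
  ok <- which(!is.na(gv))
  if (length(ok) < 2) return(NA_real_)
  sgn <- sign(gv[ok])
  flip <- which(sgn[-1] * sgn[-length(sgn)] <= 0)
  if (!length(flip)) return(NA_real_)
  stats::uniroot(gfun, c(xs[ok[flip[1]]], xs[ok[flip[1] + 1]]))$root
}

#' Mutualistic or parasitic character of a coexistence attractor
#'
#' Coexistence is `"mutualistic"` when both species sit above the density
#' they would reach alone, or when increasing either species from the
#' attractor raises its partner's growth (both off-diagonal Jacobian
#' entries positive); otherwise `"parasitic"`.
#'
#' @inheritParams findEquilibria
#' @param attractor interior attractor: one row of a [findEquilibria()]
#'   result or a numeric state `(N1, N2)`.
#' @param k_alone optional precomputed single-species equilibria (`NA`/
#'   absent treated as 0 for an obligate species).
#' @return list with `character` (`"mutualistic"` or `"parasitic"`),
#'   `above_alone` (logical per species) and `offdiag_positive`.
#' @examples
#' eq <- findEquilibria("case_1_2",
#'                      list(r1 = 1, r2 = 1, b12 = 1, b21 = 1,
#'                           h1 = 1, h2 = 1, s1 = 1, s2 = 1))
#' att <- eq[eq$class == "interior" & eq$type == "stable_node", ]
#' coexistenceCharacter("case_1_2",
#'                      list(r1 = 1, r2 = 1, b12 = 1, b21 = 1,
#'                           h1 = 1, h2 = 1, s1 = 1, s2 = 1), att)$character
#' @export
coexistenceCharacter <- function(model, params = list(), attractor,
                                 k_alone = NULL) {
  model <- as_model(model)
  params <- validateParams(model, params)
  st <- if (is.data.frame(attractor)) {
    if (nrow(attractor) != 1L) stop("'attractor' must be a single equilibrium")
    c(attractor$N1, attractor$N2)
  } else as.numeric(attractor)
  if (any(st <= 1e-10))
    stop("coexistence character requires an interior attractor; got (",
         paste(format(st, digits = 4), collapse = ", "), ")")
  if (is.null(k_alone)) {
    k_alone <- c(singleSpeciesEquilibrium(model, params, 1),
                 singleSpeciesEquilibrium(model, params, 2))
    k_alone[is.na(k_alone)] <- 0
  }
  above <- st > k_alone + 1e-9
  J <- evalJacobian(model, params, st)
  offpos <- c(J[1, 2] > 0, J[2, 1] > 0)
  ch <- if (all(above) || all(offpos)) "mutualistic" else "parasitic"
  list(character = ch, above_alone = above, offdiag_positive = offpos,
       state = st, k_alone = k_alone)
}

#' Critical benefit strength by bisection
#'
#' Locates the benefit-parameter value at which a feasible interior
#' attractor appears or disappears.  The predicate is "a bounded interior
#' attractor exists": first tested on the equilibrium set, with an orbit
#' integration fallback when the attractor lies outside the default search
#' box.  For linear facultative pairs this is the boundary between
#' bounded coexistence and unbounded growth; for obligate pairs it is the
#' minimal benefit permitting coexistence.
#'
#' @inheritParams findEquilibria
#' @param base_params fixed parameters; the benefit symbols are overridden.
#' @param benefit_symbol character vector of parameter names swept jointly
#'   (e.g. `c("b12", "b21")` for a symmetric sweep).
#' @param bracket length-2 numeric: lower and upper benefit values; the
#'   predicate must differ at the two ends.
#' @param iterations bisection iterations (default 40).
#' @return the threshold value (scalar), with attributes
#'   `feasible_at_lower` and `history` (the bisection trace).
#' @examples
#' \donttest{
#' criticalBenefitStrength("case_1_1_1",
#'                         list(r1 = 1, r2 = 1),
#'                         c("b12", "b21"), bracket = c(0.1, 3))
#' }
#' @export
criticalBenefitStrength <- function(model, base_params = list(),
                                    benefit_symbol, bracket,
                                    box = NULL,
                                    settings = analysisSettings(),
                                    iterations = 40) {
  model <- as_model(model)
  stopifnot(length(bracket) == 2, bracket[1] < bracket[2])
  feasible <- function(v) {
    p <- base_params
    for (s in benefit_symbol) p[[s]] <- v
    p <- validateParams(model, p)
    bx <- if (is.null(box)) defaultBox(model, p) else box
    eq <- tryCatch(findEquilibria(model, p, bx, settings),
                   error = function(e) NULL)
    if (!is.null(eq)) {
      inter <- eq[eq$class == "interior", ]
      if (any(inter$type %in% c("stable_node", "stable_spiral")))
        return(TRUE)
    }
    # fallback: does a representative orbit settle at an interior point
    # (possibly beyond the equilibrium-search box)?
    L <- bx[2]
    tr <- tryCatch(
      integrateModel(model, p, c(0.2 * L, 0.2 * L),
                     t_max = 4 * settings$t_max, box = bx,
                     settings = settings, keep_series = FALSE),
      error = function(e) NULL)
    !is.null(tr) && tr$terminal_event == "converged" &&
      all(tr$final > 1e-6 * L)
  }
  lo <- bracket[1]; hi <- bracket[2]
  f_lo <- feasible(lo); f_hi <- feasible(hi)
  if (identical(f_lo, f_hi))
    stop("bracketing error: interior attractor ",
         if (f_lo) "present" else "absent", " at both bracket ends")
  hist <- data.frame(lower = lo, upper = hi)
  for (i in seq_len(iterations)) {
    mid <- 0.5 * (lo + hi)
    if (identical(feasible(mid), f_lo)) lo <- mid else hi <- mid
    hist <- rbind(hist, data.frame(lower = lo, upper = hi))
  }
  structure(0.5 * (lo + hi), feasible_at_lower = f_lo, history = hist)
}

#' Sweep a parameter and track the outcome label
#'
#' Classifies the dynamics at each value of `values` (with reduced-cost
#' classification settings suitable for scans) and reports the label
#' sequence together with the bracketing intervals where the label changes.
#'
#' @inheritParams classifyDynamics
#' @param base_params fixed parameters.
#' @param symbol character vector of parameter names set jointly to each
#'   swept value.
#' @param values numeric vector of swept values (in schema range).
#' @param full_reports keep the complete `outcome_report` objects.
#' @return object of class `sweep_result`: list with `symbol`, `table`
#'   (`data.frame(value, label, low_confidence)`), `brackets`
#'   (data.frame of adjacent value pairs with differing labels), and
#'   optionally `reports`.
#' @examples
#' \donttest{
#' sw <- sweepParameter("case_1_1_1", list(r1 = 1, r2 = 1),
#'                      c("b12", "b21"), values = c(0.5, 2), grid_n = 11)
#' sw$table
#' }
#' @export
sweepParameter <- function(model, base_params = list(), symbol, values,
                           box = NULL, settings = analysisSettings(),
                           grid_n = 15, t_max = NULL,
                           probe_thresholds = FALSE,
                           detect_oscillation = FALSE,
                           full_reports = FALSE) {
  model <- as_model(model)
  if (!length(values)) {
    return(structure(list(symbol = symbol,
                          table = data.frame(value = numeric(0),
                                             label = character(0),
                                             low_confidence = logical(0)),
                          brackets = data.frame(lower = numeric(0),
                                                upper = numeric(0),
                                                from = character(0),
                                                to = character(0)),
                          reports = list()),
                     class = "sweep_result"))
  }
  reports <- vector("list", length(values))
  lab <- character(length(values)); lowc <- logical(length(values))
  for (i in seq_along(values)) {
    p <- base_params
    for (s in symbol) p[[s]] <- values[i]
    rep_i <- classifyDynamics(model, p, box = box, settings = settings,
                              grid_n = grid_n, t_max = t_max,
                              probe_thresholds = probe_thresholds,
                              detect_oscillation = detect_oscillation)
    lab[i] <- rep_i$outcome_label
    lowc[i] <- rep_i$low_confidence
    if (full_reports) reports[[i]] <- rep_i
  }
  ch <- which(lab[-1] != lab[-length(lab)])
  brackets <- data.frame(lower = values[ch], upper = values[ch + 1L],
                         from = lab[ch], to = lab[ch + 1L])
  structure(list(symbol = symbol,
                 table = data.frame(value = values, label = lab,
                                    low_confidence = lowc),
                 brackets = brackets,
                 reports = if (full_reports) reports else list()),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("<sweep_result> symbol ", paste(x$symbol, collapse = "="),
      ", ", nrow(x$table), " values\n", sep = "")
  print(x$table)
  if (nrow(x$brackets)) {
    cat("label changes:\n")
    print(x$brackets)
  }
  invisible(x)
}
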