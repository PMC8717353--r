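#' @keywords internal
"_PACKAGE"

# Internal environment holding the model registry.  Populated at load time by
# the files defining the literature models and the generic template models.
.mutdyn_registry <- new.env(parent = emptyenv())

#' Describe one model parameter
#'
#' Builds a single row of a model's parameter schema: the ASCII name used in
#' parameter lists, the typeset symbol used in the literature, the admissible
#' range, and a default value.
#'
#' @param name ASCII parameter name (e.g. `"b12"`).
#' @param symbol display symbol (e.g. `"beta12"`); defaults to `name`.
#' @param default default value.
#' @param lower,upper admissible range.
#' @param lower_open,upper_open if `TRUE` the corresponding bound is
#'   exclusive.  Most rate and density parameters are strictly positive,
#'   so the default is an open lower bound at zero.
#' @param description one-line meaning of the parameter.
#' @return a one-row `data.frame`.
#' @keywords internal
paramDescriptor <- function(name, default, symbol = name,
                            lower = 0, upper = Inf,
                            lower_open = TRUE, upper_open = TRUE,
                            description = "") {
  data.frame(name = name, symbol = symbol, default = default,
             lower = lower, upper = upper,
             lower_open = lower_open, upper_open = upper_open,
             description = description, stringsAsFactors = FALSE)
}

# shorthand: a parameter free in sign
paramFree <- function(name, default, symbol = name, description = "") {
  paramDescriptor(name, default, symbol, lower = -Inf, upper = Inf,
                  description = description)
}

#' Construct a model specification
#'
#' A `model_spec` bundles everything the phase-plane machinery needs: the
#' per-capita growth functions, the full right-hand side, an optional analytic
#' Jacobian, the parameter schema, and metadata (source, species roles,
#' which axes are invariant sets of the flow).
#'
#' @param id registry key.
#' @param source citation tag and equation number.
#' @param description one-line summary of the model.
#' @param species length-2 character vector naming the two populations.
#' @param schema `data.frame` of parameter descriptors (see
#'   [paramDescriptor()]).
#' @param growth `function(state, p)` returning the two per-capita growth
#'   rates; may be `NULL` for models without a multiplicative `Ni` factor.
#' @param rhs `function(state, p)` returning the two time-derivatives.  If
#'   `NULL` it is built as `state * growth(state, p)` with exact zeros on
#'   invariant axes.
#' @param jac optional analytic `function(state, p)` returning the 2x2
#'   Jacobian of the right-hand side.
#' @param validity `function(state, p)` returning `TRUE` or a character
#'   message naming the offending term.
#' @param axis_invariant `function(p)` (or logical vector) saying whether the
#'   axes `N1 = 0`, `N2 = 0` are invariant under the flow.
#' @param obligacy_rule optional `function(p)` overriding the default
#'   origin-limit obligacy rule (used by the historical carrying-capacity
#'   convention of the habitat-provisioning template).
#' @param validate_extra optional `function(p)` returning `TRUE` or a message
#'   for cross-parameter constraints.
#' @return an object of class `model_spec`.
#' @keywords internal
newModelSpec <- function(id, source, description, species = c("N1", "N2"),
                         schema, growth = NULL, rhs = NULL, jac = NULL,
                         validity = NULL, axis_invariant = c(TRUE, TRUE),
                         obligacy_rule = NULL, validate_extra = NULL) {
  stopifnot(is.character(id), length(id) == 1L)
  if (is.null(growth) && is.null(rhs))
    stop("either 'growth' or 'rhs' must be supplied")
  if (!is.function(axis_invariant)) {
    ai <- axis_invariant
    axis_invariant <- function(p) ai
  }
  if (is.null(validity)) validity <- function(state, p) TRUE
  structure(list(id = id, source = source, description = description,
                 species = species, schema = schema, growth = growth,
                 rhs = rhs, jac = jac, validity = validity,
                 axis_invariant = axis_invariant,
                 obligacy_rule = obligacy_rule,
                 validate_extra = validate_extra),
            class = "model_spec")
}

registerModel <- function(spec) {
  assign(spec$id, spec, envir = .mutdyn_registry)
  invisible(spec)
}

#' List registered model identifiers
#'
#' @return character vector of the registered model ids, in registration
#'   order of the underlying tables (literature models first, then the
#'   generic template models).
#' @examples
#' listModels()
#' @export
listModels <- function() {
  intersect(.registry_order(), ls(.mutdyn_registry))
}

.registry_order <- function() {
  c("gause_witt_eq1", "whittaker_eq2", "whittaker_eq3",
    "vandermeer_boucher_eq1", "addicott_eq4", "wolin_lawlor_eq5",
    "wolin_lawlor_eq6", "wright_eq7", "zhang_eq8",
    "neuhauser_fargione_eq9", "graves_eq10", "thompson_eq11_12",
    "holland_deangelis_eq13_bidir", "holland_deangelis_eq13_7_unidir",
    "fishman_hadany_eq14_15", "kang_eq16", "martignoni_eq17_18",
    "hale_eq19_7_pollination", "hale_eq20_7_dispersal",
    "case_1_1_1", "case_1_1_2", "case_1_1_3", "case_1_2",
    "case_2_1", "case_2_2", "case_3_1", "case_3_2", "case_3_3")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Retrieve a registered model
#'
#' Looks up a model by id.  Compound ids of the form
#' `"case_A:case_B"` (two generic template ids separated by a colon) build a
#' mixed-pair model in which species 1 follows the first template and
#' species 2 the second; see [pairCases()].
#'
#' @param id a registered model id, or a compound `"caseA:caseB"` id.
#' @return a `model_spec`.
#' @examples
#' m <- getModel("case_1_1_1")
#' m$species
#' @export
getModel <- function(id) {
  stopifnot(is.character(id), length(id) == 1L)
  if (grepl(":", id, fixed = TRUE)) {
    parts <- strsplit(id, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      stop("compound id must be of the form 'caseA:caseB'")
    return(pairCases(parts[1], parts[2]))
  }
  if (!exists(id, envir = .mutdyn_registry))
    stop("unknown model id '", id, "'. Registered ids: ",
         paste(.registry_order(), collapse = ", "), call. = FALSE)
  get(id, envir = .mutdyn_registry)
}

#' Default parameter values for a model
#'
#' @param model a `model_spec` or model id.
#' @return named list of the schema defaults.
#' @examples
#' modelParams("case_1_1_1")
#' @export
modelParams <- function(model) {
  model <- as_model(model)
  as.list(stats::setNames(model$schema$default, model$schema$name))
}

as_model <- function(model) {
  if (is.character(model)) getModel(model) else model
}

#' Validate a parameter set against a model schema
#'
#' Checks completeness, rejects unknown names, and enforces each
#' parameter's admissible range plus any cross-parameter constraints.
#'
#' @param model a `model_spec` or model id.
#' @param params named list or vector of parameter values.
#' @param partial if `TRUE`, missing parameters are filled from the schema
#'   defaults.
#' @return the validated (completed) parameter list, invisibly usable
#'   downstream.
#' @export
validateParams <- function(model, params, partial = TRUE) {
  model <- as_model(model)
  params <- as.list(params)
  sch <- model$schema
  unknown <- setdiff(names(params), sch$name)
  if (length(unknown))
    stop("unknown parameter(s) for model '", model$id, "': ",
         paste(unknown, collapse = ", "))
  missing <- setdiff(sch$name, names(params))
  if (length(missing)) {
    if (!partial)
      stop("missing parameter(s): ", paste(missing, collapse = ", "))
    defs <- stats::setNames(sch$default, sch$name)
    params[missing] <- defs[missing]
  }
  for (k in seq_len(nrow(sch))) {
    nm <- sch$name[k]; v <- params[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number")
    lo <- sch$lower[k]; hi <- sch$upper[k]
    bad <- if (sch$lower_open[k]) v <= lo else v < lo
    bad <- bad || if (sch$upper_open[k]) v >= hi && is.finite(hi) else v > hi
    if (bad)
      stop("parameter '", nm, "' = ", v, " outside admissible range ",
           if (sch$lower_open[k]) "(" else "[", lo, ", ", hi,
           if (sch$upper_open[k] && is.finite(hi)) ")" else "]",
           " for model '", model$id, "'")
  }
  if (!is.null(model$validate_extra)) {
    ok <- model$validate_extra(params)
    if (!isTRUE(ok)) stop("invalid parameters for '", model$id, "': ", ok)
  }
  params[sch$name]
}

#' Evaluate a model right-hand side
#'
#' Returns the pair of time-derivatives `(dN1/dt, dN2/dt)`.  For models whose
#' equations carry a multiplicative `Ni` factor, the i-th component is exactly
#' zero whenever `Ni = 0`.
#'
#' @param model a `model_spec` or model id.
#' @param params named parameter list (validated; missing entries are filled
#'   from defaults).
#' @param state numeric length-2 state `(N1, N2)`, both nonnegative.
#' @return numeric length-2 derivative.
#' @examples
#' evalRhs("case_1_1_1", list(r1 = 1, r2 = 1, b12 = 0.5, b21 = 0.5,
#'                            s1 = 1, s2 = 1), c(2, 2))
#' @export
evalRhs <- function(model, params, state) {
  model <- as_model(model)
  params <- validateParams(model, params)
  checkState(model, params, state)
  rhsRaw(model, params, state)
}

# rhs without validation overhead -- the hot path used by integrators.
rhsRaw <- function(model, params, state) {
  if (!is.null(model$rhs)) return(model$rhs(state, params))
  ai <- model$axis_invariant(params)
  g <- model$growth(state, params)
  out <- state * g
  out[state == 0 & ai] <- 0
  out
}

checkState <- function(model, params, state) {
  if (!is.numeric(state) || length(state) != 2L || any(!is.finite(state)))
    stop("state must be two finite numbers")
  if (any(state < 0))
    stop("population densities must be nonnegative")
  ok <- model$validity(state, params)
  if (!isTRUE(ok))
    stop("state (", state[1], ", ", state[2], ") outside validity domain of '",
         model$id, "': ", ok)
  invisible(TRUE)
}

#' Evaluate the Jacobian of a model right-hand side
#'
#' Uses the analytic Jacobian when the model spec provides one, otherwise
#' central finite differences with step `sqrt(.Machine$double.eps) * (1 + |Ni|)`.
#'
#' @inheritParams evalRhs
#' @param numeric_only force the finite-difference evaluation even when an
#'   analytic form exists (used to cross-check the analytic forms).
#' @return 2x2 numeric matrix.
#' @export
evalJacobian <- function(model, params, state, numeric_only = FALSE) {
  model <- as_model(model)
  params <- validateParams(model, params)
  checkState(model, params, state)
  if (!numeric_only && !is.null(model$jac))
    return(model$jac(state, params))
  jacFD(model, params, state)
}

jacFD <- function(model, params, state) {
  h <- sqrt(.Machine$double.eps) * (1 + abs(state))
  J <- matrix(0, 2, 2)
  for (j in 1:2) {
    sp <- sm <- state
    sp[j] <- state[j] + h[j]
    # keep evaluation inside the nonnegative quadrant near the axes
    sm[j] <- max(state[j] - h[j], 0)
    J[, j] <- (rhsRaw(model, params, sp) - rhsRaw(model, params, sm)) /
      (sp[j] - sm[j])
  }
  J
}

#' Per-species obligacy
#'
#' A species is obligate upon its partner when the limit of its per-capita
#' growth rate as its own density goes to zero, with the partner absent, is
#' nonpositive (negative carrying capacity in the classical convention).  The
#' habitat-provisioning template (`case_3_1`) instead uses the historical
#' convention where the sign of the carrying capacity parameter decides
#' obligacy directly.
#'
#' @inheritParams evalRhs
#' @return character vector of length 2 with values `"facultative"` or
#'   `"obligate"`, named by species.
#' @examples
#' obligacy("case_1_2", list(r1 = -0.5))
#' @export
obligacy <- function(model, params = list()) {
  model <- as_model(model)
  params <- validateParams(model, params)
  if (!is.null(model$obligacy_rule)) {
    lab <- model$obligacy_rule(params)
  } else {
    g0 <- originGrowth(model, params)
    lab <- ifelse(g0 <= 0, "obligate", "facultative")
  }
  stats::setNames(lab, model$species)
}

# per-capita growth of each species at the origin (limit Ni -> 0+, Nj = 0)
originGrowth <- function(model, params) {
  eps <- 1e-8
  vapply(1:2, function(i) {
    st <- c(0, 0); st[i] <- eps
    ok <- model$validity(st, params)
    if (!isTRUE(ok)) return(-Inf)  # undefined at the origin: cannot persist alone
    if (!is.null(model$growth)) model$growth(st, params)[i]
    else model$rhs(st, params)[i] / eps
  }, numeric(1))
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec> ", x$id, "\n", sep = "")
  cat("  source : ", x$source, "\n", sep = "")
  cat("  ", x$description, "\n", sep = "")
  cat("  species: ", paste(x$species, collapse = ", "), "\n", sep = "")
  cat("  parameters (", nrow(x$schema), "): ",
      paste(x$schema$name, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Export the model registry as a structured-text manifest
#'
#' Serialises every registered model's id, source, species, and parameter
#' schema (symbols, ranges, defaults) to JSON.
#'
#' @param path output file; if `NULL` the manifest is returned as a list.
#' @return the manifest list, invisibly when written to file.
#' @export
modelManifest <- function(path = NULL) {
  man <- lapply(.registry_order(), function(id) {
    m <- getModel(id)
    list(id = m$id, source = m$source, description = m$description,
         species = m$species,
         parameters = m$schema[, c("name", "symbol", "default",
                                   "lower", "upper", "description")])
  })
  names(man) <- .registry_order()
  if (is.null(path)) return(man)
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(man)
}
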