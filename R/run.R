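# Config-driven runs: one structured-text (YAML) config describes one
# reproducible analysis bundle (JSON report + CSV tables + figures).

.run_analyses <- c("equilibria", "nullclines", "basins", "classify",
                   "sweep", "critical", "portrait")
.run_keys <- c("model", "params", "fixture", "analyses", "box", "grid_n",
               "t_max", "seed", "outdir", "strict", "sweep", "critical")

# validate a raw config list into a canonical structure
.validateRunConfig <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a file path or a list",
                             call. = FALSE)
  unknown <- setdiff(names(config), .run_keys)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         "; allowed: ", paste(.run_keys, collapse = ", "), call. = FALSE)
  if (is.null(config$model)) stop("config requires a 'model'", call. = FALSE)
  model <- getModel(config$model)
  params <- config$params
  if (!is.null(config$fixture)) {
    fparams <- canonicalParams(config$model, config$fixture)
    # explicit params override fixture values
    params <- utils::modifyList(fparams, if (is.null(params)) list()
                                         else params)
  }
  if (is.null(params)) params <- list()
  params <- validateParams(model, params)   # config error before computation
  analyses <- config$analyses
  if (is.null(analyses)) analyses <- "classify"
  bad <- setdiff(analyses, .run_analyses)
  if (length(bad))
    stop("unknown analyses: ", paste(bad, collapse = ", "),
         "; allowed: ", paste(.run_analyses, collapse = ", "), call. = FALSE)
  if (!is.null(config$box) &&
      (length(config$box) != 2 || diff(as.numeric(config$box)) <= 0))
    stop("'box' must be two increasing numbers", call. = FALSE)
  if ("sweep" %in% analyses) {
    sw <- config$sweep
    if (is.null(sw$symbol) || is.null(sw$values))
      stop("sweep analysis requires sweep: {symbol, values}", call. = FALSE)
  }
  if ("critical" %in% analyses) {
    cr <- config$critical
    if (is.null(cr$symbol) || is.null(cr$bracket) ||
        length(cr$bracket) != 2)
      stop("critical analysis requires critical: {symbol, bracket}",
           call. = FALSE)
  }
  list(model = model, params = params, analyses = analyses,
       box = if (is.null(config$box)) NULL else as.numeric(config$box),
       grid_n = config$grid_n, t_max = config$t_max,
       seed = if (is.null(config$seed)) 0L else as.integer(config$seed),
       outdir = if (is.null(config$outdir)) "." else config$outdir,
       strict = isTRUE(config$strict),
       sweep = config$sweep, critical = config$critical)
}

#' Run a configured analysis bundle
#'
#' Reads a YAML config (or takes the equivalent named list), validates it
#' against the model schema before any computation, runs the requested
#' analyses, and writes a report bundle into the output directory:
#' `report.json` ([writeReport()]), `equilibria.csv`, `basins.csv`,
#' `sweep.csv`, `critical.json`, `portrait.svg`.  Runs are deterministic
#' given the config and seed.
#'
#' Config keys: `model` (id), `params` (named values) and/or `fixture`
#' (regime key for [canonicalParams()]), `analyses` (subset of
#' `"equilibria"`, `"nullclines"`, `"basins"`, `"classify"`, `"sweep"`,
#' `"critical"`, `"portrait"`), `box`,
#' `grid_n`, `t_max`, `seed`, `outdir`, `strict`, `sweep:
#' {symbol, values}`, `critical: {symbol, bracket}`.  Unknown keys are
#' rejected.
#'
#' @param config path to a YAML file, or a named list with the same keys.
#' @param quiet suppress step-level progress messages.
#' @return named list of results and written file paths, invisibly.  In
#'   strict mode a low-confidence classification raises an error (nonzero
#'   exit under `Rscript`).
#' @examples
#' \donttest{
#' out <- runAnalysis(list(model = "case_1_1_1", fixture = "SC",
#'                         analyses = "classify", outdir = tempdir(),
#'                         grid_n = 11))
#' }
#' @export
runAnalysis <- function(config, quiet = FALSE) {
  cfg <- .validateRunConfig(config)
  set.seed(cfg$seed)
  settings <- analysisSettings()
  say <- function(...) if (!quiet) message("[mutdyn] ", ...)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  model <- cfg$model
  box <- if (is.null(cfg$box)) defaultBox(model, cfg$params) else cfg$box
  out <- list(files = character(0))

  eq <- NULL
  needs_eq <- any(c("equilibria", "basins", "classify", "portrait") %in%
                    cfg$analyses)
  if (needs_eq) {
    say("equilibria: grid ", settings$grid_equilibria,
        ", newton tol ", settings$newton_tol)
    eq <- findEquilibria(model, cfg$params, box, settings)
    out$equilibria <- eq
  }
  if ("equilibria" %in% cfg$analyses) {
    f <- file.path(cfg$outdir, "equilibria.csv")
    utils::write.csv(as.data.frame(eq), f, row.names = FALSE)
    out$files <- c(out$files, f)
  }
  if ("nullclines" %in% cfg$analyses) {
    say("nullclines: resolution ", settings$nullcline_res)
    nc <- nullclines(model, cfg$params, box, settings = settings)
    out$nullclines <- nc
  }
  if ("basins" %in% cfg$analyses) {
    say("basins: grid ", if (is.null(cfg$grid_n)) settings$basin_n
                         else cfg$grid_n)
    bm <- basinMap(model, cfg$params, box, grid_n = cfg$grid_n,
                   t_max = cfg$t_max, settings = settings, equilibria = eq)
    out$basins <- bm
    f <- file.path(cfg$outdir, "basins.csv")
    utils::write.csv(bm$grid, f, row.names = FALSE)
    out$files <- c(out$files, f)
  }
  if ("classify" %in% cfg$analyses) {
    say("classify: conv tol ", settings$conv_tol,
        ", blowup factor ", settings$blowup_factor)
    rep <- classifyDynamics(model, cfg$params,
                            box = if (is.null(cfg$box)) NULL else cfg$box,
                            settings = settings, grid_n = cfg$grid_n,
                            t_max = cfg$t_max,
                            basin = out$basins)
    out$classify <- rep
    f <- file.path(cfg$outdir, "report.json")
    writeReport(rep, f, settings)
    out$files <- c(out$files, f)
    if (cfg$strict && isTRUE(rep$low_confidence))
      stop("strict mode: classification is low-confidence (",
           round(100 * rep$evidence$basin_fractions[["horizon"]]),
           "% of basin cells undecided)", call. = FALSE)
  }
  if ("sweep" %in% cfg$analyses) {
    say("sweep over ", cfg$sweep$symbol)
    sw <- sweepParameter(model, cfg$params, cfg$sweep$symbol,
                         as.numeric(cfg$sweep$values), box = cfg$box,
                         settings = settings)
    out$sweep <- sw
    f <- file.path(cfg$outdir, "sweep.csv")
    writeSweepCSV(sw, f)
    out$files <- c(out$files, f)
  }
  if ("critical" %in% cfg$analyses) {
    say("critical benefit strength in ", cfg$critical$symbol)
    cr <- criticalBenefitStrength(model, cfg$params, cfg$critical$symbol,
                                  as.numeric(cfg$critical$bracket),
                                  box = cfg$box, settings = settings)
    out$critical <- cr
    f <- file.path(cfg$outdir, "critical.json")
    payload <- list(symbol = cfg$critical$symbol,
                    critical = as.numeric(cr),
                    feasible_at_lower = attr(cr, "feasible_at_lower"),
                    history = attr(cr, "history"))
    writeLines(jsonlite::toJSON(payload, pretty = TRUE, auto_unbox = TRUE,
                                digits = NA), f)
    out$files <- c(out$files, f)
  }
  if ("portrait" %in% cfg$analyses) {
    say("portrait")
    f <- file.path(cfg$outdir, "portrait.svg")
    renderPortrait(model, cfg$params, box, file = f, settings = settings,
                   equilibria = eq)
    out$files <- c(out$files, f)
  }
  invisible(out)
}
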