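# Report serialization: versioned JSON for outcome reports, CSV for sweep
# tables.  Key order is fixed so identical analyses produce byte-identical
# files.

.report_schema_version <- "1"

# plain-list view of an outcome_report with stable key order
.reportPayload <- function(report, settings = analysisSettings()) {
  stopifnot(inherits(report, "outcome_report"))
  eq <- as.data.frame(report$evidence$equilibria)
  eq <- eq[, intersect(c("N1", "N2", "class", "type"), names(eq)),
           drop = FALSE]
  osc <- report$oscillation
  if (!is.null(osc) && inherits(osc, "oscillation_report"))
    osc <- list(status = osc$status, period = osc$period,
                n_peaks = osc$n_peaks, terminal_event = osc$terminal_event)
  probes <- report$evidence$probes
  if (!is.null(probes)) probes <- as.data.frame(probes)
  list(
    schema_version = .report_schema_version,
    package = "mutdyn",
    package_version = as.character(utils::packageVersion("mutdyn")),
    model = report$model,
    params = report$params,
    box = report$box,
    grid_n = report$grid_n,
    t_max = report$t_max,
    settings = unclass(settings),
    outcome_label = report$outcome_label,
    threshold_type = report$threshold_type,
    coexistence_character = report$coexistence_character,
    oscillation = osc,
    low_confidence = report$low_confidence,
    evidence = list(
      equilibria = eq,
      basin_fractions = as.list(report$evidence$basin_fractions),
      basin_counts = as.list(unclass(report$evidence$basin_counts)),
      coexistence_attractors = report$evidence$coexistence_attractors,
      k_alone = report$evidence$k_alone,
      saddle_present = report$evidence$saddle_present,
      probes = probes))
}

#' Write an outcome report as versioned JSON
#'
#' The JSON embeds the package version, schema version, full parameter set
#' and every tolerance in `settings`, with a fixed key order so that
#' identical analyses serialize byte-identically.
#'
#' @param report an [classifyDynamics()] `outcome_report`.
#' @param path output file path.
#' @param settings the [analysisSettings()] used for the analysis (echoed
#'   into the report).
#' @return `path`, invisibly.
#' @export
writeReport <- function(report, path, settings = analysisSettings()) {
  payload <- .reportPayload(report, settings)
  json <- jsonlite::toJSON(payload, pretty = TRUE, digits = NA,
                           auto_unbox = TRUE, na = "null", null = "null")
  writeLines(json, path)
  invisible(path)
}

#' Read a JSON outcome report
#'
#' @param path a file written by [writeReport()].
#' @return the parsed report payload (named list); errors when the schema
#'   version is not supported.
#' @export
readReport <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(x$schema_version, .report_schema_version))
    stop("unsupported report schema version '", x$schema_version, "'",
         call. = FALSE)
  x
}

#' Write a parameter-sweep table as CSV
#'
#' @param sweep a [sweepParameter()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSweepCSV <- function(sweep, path) {
  stopifnot(inherits(sweep, "sweep_result"))
  utils::write.csv(sweep$table, path, row.names = FALSE)
  invisible(path)
}
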