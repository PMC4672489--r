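#' SensorStore: an in-memory hierarchical sensor-data store
#'
#' A `SensorStore` holds the entity hierarchy (users, experiments, nodes,
#' streams), the raw points of every stream, and the pre-computed window
#' summaries at every aggregation level. The object wraps an environment so
#' that ingest and metadata operations update the store in place, as is
#' usual for cache-like objects; all access goes through the exported
#' generics, never through slots.
#'
#' @slot env environment holding `entities`, `streams` and `counters`.
#'
#' @seealso [SensorStore()] to construct one, [createEntity()],
#'   [appendPoints()], [saveStore()].
#' @export
setClass("SensorStore", representation(env = "environment"))

setValidity("SensorStore", function(object) {
  need <- c("entities", "streams", "counters")
  missing <- setdiff(need, ls(object@env, all.names = TRUE))
  if (length(missing))
    return(paste("store environment lacks:", paste(missing, collapse = ", ")))
  TRUE
})

#' Create an empty SensorStore
#'
#' @return A new, empty [SensorStore-class] object.
#' @examples
#' store <- SensorStore()
#' createEntity(store, "user", "csiro-hb")
#' @export
SensorStore <- function() {
  env <- new.env(parent = emptyenv())
  env$entities <- new.env(parent = emptyenv())
  env$streams <- new.env(parent = emptyenv())
  env$counters <- new.env(parent = emptyenv())
  env$counters$raw_records_read <- 0
  env$counters$summary_records_read <- 0
  new("SensorStore", env = env)
}

#' @describeIn SensorStore-class one-line overview of entity counts and
#'   stored points.
#' @param object A `SensorStore`.
#' @export
setMethod("show", "SensorStore", function(object) {
  ids <- ls(object@env$entities, all.names = TRUE)
  kinds <- vapply(ids, function(i) object@env$entities[[i]]$kind, character(1))
  np <- sum(vapply(ls(object@env$streams, all.names = TRUE),
                   function(s) nrow(object@env$streams[[s]]$raw), numeric(1)))
  cat(sprintf(
    "SensorStore: %d users, %d experiments, %d nodes, %d streams, %d raw points\n",
    sum(kinds == "user"), sum(kinds == "experiment"),
    sum(kinds == "node"), sum(kinds == "stream"), np))
})

#' DiagnosticReport: daily sensor-network QC findings
#'
#' Produced by [dailyReport()]. Collects, for one experiment and one UTC
#' calendar day, three families of faults: gaps between successive readings
#' that exceed a threshold, values outside configured bounds, and streams
#' that reported nothing at all that day. A stream listed under
#' `missing_sensors` never also appears in `gap_errors`.
#'
#' @slot experiment experiment identifier the report covers.
#' @slot day UTC epoch seconds of the report day's midnight.
#' @slot config the [diagnosticConfig()] list used.
#' @slot gap_errors data.frame: stream, gap_start, gap_length (seconds).
#' @slot range_errors data.frame: stream, timestamp, value, bound.
#' @slot missing_sensors character vector of stream identifiers.
#' @slot generated_at UTC epoch seconds the report was generated.
#' @export
setClass("DiagnosticReport", representation(
  experiment = "character",
  day = "numeric",
  config = "list",
  gap_errors = "data.frame",
  range_errors = "data.frame",
  missing_sensors = "character",
  generated_at = "numeric"
))

#' @describeIn DiagnosticReport-class print the human-readable report text.
#' @param object A `DiagnosticReport`.
#' @export
setMethod("show", "DiagnosticReport", function(object) {
  cat(reportToText(object), sep = "\n")
})
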