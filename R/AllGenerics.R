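# Generics for operations dispatched on SensorStore / DiagnosticReport.
# Documentation lives with the methods.

#' @export
setGeneric("createEntity", function(store, kind, name, parent = NULL,
                                    attrs = list())
  standardGeneric("createEntity"))

#' @export
setGeneric("deleteEntity", function(store, entity)
  standardGeneric("deleteEntity"))

#' @export
setGeneric("listChildren", function(store, parent = NULL)
  standardGeneric("listChildren"))

#' @export
setGeneric("setMetadata", function(store, entity, key, value)
  standardGeneric("setMetadata"))

#' @export
setGeneric("getMetadata", function(store, entity)
  standardGeneric("getMetadata"))

#' @export
setGeneric("filterStreams", function(store, user, experiment = NULL,
                                     node = NULL, stream = NULL, unit = NULL,
                                     metadata = list())
  standardGeneric("filterStreams"))

#' @export
setGeneric("appendPoints", function(store, stream, points,
                                    duplicatePolicy = c("replace", "reject"))
  standardGeneric("appendPoints"))

#' @export
setGeneric("getRaw", function(store, stream, from = 0, to = Inf)
  standardGeneric("getRaw"))

#' @export
setGeneric("getWindowStats", function(store, stream, level, from = 0,
                                      to = Inf)
  standardGeneric("getWindowStats"))

#' @export
setGeneric("streamSummary", function(store, stream)
  standardGeneric("streamSummary"))

#' @export
setGeneric("touchCounter", function(store) standardGeneric("touchCounter"))

#' @export
setGeneric("resetTouchCounter", function(store)
  standardGeneric("resetTouchCounter"))

#' @export
setGeneric("saveStore", function(store, dir) standardGeneric("saveStore"))

#' @export
setGeneric("ingestCsv", function(store, path, spec, createMissing = FALSE,
                                 duplicatePolicy = "replace")
  standardGeneric("ingestCsv"))

#' @export
setGeneric("batchUpload", function(store, stream, points, chunkSize = 100L,
                                   duplicatePolicy = "replace")
  standardGeneric("batchUpload"))

#' @export
setGeneric("apiRequest", function(store, method, path, query = list(),
                                  body = NULL)
  standardGeneric("apiRequest"))

#' @export
setGeneric("detectGaps", function(store, stream, day, threshold)
  standardGeneric("detectGaps"))

#' @export
setGeneric("detectRangeViolations", function(store, stream, day, minAllowed,
                                             maxAllowed)
  standardGeneric("detectRangeViolations"))

#' @export
setGeneric("dailyReport", function(store, experiment, config)
  standardGeneric("dailyReport"))
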