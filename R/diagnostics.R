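# Daily sensor-network QC: the faults field technicians need flagged the
# morning after — streams that went quiet (gaps), readings outside
# physically plausible bounds (range), and sensors that reported nothing
# at all (missing). One report covers one experiment and one UTC day.

#' Configuration for a daily diagnostic report
#'
#' @param gapThreshold seconds; an interval between successive readings
#'   longer than this (strictly) is a gap. Must be positive.
#' @param minAllowed,maxAllowed value bounds; readings strictly below /
#'   above are range violations. `minAllowed < maxAllowed`.
#' @param day the report day (UTC): a `Date`, `"YYYY-MM-DD"` string or
#'   epoch seconds.
#' @param expectedPeriod nominal reporting interval in seconds
#'   (informational; a 15-min network uses 900).
#' @return A `DiagnosticConfig` list for [dailyReport()].
#' @export
diagnosticConfig <- function(gapThreshold, minAllowed, maxAllowed, day,
                             expectedPeriod = 900) {
  stopifnot(gapThreshold > 0, minAllowed < maxAllowed)
  structure(list(gapThreshold = as.numeric(gapThreshold),
                 minAllowed = as.numeric(minAllowed),
                 maxAllowed = as.numeric(maxAllowed),
                 day = dayStart(day),
                 expectedPeriod = as.numeric(expectedPeriod)),
            class = "DiagnosticConfig")
}

#' Detect reporting gaps in a stream on one day
#'
#' Reports every maximal interval between successive readings that is
#' strictly longer than `threshold`, including the edge intervals from
#' midnight to the first reading and from the last reading to the next
#' midnight (a sensor dying at 01:00 must be caught). A stream with zero
#' points that day yields no gaps — it is a missing sensor, not a gappy
#' one.
#'
#' @param store a [SensorStore-class].
#' @param stream stream path.
#' @param day UTC day (`Date`, `"YYYY-MM-DD"` or epoch seconds).
#' @param threshold gap threshold in seconds (> 0).
#' @return data.table: `stream`, `gap_start`, `gap_length` (seconds).
#' @aliases detectGaps
#' @export
setMethod("detectGaps", "SensorStore",
          function(store, stream, day, threshold) {
  stopifnot(threshold > 0)
  d0 <- dayStart(day)
  pts <- getRaw(store, stream, d0, d0 + 86400)
  empty <- data.table(stream = character(0), gap_start = numeric(0),
                      gap_length = numeric(0))
  if (nrow(pts) == 0L) return(empty)
  edges <- c(d0, pts$t, d0 + 86400)
  len <- diff(edges)
  hit <- len > threshold
  if (!any(hit)) return(empty)
  data.table(stream = stream, gap_start = edges[-length(edges)][hit],
             gap_length = len[hit])
})

#' Detect out-of-range readings in a stream on one day
#'
#' Flags every reading strictly below `minAllowed` or strictly above
#' `maxAllowed`. The scan is screened through the pre-computed windows:
#' the daily window's min/max is consulted first, then the 15-minute
#' windows, and raw points are read only inside 15-minute windows whose
#' extremes already prove a violation — a clean day touches no raw data.
#'
#' @param store a [SensorStore-class].
#' @param stream stream path.
#' @param day UTC day.
#' @param minAllowed,maxAllowed bounds (`minAllowed < maxAllowed`); values
#'   equal to a bound are in range.
#' @return data.table: `stream`, `timestamp`, `value`, `bound` (`"min"`
#'   or `"max"`).
#' @aliases detectRangeViolations
#' @export
setMethod("detectRangeViolations", "SensorStore",
          function(store, stream, day, minAllowed, maxAllowed) {
  stopifnot(minAllowed < maxAllowed)
  d0 <- dayStart(day)
  empty <- data.table(stream = character(0), timestamp = numeric(0),
                      value = numeric(0), bound = character(0))
  dayTab <- getWindowStats(store, stream, "day1", d0, d0 + 86400)
  if (nrow(dayTab) == 0L || sum(dayTab$count) == 0L) return(empty)
  if (min(dayTab$min) >= minAllowed && max(dayTab$max) <= maxAllowed)
    return(empty)
  qTab <- getWindowStats(store, stream, "min15", d0, d0 + 86400)
  flagged <- qTab[min < minAllowed | max > maxAllowed]
  if (nrow(flagged) == 0L) return(empty)
  out <- lapply(seq_len(nrow(flagged)), function(i) {
    w <- flagged[i]
    pts <- getRaw(store, stream, w$start, w$start + 900)
    pts[v < minAllowed | v > maxAllowed,
        .(stream = stream, timestamp = t, value = v,
          bound = fifelse(v < minAllowed, "min", "max"))]
  })
  res <- rbindlist(out)
  if (nrow(res) == 0L) empty else res[order(timestamp)]
})

#' Daily QC report for an experiment
#'
#' Runs the gap, range and missing-sensor detectors over every stream of
#' an experiment for one UTC day and aggregates the findings into a
#' [DiagnosticReport-class]. Streams with zero points that day appear
#' only under `missing_sensors`; detectors run deterministically in
#' stream-path order.
#'
#' @param store a [SensorStore-class].
#' @param experiment experiment path (`user/experiment`).
#' @param config a [diagnosticConfig()].
#' @return A [DiagnosticReport-class].
#' @aliases dailyReport
#' @export
setMethod("dailyReport", "SensorStore",
          function(store, experiment, config) {
  stopifnot(inherits(config, "DiagnosticConfig"))
  assertKind(store, experiment, "experiment")
  d0 <- config$day
  streams <- sort(unlist(lapply(listChildren(store, experiment),
                                function(nd) listChildren(store, nd))))
  gaps <- list()
  ranges <- list()
  missing <- character(0)
  for (s in streams) {
    dayTab <- getWindowStats(store, s, "day1", d0, d0 + 86400)
    if (nrow(dayTab) == 0L || sum(dayTab$count) == 0L) {
      missing <- c(missing, s)
      next
    }
    gaps[[s]] <- detectGaps(store, s, d0, config$gapThreshold)
    ranges[[s]] <- detectRangeViolations(store, s, d0, config$minAllowed,
                                         config$maxAllowed)
  }
  emptyGaps <- data.table(stream = character(0), gap_start = numeric(0),
                          gap_length = numeric(0))
  emptyRanges <- data.table(stream = character(0), timestamp = numeric(0),
                            value = numeric(0), bound = character(0))
  new("DiagnosticReport",
      experiment = experiment,
      day = d0,
      config = unclass(config),
      gap_errors = as.data.frame(
        if (length(gaps)) rbindlist(gaps) else emptyGaps),
      range_errors = as.data.frame(
        if (length(ranges)) rbindlist(ranges) else emptyRanges),
      missing_sensors = missing,
      generated_at = as.numeric(Sys.time()))
})

#' Render a diagnostic report
#'
#' @param report a [DiagnosticReport-class].
#' @return `reportToText`: character vector of report lines.
#'   `reportToJSON`: a JSON string; [reportFromJSON()] parses it back into
#'   an identical report.
#' @export
reportToText <- function(report) {
  stopifnot(is(report, "DiagnosticReport"))
  g <- report@gap_errors
  r <- report@range_errors
  lines <- c(
    sprintf("Diagnostic report for %s on %s (generated %s)",
            report@experiment, substr(isoTime(report@day), 1, 10),
            isoTime(report@generated_at)),
    sprintf("Gap errors (interval > %gs): %d",
            report@config$gapThreshold, nrow(g)))
  if (nrow(g))
    lines <- c(lines, sprintf("  %s: gap of %gs starting %s",
                              g$stream, g$gap_length, isoTime(g$gap_start)))
  lines <- c(lines, sprintf("Range errors (outside [%g, %g]): %d",
                            report@config$minAllowed,
                            report@config$maxAllowed, nrow(r)))
  if (nrow(r))
    lines <- c(lines, sprintf("  %s: value %g beyond %s bound at %s",
                              r$stream, r$value, r$bound,
                              isoTime(r$timestamp)))
  lines <- c(lines, sprintf("Missing sensors (no data that day): %d",
                            length(report@missing_sensors)))
  if (length(report@missing_sensors))
    lines <- c(lines, paste0("  ", report@missing_sensors))
  lines
}

#' @rdname reportToText
#' @export
reportToJSON <- function(report) {
  stopifnot(is(report, "DiagnosticReport"))
  g <- report@gap_errors
  r <- report@range_errors
  jsonlite::toJSON(list(
    experiment = report@experiment,
    day = substr(isoTime(report@day), 1, 10),
    config = report@config,
    gap_errors = data.frame(stream = g$stream,
                            gap_start = isoTime(g$gap_start),
                            gap_length = g$gap_length),
    range_errors = data.frame(stream = r$stream,
                              timestamp = isoTime(r$timestamp),
                              value = r$value, bound = r$bound),
    missing_sensors = report@missing_sensors,
    generated_at = isoTime(report@generated_at)),
    auto_unbox = TRUE, digits = NA)
}

#' @rdname reportToText
#' @param json a JSON string from [reportToJSON()].
#' @export
reportFromJSON <- function(json) {
  x <- jsonlite::fromJSON(json)
  g <- as.data.frame(x$gap_errors)
  r <- as.data.frame(x$range_errors)
  new("DiagnosticReport",
      experiment = x$experiment,
      day = dayStart(x$day),
      config = as.list(x$config),
      gap_errors = if (nrow(g))
        data.frame(stream = g$stream, gap_start = parseTime(g$gap_start),
                   gap_length = g$gap_length)
      else data.frame(stream = character(0), gap_start = numeric(0),
                      gap_length = numeric(0)),
      range_errors = if (nrow(r))
        data.frame(stream = r$stream, timestamp = parseTime(r$timestamp),
                   value = r$value, bound = r$bound)
      else data.frame(stream = character(0), timestamp = numeric(0),
                      value = numeric(0), bound = character(0)),
      missing_sensors = as.character(x$missing_sensors),
      generated_at = parseTime(x$generated_at))
}
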