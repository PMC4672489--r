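# CSV and batch ingestion (the manual-upload and script-upload paths).

#' Describe the layout of a CSV file of sensor readings
#'
#' A long-format CSV has one reading per row: a timestamp, a value and —
#' either in a column or fixed for the whole file — the stream the reading
#' belongs to, addressed by its `user/experiment/node/stream` path.
#' Exactly one of `streamCol` / `streamPath` must be given.
#'
#' @param timestampCol,valueCol column names for timestamp and value.
#' @param streamCol column holding the stream path, or `NULL`.
#' @param streamPath fixed stream path for every row, or `NULL`.
#' @param timestampFormat `"iso8601"` (also accepts `YYYY-MM-DD HH:MM:SS`)
#'   or `"epoch"` (seconds since the UTC epoch).
#' @param delimiter field separator (default `,`).
#' @param unit measurement unit used when streams are created on the fly.
#' @return A `CsvIngestSpec` list for [ingestCsv()].
#' @export
csvIngestSpec <- function(timestampCol = "timestamp", valueCol = "value",
                          streamCol = NULL, streamPath = NULL,
                          timestampFormat = c("iso8601", "epoch"),
                          delimiter = ",", unit = "") {
  if (is.null(streamCol) == is.null(streamPath))
    stop("exactly one of streamCol / streamPath must be set", call. = FALSE)
  structure(list(timestampCol = timestampCol, valueCol = valueCol,
                 streamCol = streamCol, streamPath = streamPath,
                 timestampFormat = match.arg(timestampFormat),
                 delimiter = delimiter, unit = unit),
            class = "CsvIngestSpec")
}

#' Ingest a CSV file of readings
#'
#' Parses the file under `spec`, appends every well-formed row to its
#' stream via [appendPoints()], and collects malformed rows (bad
#' timestamps, non-numeric values, unknown streams) with their line
#' numbers and reasons. With `createMissing = TRUE`, streams named by the
#' rows are created on the fly, along with any missing ancestors.
#'
#' @param store a [SensorStore-class].
#' @param path CSV file path.
#' @param spec a [csvIngestSpec()].
#' @param createMissing create referenced streams (and ancestors) that do
#'   not exist yet, instead of rejecting their rows.
#' @param duplicatePolicy passed to [appendPoints()].
#' @return List with `accepted`, `rejected`, a `bad_rows` data.table
#'   (line, reason; line numbers count the header), and `per_stream`, the
#'   per-stream [appendPoints()] reports.
#' @aliases ingestCsv
#' @export
setMethod("ingestCsv", "SensorStore",
          function(store, path, spec, createMissing = FALSE,
                   duplicatePolicy = "replace") {
  stopifnot(inherits(spec, "CsvIngestSpec"))
  raw <- fread(path, sep = spec$delimiter, colClasses = "character",
               header = TRUE, showProgress = FALSE)
  need <- c(spec$timestampCol, spec$valueCol, spec$streamCol)
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("CSV lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  n <- nrow(raw)
  line <- seq_len(n) + 1L  # header is line 1
  ts <- if (spec$timestampFormat == "epoch") {
    suppressWarnings(as.numeric(raw[[spec$timestampCol]]))
  } else {
    parseTime(raw[[spec$timestampCol]])
  }
  val <- suppressWarnings(as.numeric(raw[[spec$valueCol]]))
  sid <- if (is.null(spec$streamCol)) rep(spec$streamPath, n)
         else raw[[spec$streamCol]]

  bad <- data.table(line = integer(0), reason = character(0))
  badT <- is.na(ts) | ts != floor(ts)
  badV <- !badT & !is.finite(val)
  if (any(badT)) bad <- rbind(bad, data.table(line = line[badT],
                                              reason = "bad timestamp"))
  if (any(badV)) bad <- rbind(bad, data.table(line = line[badV],
                                              reason = "non-finite value"))
  keep <- !badT & !badV

  isStreamPath <- function(id)
    length(strsplit(id, "/", fixed = TRUE)[[1L]]) == 4L
  known <- logical(n)
  for (s in unique(sid[keep])) {
    rows <- keep & sid == s
    if (!entityExists(store, s) || !isStreamPath(s)) {
      if (createMissing && isStreamPath(s)) {
        ensureStreamPath(store, s, unit = spec$unit)
      } else {
        bad <- rbind(bad, data.table(line = line[rows],
                                     reason = "no such stream"))
        next
      }
    }
    known <- known | rows
  }

  perStream <- list()
  for (s in unique(sid[known])) {
    rows <- known & sid == s
    perStream[[s]] <- appendPoints(store, s,
                                   data.table(t = ts[rows], v = val[rows]),
                                   duplicatePolicy = duplicatePolicy)
  }
  accepted <- sum(vapply(perStream, `[[`, 0, "accepted"))
  inRejected <- sum(vapply(perStream, `[[`, 0, "rejected"))
  list(accepted = accepted,
       rejected = nrow(bad) + inRejected,
       bad_rows = bad[order(line)],
       per_stream = perStream)
})

ensureStreamPath <- function(store, streamId, unit = "") {
  parts <- strsplit(streamId, "/", fixed = TRUE)[[1L]]
  stopifnot(length(parts) == 4L)
  for (depth in 1:4) {
    id <- paste(parts[seq_len(depth)], collapse = "/")
    if (!entityExists(store, id)) {
      parent <- if (depth == 1L) NULL
                else paste(parts[seq_len(depth - 1L)], collapse = "/")
      attrs <- if (depth == 4L) list(unit = unit) else list()
      createEntity(store, ENTITY_KINDS[depth], parts[depth], parent, attrs)
    }
  }
  invisible(streamId)
}

#' Upload points to a stream in fixed-size chunks
#'
#' Script/batch upload path: splits `points` into chunks of `chunkSize`
#' and appends each via [appendPoints()]. Chunking is invisible in the
#' final state — any chunk size yields the same raw data and window
#' summaries as a single append.
#'
#' @param store a [SensorStore-class].
#' @param stream stream path.
#' @param points as for [appendPoints()].
#' @param chunkSize points per request (>= 1); the write-benchmark shape
#'   of the original system used blocks of 100.
#' @param duplicatePolicy passed to [appendPoints()].
#' @return Combined ingest report (accepted, rejected, windows_touched,
#'   reasons, chunks).
#' @aliases batchUpload
#' @export
setMethod("batchUpload", "SensorStore",
          function(store, stream, points, chunkSize = 100L,
                   duplicatePolicy = "replace") {
  stopifnot(chunkSize >= 1L)
  pts <- as.data.table(points)
  n <- nrow(pts)
  streamRecord(store, stream)
  if (n == 0L)
    return(list(accepted = 0L, rejected = 0L, windows_touched = 0L,
                reasons = data.table(row = integer(0), t = numeric(0),
                                     reason = character(0)),
                chunks = 0L))
  starts <- seq(1L, n, by = chunkSize)
  reports <- lapply(starts, function(i) {
    appendPoints(store, stream, pts[i:min(i + chunkSize - 1L, n)],
                 duplicatePolicy = duplicatePolicy)
  })
  list(accepted = sum(vapply(reports, `[[`, 0, "accepted")),
       rejected = sum(vapply(reports, `[[`, 0, "rejected")),
       windows_touched = sum(vapply(reports, `[[`, 0, "windows_touched")),
       reasons = rbindlist(lapply(reports, `[[`, "reasons")),
       chunks = length(starts))
})

#' Write query results as CSV
#'
#' Renders aggregated window rows (from [getWindowStats()]) or raw points
#' (from [getRaw()]) in the download format: aggregated columns are
#' `stream,level,window_start,count,mean,std,min,min_time,max,max_time,
#' last,last_time`; raw columns are `stream,timestamp,value`. Timestamps
#' are ISO-8601 UTC.
#'
#' @param x a data.table from [getWindowStats()] or [getRaw()].
#' @param stream the stream path the rows belong to.
#' @param level the queried level (`"raw"` for raw points).
#' @param file output path, or `""` for stdout.
#' @return The written data.frame, invisibly.
#' @export
writeQueryCsv <- function(x, stream, level, file = "") {
  if (identical(level, "raw")) {
    out <- data.frame(stream = rep(stream, nrow(x)),
                      timestamp = isoTime(x$t), value = x$v)
  } else {
    lvl <- matchLevel(level)
    out <- data.frame(stream = rep(stream, nrow(x)),
                      level = API_LEVEL_NAMES[[lvl]],
                      window_start = isoTime(x$start),
                      count = x$count, mean = x$mean, std = x$std,
                      min = x$min, min_time = isoTime(x$min_time),
                      max = x$max, max_time = isoTime(x$max_time),
                      last = x$last, last_time = isoTime(x$last_time))
  }
  fwrite(out, file)
  invisible(out)
}
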