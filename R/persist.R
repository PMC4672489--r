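# JSON-lines persistence. Layout:
#   <dir>/entities.jsonl                 one record per entity
#   <dir>/data/<stream-id>.jsonl         {"t": ISO-8601 UTC, "v": value}
#   <dir>/agg/<stream-id>.<level>.jsonl  one record per window
# Stream identifiers are slash-joined paths; "/" maps to "@" in file names
# ("@" cannot occur in entity names). Raw files are written sorted by
# timestamp. On load, window summaries are cross-checked against the raw
# point count and rebuilt from raw on mismatch (or when the files are
# absent), so the raw files alone are sufficient to restore a store.

encodeStreamFile <- function(id) gsub("/", "@", id, fixed = TRUE)

#' Persist a store to a directory of JSON-lines files
#'
#' Writes the entity tree, every stream's raw points (sorted, ISO-8601
#' timestamps) and every window-summary table as plain-text JSON-lines.
#' The format is transparent and diff-able; [loadStore()] restores an
#' identical store.
#'
#' @param store a [SensorStore-class].
#' @param dir target directory (created if needed).
#' @return `dir`, invisibly.
#' @aliases saveStore
#' @export
setMethod("saveStore", "SensorStore", function(store, dir) {
  dir.create(file.path(dir, "data"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "agg"), recursive = TRUE, showWarnings = FALSE)

  ids <- ls(store@env$entities, all.names = TRUE)
  depth <- lengths(strsplit(ids, "/", fixed = TRUE))
  ids <- ids[order(depth, ids)]
  lines <- vapply(ids, function(id) {
    rec <- store@env$entities[[id]]
    jsonlite::toJSON(list(kind = rec$kind, name = rec$name,
                          parent = rec$parent, attrs = rec$attrs,
                          metadata = rec$metadata),
                     auto_unbox = TRUE, null = "null", digits = NA)
  }, character(1))
  writeLines(lines, file.path(dir, "entities.jsonl"))

  for (sid in ls(store@env$streams, all.names = TRUE)) {
    rec <- store@env$streams[[sid]]
    enc <- encodeStreamFile(sid)
    # %.17g decimals round-trip IEEE doubles exactly
    writeLines(
      sprintf('{"t":"%s","v":%.17g}', isoTime(rec$raw$t), rec$raw$v),
      file.path(dir, "data", paste0(enc, ".jsonl")))
    for (lvl in WINDOW_LEVELS) {
      tab <- rec$agg[[lvl]]
      writeLines(
        sprintf(paste0(
          '{"level":"%s","start":"%s","count":%d,"mean":%.17g,',
          '"std":%.17g,"m2":%.17g,"min":%.17g,"min_time":"%s",',
          '"max":%.17g,"max_time":"%s","last":%.17g,"last_time":"%s"}'),
          API_LEVEL_NAMES[[lvl]], isoTime(tab$start), as.integer(tab$count),
          tab$mean, sqrt(tab$m2 / tab$count), tab$m2,
          tab$min, isoTime(tab$min_time),
          tab$max, isoTime(tab$max_time),
          tab$last, isoTime(tab$last_time)),
        file.path(dir, "agg", paste0(enc, ".", lvl, ".jsonl")))
    }
  }
  invisible(dir)
})

streamInJsonl <- function(path) {
  if (!file.exists(path) || file.size(path) == 0) return(NULL)
  con <- file(path, open = "rb")
  on.exit(close(con))
  jsonlite::stream_in(con, verbose = FALSE)
}

#' Load a store persisted with saveStore
#'
#' Entities are re-created through the normal constructors (so hierarchy
#' invariants are re-validated), raw points are re-attached, and window
#' summaries are taken from the persisted tables when their point counts
#' reconcile with raw — otherwise they are rebuilt from the raw points.
#'
#' @param dir directory written by [saveStore()].
#' @return A [SensorStore-class].
#' @export
loadStore <- function(dir) {
  store <- SensorStore()
  epath <- file.path(dir, "entities.jsonl")
  if (!file.exists(epath)) stop("not a store directory: ", dir, call. = FALSE)
  for (line in readLines(epath)) {
    rec <- jsonlite::fromJSON(line, simplifyVector = FALSE)
    id <- createEntity(store, rec$kind, rec$name,
                       parent = rec$parent, attrs = rec$attrs)
    for (k in names(rec$metadata))
      setMetadata(store, id, k, rec$metadata[[k]])
  }
  for (sid in ls(store@env$streams, all.names = TRUE)) {
    enc <- encodeStreamFile(sid)
    rawDf <- streamInJsonl(file.path(dir, "data", paste0(enc, ".jsonl")))
    if (is.null(rawDf) || nrow(rawDf) == 0L) next
    raw <- data.table(t = parseTime(rawDf$t), v = as.numeric(rawDf$v))
    setkey(raw, t)
    rec <- store@env$streams[[sid]]
    rec$raw <- raw
    agg <- list()
    ok <- TRUE
    for (lvl in WINDOW_LEVELS) {
      df <- streamInJsonl(file.path(dir, "agg", paste0(enc, ".", lvl,
                                                       ".jsonl")))
      if (is.null(df) || sum(df$count) != nrow(raw)) {
        ok <- FALSE
        break
      }
      tab <- data.table(start = parseTime(df$start),
                        count = as.integer(df$count),
                        mean = as.numeric(df$mean), m2 = as.numeric(df$m2),
                        min = as.numeric(df$min),
                        min_time = parseTime(df$min_time),
                        max = as.numeric(df$max),
                        max_time = parseTime(df$max_time),
                        last = as.numeric(df$last),
                        last_time = parseTime(df$last_time))
      setkey(tab, start)
      agg[[lvl]] <- tab
    }
    if (!ok)
      agg <- sapply(WINDOW_LEVELS,
                    function(lvl) batchStatsTable(raw$t, raw$v, lvl),
                    simplify = FALSE)
    rec$agg <- agg
    store@env$streams[[sid]] <- rec
  }
  store
}
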