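# Append-oriented time-series storage. Raw points live in a keyed
# data.table per stream; every append updates all seven window levels
# incrementally by computing single-pass partial summaries of the batch per
# window and merging them into the stored rows (the mergeability contract
# makes this exact). Aggregated reads never touch raw points; a touch
# counter instruments both paths so the pre-aggregation contract is
# testable.

streamRecord <- function(store, stream) {
  rec <- store@env$streams[[stream]]
  if (is.null(rec)) stop("no such stream: ", stream, call. = FALSE)
  rec
}

#' Append data points to a stream
#'
#' Validates, stores and aggregates a batch of points in one atomic
#' operation: on any error the store is unchanged. Rows with non-finite
#' values or malformed timestamps are rejected individually (with
#' reasons), not fatal. Out-of-order batches are fully supported: window
#' summaries do not depend on arrival order.
#'
#' Duplicate timestamps within a stream are resolved by `duplicatePolicy`:
#' `"replace"` (default) keeps the newest write and rebuilds the affected
#' 1-minute windows from raw before re-merging every coarser level;
#' `"reject"` refuses the colliding rows and reports them.
#'
#' @param store a [SensorStore-class].
#' @param stream stream path.
#' @param points a data.frame (or data.table) with columns `t` (UTC epoch
#'   seconds, integral) and `v` (numeric), or a list with those elements.
#' @param duplicatePolicy `"replace"` or `"reject"`.
#' @return An ingest report: list with `accepted`, `rejected`,
#'   `windows_touched` and a `reasons` data.table (row, t, reason) for the
#'   rejected rows.
#' @aliases appendPoints
#' @export
setMethod("appendPoints", "SensorStore",
          function(store, stream, points,
                   duplicatePolicy = c("replace", "reject")) {
  duplicatePolicy <- match.arg(duplicatePolicy)
  rec <- streamRecord(store, stream)
  if (!all(c("t", "v") %in% names(points)))
    stop("points must have columns t and v", call. = FALSE)
  pts <- data.table(t = as.numeric(points[["t"]]),
                    v = as.numeric(points[["v"]]),
                    row = seq_along(points[["t"]]))

  reasonList <- list()
  badT <- !is.finite(pts$t) | pts$t != floor(pts$t)
  badV <- !badT & !is.finite(pts$v)
  if (any(badT))
    reasonList <- c(reasonList,
                    list(pts[badT, .(row, t, reason = "bad timestamp")]))
  if (any(badV))
    reasonList <- c(reasonList,
                    list(pts[badV,
                             .(row, t, reason = "non-finite value rejected")]))
  if (any(badT | badV)) pts <- pts[!badT & !badV]

  # duplicates inside the batch: last write wins under replace,
  # first wins under reject
  if (anyDuplicated(pts$t)) {
    dup <- if (duplicatePolicy == "replace") duplicated(pts$t, fromLast = TRUE)
           else duplicated(pts$t)
    reasonList <- c(reasonList,
                    list(pts[dup, .(row, t, reason = "duplicate timestamp")]))
    pts <- pts[!dup]
  }

  raw <- rec$raw
  collides <- if (nrow(raw)) pts$t %in% raw$t else rep(FALSE, nrow(pts))
  if (duplicatePolicy == "reject" && any(collides)) {
    reasonList <- c(reasonList,
                    list(pts[collides,
                             .(row, t, reason = "duplicate timestamp")]))
    pts <- pts[!collides]
    collides <- rep(FALSE, nrow(pts))
  }

  touched <- 0L
  if (nrow(pts) == 0L) {
    newRaw <- raw
    newAgg <- rec$agg
  } else if (!any(collides)) {
    # pure-append fast path: single-pass partials per level, merged in
    newRaw <- rbind(raw, pts[, .(t, v)])
    setkey(newRaw, t)
    newAgg <- rec$agg
    for (lvl in WINDOW_LEVELS) {
      part <- batchStatsTable(pts$t, pts$v, lvl)
      touched <- touched + nrow(part)
      newAgg[[lvl]] <- mergeStatsTables(newAgg[[lvl]], part)
    }
  } else {
    # replacements present: apply raw edits, then rebuild the affected
    # 1-minute windows from raw and re-merge each coarser level from its
    # children ("un-updating" min/max incrementally is ill-defined)
    newRaw <- copy(raw)
    repl <- pts[collides]
    newRaw[.(repl$t), v := repl$v]
    adds <- pts[!collides]
    if (nrow(adds)) {
      newRaw <- rbind(newRaw, adds[, .(t, v)])
      setkey(newRaw, t)
    }
    rebuilt <- rebuildWindows(newRaw, rec$agg,
                              unique(windowStart(pts$t, "min1")))
    newAgg <- rebuilt$agg
    touched <- rebuilt$touched
  }

  rec$raw <- newRaw
  rec$agg <- newAgg
  store@env$streams[[stream]] <- rec
  reasons <- if (length(reasonList)) {
    rl <- rbindlist(reasonList)
    rl[order(row)]
  } else {
    data.table(row = integer(0), t = numeric(0), reason = character(0))
  }
  list(accepted = nrow(pts), rejected = nrow(reasons),
       windows_touched = touched, reasons = reasons)
})

# Recompute the given min1 windows from raw, then re-merge every ancestor
# window (min15 from min1, ..., year1 from month1, overall from year1).
rebuildWindows <- function(raw, agg, min1Starts) {
  agg <- lapply(agg, copy)
  touched <- 0L
  affected <- sort(min1Starts)
  sub <- raw[t >= min(affected) & t < max(affected) + 60]
  sub <- sub[windowStart(t, "min1") %in% affected]
  fresh <- batchStatsTable(sub$t, sub$v, "min1")
  tab <- agg[["min1"]][!start %in% affected]
  agg[["min1"]] <- rbindlist(list(tab, fresh))
  setkey(agg[["min1"]], start)
  touched <- touched + nrow(fresh)

  child <- "min1"
  childAffected <- affected
  while (child != "overall") {
    parent <- LEVEL_PARENT[[child]]
    pAffected <- sort(unique(windowStart(childAffected, parent)))
    pEnd <- windowNext(pAffected, parent)
    ctab <- agg[[child]]
    rows <- lapply(seq_along(pAffected), function(i) {
      kids <- ctab[start >= pAffected[i] & start < pEnd[i]]
      cbind(data.table(start = pAffected[i]), foldStatsTable(kids))
    })
    fresh <- rbindlist(rows)
    fresh <- fresh[count > 0L]
    keep <- agg[[parent]][!start %in% pAffected]
    agg[[parent]] <- rbindlist(list(keep, fresh))
    setkey(agg[[parent]], start)
    touched <- touched + nrow(fresh)
    child <- parent
    childAffected <- pAffected
  }
  list(agg = agg, touched = touched)
}

#' Read raw points of a stream over a half-open time range
#'
#' Returns exactly the points with `from <= t < to`, ascending by
#' timestamp (regardless of ingest order). Every point returned counts
#' toward the store's `raw_records_read` touch counter.
#'
#' @param store a [SensorStore-class].
#' @param stream stream path.
#' @param from,to UTC epoch seconds; `from` must not exceed `to`.
#' @return data.table with columns `t`, `v`.
#' @aliases getRaw
#' @export
setMethod("getRaw", "SensorStore",
          function(store, stream, from = 0, to = Inf) {
  rec <- streamRecord(store, stream)
  if (from > to) stop("empty range: from exceeds to", call. = FALSE)
  out <- rec$raw[t >= from & t < to]
  ctr <- store@env$counters
  ctr$raw_records_read <- ctr$raw_records_read + nrow(out)
  out[]
})

#' Read pre-computed window statistics of a stream
#'
#' Returns all windows at `level` whose start lies in `[from, to)`,
#' ascending. This reads only summary rows — the raw-record touch counter
#' is untouched, which is the pre-aggregation contract that keeps query
#' cost independent of stream length.
#'
#' @param store a [SensorStore-class].
#' @param stream stream path.
#' @param level a summary level (see [windowLevels()]); `raw` is an error —
#'   use [getRaw()].
#' @param from,to window-start range (UTC epoch seconds), half-open. Note
#'   the `overall` window sits at sentinel start 0.
#' @return data.table with columns `start`, `count`, `mean`, `std`
#'   (population), `min`, `min_time`, `max`, `max_time`, `last`,
#'   `last_time`, and the mergeable accumulator `m2`.
#' @aliases getWindowStats
#' @export
setMethod("getWindowStats", "SensorStore",
          function(store, stream, level, from = 0, to = Inf) {
  rec <- streamRecord(store, stream)
  level <- matchLevel(level)
  if (from > to) stop("empty range: from exceeds to", call. = FALSE)
  tab <- rec$agg[[level]][start >= from & start < to]
  ctr <- store@env$counters
  ctr$summary_records_read <- ctr$summary_records_read + nrow(tab)
  decorateStats(tab)
})

decorateStats <- function(tab) {
  out <- copy(tab)
  out[, std := sqrt(m2 / count)]
  setcolorder(out, c("start", "count", "mean", "std", "min", "min_time",
                     "max", "max_time", "last", "last_time", "m2"))
  out[]
}

#' Per-level overview of a stream
#'
#' One row per aggregation level (including `raw`, which mirrors the
#' all-time `overall` window): count, mean, population standard deviation,
#' min/max with occurrence times, and the last value/timestamp. Each row
#' equals the merge of every stored window at that level; no raw points
#' are read.
#'
#' @param store a [SensorStore-class].
#' @param stream stream path.
#' @return data.table with one row per level.
#' @aliases streamSummary
#' @export
setMethod("streamSummary", "SensorStore", function(store, stream) {
  rec <- streamRecord(store, stream)
  ctr <- store@env$counters
  rows <- lapply(WINDOW_LEVELS, function(lvl) {
    tab <- rec$agg[[lvl]]
    ctr$summary_records_read <- ctr$summary_records_read + nrow(tab)
    cbind(data.table(level = lvl), foldStatsTable(tab))
  })
  overall <- rows[[match("overall", WINDOW_LEVELS)]]
  rawRow <- copy(overall)[, level := "raw"]
  out <- rbindlist(c(list(rawRow), rows))
  out[, std := fifelse(count > 0L, sqrt(m2 / count), NA_real_)]
  setcolorder(out, c("level", "count", "mean", "std", "min", "min_time",
                     "max", "max_time", "last", "last_time", "m2"))
  out[]
})

#' Touch counters: instrumentation of raw vs summary reads
#'
#' The store counts every raw point and every summary row its read paths
#' return. These counters make the pre-aggregation contract observable:
#' [getWindowStats()] never increments `raw_records_read`, and the
#' operation-count benchmark ([runLatencyBenchmark()]) is built on them.
#'
#' @param store a [SensorStore-class].
#' @return `touchCounter` returns `list(raw_records_read,
#'   summary_records_read)`; `resetTouchCounter` zeroes both, invisibly.
#' @rdname touchCounter
#' @aliases touchCounter
#' @export
setMethod("touchCounter", "SensorStore", function(store) {
  list(raw_records_read = store@env$counters$raw_records_read,
       summary_records_read = store@env$counters$summary_records_read)
})

#' @rdname touchCounter
#' @aliases resetTouchCounter
#' @export
setMethod("resetTouchCounter", "SensorStore", function(store) {
  store@env$counters$raw_records_read <- 0
  store@env$counters$summary_records_read <- 0
  invisible(store)
})
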