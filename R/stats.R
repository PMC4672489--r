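# Mergeable window statistics.
#
# Every window carries (count, mean, m2, min/min_time, max/max_time,
# last/last_time) where m2 is the sum of squared deviations from the mean.
# Storing m2 rather than a standard deviation makes summaries exactly
# mergeable across disjoint partitions (the parallel moment combination),
# which is what lets batch ingest, hierarchical rollup and partitioned
# processing all agree with a single sequential pass. Standard deviation is
# derived on read.

STATS_COLS <- c("count", "mean", "m2", "min", "min_time", "max", "max_time",
                "last", "last_time")

#' Empty window statistics accumulator
#'
#' @return A `WindowStats` object with `count = 0`; all other fields are
#'   `NA` until the first update.
#' @seealso [statsUpdate()], [statsMerge()], [statsStd()]
#' @export
statsNew <- function() {
  structure(list(count = 0L, mean = NA_real_, m2 = NA_real_,
                 min = NA_real_, min_time = NA_real_,
                 max = NA_real_, max_time = NA_real_,
                 last = NA_real_, last_time = NA_real_),
            class = "WindowStats")
}

#' Update window statistics with one data point
#'
#' Single-pass (Welford) moment update: the count increments, mean and m2
#' follow the numerically stable recurrence, min/max track the extreme
#' values with the earliest occurrence time on ties, and `last` tracks the
#' point with the greatest data timestamp seen so far — not the most recent
#' arrival, so out-of-order ingest is well defined.
#'
#' @param s a `WindowStats` from [statsNew()] or a previous update.
#' @param t UTC timestamp (seconds since epoch) of the point.
#' @param v finite numeric value.
#' @return The updated `WindowStats`.
#' @examples
#' s <- statsUpdate(statsNew(), 0, 5)
#' s$count  # 1
#' @export
statsUpdate <- function(s, t, v) {
  stopifnot(inherits(s, "WindowStats"))
  if (!is.finite(v)) stop("non-finite value rejected", call. = FALSE)
  if (s$count == 0L) {
    s$count <- 1L
    s$mean <- v
    s$m2 <- 0
    s$min <- s$max <- s$last <- v
    s$min_time <- s$max_time <- s$last_time <- t
    return(s)
  }
  s$count <- s$count + 1L
  delta <- v - s$mean
  s$mean <- s$mean + delta / s$count
  s$m2 <- s$m2 + delta * (v - s$mean)
  if (v < s$min || (v == s$min && t < s$min_time)) {
    s$min <- v
    s$min_time <- t
  }
  if (v > s$max || (v == s$max && t < s$max_time)) {
    s$max <- v
    s$max_time <- t
  }
  if (t > s$last_time) {
    s$last <- v
    s$last_time <- t
  }
  s
}

#' Merge two window statistics over disjoint point sets
#'
#' Exact parallel combination of two accumulators: counts add, mean/m2
#' combine with the pairwise update, min/max keep the extreme with the
#' earliest occurrence time on ties, and `last` comes from the operand with
#' the greater last timestamp. The empty accumulator is the identity.
#'
#' @param a,b `WindowStats` objects summarising disjoint point multisets.
#' @return The `WindowStats` of the union.
#' @export
statsMerge <- function(a, b) {
  stopifnot(inherits(a, "WindowStats"), inherits(b, "WindowStats"))
  if (a$count == 0L) return(b)
  if (b$count == 0L) return(a)
  n <- a$count + b$count
  delta <- b$mean - a$mean
  takeMinA <- a$min < b$min || (a$min == b$min && a$min_time <= b$min_time)
  takeMaxA <- a$max > b$max || (a$max == b$max && a$max_time <= b$max_time)
  takeLastA <- a$last_time >= b$last_time
  structure(list(
    count = n,
    mean = a$mean + delta * b$count / n,
    m2 = max(a$m2 + b$m2 + delta^2 * (a$count / n) * b$count, 0),
    min = if (takeMinA) a$min else b$min,
    min_time = if (takeMinA) a$min_time else b$min_time,
    max = if (takeMaxA) a$max else b$max,
    max_time = if (takeMaxA) a$max_time else b$max_time,
    last = if (takeLastA) a$last else b$last,
    last_time = if (takeLastA) a$last_time else b$last_time),
    class = "WindowStats")
}

#' Standard deviation of a window
#'
#' @param s a `WindowStats`, or a data.frame of window rows with `count`
#'   and `m2` columns (vectorised).
#' @param mode `"population"` (divide by n, the default) or `"sample"`
#'   (divide by n - 1).
#' @return Numeric standard deviation(s). Errors with "undefined std" when
#'   the count is insufficient (population needs n >= 1, sample n >= 2).
#' @export
statsStd <- function(s, mode = c("population", "sample")) {
  mode <- match.arg(mode)
  if (inherits(s, "WindowStats")) {
    n <- s$count
    m2 <- s$m2
  } else {
    n <- s$count
    m2 <- s$m2
  }
  need <- if (mode == "population") 1L else 2L
  if (any(n < need)) stop("undefined std", call. = FALSE)
  sqrt(m2 / (if (mode == "population") n else n - 1L))
}

#' @export
print.WindowStats <- function(x, ...) {
  if (x$count == 0L) {
    cat("WindowStats: empty\n")
  } else {
    cat(sprintf(
      "WindowStats: n=%d mean=%.6g sd=%.6g min=%.6g@%s max=%.6g@%s last=%.6g@%s\n",
      x$count, x$mean, sqrt(x$m2 / x$count),
      x$min, isoTime(x$min_time), x$max, isoTime(x$max_time),
      x$last, isoTime(x$last_time)))
  }
  invisible(x)
}

# ---- internal table machinery --------------------------------------------
# Window summaries of a stream are stored per level as a data.table keyed by
# window start, with the STATS_COLS columns.

emptyStatsTable <- function() {
  tab <- data.table(start = numeric(0), count = integer(0),
                    mean = numeric(0), m2 = numeric(0),
                    min = numeric(0), min_time = numeric(0),
                    max = numeric(0), max_time = numeric(0),
                    last = numeric(0), last_time = numeric(0))
  setkey(tab, start)
  tab
}

# Incremental single-pass stats of a batch of points, grouped by window.
# Points are processed in the order given (arrival order).
batchStatsTable <- function(t, v, level) {
  if (length(t) == 0L) return(emptyStatsTable())
  starts <- windowStart(t, level)
  u <- sort(unique(starts))
  g <- match(starts, u)
  acc <- .groupWelford(as.integer(g), as.numeric(t), as.numeric(v),
                       length(u))
  tab <- data.table(start = u, count = acc$count, mean = acc$mean,
                    m2 = acc$m2, min = acc$min, min_time = acc$min_time,
                    max = acc$max, max_time = acc$max_time,
                    last = acc$last, last_time = acc$last_time)
  setkey(tab, start)
  tab
}

# Vectorised pairwise combination of aligned one-row-per-window tables.
# x and y must have the same number of rows (row i of x merges with row i
# of y); both counts must be >= 1.
combineStatsRows <- function(x, y) {
  n <- x$count + y$count
  delta <- y$mean - x$mean
  mean <- x$mean + delta * y$count / n
  m2 <- x$m2 + y$m2 + delta^2 * (x$count / n) * y$count
  takeMinX <- x$min < y$min | (x$min == y$min & x$min_time <= y$min_time)
  takeMaxX <- x$max > y$max | (x$max == y$max & x$max_time <= y$max_time)
  takeLastX <- x$last_time >= y$last_time
  data.table(
    count = n, mean = mean, m2 = pmax(m2, 0),
    min = fifelse(takeMinX, x$min, y$min),
    min_time = fifelse(takeMinX, x$min_time, y$min_time),
    max = fifelse(takeMaxX, x$max, y$max),
    max_time = fifelse(takeMaxX, x$max_time, y$max_time),
    last = fifelse(takeLastX, x$last, y$last),
    last_time = fifelse(takeLastX, x$last_time, y$last_time))
}

# Merge two keyed stats tables window-by-window (union of window starts).
mergeStatsTables <- function(a, b) {
  if (nrow(a) == 0L) return(copy(b))
  if (nrow(b) == 0L) return(copy(a))
  ia <- match(b$start, a$start)
  hit <- !is.na(ia)
  if (!any(hit)) {
    out <- rbindlist(list(a, b))
  } else {
    x <- a[ia[hit]]
    y <- b[which(hit)]
    merged <- cbind(data.table(start = y$start), combineStatsRows(x, y))
    out <- rbindlist(list(a[-ia[hit]], b[which(!hit)], merged))
  }
  setkey(out, start)
  out
}

# Fold all rows of a stats table into a single combined row (closed-form
# multiway moment combination; equals iterated pairwise merging).
foldStatsTable <- function(tab) {
  if (nrow(tab) == 0L)
    return(data.table(count = 0L, mean = NA_real_, m2 = NA_real_,
                      min = NA_real_, min_time = NA_real_,
                      max = NA_real_, max_time = NA_real_,
                      last = NA_real_, last_time = NA_real_))
  n <- sum(tab$count)
  gm <- sum(tab$count * tab$mean) / n
  m2 <- sum(tab$m2) + sum(tab$count * (tab$mean - gm)^2)
  imin <- which(tab$min == min(tab$min))
  imin <- imin[which.min(tab$min_time[imin])]
  imax <- which(tab$max == max(tab$max))
  imax <- imax[which.min(tab$max_time[imax])]
  ilast <- which.max(tab$last_time)
  data.table(count = n, mean = gm, m2 = max(m2, 0),
             min = tab$min[imin], min_time = tab$min_time[imin],
             max = tab$max[imax], max_time = tab$max_time[imax],
             last = tab$last[ilast], last_time = tab$last_time[ilast])
}
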