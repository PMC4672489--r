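# Aggregation windows: eight levels, of which "raw" is pass-through and the
# other seven carry summary rows. Sub-day levels are fixed spans counted
# from the UTC epoch; month/year follow the UTC calendar; "overall" is a
# single window with sentinel start 0. All windows are half-open
# [start, nextStart).

#' Aggregation window levels
#'
#' The eight aggregation levels maintained per stream: `raw` (no summary
#' rows), `min1`, `min15`, `hour1`, `day1` (epoch-aligned fixed spans of
#' 60, 900, 3600 and 86400 s), `min15`, `month1` and `year1` (UTC-calendar
#' aligned) and `overall` (one all-time window, sentinel start 0).
#'
#' @return `windowLevels()` returns the seven summary level names in
#'   ascending span order (raw excluded).
#' @export
windowLevels <- function() WINDOW_LEVELS

WINDOW_LEVELS <- c("min1", "min15", "hour1", "day1", "month1", "year1",
                   "overall")
LEVEL_SPANS <- c(min1 = 60, min15 = 900, hour1 = 3600, day1 = 86400)

# External (API/CLI) spellings of each level.
API_LEVEL_NAMES <- c(
  raw = "raw", min1 = "1-min", min15 = "15-min", hour1 = "1-hour",
  day1 = "1-day", month1 = "1-month", year1 = "1-year", overall = "overall")

matchLevel <- function(level, allowRaw = FALSE) {
  stopifnot(is.character(level), length(level) == 1L)
  if (level %in% names(API_LEVEL_NAMES) == FALSE) {
    hit <- names(API_LEVEL_NAMES)[match(level, API_LEVEL_NAMES)]
    if (is.na(hit)) stop("bad level: ", level, call. = FALSE)
    level <- hit
  }
  if (level == "raw" && !allowRaw)
    stop("raw has no windows", call. = FALSE)
  level
}

#' Window start of a timestamp at an aggregation level
#'
#' Maps UTC timestamps (seconds since epoch) to the start of the enclosing
#' window. Sub-day levels truncate to the enclosing 60 / 900 / 3600 /
#' 86400 s boundary counted from the epoch; `month1` and `year1` truncate to
#' the first instant of the enclosing UTC calendar month / year; `overall`
#' maps everything to the sentinel start 0. Windows are half-open
#' `[start, windowNext(start, level))`.
#'
#' @param t numeric vector of UTC timestamps (seconds since epoch).
#' @param level one of `min1`, `min15`, `hour1`, `day1`, `month1`, `year1`,
#'   `overall` (or the external spellings `1-min`, ..., `overall`). `raw`
#'   is an error: raw data has no windows.
#' @return numeric vector of window starts, same length as `t`.
#' @examples
#' iso <- function(s) as.numeric(as.POSIXct(s, tz = "UTC"))
#' windowStart(iso("2015-06-15 10:37:45"), "hour1")  # 2015-06-15 10:00:00
#' @export
windowStart <- function(t, level) {
  level <- matchLevel(level)
  if (level %in% names(LEVEL_SPANS)) {
    span <- LEVEL_SPANS[[level]]
    return((t %/% span) * span)
  }
  if (level == "overall") return(rep(0, length(t)))
  # calendar levels: truncate via POSIXlt on the distinct days only
  d <- t %/% 86400
  ud <- unique(d)
  lt <- as.POSIXlt(ud * 86400, origin = "1970-01-01", tz = "UTC")
  lt$sec <- 0
  lt$min <- 0L
  lt$hour <- 0L
  lt$mday <- 1L
  if (level == "year1") lt$mon <- 0L
  starts <- as.numeric(as.POSIXct(lt))
  starts[match(d, ud)]
}

#' @rdname windowStart
#' @param start numeric vector of window starts (as returned by
#'   `windowStart`).
#' @return `windowNext` returns the start of the following window (the
#'   exclusive end of each half-open window); `Inf` for `overall`.
#' @export
windowNext <- function(start, level) {
  level <- matchLevel(level)
  if (level %in% names(LEVEL_SPANS)) return(start + LEVEL_SPANS[[level]])
  if (level == "overall") return(rep(Inf, length(start)))
  lt <- as.POSIXlt(start, origin = "1970-01-01", tz = "UTC")
  if (level == "month1") lt$mon <- lt$mon + 1L else lt$year <- lt$year + 1L
  as.numeric(as.POSIXct(lt))
}

# Parent level used when re-merging summaries upward after a rebuild.
LEVEL_PARENT <- c(min1 = "min15", min15 = "hour1", hour1 = "day1",
                  day1 = "month1", month1 = "year1", year1 = "overall")

isoTime <- function(t) {
  out <- rep(NA_character_, length(t))
  ok <- is.finite(t)
  out[ok] <- format(as.POSIXct(t[ok], origin = "1970-01-01", tz = "UTC"),
                    "%Y-%m-%dT%H:%M:%SZ")
  out
}

# Accepts ISO-8601 UTC strings or (string/numeric) epoch seconds.
parseTime <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- as.character(x)
  out <- suppressWarnings(as.numeric(x))
  for (fmt in c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS",
                "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d")) {
    need <- is.na(out) & !is.na(x)
    if (!any(need)) break
    p <- strptime(x[need], fmt, tz = "UTC")
    out[need] <- round(as.numeric(p))
  }
  out
}

# Midnight (UTC epoch seconds) of a day given as Date, "YYYY-MM-DD" or epoch.
dayStart <- function(day) {
  if (inherits(day, "Date")) return(as.numeric(day) * 86400)
  if (is.character(day)) {
    t <- parseTime(day)
    if (is.na(t)) stop("bad day: ", day, call. = FALSE)
    return((t %/% 86400) * 86400)
  }
  (as.numeric(day) %/% 86400) * 86400
}
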