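# Operation-count latency benchmark: the hardware-independent analogue of
# timing pre-aggregated queries against SQL GROUP BY. For each simulated
# dataset size, a fixed-span query is answered (a) from the window
# summaries and (b) by a full brute-force scan; the records each engine
# touches are counted. Pre-aggregated counts should be constant in dataset
# size while the brute-force scan grows linearly with one slope per level
# family (the per-month point count). Wall-clock seconds are logged for
# orientation but never asserted — they are machine properties, not
# algorithm properties.

#' Run the pre-aggregation vs brute-force scaling benchmark
#'
#' Builds the benchmark layout — one stream per dataset duration, each
#' holding `months` cumulative 30-day months of seeded simulated
#' irradiance — then answers the same fixed-span window query from both
#' engines and records the number of records touched.
#'
#' @param monthsList dataset sizes in months, one stream each (the
#'   original study used 1..12; the default 1, 2, 4, 8 spans a factor of
#'   eight).
#' @param levels summary levels to query (see [windowLevels()]).
#' @param freq sampling period in seconds for the simulated data (1
#'   reproduces the study's 1 Hz sizes; 60 preserves all structural
#'   properties at 1/60 the cost).
#' @param queryDay which day of the first month the fixed one-day query
#'   span covers (default 10).
#' @param seed RNG seed for the simulator.
#' @param store optionally, a pre-built [SensorStore-class] with the
#'   benchmark layout (as returned in `$store`); by default a fresh one
#'   is built.
#' @return List: `results` (data.table over engine x months x level with
#'   `summary_records_read`, `raw_records_read`, `windows`,
#'   `elapsed_s`), `slopes` (per level: fitted slope of brute-force raw
#'   records vs months, and the per-month point count it should match),
#'   `preaggConstant` (per level: is the pre-aggregated count constant
#'   across dataset sizes?), `span`, and `store` (invisible reuse).
#' @export
runLatencyBenchmark <- function(monthsList = c(1L, 2L, 4L, 8L),
                                levels = c("hour1", "day1"),
                                freq = 60, queryDay = 10L, seed = 1L,
                                store = NULL) {
  stopifnot(length(monthsList) >= 2L, all(monthsList >= 1L))
  levels <- vapply(levels, matchLevel, character(1))
  t0 <- dayStart("2013-01-01")
  if (is.null(store)) {
    store <- SensorStore()
    createEntity(store, "user", "bench")
    createEntity(store, "experiment", "irradiance", "bench")
    createEntity(store, "node", "sim", "bench/irradiance")
    for (m in monthsList) {
      sid <- createEntity(store, "stream", sprintf("m%02d", m),
                          "bench/irradiance/sim",
                          attrs = list(unit = "W/m2"))
      appendPoints(store, sid,
                   simulateIrradiance(months = m, freq = freq, seed = seed))
    }
  }
  from <- t0 + (queryDay - 1L) * 86400
  to <- from + 86400

  rows <- list()
  for (m in monthsList) {
    sid <- sprintf("bench/irradiance/sim/m%02d", m)
    for (lvl in levels) {
      resetTouchCounter(store)
      el <- system.time(
        win <- getWindowStats(store, sid, lvl, from, to))[["elapsed"]]
      tc <- touchCounter(store)
      rows[[length(rows) + 1L]] <- data.table(
        engine = "preaggregated", months = m, level = lvl,
        summary_records_read = tc$summary_records_read,
        raw_records_read = tc$raw_records_read,
        windows = nrow(win), elapsed_s = el)

      resetTouchCounter(store)
      el <- system.time({
        pts <- getRaw(store, sid, 0, Inf)  # full scan, as GROUP BY would
        agg <- bruteForceAggregate(pts$t, pts$v, lvl)
        win <- agg[start >= from & start < to]
      })[["elapsed"]]
      tc <- touchCounter(store)
      rows[[length(rows) + 1L]] <- data.table(
        engine = "brute_force", months = m, level = lvl,
        summary_records_read = tc$summary_records_read,
        raw_records_read = tc$raw_records_read,
        windows = nrow(win), elapsed_s = el)
    }
  }
  results <- rbindlist(rows)

  pointsPerMonth <- 30 * 86400 / freq
  slopes <- results[engine == "brute_force",
                    .(slope = coef(lm(raw_records_read ~ months))[[2L]],
                      points_per_month = pointsPerMonth),
                    by = level]
  slopes[, slope_ratio := slope / points_per_month]
  constant <- results[engine == "preaggregated",
                      .(constant = uniqueN(summary_records_read) == 1L),
                      by = level]
  list(results = results[], slopes = slopes[], preaggConstant = constant[],
       span = c(from = from, to = to), store = store)
}

#' Render a benchmark result as text lines
#'
#' States, per level, whether the pre-aggregated record counts are
#' constant across dataset sizes and how close the fitted brute-force
#' slope is to the per-month point count.
#'
#' @param bench result of [runLatencyBenchmark()].
#' @return Character vector of report lines.
#' @export
benchReportText <- function(bench) {
  lines <- c("Pre-aggregation vs brute-force scaling (records touched)",
             sprintf("query span: [%s, %s)", isoTime(bench$span[["from"]]),
                     isoTime(bench$span[["to"]])))
  for (i in seq_len(nrow(bench$slopes))) {
    lvl <- bench$slopes$level[i]
    const <- bench$preaggConstant[level == lvl]$constant
    lines <- c(lines, sprintf(
      "%s: preaggregated records %s across dataset sizes; brute-force slope %.1f raw records/month (expected %.1f, ratio %.3f)",
      API_LEVEL_NAMES[[lvl]],
      if (const) "CONSTANT" else "NOT constant",
      bench$slopes$slope[i], bench$slopes$points_per_month[i],
      bench$slopes$slope_ratio[i]))
  }
  lines
}
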