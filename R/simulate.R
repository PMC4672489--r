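# Seeded synthetic solar irradiance and the brute-force aggregation
# oracle. The simulator produces a clear-sky diurnal shape from a standard
# declination + hour-angle solar-elevation approximation (the benchmark
# needs a plausible diurnal signal, not ephemeris accuracy), with additive
# sensor noise, clipped at zero, and exactly zero whenever the sun is below
# the horizon. Benchmark months are 30 days, making one month at 1 Hz
# exactly 2,592,000 points.

# Evaluate code with a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Sine of solar elevation from day-of-year, seconds-of-day (UTC) and
# latitude, using the 23.44 deg declination approximation and the hour
# angle about a 12:00 UTC solar noon (longitude 0 convention).
sinSolarElevation <- function(doy, secOfDay, latitudeDeg) {
  decl <- (23.44 * pi / 180) * sin(2 * pi * (284 + doy) / 365)
  lat <- latitudeDeg * pi / 180
  hourAngle <- (secOfDay / 3600 - 12) * 15 * pi / 180
  sin(lat) * sin(decl) + cos(lat) * cos(decl) * cos(hourAngle)
}

#' Simulate solar irradiance at fixed frequency
#'
#' Generates a deterministic (seeded) irradiance series: a diurnal
#' clear-sky sinusoid-by-elevation shape scaled to `peak`, plus additive
#' Gaussian sensor noise, clipped at zero; readings are exactly zero at
#' night (solar elevation <= 0). Months are 30 days by benchmark
#' convention, so one month at 1 Hz is exactly 2,592,000 points.
#'
#' @param months number of 30-day months to generate (>= 1).
#' @param start UTC start day (`Date` or `"YYYY-MM-DD"`); default
#'   2013-01-01.
#' @param freq sampling period in seconds (1 = 1 Hz; larger values give
#'   structurally identical, faster-to-process series).
#' @param latitude site latitude in decimal degrees (default -35, a
#'   southern-hemisphere field-trial site).
#' @param peak clear-sky peak irradiance in W/m2 (default 1000).
#' @param noiseSd additive sensor noise standard deviation in W/m2
#'   (default 5, about 0.5% of peak).
#' @param seed integer RNG seed; the same seed always yields the same
#'   series.
#' @return data.table with columns `t` (UTC epoch seconds) and `v`
#'   (irradiance, W/m2), length `months * 30 * 86400 / freq`.
#' @examples
#' day <- simulateIrradiance(months = 1, freq = 3600, seed = 1)
#' nrow(day)  # 720 hourly samples in one 30-day month
#' @export
simulateIrradiance <- function(months = 1L, start = "2013-01-01", freq = 1,
                               latitude = -35, peak = 1000, noiseSd = 5,
                               seed = 1L) {
  if (months < 1) stop("months must be >= 1", call. = FALSE)
  stopifnot(freq >= 1, (86400 %% freq) == 0)
  t0 <- dayStart(start)
  n <- as.integer(months) * 30L * (86400L %/% as.integer(freq))
  t <- t0 + as.numeric(seq_len(n) - 1L) * freq
  secOfDay <- t %% 86400
  d <- t %/% 86400
  ud <- unique(d)
  doyU <- as.POSIXlt(ud * 86400, origin = "1970-01-01", tz = "UTC")$yday + 1L
  doy <- doyU[match(d, ud)]
  sinel <- sinSolarElevation(doy, secOfDay, latitude)
  up <- sinel > 0
  v <- numeric(n)
  noise <- withSeed(seed, rnorm(sum(up), 0, noiseSd))
  v[up] <- pmax(peak * sinel[up] + noise, 0)
  data.table(t = t, v = v)
}

#' Brute-force window aggregation (the oracle)
#'
#' Recomputes per-window statistics from scratch with a plain two-pass
#' algorithm (group, then mean, then squared deviations), the way a SQL
#' `GROUP BY` over raw rows would: average, min, max, count and standard
#' deviation per window, plus the extreme-occurrence and last timestamps.
#' It shares only the window-boundary computation ([windowStart()]) with
#' the incremental engine and exists to verify it.
#'
#' @param t,v numeric vectors: UTC epoch timestamps and values.
#' @param level a summary level (see [windowLevels()]).
#' @return data.table with the same columns as [getWindowStats()],
#'   ascending by window start.
#' @export
bruteForceAggregate <- function(t, v, level) {
  level <- matchLevel(level)
  if (length(t) == 0L) return(decorateStats(emptyStatsTable()))
  t <- as.numeric(t)
  v <- as.numeric(v)
  starts <- windowStart(t, level)
  u <- sort(unique(starts))
  g <- match(starts, u)
  k <- length(u)
  cnt <- tabulate(g, k)
  mu <- rowsum(v, g, reorder = TRUE)[, 1L] / cnt
  m2 <- rowsum((v - mu[g])^2, g, reorder = TRUE)[, 1L]
  oMin <- order(g, v, t)
  iMin <- oMin[!duplicated(g[oMin])]
  oMax <- order(g, -v, t)
  iMax <- oMax[!duplicated(g[oMax])]
  oLast <- order(g, t)
  iLast <- oLast[cumsum(cnt)]
  tab <- data.table(start = u, count = cnt, mean = mu, m2 = m2,
                    min = v[iMin], min_time = t[iMin],
                    max = v[iMax], max_time = t[iMax],
                    last = v[iLast], last_time = t[iLast])
  setkey(tab, start)
  decorateStats(tab)
}
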