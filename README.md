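# sensorstore

Field phenomics and environmental monitoring produce sensor time series at
rates — one reading per second and up, across hundreds of streams — that
make "query the raw table and aggregate" workflows painfully slow exactly
when researchers most need a quick look: the morning after upload, to check
which sensors died overnight and what the crop canopy did yesterday.

`sensorstore` is an R implementation of the pre-aggregation architecture
that solves this. Readings are organised in a four-layer hierarchy —
**user → experiment → node (plot) → stream (measured variable)** — with
key/value metadata attachable at every layer (sowing date on the
experiment, treatment on the plot, sensor depth and type on the stream).
Every stream maintains, for each of seven fixed time-aggregation windows
(1-min, 15-min, 1-hour, 1-day, 1-month, 1-year and overall), a running
summary that is updated incrementally as data arrive. Statistical queries
at any aggregation level are then answered from those summary rows alone
and never rescan raw points, so their cost is independent of how much
history a stream has accumulated.

## The statistics

Each window keeps `(n, mean, M2, min, argmin, max, argmax, last)` where
`M2 = Σ(xᵢ − x̄)²` is the sum of squared deviations. A new point updates
the moments with the numerically stable single-pass (Welford) recurrence

    n ← n + 1;  δ = x − x̄;  x̄ ← x̄ + δ/n;  M2 ← M2 + δ(x − x̄)

and two windows over disjoint point sets combine exactly with the parallel
(pairwise) rule

    n = n₁ + n₂;  δ = x̄₂ − x̄₁;  x̄ = x̄₁ + δ·n₂/n;
    M2 = M2₁ + M2₂ + δ²·n₁n₂/n

Storing `M2` rather than a standard deviation is what makes the summaries
*mergeable*: batch ingest, out-of-order arrival, hierarchical rollup
(a month window equals the merge of its day windows) and partitioned
processing all agree exactly with a single sequential pass. Standard
deviation is derived on read (population `√(M2/n)` by default, sample by
flag). Min/max ties keep the earliest occurrence time; `last` follows the
greatest data timestamp, not arrival order — so every summary is a pure
function of the data set, independent of how it arrived.

The per-point update loop is compiled (Rcpp); everything is exact, no
sketches or approximations.

## Worked example

```r
library(sensorstore)
library(data.table)

store <- SensorStore()
createEntity(store, "user", "csiro-hb")
createEntity(store, "experiment", "yanco-2013", "csiro-hb")
createEntity(store, "node", "plot-R1C4", "csiro-hb/yanco-2013")
sid <- createEntity(store, "stream", "canopy-temp",
                    "csiro-hb/yanco-2013/plot-R1C4",
                    attrs = list(unit = "degC"))
setMetadata(store, "csiro-hb/yanco-2013/plot-R1C4", "treatment", "irrigated")

# one day of 15-min readings, warm around mid-day
t0 <- as.numeric(as.POSIXct("2013-11-01", tz = "UTC"))
tt <- seq(t0, t0 + 86399, by = 900)
appendPoints(store, sid, data.table(
  t = tt, v = 22 + 8 * sin(pi * (tt - t0) / 86400)))

streamSummary(store, sid)[level %in% c("raw", "hour1", "day1"),
                          .(level, count, mean, std, min, max)]
#>     level count    mean      std   min   max
#>    <char> <int>   <num>    <num> <num> <num>
#> 1:    raw    96 27.0925 2.463008    22    30
#> 2:  hour1    96 27.0925 2.463008    22    30
#> 3:   day1    96 27.0925 2.463008    22    30
```

Every level reports the same 96 points (the conservation invariant); the
mean of `22 + 8·sin` over the day is ≈ 22 + 8·(2/π) ≈ 27.09, and the
windows reproduce it from their merged summaries without touching a raw
row. An hourly query returns 24 pre-computed windows of 4 points each:

```r
nrow(getWindowStats(store, sid, "hour1"))   # 24
touchCounter(store)$raw_records_read        # 0 — summaries only
```

Daily QC for the experiment (gap, range and missing-sensor detection):

```r
rep <- dailyReport(store, "csiro-hb/yanco-2013",
                   diagnosticConfig(gapThreshold = 1800, minAllowed = -10,
                                    maxAllowed = 60, day = "2013-11-01"))
rep
#> Diagnostic report for csiro-hb/yanco-2013 on 2013-11-01 (generated ...)
#> Gap errors (interval > 1800s): 0
#> Range errors (outside [-10, 60]): 0
#> Missing sensors (no data that day): 0
```

A command-line front-end with verbs `init`, `create`, `meta`, `ingest`,
`query`, `summary`, `report`, `simulate` and `bench` is installed at
`inst/cli/sensorstore`; it persists stores as plain JSON-lines directories.

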