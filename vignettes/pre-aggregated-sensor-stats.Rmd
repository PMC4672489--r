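---
title: "Pre-aggregated statistics for sensor time series: model, design and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pre-aggregated statistics for sensor time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sensorstore)
library(data.table)
```

## The problem and the model

High-frequency field sensors (canopy-temperature thermopiles, soil-moisture
probes, weather stations, pyranometers) produce time series whose *summary
behaviour* — daily means, extremes and their timing, variability — matters
far more to a field scientist than any individual reading. Answering those
summary questions by scanning raw tables costs time proportional to the
accumulated history, which is exactly the wrong scaling for data that grow
by a point per second.

`sensorstore` inverts the cost: summaries are computed *at ingest*, once
per point, into fixed time-aggregation windows, and queries read only the
pre-computed window rows. Two ideas carry the whole design:

1. **A fixed window hierarchy.** Every stream maintains seven levels:
   1-minute, 15-minute, 1-hour and 1-day windows are fixed spans aligned
   to the UTC epoch (60, 900, 3600, 86400 s); 1-month and 1-year windows
   follow the UTC calendar (they cannot be fixed spans); and a single
   *overall* window (sentinel start 0) summarises the stream's whole
   history. All windows are half-open `[start, next)`. Raw data is the
   eighth, pass-through level.

2. **Mergeable moments.** A window stores
   `(n, mean, M2, min/argmin, max/argmax, last/last time)` with
   `M2 = Σ(xᵢ − x̄)²`. Points enter via the single-pass Welford
   recurrence; two windows over disjoint point sets combine exactly via
   the parallel combination
   `M2 = M2₁ + M2₂ + δ²·n₁n₂/n` with `δ = x̄₂ − x̄₁`. Because the
   *accumulator* (not a derived standard deviation) is stored, merging is
   exact, which makes four different things the same computation:
   batch ingest (a batch's partial summaries are merged into stored
   windows), hierarchical rollup (a month equals the merge of its days),
   recovery after replacement (rebuilt 1-minute windows re-merge upward),
   and partitioned processing (any split of the data, merged in any
   order, reproduces the sequential result). The package's tests exercise
   each of these as a separate invariant.

Above the window engine sits a four-layer entity model — user, experiment,
node (an experimental unit such as a ~2 m × ~6 m plot), stream (one
measured variable with a unit) — with string key/value metadata at every
layer. Metadata is what makes filtering scientifically useful: "all
soil-moisture streams under irrigated plots" is a metadata predicate plus
a name pattern, evaluated against each stream and its ancestors.

## Determinism under disorder

Field data arrive out of order: batteries die, loggers buffer, files are
re-uploaded. Three definitional choices make every summary a pure function
of the point *set*, independent of arrival order:

* **`last` follows the greatest data timestamp**, not the most recent
  arrival.
* **Min/max ties keep the earliest occurrence time**, a deterministic,
  order-independent tie-break.
* **Duplicate timestamps** within a stream are resolved by policy:
  `replace` (default — last write wins; re-uploading a corrected file is
  the common field workflow) or `reject` (collisions reported, store
  unchanged). Replacement does not try to "un-update" accumulators —
  subtraction is ill-defined for min/max — instead the affected 1-minute
  windows are rebuilt from raw and every coarser level is re-merged from
  its children. Correctness over speed; replacements are rare events.

Timestamps are integer UTC seconds throughout (the data this store is
built for arrive at 1 Hz or slower; sub-second support is a non-goal).
Each experiment carries a timezone label, but it is display-only — all
storage and window arithmetic is UTC, so windows never shift under
daylight-saving rules.

## Numerical choices

* Moments use the Welford/parallel recurrences; `M2` is clamped at 0
  against floating-point cancellation. Count/min/max/occurrence
  times/last are exact integers or copies of inputs, and tests assert
  them *identical* to a brute-force oracle; mean and `M2` are asserted to
  1e-9 relative.
* Standard deviation defaults to the **population** form `√(M2/n)` —
  the common streaming-moment definition and what SQL `STDDEV_POP`-style
  baselines compute — with the sample form available by flag. A window
  with one point has sd 0; the sample form errors below n = 2
  ("undefined std").
* The brute-force oracle (`bruteForceAggregate`) is deliberately a
  different algorithm: vectorised two-pass (group, mean, then squared
  deviations) built on `tabulate`/`rowsum` and ordering, sharing only the
  window-boundary function with the engine. Equivalence tests between
  the two paths are meaningful because the code paths are disjoint.

## Instrumentation instead of wall clocks

The performance claim worth testing is architectural, not horological:
*aggregated queries touch a number of records independent of stream
length, while a scan-and-group engine touches every raw record*. The
store counts the records each read path returns (`touchCounter`), and
`runLatencyBenchmark` turns that into the scaling experiment: cumulative
datasets of growing duration, one stream each, the same fixed-span query
answered by both engines. Pre-aggregated counts are constant in dataset
size; the brute-force count grows linearly with fitted slope equal to the
per-month point count. Wall-clock seconds are logged for orientation but
never asserted — they are properties of the machine, not the algorithm.

## The synthetic irradiance generator

The benchmark input is seeded synthetic solar irradiance at fixed
frequency, emulating a pyranometer: sine-of-solar-elevation diurnal shape
from the standard declination + hour-angle approximation, scaled to a
clear-sky peak, plus additive Gaussian sensor noise, clipped at zero, and
exactly zero at night. Defaults — latitude −35° (a southern-hemisphere
field-trial site), peak 1000 W/m², noise sd 5 W/m² (≈0.5 % of peak, a
realistic instrument noise floor), start 2013-01-01 — were chosen once as
plausible and are documented here rather than tuned; the generator's
contract is structural (deterministic under seed, correct length, night
zeros, daily maxima within an hour of solar noon, count conservation),
not radiometric accuracy. Benchmark months are 30 days, making one month
at 1 Hz exactly 2,592,000 points; calendar months remain in force inside
the store's monthly windows.

What the generator does *not* emulate: cloud fields and weather (its days
are all clear-sky), sensor drift and calibration error, missing data and
outages (the QC fixtures plant those separately), or cross-stream
correlation. Tests passing on this input therefore demonstrate the
storage and aggregation contracts — exactness, mergeability, scaling —
not robustness to every pathology of real field data.

```{r generator}
day <- simulateIrradiance(months = 1, freq = 600, seed = 1)
pts <- day[t < t[1] + 86400]
plot(pts$t %% 86400 / 3600, pts$v, type = "l",
     xlab = "hour of day (UTC)", ylab = "irradiance (W/m2)")
```

## Quality-control reports

The diagnostics module reproduces the daily fault report a sensor-network
operator needs: for one experiment and one UTC day, every stream is
screened for **gaps** (interval between successive readings strictly
exceeding a threshold, including the edges from midnight to the first
reading and from the last reading to midnight — a sensor dying at 01:00
must be caught), **range violations** (readings strictly outside
configured bounds; equality is in range), and **missing sensors** (no
data at all that day — such streams are excluded from gap detection by
definition). Range screening consults the daily window's min/max first
and descends through 15-minute windows to raw only where a window proves
a violation, so a clean day touches no raw data. All thresholds are
configuration: the deployments this mirrors chose their own gap times and
temperature bounds, and no default is privileged. Faulty values are
reported, never tagged or cleaned in place — the supported workflow is to
clean externally and re-ingest as a new stream.

## Interfaces

Ingest accepts long-format CSV (timestamp, value, and a stream path fixed
or per-row; RFC-4180 dialect, configurable delimiter, ISO-8601 or epoch
timestamps) and chunked batch upload whose chunking is invisible in the
final state. The REST contract is implemented as a request router
(`apiRequest`) mapping method + path + query + JSON body to the library
operations and returning HTTP-style status codes with JSON bodies that
are byte-identical to the library's own serialisers; any HTTP front-end
can delegate to it, and the package deliberately does not bundle a socket
server. Persistence is one directory of plain JSON-lines files (entities,
raw points with ISO timestamps, window summaries) written with
round-trip-exact decimal formatting; summaries are cross-checked against
raw counts on load and rebuilt from raw on mismatch, so the raw files
alone are sufficient.

## Problem sizes used in the test suite

The suite verifies oracle equivalence on 1,000 randomized streams of up
to 5,000 points each across all seven levels; merge correctness over
random partitions into up to 16 parts; hierarchical consistency on a
simulated month at one point per minute; the 1 Hz month only where its
exact size (2,592,000) is itself the claim; and the scaling benchmark on
1–12 cumulative months at one point per minute or coarser. These sizes
were chosen to exercise every contract at full statistical strength while
keeping the default test run fast; the 1 Hz generator reproduces the full
published data sizes when asked.

## Known limitations

* Window durations are fixed; there are no sliding or custom windows.
* One value per timestamp per stream; sub-second sampling is out of scope.
* Metadata values are strings; numeric range predicates over metadata are
  not supported.
* The store is in-memory with file persistence — a deliberate
  replacement of distributed NoSQL tiers by a transparent, diff-able
  layout; the mergeability contract is the scalability surface, not a
  cluster.
* No authentication or access control: a user entity is an organisational
  node, not a security principal.
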