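# Fixtures emulate a 15-min canopy-temperature network: regular streams,
# one stream with a dropped reading (gap), spiked values (range) and dead
# sensors (missing).

test_that("a regular 15-min stream has no gaps under a 30-min threshold", {
  store <- SensorStore()
  sid <- singleStream(store)
  appendPoints(store, sid, regularDay("2013-11-01"))
  expect_equal(nrow(detectGaps(store, sid, "2013-11-01", 1800)), 0)
})

test_that("one dropped 15-min reading makes exactly one 30-min gap", {
  store <- SensorStore()
  sid <- singleStream(store)
  pts <- regularDay("2013-11-01")
  dropT <- iso("2013-11-01 10:30:00")
  appendPoints(store, sid, pts[t != dropT])
  gaps <- detectGaps(store, sid, "2013-11-01", 1200)
  expect_equal(nrow(gaps), 1)
  expect_equal(gaps$gap_start, dropT - 900)
  expect_equal(gaps$gap_length, 1800)
})

test_that("day-boundary silence counts as a gap", {
  store <- SensorStore()
  sid <- singleStream(store)
  pts <- regularDay("2013-11-01")
  # sensor died at 01:00
  appendPoints(store, sid, pts[t < iso("2013-11-01 01:00:00")])
  gaps <- detectGaps(store, sid, "2013-11-01", 1800)
  expect_equal(nrow(gaps), 1)
  expect_equal(gaps$gap_start, iso("2013-11-01 00:45:00"))
  expect_equal(gaps$gap_length, 86400 - 45 * 60)
})

test_that("a silent stream yields no gap errors (it is missing instead)", {
  store <- SensorStore()
  sid <- singleStream(store)
  expect_equal(nrow(detectGaps(store, sid, "2013-11-01", 900)), 0)
})

test_that("range detection flags planted spikes with the right bound", {
  store <- SensorStore()
  sid <- singleStream(store)
  pts <- regularDay("2013-11-01", base = 25)
  spikes <- c(iso("2013-11-01 03:00:00"), iso("2013-11-01 12:15:00"),
              iso("2013-11-01 20:30:00"))
  pts[t == spikes[1], v := -15]
  pts[t == spikes[2], v := 75]
  pts[t == spikes[3], v := 90]
  appendPoints(store, sid, pts)
  hits <- detectRangeViolations(store, sid, "2013-11-01", -10, 60)
  expect_equal(nrow(hits), 3)
  expect_equal(hits$timestamp, spikes)
  expect_equal(hits$bound, c("min", "max", "max"))
  # in-range day is empty
  clean <- SensorStore()
  cid <- singleStream(clean)
  appendPoints(clean, cid, regularDay("2013-11-01", base = 25))
  expect_equal(nrow(detectRangeViolations(clean, cid, "2013-11-01",
                                          -10, 60)), 0)
})

test_that("bounds are strict: equality is not a violation", {
  store <- SensorStore()
  sid <- singleStream(store)
  pts <- regularDay("2013-11-01", base = 20)
  pts[1, v := -10]
  pts[2, v := 60]
  appendPoints(store, sid, pts)
  expect_equal(nrow(detectRangeViolations(store, sid, "2013-11-01",
                                          -10, 60)), 0)
})

test_that("window screening equals a raw scan but touches less raw data", {
  set.seed(31)
  store <- SensorStore()
  sid <- singleStream(store)
  pts <- regularDay("2013-11-01", base = 25)
  pts$v <- pts$v + rnorm(nrow(pts), 0, 3)
  pts$v[c(10, 50)] <- c(80, -30)
  appendPoints(store, sid, pts)
  resetTouchCounter(store)
  hits <- detectRangeViolations(store, sid, "2013-11-01", -10, 60)
  screenedRaw <- touchCounter(store)$raw_records_read
  raw <- getRaw(store, sid, dayS <- iso("2013-11-01"), dayS + 86400)
  oracle <- raw[v < -10 | v > 60]
  expect_equal(hits$timestamp, oracle$t)
  expect_equal(hits$value, oracle$v)
  # only the two flagged 15-min windows were descended into
  expect_lte(screenedRaw, 2 * 1)
  expect_lt(screenedRaw, nrow(raw))
  # and a clean stream touches no raw at all
  clean <- SensorStore()
  cid <- singleStream(clean)
  appendPoints(clean, cid, regularDay("2013-11-01", base = 25))
  resetTouchCounter(clean)
  detectRangeViolations(clean, cid, "2013-11-01", -10, 60)
  expect_equal(touchCounter(clean)$raw_records_read, 0)
})

test_that("the daily report aggregates all three detectors per experiment", {
  store <- fixtureTree()
  day <- "2013-11-01"
  streams <- filterStreams(store, "csiro-hb", stream = "canopy-temp")
  # healthy streams everywhere...
  for (s in streams[-(1:2)])
    appendPoints(store, s, regularDay(day, base = 25))
  # ...except one gappy sensor and one dead sensor
  gappy <- streams[2]
  pts <- regularDay(day, base = 25)
  appendPoints(store, gappy, pts[t < iso("2013-11-01 06:00:00") |
                                   t >= iso("2013-11-01 08:00:00")])
  dead <- streams[1]

  cfg <- diagnosticConfig(1800, -10, 60, day)
  rep <- dailyReport(store, "csiro-hb/yanco-2013", cfg)
  expect_s4_class(rep, "DiagnosticReport")
  expect_equal(rep@gap_errors$stream, gappy)
  expect_equal(nrow(rep@gap_errors), 1)
  # readings absent in [06:00, 08:00): silence from 05:45 until 08:00
  expect_equal(rep@gap_errors$gap_length, 8100)
  # the 6 moisture streams never reported either; dead + those are missing
  expect_true(dead %in% rep@missing_sensors)
  expect_false(gappy %in% rep@missing_sensors)
  expect_false(any(rep@missing_sensors %in% rep@gap_errors$stream))
  expect_equal(nrow(rep@range_errors), 0)
})

test_that("a healthy experiment yields an empty report", {
  store <- fixtureTree()
  day <- "2013-11-01"
  for (s in filterStreams(store, "csiro-hb"))
    appendPoints(store, s, regularDay(day, base = 22))
  rep <- dailyReport(store, "csiro-hb/yanco-2013",
                     diagnosticConfig(1800, -10, 60, day))
  expect_equal(nrow(rep@gap_errors), 0)
  expect_equal(nrow(rep@range_errors), 0)
  expect_length(rep@missing_sensors, 0)
})

test_that("reports serialise to JSON and parse back identically", {
  store <- fixtureTree()
  day <- "2013-11-01"
  streams <- filterStreams(store, "csiro-hb", stream = "canopy-temp")
  pts <- regularDay(day, base = 25)
  pts[50, v := 99]
  appendPoints(store, streams[1], pts[-5])
  rep <- dailyReport(store, "csiro-hb/yanco-2013",
                     diagnosticConfig(900, -10, 60, day))
  back <- reportFromJSON(reportToJSON(rep))
  expect_equal(back@experiment, rep@experiment)
  expect_equal(back@day, rep@day)
  expect_equal(back@gap_errors, rep@gap_errors)
  expect_equal(back@range_errors, rep@range_errors)
  expect_equal(back@missing_sensors, rep@missing_sensors)
  expect_type(reportToText(rep), "character")
})

test_that("detectors achieve perfect precision and recall on planted faults", {
  set.seed(37)
  day <- "2013-11-05"
  d0 <- iso(day)
  store <- SensorStore()
  createEntity(store, "user", "qc")
  createEntity(store, "experiment", "trial", "qc")
  planted <- list(gaps = character(0), spikes = list(), dead = character(0))
  for (i in 1:20) {
    nd <- createEntity(store, "node", sprintf("n%02d", i), "qc/trial")
    sid <- createEntity(store, "stream", "temp", nd,
                        attrs = list(unit = "degC"))
    kind <- sample(c("healthy", "gap", "spike", "dead"), 1)
    pts <- regularDay(day, base = 25)
    pts$v <- pts$v + rnorm(nrow(pts), 0, 2)
    if (kind == "dead") {
      planted$dead <- c(planted$dead, sid)
      next
    }
    if (kind == "gap") {
      drop <- sample(5:90, 1)
      pts <- pts[-(drop:(drop + 3))]  # one 75-min hole
      planted$gaps <- c(planted$gaps, sid)
    }
    if (kind == "spike") {
      j <- sample(nrow(pts), 2)
      pts$v[j] <- c(95, -40)
      planted$spikes[[sid]] <- sort(pts$t[j])
    }
    appendPoints(store, sid, pts)
  }
  rep <- dailyReport(store, "qc/trial", diagnosticConfig(1800, -10, 60, day))
  expect_setequal(unique(rep@gap_errors$stream), planted$gaps)
  expect_setequal(rep@missing_sensors, planted$dead)
  expect_setequal(unique(rep@range_errors$stream), names(planted$spikes))
  for (sid in names(planted$spikes))
    expect_equal(
      sort(rep@range_errors$timestamp[rep@range_errors$stream == sid]),
      planted$spikes[[sid]])
})
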