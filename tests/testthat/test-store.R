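test_that("appending in-order points fills the expected hourly windows", {
  store <- SensorStore()
  sid <- singleStream(store)
  t0 <- iso("2015-06-15 10:30:00")
  pts <- data.table(t = t0 + (0:99) * 120, v = 1:100)  # every 2 min
  rep <- appendPoints(store, sid, pts)
  expect_equal(rep$accepted, 100)
  expect_equal(rep$rejected, 0)
  hours <- getWindowStats(store, sid, "hour1")
  # brute-force window assignment: distinct hours covered by the points
  expect_equal(nrow(hours), length(unique(pts$t %/% 3600)))
  expect_equal(sum(hours$count), 100)
  expect_error(appendPoints(store, "u/e/n/ghost", pts), "no such stream")
})

test_that("non-finite values and bad timestamps are rejected row-wise", {
  store <- SensorStore()
  sid <- singleStream(store)
  rep <- appendPoints(store, sid, data.table(t = c(1, 2, 2.5, 3),
                                             v = c(1, NaN, 1, Inf)))
  expect_equal(rep$accepted, 1)
  expect_equal(rep$rejected, 3)
  expect_setequal(rep$reasons$reason,
                  c("non-finite value rejected", "bad timestamp"))
  expect_equal(getRaw(store, sid)$t, 1)
})

test_that("duplicate policy reject refuses collisions, replace rebuilds", {
  store <- SensorStore()
  sid <- singleStream(store)
  appendPoints(store, sid, data.table(t = 1:10, v = rep(1, 10)))
  rep <- appendPoints(store, sid, data.table(t = c(5, 11), v = c(9, 9)),
                      duplicatePolicy = "reject")
  expect_equal(rep$accepted, 1)
  expect_equal(rep$rejected, 1)
  expect_equal(getRaw(store, sid)[t == 5]$v, 1)

  rep <- appendPoints(store, sid, data.table(t = 5, v = 42),
                      duplicatePolicy = "replace")
  expect_equal(rep$accepted, 1)
  expect_equal(getRaw(store, sid)[t == 5]$v, 42)
  # windows reflect the replacement exactly (oracle recompute)
  raw <- getRaw(store, sid)
  for (lvl in c("min1", "hour1", "overall"))
    expectMatchesOracle(getWindowStats(store, sid, lvl),
                        bruteForceAggregate(raw$t, raw$v, lvl))
})

test_that("re-ingesting an identical batch under replace is idempotent", {
  store <- SensorStore()
  sid <- singleStream(store)
  set.seed(21)
  pts <- data.table(t = sample.int(100000, 500), v = rnorm(500))
  appendPoints(store, sid, pts)
  before <- lapply(windowLevels(), function(l) getWindowStats(store, sid, l))
  appendPoints(store, sid, pts, duplicatePolicy = "replace")
  after <- lapply(windowLevels(), function(l) getWindowStats(store, sid, l))
  expect_equal(nrow(getRaw(store, sid)), 500)
  expect_equal(after, before)
})

test_that("getRaw returns a sorted half-open range regardless of ingest order", {
  store <- SensorStore()
  sid <- singleStream(store)
  set.seed(8)
  t <- sample(0:999, 600)  # scrambled arrival
  appendPoints(store, sid, data.table(t = t, v = t * 2))
  expect_equal(nrow(getRaw(store, sid, 5000, 6000)), 0)
  r <- getRaw(store, sid, 0, Inf)
  expect_equal(r$t, sort(as.numeric(t)))
  # half-open: t = 100 included, t = 200 excluded
  sub <- getRaw(store, sid, 100, 200)
  expect_true(all(sub$t >= 100 & sub$t < 200))
  expect_error(getRaw(store, sid, 10, 5), "empty range")
  # a 1 Hz minute holds 60 points
  s2 <- SensorStore()
  sid2 <- singleStream(s2)
  appendPoints(s2, sid2, data.table(t = 0:999, v = 0))
  expect_equal(nrow(getRaw(s2, sid2, 120, 180)), 60)
})

test_that("aggregated reads never touch raw records", {
  store <- SensorStore()
  sid <- singleStream(store)
  appendPoints(store, sid, data.table(t = 0:4999, v = rnorm(5000)))
  resetTouchCounter(store)
  getWindowStats(store, sid, "hour1")
  streamSummary(store, sid)
  tc <- touchCounter(store)
  expect_equal(tc$raw_records_read, 0)
  expect_gt(tc$summary_records_read, 0)
  resetTouchCounter(store)
  k <- nrow(getRaw(store, sid, 100, 1100))
  expect_equal(touchCounter(store)$raw_records_read, k)
  expect_equal(k, 1000)
})

test_that("adjacent half-open window queries concatenate to the union", {
  store <- SensorStore()
  sid <- singleStream(store)
  t0 <- iso("2015-06-15")
  appendPoints(store, sid, data.table(t = t0 + seq(0, 86399, by = 30),
                                      v = 1))
  mid <- t0 + 43200
  a <- getWindowStats(store, sid, "min15", t0, mid)
  b <- getWindowStats(store, sid, "min15", mid, t0 + 86400)
  whole <- getWindowStats(store, sid, "min15", t0, t0 + 86400)
  expect_equal(as.data.frame(rbind(a, b)), as.data.frame(whole))
  expect_equal(nrow(getWindowStats(store, sid, "hour1",
                                   t0 + 10 * 86400, t0 + 11 * 86400)), 0)
  expect_error(getWindowStats(store, sid, "raw"), "raw has no windows")
})

test_that("stream summary conserves counts and merges all windows", {
  store <- SensorStore()
  sid <- singleStream(store)
  set.seed(13)
  pts <- data.table(t = sample.int(5e6, 2000), v = rnorm(2000))
  appendPoints(store, sid, pts)
  s <- streamSummary(store, sid)
  expect_equal(nrow(s), 8)  # raw + seven summary levels
  expect_true(all(s$count == 2000))
  overall <- s[s$level == "overall"]
  expect_equal(overall$min, min(pts$v))
  expect_equal(overall$max, max(pts$v))
  expect_equal(overall$mean, mean(pts$v), tolerance = 1e-12)
  expect_equal(overall$last, pts$v[which.max(pts$t)])
  # a single-point stream shows count 1 and std 0 at every level
  s2 <- SensorStore()
  sid2 <- singleStream(s2)
  appendPoints(s2, sid2, data.table(t = 1000, v = 3.5))
  sm <- streamSummary(s2, sid2)
  expect_true(all(sm$count == 1))
  expect_true(all(sm$std == 0))
})

test_that("appending one point only moves the summaries it affects", {
  store <- SensorStore()
  sid <- singleStream(store)
  t0 <- iso("2015-06-15")
  appendPoints(store, sid, data.table(t = t0 + seq(0, 7199, 60), v = 10))
  before <- getWindowStats(store, sid, "hour1")
  appendPoints(store, sid, data.table(t = t0 + 10 * 3600, v = 99))
  after <- getWindowStats(store, sid, "hour1")
  expect_equal(nrow(after), nrow(before) + 1)
  expect_equal(after[after$start %in% before$start], before)
  newWin <- after[!after$start %in% before$start]
  expect_equal(newWin$count, 1L)
  expect_equal(newWin$mean, 99)
})

test_that("out-of-order ingest yields the same state as sorted ingest", {
  set.seed(17)
  t <- sample.int(3e6, 3000)
  v <- rnorm(3000)
  mk <- function(ord) {
    store <- SensorStore()
    sid <- singleStream(store)
    appendPoints(store, sid, data.table(t = t[ord], v = v[ord]))
    store
  }
  a <- mk(seq_along(t))
  b <- mk(order(t))
  for (lvl in windowLevels())
    expect_equal(getWindowStats(a, "u/e/n/s", lvl),
                 getWindowStats(b, "u/e/n/s", lvl), tolerance = 1e-12)
})

test_that("a persisted store reloads with identical data and summaries", {
  store <- SensorStore()
  sid <- singleStream(store)
  set.seed(19)
  appendPoints(store, sid, data.table(t = sample.int(4e6, 2500),
                                      v = rnorm(2500, 20, 5)))
  setMetadata(store, sid, "depth", "30cm")
  dir <- withr::local_tempdir()
  saveStore(store, dir)
  again <- loadStore(dir)
  expect_identical(getRaw(again, sid), getRaw(store, sid))
  for (lvl in windowLevels())
    expect_identical(getWindowStats(again, sid, lvl),
                     getWindowStats(store, sid, lvl))
  expect_identical(streamSummary(again, sid), streamSummary(store, sid))
  # summaries rebuilt from raw when the persisted tables are lost
  unlink(file.path(dir, "agg"), recursive = TRUE)
  rebuilt <- loadStore(dir)
  for (lvl in c("min15", "month1"))
    expectMatchesOracle(getWindowStats(rebuilt, sid, lvl),
                        getWindowStats(store, sid, lvl), tol = 1e-12)
})
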