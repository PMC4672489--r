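library(data.table)

iso <- function(s) as.numeric(as.POSIXct(s, tz = "UTC"))

# A small field-trial tree: one user, one experiment, 8 plots (4 irrigated,
# 4 rainfed), each with a canopy-temperature and a soil-moisture stream.
fixtureTree <- function() {
  store <- SensorStore()
  createEntity(store, "user", "csiro-hb",
               attrs = list(description = "field phenomics group"))
  createEntity(store, "experiment", "yanco-2013", "csiro-hb",
               attrs = list(timezone = "Australia/Sydney"))
  for (i in 1:8) {
    nd <- createEntity(store, "node",
                       sprintf("plot-R%dC%d", (i - 1) %/% 4 + 1,
                               (i - 1) %% 4 + 1),
                       "csiro-hb/yanco-2013")
    setMetadata(store, nd, "treatment",
                if (i <= 4) "irrigated" else "rainfed")
    createEntity(store, "stream", "canopy-temp", nd,
                 attrs = list(unit = "degC"))
    createEntity(store, "stream", "soil-moisture-30cm", nd,
                 attrs = list(unit = "%vol"))
  }
  store
}

# One user/experiment/node with a single stream, returning its path.
singleStream <- function(store = SensorStore(), name = "s", unit = "degC") {
  if (!"u" %in% listChildren(store)) {
    createEntity(store, "user", "u")
    createEntity(store, "experiment", "e", "u")
    createEntity(store, "node", "n", "u/e")
  }
  createEntity(store, "stream", name, "u/e/n", attrs = list(unit = unit))
}

# Regular readings every `period` seconds across day `day`, value `base`.
regularDay <- function(day, period = 900, base = 20) {
  d0 <- as.numeric(as.Date(day)) * 86400
  data.table(t = seq(d0, d0 + 86400 - period, by = period), v = base)
}

# Compare incremental window stats against the brute-force oracle at one
# level: order/count/min/max and their times exact, moments to relative tol.
expectMatchesOracle <- function(inc, orc, tol = 1e-9) {
  expect_equal(nrow(inc), nrow(orc))
  expect_identical(inc$start, orc$start)
  expect_identical(as.integer(inc$count), as.integer(orc$count))
  expect_identical(inc$min, orc$min)
  expect_identical(inc$max, orc$max)
  expect_identical(inc$min_time, orc$min_time)
  expect_identical(inc$max_time, orc$max_time)
  expect_identical(inc$last, orc$last)
  expect_identical(inc$last_time, orc$last_time)
  relErr <- function(a, b) abs(a - b) / pmax(abs(b), 1)
  expect_lt(max(relErr(inc$mean, orc$mean), 0), tol)
  expect_lt(max(relErr(inc$m2, orc$m2), 0), tol)
}
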