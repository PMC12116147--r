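## Shared fixtures, all generated in code.

.fixtureCache <- new.env(parent = emptyenv())

## Small scene reused by unit tests (memoised per test run).
tinyConfig <- function(seed = 42, ...)
  sceneConfig(nLat = 8, nLon = 8, nDays = 12, nStations = 10, seed = seed, ...)

tinyScene <- function() {
  if (is.null(.fixtureCache$scene))
    .fixtureCache$scene <- simulateScene(tinyConfig())
  .fixtureCache$scene
}

## Hourly daytime axis: `hoursPerDay` hours from 09:00, `nDays` days.
daytimeAxis <- function(nDays, hoursPerDay, startDate = "2016-01-01") {
  d0 <- as.POSIXct(paste(startDate, "09:00:00"), tz = "UTC")
  as.POSIXct(rep(d0 + 86400 * (seq_len(nDays) - 1), each = hoursPerDay) +
               3600 * (seq_len(hoursPerDay) - 1), tz = "UTC")
}

## Random masked cube on a daytime axis (overnight gaps included).
randomCube <- function(seed, nT = 6, nLat = 6, nLon = 7, missFrac = 0.3,
                       hoursPerDay = 3) {
  set.seed(seed)
  nDays <- ceiling(nT / hoursPerDay)
  tm <- daytimeAxis(nDays, hoursPerDay)[seq_len(nT)]
  v <- array(rnorm(nT * nLat * nLon, 50, 15), c(nT, nLat, nLon))
  v[sample.int(length(v), round(missFrac * length(v)))] <- NA
  GridCube("x", v, tm, seq_len(nLat), seq_len(nLon))
}

## RF configuration used for cross-validation in tests: desk-scale tree
## count (cross-validated R2 here is insensitive to tree count beyond a few
## dozen trees; the package defaults keep the full-size tuned values).
testRfGrid <- function(mode)
  data.frame(n_tree = 50,
             m_try = defaultHyperparameters("RF", mode)$m_try)
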