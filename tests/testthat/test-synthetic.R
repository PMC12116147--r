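test_that("generator output is a pure function of config and seed", {
  cfg <- tinyConfig(seed = 7)
  a <- makeLatentPM25(cfg)
  b <- makeLatentPM25(cfg)
  expect_identical(a@values, b@values)
  s1 <- simulateScene(cfg)
  s2 <- simulateScene(cfg)
  expect_identical(s1@satellite$AOD@values, s2@satellite$AOD@values)
  expect_identical(s1@stations@records$pm25, s2@stations@records$pm25)
  expect_identical(s1@population, s2@population)
  ## a different seed changes the realization
  s3 <- simulateScene(tinyConfig(seed = 8))
  expect_false(identical(s1@truth@values, s3@truth@values))
})

test_that("degenerate noise-free configuration yields the constant base field", {
  cfg <- sceneConfig(nLat = 4, nLon = 4, nDays = 4, hoursPerDay = 2,
                     seasons = rep("DJF", 4), pm25Base = c(DJF = 50),
                     spatialGradient = 0, corrLengthCells = 0, ar1Rho = 0,
                     sigmaField = 0, diurnalAmplitude = 0, nStations = 2,
                     seed = 1)
  truth <- makeLatentPM25(cfg)
  expect_true(all(truth@valid))
  expect_equal(unname(as.vector(truth@values)),
               rep(50, length(truth@values)))
})

test_that("seasonal marginal means track the configured base levels", {
  truth <- tinyScene()@truth
  seas <- seasonOf(truth@time)
  base <- tinyConfig()@pm25Base
  for (s in unique(seas)) {
    got <- mean(truth@values[seas == s, , ])
    expect_lt(abs(got - base[[s]]) / base[[s]], 0.05)
  }
})

test_that("TOAR-family cubes share one mask and AOD coverage nests inside it", {
  sc <- tinyScene()
  fam <- c("R1", "R3", "R6", "rho086", "rho226",
           "SensorZenith", "SensorAzimuth", "SolarZenith", "SolarAzimuth")
  for (nm in fam[-1])
    expect_identical(sc@satellite[[nm]]@valid, sc@satellite$R1@valid)
  ## AOD mask differs and is strictly sparser, never valid where TOAR is not
  expect_false(identical(sc@satellite$AOD@valid, sc@satellite$R1@valid))
  expect_false(any(sc@satellite$AOD@valid & !sc@satellite$R1@valid))
})

test_that("realized cloud fractions match the configured per-season targets", {
  sc <- tinyScene()
  cfg <- sc@config
  seas <- rep(cfg@seasons, each = cfg@hoursPerDay)
  for (s in unique(seas)) {
    gotT <- mean(!sc@satellite$R1@valid[seas == s, , ])
    gotA <- mean(!sc@satellite$AOD@valid[seas == s, , ])
    expect_lt(abs(gotT - cfg@cloudFractionToar[[s]]), 0.02)
    expect_lt(abs(gotA - cfg@cloudFractionAod[[s]]), 0.02)
  }
})

test_that("satellite rendering obeys its physical limits", {
  cfg <- sceneConfig(nLat = 5, nLon = 5, nDays = 2, hoursPerDay = 3,
                     seasons = rep("DJF", 2), pm25Base = c(DJF = 40),
                     nStations = 3, sigmaReflectance = 0, sigmaRetrieval = 0,
                     cloudFractionToar = c(DJF = 0),
                     cloudFractionAod = c(DJF = 0), seed = 5)
  met <- generateMet(cfg)
  truth0 <- makeLatentPM25(cfg)
  rhF <- interpolateMet(met$RH, truth0@lat, truth0@lon)
  pbF <- interpolateMet(assignTemporalNearest(met$PBLH, truth0@time),
                        truth0@lat, truth0@lon)
  surface <- list(R1 = matrix(0.1, 5, 5), R3 = matrix(0.15, 5, 5),
                  R6 = matrix(0.25, 5, 5), rho086 = matrix(0.3, 5, 5),
                  rho226 = matrix(0.22, 5, 5))

  ## zero-aerosol limit: bands collapse to surface reflectance, AOD to 0
  zero <- GridCube("pm25", array(0, dim(truth0@values)), truth0@time,
                   truth0@lat, truth0@lon)
  sat0 <- renderSatellite(zero, rhF, pbF, cfg, surface = surface)
  expect_equal(unique(as.vector(sat0$R1@values)), 0.1)
  expect_equal(max(abs(sat0$AOD@values)), 0)

  ## linearity of the link: doubling PM2.5 doubles noise-free AOD
  sat1 <- renderSatellite(truth0, rhF, pbF, cfg, surface = surface)
  doubled <- GridCube("pm25", 2 * truth0@values, truth0@time,
                      truth0@lat, truth0@lon)
  sat2 <- renderSatellite(doubled, rhF, pbF, cfg, surface = surface)
  expect_equal(sat2$AOD@values, 2 * sat1$AOD@values, tolerance = 1e-12)

  ## saturated humidity blows up the growth factor -> generation error
  rhBad <- GridCube("RH", array(100, dim(rhF@values)), rhF@time,
                    rhF@lat, rhF@lon, units = "%")
  expect_error(renderSatellite(truth0, rhBad, pbF, cfg, surface = surface),
               "RH")
})

test_that("station sampling is seeded, placed in-grid and noise-calibrated", {
  sc <- tinyScene()
  cfg <- sc@config
  st1 <- sampleStations(sc@truth, cfg, sc@population)
  st2 <- sampleStations(sc@truth, cfg, sc@population)
  expect_identical(st1@sites, st2@sites)
  expect_identical(st1@records$pm25, st2@records$pm25)

  ## noise-free stations reproduce the truth at their host cells exactly
  cfg0 <- tinyConfig(seed = 9, sigmaStation = 0)
  tr <- makeLatentPM25(cfg0)
  st0 <- sampleStations(tr, cfg0)
  cells <- stationCells(st0, tr@lat, tr@lon)
  for (k in seq_len(3)) {
    sid <- cells$station_id[k]
    got <- st0@records$pm25[st0@records$station_id == sid]
    expect_equal(got, tr@values[, cells$row[k], cells$col[k]])
  }

  ## residual sd recovers sigmaStation (floor at 0 barely binds here)
  cells <- stationCells(st1, sc@truth@lat, sc@truth@lon)
  res <- unlist(lapply(seq_len(nrow(cells)), function(k) {
    sid <- cells$station_id[k]
    st1@records$pm25[st1@records$station_id == sid] -
      sc@truth@values[, cells$row[k], cells$col[k]]
  }))
  expect_gt(sd(res), cfg@sigmaStation * 0.9)
  expect_lt(sd(res), cfg@sigmaStation * 1.1)
})

test_that("scene configuration rejects impossible settings", {
  expect_error(sceneConfig(nLat = 0), "positive")
  expect_error(sceneConfig(nStations = 0), "positive|nStations")
  expect_error(sceneConfig(nLat = 3, nLon = 3, nStations = 10), "stations")
  expect_error(sceneConfig(pm25Base = c(DJF = -1, MAM = 50, JJA = 30,
                                        SON = 40)), "positive")
  expect_error(sceneConfig(cloudFractionToar = c(DJF = 1.2, MAM = .5,
                                                 JJA = .5, SON = .5)),
               "0,1|\\[0")
})

test_that("PBLH is generated twice daily while other met fields are hourly", {
  sc <- tinyScene()
  cfg <- sc@config
  expect_length(sc@met$PBLH@time, 2L * cfg@nDays)
  expect_length(sc@met$RH@time, cfg@nDays * cfg@hoursPerDay)
  expect_true(all(sc@met$RH@values < 100))
})
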