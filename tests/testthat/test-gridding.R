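test_that("hourly averaging keeps cloud-free samples only", {
  expect_equal(hourlyAverage(c(0.3, 0.3, 0.3), rep(TRUE, 3)), 0.3)
  expect_equal(hourlyAverage(c(0.2, 0.4, 0.9), c(TRUE, TRUE, FALSE)), 0.3)
  expect_true(is.na(hourlyAverage(rep(0.5, 6), rep(FALSE, 6))))
  expect_equal(hourlyAverage(0.7, TRUE), 0.7)  # idempotent on single samples
  expect_error(hourlyAverage(rep(0.1, 7), rep(TRUE, 7)), "cadence")
})

test_that("sub-hourly cubes aggregate to hourly means cellwise", {
  ## 10-min cadence fixture: 6 samples per hour, 2 hours, tiny grid
  sub <- as.POSIXct("2016-06-01 09:00", tz = "UTC") + 600 * (0:11)
  v <- array(NA_real_, c(12, 2, 2))
  v[, 1, 1] <- c(1, 2, 3, NA, NA, NA, 10, 10, 10, 10, 10, 10)
  v[, 2, 2] <- NA                       # fully cloudy cell
  v[, 1, 2] <- 5                        # always clear
  cube <- GridCube("x", v, sub, 1:2, 1:2)
  h <- hourlyAverageCube(cube)
  expect_length(h@time, 2)
  expect_equal(h@values[1, 1, 1], 2)    # mean of the three clear samples
  expect_equal(h@values[2, 1, 1], 10)
  expect_true(all(is.na(h@values[, 2, 2])))
  expect_equal(h@values[, 1, 2], c(5, 5))
})

test_that("NDVI follows the band-ratio definition with mask propagation", {
  tm <- daytimeAxis(1, 1)
  mk <- function(x) GridCube("r", array(x, c(1, 2, 2)), tm, 1:2, 1:2)
  a <- mk(c(0.4, 0.3, 0.2, NA))
  b <- mk(c(0.1, 0.3, -0.2, 0.1))
  nd <- computeNDVI(a, b)
  expect_equal(nd@values[1, 1, 1], 0.6)          # (0.4-0.1)/(0.4+0.1)
  expect_equal(nd@values[1, 2, 1], 0)            # equal bands
  expect_true(is.na(nd@values[1, 1, 2]))         # zero denominator
  expect_true(is.na(nd@values[1, 2, 2]))         # missing propagates
  wrongGrid <- GridCube("r", array(0.1, c(1, 3, 3)), tm, 1:3, 1:3)
  expect_error(computeNDVI(a, wrongGrid), "grid")
})

test_that("bilinear interpolation is exact at nodes and for affine fields", {
  tm <- daytimeAxis(1, 2)
  lat <- c(0, 1, 2); lon <- c(10, 12, 14)
  v <- array(rnorm(2 * 3 * 3), c(2, 3, 3))
  coarse <- GridCube("m", v, tm, lat, lon)

  atNodes <- interpolateMet(coarse, lat, lon)
  expect_equal(atNodes@values, v)

  ## center of four nodes = their average
  ctr <- interpolateMet(coarse, 0.5, 11)
  expect_equal(ctr@values[1, 1, 1], mean(v[1, 1:2, 1:2]))

  ## any affine-in-(lat,lon) field is reproduced exactly
  aff <- GridCube("m", outer(rep(1, 2), outer(2 * lat, 3 * lon, "+")),
                  tm, lat, lon)
  fine <- interpolateMet(aff, seq(0, 2, 0.25), seq(10, 14, 0.5))
  want <- outer(rep(1, 2), outer(2 * seq(0, 2, 0.25),
                                 3 * seq(10, 14, 0.5), "+"))
  expect_equal(fine@values, want)

  ## spatially constant field stays constant
  cst <- interpolateMet(GridCube("m", array(7, c(2, 3, 3)), tm, lat, lon),
                        c(0.3, 1.7), c(10.1, 13.9))
  expect_equal(as.vector(cst@values), rep(7, length(cst@values)))

  expect_error(interpolateMet(coarse, c(-1, 1), lon), "hull")
})

test_that("temporal-nearest assignment picks closest slice, earlier on ties", {
  lat <- 1:2; lon <- 1:2
  d0 <- as.POSIXct("2016-01-01", tz = "UTC")
  sparse <- GridCube("PBLH",
                     array(rep(c(100, 900), each = 1), c(2, 2, 2)),
                     d0 + 3600 * c(6, 18), lat, lon)
  hours <- d0 + 3600 * c(10, 12, 15)
  out <- assignTemporalNearest(sparse, hours)
  expect_equal(out@values[1, 1, 1], 100)  # |10-6| < |18-10|
  expect_equal(out@values[2, 1, 1], 100)  # exact midpoint -> earlier slice
  expect_equal(out@values[3, 1, 1], 900)

  ## identity when the axes coincide
  idt <- assignTemporalNearest(sparse, sparse@time)
  expect_equal(idt@values, sparse@values)
})

test_that("QC drops sub-detection-limit records and keeps the boundary", {
  sites <- data.frame(station_id = c("A", "B"), lat = c(1, 2), lon = c(1, 2))
  tm <- daytimeAxis(1, 3)
  rec <- data.frame(station_id = rep(c("A", "B"), each = 3),
                    time = rep(tm, 2),
                    pm25 = c(0.5, 1.0, 12.3, 0.2, 0.4, 0.9))
  ss <- StationSeries(sites, rec)
  suppressWarnings(expect_message(out <- qcFilterPM25(ss), "dropped 4 of 6"))
  expect_equal(sort(out@records$pm25), c(1.0, 12.3))

  ## all values >= 1: unchanged
  ok <- StationSeries(sites[1, ], data.frame(station_id = "A", time = tm,
                                             pm25 = c(1, 5, 9)))
  expect_equal(suppressMessages(qcFilterPM25(ok))@records$pm25, c(1, 5, 9))

  ## a station losing every record triggers a warning
  expect_warning(suppressMessages(qcFilterPM25(ss)), "B")
})

test_that("station matching maps to nearest cells and gates on validity", {
  sc <- tinyScene()
  stack <- buildGridStack(sc, gapFilled = FALSE)
  stations <- suppressMessages(qcFilterPM25(sc@stations))
  rows <- matchStations(stations, stack, "TOAR")
  expect_gt(nrow(rows), 0)
  ## every retained row has valid satellite predictors at source
  for (nm in c("R1", "R3", "R6", "NDVI"))
    expect_false(anyNA(rows[[nm]]))
  ## validity gate: rows only where the TOAR mask is TRUE at the host cell
  idx <- cbind(match(as.numeric(rows$time), as.numeric(sc@truth@time)),
               rows$row, rows$col)
  expect_true(all(stack@cubes$R1@valid[idx]))
  expect_true(all(stack@cubes$NDVI@valid[idx]))

  ## a station outside the grid is named in the error
  far <- StationSeries(data.frame(station_id = "OUT", lat = 80, lon = 10),
                       data.frame(station_id = "OUT",
                                  time = sc@truth@time[1], pm25 = 10))
  expect_error(matchStations(far, stack, "TOAR"), "OUT")
})

test_that("gap filling enlarges the training table, never shrinks it", {
  sc <- tinyScene()
  for (mode in c("TOAR", "AOD")) {
    gf <- buildTrainingTable(sc, mode, gapFilled = TRUE)
    og <- buildTrainingTable(sc, mode, gapFilled = FALSE)
    expect_gte(nrow(gf$table@data), nrow(og$table@data))
  }
})
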