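## Synthetic-scene generator: a seeded emulation of the inputs the pipeline
## expects from a geostationary-satellite / reanalysis / station-network
## stack, with known latent PM2.5 ground truth.

#' Build a scene configuration
#'
#' Returns a \linkS4class{SceneConfig} whose defaults define the reference
#' study conditions used throughout the package's tests: a 20 x 20 grid of
#' nominal 5 km cells, 90 daytime days (eight hours 09:00-16:00) spread in
#' four equal blocks over the meteorological seasons, 50 stations, seasonal
#' PM2.5 levels peaking in winter (73.3 / 56.63 / 31.91 / 45.62 ug/m3 for
#' DJF / MAM / JJA / SON), a north-south gradient, and cloud loss averaging
#' about 58\% for the TOAR product with heavier, winter-peaking loss for AOD.
#'
#' Station noise (\code{sigmaStation} = 10 ug/m3, instrument plus
#' cell-representativeness error) and retrieval noise
#' (\code{sigmaRetrieval} = 0.08 AOD units, \code{sigmaReflectance} = 0.008)
#' together set a generative cross-validation R-squared ceiling of about 0.8
#' at these signal levels; see the package vignette for the variance budget.
#'
#' @param nLat,nLon grid dimensions.
#' @param cellKm nominal cell size (km); sets the lat/lon spacing.
#' @param nDays number of daytime days, allocated to seasons in equal blocks
#'   unless \code{seasons} is given explicitly.
#' @param hoursPerDay daytime hours per day, starting 09:00 local.
#' @param seasons optional explicit season label per day.
#' @param pm25Base named seasonal mean PM2.5 levels (ug/m3).
#' @param spatialGradient northward trend (ug/m3 per row), mean-centered.
#' @param corrLengthCells spatial correlation length of the anomaly field.
#' @param ar1Rho hour-to-hour AR(1) coefficient of the anomaly field.
#' @param sigmaField marginal sd of the spatiotemporal anomaly (ug/m3).
#' @param diurnalAmplitude amplitude of a zero-mean within-day cycle that
#'   peaks mid-morning (ug/m3).
#' @param cloudFractionToar,cloudFractionAod named per-season missingness
#'   fractions for the TOAR family and AOD.
#' @param nStations station count.
#' @param sigmaStation station observation noise sd (ug/m3).
#' @param sigmaRetrieval AOD observation noise sd (unitless).
#' @param sigmaReflectance TOAR band noise sd (unitless).
#' @param stationWeighting exponent on population density when placing
#'   stations (0 = uniform; larger = more urban-biased).
#' @param aodCoefficient,rhExponent,scaleHeight parameters of the
#'   PM2.5-to-AOD link: AOD = a * PM25 * (1 - RH/100)^(-kappa) * H0 / PBLH.
#' @param seed integer master seed; every generated artifact is a pure
#'   function of the configuration including this seed.
#' @return a validated \linkS4class{SceneConfig}.
#' @examples
#' cfg <- sceneConfig(nLat = 6, nLon = 6, nDays = 8, nStations = 5, seed = 7)
#' cfg
#' @export
sceneConfig <- function(nLat = 20, nLon = 20, cellKm = 5,
                        nDays = 90, hoursPerDay = 8, seasons = NULL,
                        pm25Base = c(DJF = 73.3, MAM = 56.63,
                                     JJA = 31.91, SON = 45.62),
                        spatialGradient = 0.8,
                        corrLengthCells = 3, ar1Rho = 0.7, sigmaField = 12,
                        diurnalAmplitude = 3,
                        cloudFractionToar = c(DJF = 0.62, MAM = 0.58,
                                              JJA = 0.55, SON = 0.57),
                        cloudFractionAod = c(DJF = 0.80, MAM = 0.68,
                                             JJA = 0.62, SON = 0.66),
                        nStations = 50, sigmaStation = 10,
                        sigmaRetrieval = 0.08, sigmaReflectance = 0.008,
                        stationWeighting = 1,
                        aodCoefficient = 0.005, rhExponent = 0.6,
                        scaleHeight = 1000, seed = 1) {
  if (is.null(seasons)) {
    per <- ceiling(nDays / 4)
    seasons <- rep(SEASONS, each = per)[seq_len(nDays)]
  }
  new("SceneConfig",
      nLat = as.integer(nLat), nLon = as.integer(nLon), cellKm = cellKm,
      nDays = as.integer(nDays), hoursPerDay = as.integer(hoursPerDay),
      seasons = seasons, pm25Base = pm25Base,
      spatialGradient = spatialGradient,
      corrLengthCells = corrLengthCells, ar1Rho = ar1Rho,
      sigmaField = sigmaField, diurnalAmplitude = diurnalAmplitude,
      cloudFractionToar = cloudFractionToar,
      cloudFractionAod = cloudFractionAod,
      nStations = as.integer(nStations), sigmaStation = sigmaStation,
      sigmaRetrieval = sigmaRetrieval, sigmaReflectance = sigmaReflectance,
      stationWeighting = stationWeighting,
      aodCoefficient = aodCoefficient, rhExponent = rhExponent,
      scaleHeight = scaleHeight, seed = as.integer(seed))
}

## Calendar months available to each season; consecutive days of one season
## are laid out month by month so day-of-month stays in range.
.seasonMonths <- list(DJF = c(1L, 2L, 12L), MAM = c(4L, 3L, 5L),
                      JJA = c(7L, 6L, 8L), SON = c(10L, 9L, 11L))

#' Daytime hourly time axis of a scene
#'
#' Maps each day to a calendar date in 2016 whose month belongs to the day's
#' configured season (season blocks fill their months in order), then expands
#' each day into \code{hoursPerDay} hourly timestamps starting 09:00.
#' Nights are simply absent from the axis.
#'
#' @param config a \linkS4class{SceneConfig}.
#' @return \code{POSIXct} vector of length \code{nDays * hoursPerDay} (UTC).
#' @export
sceneTimeAxis <- function(config) {
  dates <- .sceneDates(config)
  hours <- 9L + seq_len(config@hoursPerDay) - 1L
  tm <- rep(dates, each = config@hoursPerDay) + 3600 * rep(hours, config@nDays)
  as.POSIXct(tm, tz = "UTC")
}

.sceneDates <- function(config) {
  out <- rep(as.POSIXct(NA), config@nDays)
  used <- list()
  for (d in seq_len(config@nDays)) {
    s <- config@seasons[d]
    k <- if (is.null(used[[s]])) 0L else used[[s]]
    months <- .seasonMonths[[s]]
    month <- months[(k %/% 28L) + 1L]
    dom <- (k %% 28L) + 1L
    out[d] <- as.POSIXct(sprintf("2016-%02d-%02d", month, dom), tz = "UTC")
    used[[s]] <- k + 1L
  }
  out
}

## Fine-grid axes: cell centers on a regular lat/lon lattice around 30N.
.sceneAxes <- function(config) {
  dlat <- config@cellKm / 111
  dlon <- config@cellKm / (111 * cos(30 * pi / 180))
  list(lat = 29 + dlat * (seq_len(config@nLat) - 1L),
       lon = 118 + dlon * (seq_len(config@nLon) - 1L))
}

## Coarse meteorological axes: 0.25-degree lattice enclosing the fine grid.
.coarseAxes <- function(config) {
  f <- .sceneAxes(config)
  list(lat = seq(0.25 * floor(min(f$lat) / 0.25 - 1),
                 0.25 * ceiling(max(f$lat) / 0.25 + 1), by = 0.25),
       lon = seq(0.25 * floor(min(f$lon) / 0.25 - 1),
                 0.25 * ceiling(max(f$lon) / 0.25 + 1), by = 0.25))
}

#' Generate the latent PM2.5 truth field
#'
#' The latent field is the sum of (i) the configured seasonal base level of
#' each day, (ii) a mean-centered north-south linear trend, (iii) a
#' zero-mean within-day diurnal cycle peaking mid-morning, and (iv) a
#' spatially Gaussian-correlated, temporally AR(1) anomaly with marginal sd
#' \code{sigmaField}; the result is floored at 0.5 ug/m3. Deterministic
#' given the configuration.
#'
#' @param config a \linkS4class{SceneConfig}.
#' @return a fully valid PM2.5 \linkS4class{GridCube} (ug/m3).
#' @export
makeLatentPM25 <- function(config) {
  validObject(config)
  set.seed(config@seed)
  nT <- config@nDays * config@hoursPerDay
  tm <- sceneTimeAxis(config)
  ax <- .sceneAxes(config)
  base <- rep(config@pm25Base[config@seasons], each = config@hoursPerDay)
  rowTrend <- config@spatialGradient *
    (seq_len(config@nLat) - (config@nLat + 1) / 2)
  dayHours <- 9L + seq_len(config@hoursPerDay) - 1L
  hour <- rep(dayHours, config@nDays)
  diShape <- cos(pi * (hour - 10) / 8) -
    mean(cos(pi * (dayHours - 10) / 8))
  anom <- if (config@sigmaField > 0)
    config@sigmaField * ar1FieldStack(nT, config@nLat, config@nLon,
                                      config@corrLengthCells, config@ar1Rho)
  else array(0, c(nT, config@nLat, config@nLon))
  vals <- anom +
    array(rep(base + config@diurnalAmplitude * diShape,
              config@nLat * config@nLon), c(nT, config@nLat, config@nLon)) +
    aperm(array(rep(rowTrend, nT * config@nLon),
                c(config@nLat, nT, config@nLon)), c(2, 1, 3))
  vals <- pmax(vals, 0.5)
  GridCube("pm25", vals, tm, ax$lat, ax$lon, units = "ug/m3")
}

## -- meteorology ------------------------------------------------------------

.seasonScale <- function(config, values) {
  ## per-slice scalar taken from a named per-season vector
  rep(values[config@seasons], each = config@hoursPerDay)
}

#' Generate coarse-grid meteorology
#'
#' Seven hourly fields (RH, SP, TCW, U10, V10, T, TCO) on the 0.25-degree
#' coarse lattice enclosing the scene, plus PBLH at two timestamps per day
#' (06:00 morning, 15:00 afternoon). Each field is a seasonal base plus a
#' smooth AR(1) spatiotemporal perturbation; RH is clamped to [20, 95] so
#' the hygroscopic growth factor stays finite.
#'
#' @param config a \linkS4class{SceneConfig}.
#' @return named list of \linkS4class{GridCube}s on the coarse grid.
#' @export
generateMet <- function(config) {
  set.seed(config@seed + 1L)
  ax <- .coarseAxes(config)
  nT <- config@nDays * config@hoursPerDay
  tm <- sceneTimeAxis(config)
  nla <- length(ax$lat); nlo <- length(ax$lon)
  fld <- function(rho = 0.8, cl = 1.2) ar1FieldStack(nT, nla, nlo, cl, rho)
  addBase <- function(arr, base) arr + array(rep(base, nla * nlo), dim(arr))
  cube <- function(name, vals, units)
    GridCube(name, vals, tm, ax$lat, ax$lon, units = units)

  rh <- addBase(8 * fld(), .seasonScale(config, c(DJF = 62, MAM = 65,
                                                  JJA = 74, SON = 66)))
  rh <- pmin(pmax(rh, 20), 95)
  t2m <- addBase(2 * fld(), .seasonScale(config, c(DJF = 277, MAM = 288,
                                                   JJA = 302, SON = 291)))
  tcw <- pmax(addBase(5 * fld(), .seasonScale(config, c(DJF = 14, MAM = 28,
                                                        JJA = 48, SON = 26))), 2)
  met <- list(
    RH  = cube("RH", rh, "%"),
    SP  = cube("SP", 1013 + 4 * fld(rho = 0.95, cl = 2), "hPa"),
    TCW = cube("TCW", tcw, "kg/m2"),
    U10 = cube("U10", 3 * fld(), "m/s"),
    V10 = cube("V10", 3 * fld(), "m/s"),
    T   = cube("T", t2m, "K"),
    TCO = cube("TCO", 0.0065 + 4e-4 * fld(rho = 0.95, cl = 2), "kg/m2")
  )

  ## PBLH twice daily: shallow morning layer, season-dependent afternoon one
  dates <- .sceneDates(config)
  pblhTimes <- as.POSIXct(rep(dates, each = 2) + 3600 * c(6, 15), tz = "UTC")
  afternoonBase <- c(DJF = 800, MAM = 1100, JJA = 1400, SON = 1000)
  nTP <- length(pblhTimes)
  pb <- 250 * ar1FieldStack(nTP, nla, nlo, 1.2, 0.5)
  base <- rep(450, nTP)                                  # 06:00 slots
  base[seq(2, nTP, by = 2)] <- afternoonBase[config@seasons]  # 15:00 slots
  pb <- pmax(pb + array(rep(base, nla * nlo), dim(pb)), 200)
  met$PBLH <- GridCube("PBLH", pb, pblhTimes, ax$lat, ax$lon, units = "m")
  met
}

## -- satellite rendering ----------------------------------------------------

## Static surface reflectance rasters for the five bands.
.generateSurface <- function(config) {
  set.seed(config@seed + 2L)
  mk <- function(base, amp)
    pmax(base + amp * smoothField(config@nLat, config@nLon,
                                  config@corrLengthCells), 0.01)
  list(R1 = mk(0.10, 0.02), R3 = mk(0.15, 0.03), R6 = mk(0.25, 0.04),
       rho086 = mk(0.30, 0.04), rho226 = mk(0.22, 0.03))
}

## Deterministic smooth observation-angle cubes (degrees).
.generateAngles <- function(config) {
  tm <- sceneTimeAxis(config)
  ax <- .sceneAxes(config)
  nT <- length(tm)
  hour <- as.integer(format(tm, "%H"))
  seasonAdj <- c(DJF = 8, MAM = 0, JJA = -5, SON = 2)
  sAdj <- rep(seasonAdj[config@seasons], each = config@hoursPerDay)
  latIdx <- seq_len(config@nLat); lonIdx <- seq_len(config@nLon)
  grid3 <- function(ft, fi, fj)
    outer(ft, outer(fi, fj, "+"), "+")  # (t) + (i) + (j), dim nT x nLat x nLon
  sza <- grid3(25 + 9 * abs(hour - 12.5) + sAdj, 0.3 * latIdx, 0 * lonIdx)
  saa <- grid3(90 + 20 * (hour - 9), 0 * latIdx, 0.5 * lonIdx)
  vza <- grid3(rep(0, nT), 1.5 * latIdx, 30 + 1.2 * lonIdx)
  vaa <- grid3(rep(200, nT), 0 * latIdx, 0.8 * lonIdx)
  mk <- function(name, a) GridCube(name, a, tm, ax$lat, ax$lon, units = "deg")
  list(SolarZenith = mk("SolarZenith", sza),
       SolarAzimuth = mk("SolarAzimuth", saa),
       SensorZenith = mk("SensorZenith", vza),
       SensorAzimuth = mk("SensorAzimuth", vaa))
}

## Thresholded correlated cloud field: TRUE = cloudy. fractions is a
## per-slice vector of target cloud fractions. Each slice is thresholded at
## the empirical quantile of its own correlated field, so the realized
## missingness matches the configured fraction exactly (up to cell-count
## rounding) while gaps stay spatially and temporally clumped.
.cloudMask <- function(nT, nLat, nLon, corrLength, rho, fractions) {
  g <- ar1FieldStack(nT, nLat, nLon, corrLength, rho)
  out <- array(FALSE, c(nT, nLat, nLon))
  nCell <- nLat * nLon
  for (t in seq_len(nT)) {
    k <- round(fractions[t] * nCell)
    if (k > 0) {
      sl <- g[t, , ]
      out[t, , ][order(sl)[seq_len(k)]] <- TRUE
    }
  }
  out
}

#' Render satellite observations from a truth field
#'
#' Converts the latent PM2.5 cube into observed satellite products through a
#' simple physical link: true AOD is proportional to PM2.5, amplified by
#' hygroscopic growth \eqn{(1 - RH/100)^{-\kappa}} and diluted by the
#' boundary-layer height (\code{scaleHeight / PBLH}); each TOAR band is its
#' static surface reflectance plus a band-dependent aerosol path term
#' \eqn{c_b \cdot AOD / \cos(SZA)} plus Gaussian noise; observed AOD is true
#' AOD plus noise. Correlated, AR(1)-in-time cloud masks are thresholded at
#' the configured per-season fractions; the AOD mask is the TOAR mask plus
#' an independent extra-loss field (AOD retrieval fails wherever the scene
#' is cloudy, and then some), so AOD coverage is everywhere a subset of TOAR
#' coverage.
#'
#' @param truth PM2.5 \linkS4class{GridCube} on the fine grid.
#' @param rhFine,pblhFine RH and PBLH cubes on the fine hourly grid (as
#'   produced by \code{\link{interpolateMet}} and
#'   \code{\link{assignTemporalNearest}}).
#' @param config a \linkS4class{SceneConfig}.
#' @param surface optional list of static surface reflectance matrices
#'   (defaults are generated from the seed).
#' @return named list of satellite \linkS4class{GridCube}s (bands R1, R3,
#'   R6, rho086, rho226, AOD, four angles).
#' @export
renderSatellite <- function(truth, rhFine, pblhFine, config,
                            surface = NULL) {
  stopIfMisaligned(truth, rhFine, "truth and RH")
  stopIfMisaligned(truth, pblhFine, "truth and PBLH")
  rh <- cubeValues(rhFine)
  if (any(rh >= 100, na.rm = TRUE))
    stop("RH >= 100% encountered: hygroscopic growth factor diverges")
  if (is.null(surface)) surface <- .generateSurface(config)
  set.seed(config@seed + 3L)

  nT <- length(truth@time)
  nla <- config@nLat; nlo <- config@nLon
  growth <- (1 - rh / 100)^(-config@rhExponent)
  aodTrue <- config@aodCoefficient * cubeValues(truth) * growth *
    (config@scaleHeight / cubeValues(pblhFine))

  angles <- .generateAngles(config)
  cosSza <- cos(cubeValues(angles$SolarZenith) * pi / 180)

  bandCoef <- c(R1 = 0.12, R3 = 0.08, R6 = 0.02, rho086 = 0.05, rho226 = 0.02)
  noise <- function(sdv) array(rnorm(nT * nla * nlo, 0, sdv), c(nT, nla, nlo))
  surfArr <- function(m) aperm(array(rep(m, nT), c(nla, nlo, nT)), c(3, 1, 2))
  bands <- lapply(names(bandCoef), function(b)
    surfArr(surface[[b]]) + bandCoef[[b]] * aodTrue / cosSza +
      noise(config@sigmaReflectance))
  names(bands) <- names(bandCoef)
  aodObs <- aodTrue + noise(config@sigmaRetrieval)

  perSlice <- function(fr) rep(fr[config@seasons], each = config@hoursPerDay)
  fToar <- perSlice(config@cloudFractionToar)
  fAod <- perSlice(config@cloudFractionAod)
  toarCloud <- .cloudMask(nT, nla, nlo, 2.5, 0.6, fToar)
  ## extra AOD-only retrieval loss on top of the shared cloud deck, drawn
  ## from an independent correlated field and thresholded among the cells
  ## the cloud deck left visible, so AOD coverage is a subset of TOAR's and
  ## hits its own configured per-season fraction
  fExtra <- ifelse(fAod > fToar, (fAod - fToar) / (1 - fToar), 0)
  gExtra <- ar1FieldStack(nT, nla, nlo, 2.5, 0.6)
  aodCloud <- toarCloud
  for (t in seq_len(nT)) {
    free <- which(!toarCloud[t, , ])
    k <- round(fExtra[t] * length(free))
    if (k > 0) {
      sl <- gExtra[t, , ][free]
      aodCloud[t, , ][free[order(sl)[seq_len(k)]]] <- TRUE
    }
  }

  tm <- truth@time; ax <- .sceneAxes(config)
  maskCube <- function(name, vals, cloudy, units = "") {
    vals[cloudy] <- NA_real_
    GridCube(name, vals, tm, ax$lat, ax$lon, units = units)
  }
  out <- list(
    R1 = maskCube("R1", bands$R1, toarCloud),
    R3 = maskCube("R3", bands$R3, toarCloud),
    R6 = maskCube("R6", bands$R6, toarCloud),
    rho086 = maskCube("rho086", bands$rho086, toarCloud),
    rho226 = maskCube("rho226", bands$rho226, toarCloud),
    AOD = maskCube("AOD", aodObs, aodCloud))
  for (nm in names(angles)) {
    v <- cubeValues(angles[[nm]])
    out[[nm]] <- maskCube(nm, v, toarCloud, units = "deg")
  }
  out
}

#' Place stations and sample their hourly series
#'
#' Station host cells are drawn without replacement, with probability
#' proportional to \code{population^stationWeighting} (uniform when the
#' exponent is 0), emulating an urban-biased monitoring network. Each
#' station's hourly series is the truth at its host cell plus Gaussian noise
#' of sd \code{sigmaStation}, floored at 0.
#'
#' @param truth PM2.5 \linkS4class{GridCube}.
#' @param config a \linkS4class{SceneConfig}.
#' @param population optional lat x lon matrix for density weighting.
#' @return a \linkS4class{StationSeries} (all records initially QC-pass).
#' @export
sampleStations <- function(truth, config, population = NULL) {
  if (config@nStations < 1L) stop("nStations must be positive")
  set.seed(config@seed + 4L)
  nla <- length(truth@lat); nlo <- length(truth@lon)
  w <- if (is.null(population) || config@stationWeighting == 0)
    rep(1, nla * nlo)
  else as.vector(population)^config@stationWeighting
  cells <- sample.int(nla * nlo, config@nStations, prob = w)
  ri <- (cells - 1L) %% nla + 1L
  ci <- (cells - 1L) %/% nla + 1L
  ids <- sprintf("S%03d", seq_len(config@nStations))
  sites <- data.frame(station_id = ids, lat = truth@lat[ri],
                      lon = truth@lon[ci])
  nT <- length(truth@time)
  obs <- vapply(seq_len(config@nStations), function(s)
    pmax(truth@values[, ri[s], ci[s]] +
           rnorm(nT, 0, config@sigmaStation), 0), numeric(nT))
  records <- data.frame(
    station_id = rep(ids, each = nT),
    time = rep(truth@time, config@nStations),
    pm25 = as.vector(obs),
    qc_pass = TRUE)
  StationSeries(sites, records)
}

#' Generate the static population raster
#'
#' Log-normal marginal with spatial correlation plus one urban hotspot
#' (a Gaussian bump multiplying the field), static over the scene.
#'
#' @param config a \linkS4class{SceneConfig}.
#' @return lat x lon matrix of persons per cell.
#' @export
generatePopulation <- function(config) {
  set.seed(config@seed + 5L)
  nla <- config@nLat; nlo <- config@nLon
  base <- exp(log(500) + 0.8 * smoothField(nla, nlo, config@corrLengthCells))
  r0 <- sample.int(nla, 1); c0 <- sample.int(nlo, 1)
  d2 <- outer((seq_len(nla) - r0)^2, (seq_len(nlo) - c0)^2, "+")
  base * (1 + 15 * exp(-d2 / (2 * 3^2)))
}

#' Simulate a complete synthetic scene
#'
#' Orchestrates the generator: latent truth, coarse meteorology, satellite
#' rendering (with RH/PBLH first brought to the fine hourly grid exactly as
#' the gridding stage will do), station sampling and the population raster.
#' Every component is a pure function of the configuration.
#'
#' @param config a \linkS4class{SceneConfig}.
#' @return a \linkS4class{SceneBundle}.
#' @examples
#' sc <- simulateScene(sceneConfig(nLat = 6, nLon = 6, nDays = 8,
#'                                 nStations = 5, seed = 3))
#' sc
#' @export
simulateScene <- function(config) {
  validObject(config)
  truth <- makeLatentPM25(config)
  met <- generateMet(config)
  rhFine <- interpolateMet(met$RH, truth@lat, truth@lon)
  pblhHourly <- assignTemporalNearest(met$PBLH, truth@time)
  pblhFine <- interpolateMet(pblhHourly, truth@lat, truth@lon)
  satellite <- renderSatellite(truth, rhFine, pblhFine, config)
  population <- generatePopulation(config)
  stations <- sampleStations(truth, config, population)
  new("SceneBundle", satellite = satellite, met = met, stations = stations,
      population = population, truth = truth, config = config)
}
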