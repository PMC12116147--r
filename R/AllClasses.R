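#' @import methods
#' @importFrom stats cor lm coef rnorm runif qnorm sd var predict
#'   complete.cases setNames
#' @importFrom utils head
NULL

setOldClass("POSIXct")

## ---------------------------------------------------------------------------
## GridCube: one variable on a (time, lat, lon) lattice with a validity mask
## ---------------------------------------------------------------------------

#' GridCube: a masked spatiotemporal field
#'
#' The universal carrier for satellite, meteorological and predicted fields:
#' one variable on a regular (time, lat, lon) lattice together with a logical
#' validity mask. Invalid cells hold \code{NA} and never enter arithmetic;
#' all mask-aware operations in the package read values only where the mask
#' is \code{TRUE}.
#'
#' @slot variable variable name, e.g. \code{"R1"} or \code{"pm25"}.
#' @slot units unit string, e.g. \code{"ug/m3"}; \code{""} for unitless.
#' @slot time strictly increasing hourly \code{POSIXct} axis (daytime hours
#'   only; the overnight gap simply has no timestamps).
#' @slot lat ascending latitude axis of cell centers (degrees north).
#' @slot lon ascending longitude axis of cell centers (degrees east).
#' @slot values numeric array of dim (time, lat, lon); \code{NA} where invalid.
#' @slot valid logical array of the same dimension.
#'
#' @examples
#' tm <- as.POSIXct("2016-01-01 09:00", tz = "UTC") + 3600 * (0:3)
#' cube <- GridCube("toy", array(1, c(4, 2, 3)), tm, c(30, 31), c(118, 119, 120))
#' nValid(cube)
#' @export
setClass("GridCube",
  representation(
    variable = "character",
    units    = "character",
    time     = "POSIXct",
    lat      = "numeric",
    lon      = "numeric",
    values   = "array",
    valid    = "array"
  )
)

setValidity("GridCube", function(object) {
  d <- c(length(object@time), length(object@lat), length(object@lon))
  if (!identical(dim(object@values), as.integer(d)))
    return(sprintf("values dim (%s) does not match axes (%s)",
                   paste(dim(object@values), collapse = "x"),
                   paste(d, collapse = "x")))
  if (!identical(dim(object@valid), as.integer(d)))
    return("valid mask dim does not match axes")
  if (!is.logical(object@valid)) return("valid mask must be logical")
  if (length(object@time) > 1 && any(diff(as.numeric(object@time)) <= 0))
    return("time axis must be strictly increasing")
  if (is.unsorted(object@lat, strictly = TRUE) && length(object@lat) > 1)
    return("lat axis must be strictly ascending")
  if (is.unsorted(object@lon, strictly = TRUE) && length(object@lon) > 1)
    return("lon axis must be strictly ascending")
  if (anyNA(object@valid)) return("valid mask may not contain NA")
  if (anyNA(object@values[object@valid]))
    return("NA value inside the valid mask")
  TRUE
})

#' Construct a GridCube
#'
#' @param variable variable name.
#' @param values numeric array (time x lat x lon). \code{NA} entries are
#'   marked invalid when \code{valid} is not supplied.
#' @param time,lat,lon coordinate axes (see \linkS4class{GridCube}).
#' @param units unit string.
#' @param valid optional logical array; defaults to \code{!is.na(values)}.
#' @return a \linkS4class{GridCube}.
#' @export
GridCube <- function(variable, values, time, lat, lon, units = "",
                     valid = NULL) {
  values <- array(as.numeric(values),
                  dim = c(length(time), length(lat), length(lon)))
  if (is.null(valid)) valid <- !is.na(values)
  valid <- array(as.logical(valid), dim = dim(values))
  values[!valid] <- NA_real_
  new("GridCube", variable = variable, units = units,
      time = as.POSIXct(time, tz = "UTC"), lat = as.numeric(lat),
      lon = as.numeric(lon), values = values, valid = valid)
}

setMethod("show", "GridCube", function(object) {
  cat(sprintf("GridCube '%s'%s: %d h x %d lat x %d lon, %d/%d valid (%.1f%%)\n",
              object@variable,
              if (nzchar(object@units)) paste0(" [", object@units, "]") else "",
              length(object@time), length(object@lat), length(object@lon),
              nValid(object), length(object@values),
              100 * nValid(object) / length(object@values)))
  rng <- range(object@time)
  cat(sprintf("  time: %s .. %s\n", format(rng[1]), format(rng[2])))
})

## ---------------------------------------------------------------------------
## StationSeries
## ---------------------------------------------------------------------------

#' StationSeries: ground-station PM2.5 time series
#'
#' Hourly PM2.5 observations from a monitoring network, with station
#' coordinates and QC flags.
#'
#' @slot sites data.frame with columns \code{station_id, lat, lon}.
#' @slot records data.frame with columns
#'   \code{station_id, time, pm25, qc_pass}; at most one record per
#'   station-hour.
#' @export
setClass("StationSeries",
  representation(sites = "data.frame", records = "data.frame"))

setValidity("StationSeries", function(object) {
  need <- c("station_id", "lat", "lon")
  if (!all(need %in% names(object@sites)))
    return("sites needs columns station_id, lat, lon")
  needr <- c("station_id", "time", "pm25", "qc_pass")
  if (!all(needr %in% names(object@records)))
    return("records needs columns station_id, time, pm25, qc_pass")
  if (anyDuplicated(object@sites$station_id))
    return("duplicate station_id in sites")
  key <- paste(object@records$station_id, format(object@records$time))
  if (anyDuplicated(key)) return("more than one record per station-hour")
  if (!all(object@records$station_id %in% object@sites$station_id))
    return("record for unknown station")
  TRUE
})

#' Construct a StationSeries
#' @param sites data.frame (\code{station_id, lat, lon}).
#' @param records data.frame (\code{station_id, time, pm25, qc_pass});
#'   \code{qc_pass} defaults to \code{TRUE}.
#' @return a \linkS4class{StationSeries}.
#' @export
StationSeries <- function(sites, records) {
  if (is.null(records$qc_pass)) records$qc_pass <- TRUE
  records$time <- as.POSIXct(records$time, tz = "UTC")
  new("StationSeries", sites = as.data.frame(sites),
      records = as.data.frame(records))
}

setMethod("show", "StationSeries", function(object) {
  cat(sprintf("StationSeries: %d stations, %d records (%d QC-pass)\n",
              nrow(object@sites), nrow(object@records),
              sum(object@records$qc_pass)))
})

## ---------------------------------------------------------------------------
## SceneConfig
## ---------------------------------------------------------------------------

#' SceneConfig: parameters of the synthetic-scene generator
#'
#' Bundles every knob of the synthetic study area: grid size, seasonal PM2.5
#' levels, spatial/temporal correlation, per-season cloud fractions for the
#' TOAR and AOD products, station network size, and the noise standard
#' deviations. See \code{\link{sceneConfig}} for the defaults and their
#' rationale.
#'
#' @export
setClass("SceneConfig",
  representation(
    nLat = "integer", nLon = "integer", cellKm = "numeric",
    nDays = "integer", hoursPerDay = "integer",
    seasons = "character",           # one label per day (DJF/MAM/JJA/SON)
    pm25Base = "numeric",            # named per season, ug/m3
    spatialGradient = "numeric",     # ug/m3 per row, northward
    corrLengthCells = "numeric",
    ar1Rho = "numeric",
    sigmaField = "numeric",          # anomaly sd, ug/m3
    diurnalAmplitude = "numeric",    # ug/m3, zero-mean within the day
    cloudFractionToar = "numeric",   # named per season, in [0,1]
    cloudFractionAod = "numeric",
    nStations = "integer",
    sigmaStation = "numeric",        # ug/m3
    sigmaRetrieval = "numeric",      # AOD noise sd, unitless
    sigmaReflectance = "numeric",    # TOAR band noise sd, unitless
    stationWeighting = "numeric",    # population-density weighting exponent
    aodCoefficient = "numeric",      # a in AOD = a * PM25 * g(RH) * H0/PBLH
    rhExponent = "numeric",          # kappa in g(RH) = (1 - RH/100)^(-kappa)
    scaleHeight = "numeric",         # H0, m
    seed = "integer"
  )
)

setValidity("SceneConfig", function(object) {
  if (object@nLat < 1L || object@nLon < 1L || object@nDays < 1L ||
      object@hoursPerDay < 1L)
    return("grid and time dimensions must be positive")
  if (length(object@seasons) != object@nDays)
    return("seasons must carry one label per day")
  if (!all(object@seasons %in% names(object@pm25Base)))
    return("every season label needs a pm25Base entry")
  if (any(object@pm25Base <= 0)) return("pm25Base must be strictly positive")
  fr <- c(object@cloudFractionToar, object@cloudFractionAod)
  if (any(fr < 0 | fr > 1)) return("cloud fractions must lie in [0,1]")
  if (object@ar1Rho < 0 || object@ar1Rho >= 1)
    return("ar1Rho must lie in [0,1)")
  if (object@nStations < 1L) return("nStations must be positive")
  if (object@nStations > object@nLat * object@nLon)
    return("more stations than grid cells")
  TRUE
})

setMethod("show", "SceneConfig", function(object) {
  cat(sprintf(
    "SceneConfig: %dx%d cells (%.0f km), %d days x %d h, %d stations, seed %d\n",
    object@nLat, object@nLon, object@cellKm, object@nDays,
    object@hoursPerDay, object@nStations, object@seed))
  cat("  pm25Base:",
      paste(sprintf("%s=%.2f", names(object@pm25Base), object@pm25Base),
            collapse = ", "), "\n")
  cat("  cloud TOAR:",
      paste(sprintf("%s=%.2f", names(object@cloudFractionToar),
                    object@cloudFractionToar), collapse = ", "),
      "| AOD:",
      paste(sprintf("%s=%.2f", names(object@cloudFractionAod),
                    object@cloudFractionAod), collapse = ", "), "\n")
})

## ---------------------------------------------------------------------------
## SceneBundle
## ---------------------------------------------------------------------------

#' SceneBundle: one synthetic scene
#'
#' Everything a pipeline run consumes: satellite cubes (three TOAR bands, the
#' two NDVI input reflectances, AOD, four observation angles), coarse-grid
#' meteorology (RH, SP, TCW, U10, V10, T, TCO hourly; PBLH twice daily), the
#' station network, a static population raster, and the fully valid latent
#' PM2.5 truth cube the scene was generated from.
#'
#' @slot satellite named list of \linkS4class{GridCube}s on the fine grid:
#'   R1, R3, R6, rho086, rho226, AOD, SensorZenith, SensorAzimuth,
#'   SolarZenith, SolarAzimuth. TOAR-family cubes share one mask; AOD has its
#'   own (a superset of the TOAR mask).
#' @slot met named list of \linkS4class{GridCube}s on the coarse grid:
#'   RH, SP, TCW, U10, V10, T, TCO (hourly) and PBLH (twice daily).
#' @slot stations a \linkS4class{StationSeries}.
#' @slot population lat x lon matrix of persons per cell (static).
#' @slot truth fully valid PM2.5 \linkS4class{GridCube} (ug/m3).
#' @slot config the generating \linkS4class{SceneConfig}.
#' @export
setClass("SceneBundle",
  representation(
    satellite = "list", met = "list", stations = "StationSeries",
    population = "matrix", truth = "GridCube", config = "SceneConfig"))

setValidity("SceneBundle", function(object) {
  sat <- object@satellite
  need <- c("R1", "R3", "R6", "rho086", "rho226", "AOD",
            "SensorZenith", "SensorAzimuth", "SolarZenith", "SolarAzimuth")
  if (!all(need %in% names(sat)))
    return(paste("satellite list missing:",
                 paste(setdiff(need, names(sat)), collapse = ", ")))
  ax <- function(cb) list(cb@time, cb@lat, cb@lon)
  ref <- ax(object@truth)
  for (nm in need)
    if (!identical(ax(sat[[nm]]), ref))
      return(sprintf("satellite cube '%s' not on the truth grid", nm))
  if (any(!object@truth@valid)) return("truth cube must be fully valid")
  toarFam <- setdiff(need, "AOD")
  m0 <- sat[[toarFam[1]]]@valid
  for (nm in toarFam[-1])
    if (!identical(sat[[nm]]@valid, m0))
      return("TOAR-family cubes must share one validity mask")
  if (!identical(dim(object@population),
                 c(length(ref[[2]]), length(ref[[3]]))))
    return("population raster must be lat x lon on the fine grid")
  TRUE
})

setMethod("show", "SceneBundle", function(object) {
  cfg <- object@config
  cat(sprintf("SceneBundle: %dx%d grid, %d hourly slices, %d stations\n",
              cfg@nLat, cfg@nLon, length(object@truth@time),
              nrow(object@stations@sites)))
  vf <- function(cb) mean(cb@valid)
  cat(sprintf("  TOAR valid: %.1f%% | AOD valid: %.1f%%\n",
              100 * vf(object@satellite$R1), 100 * vf(object@satellite$AOD)))
})

## ---------------------------------------------------------------------------
## GridStack: aligned hourly predictor cubes on the analysis grid
## ---------------------------------------------------------------------------

#' GridStack: aligned hourly predictor cubes
#'
#' The product of the gridding stage: all predictor fields (satellite bands,
#' angles, NDVI, AOD, interpolated meteorology, temporally assigned PBLH) on
#' one shared fine (time, lat, lon) lattice, ready for station matching and
#' grid prediction.
#'
#' @slot cubes named list of \linkS4class{GridCube}s sharing all three axes.
#' @export
setClass("GridStack", representation(cubes = "list"))

setValidity("GridStack", function(object) {
  if (length(object@cubes) == 0) return("empty stack")
  if (is.null(names(object@cubes)) || any(!nzchar(names(object@cubes))))
    return("cubes must be named")
  ref <- object@cubes[[1]]
  for (nm in names(object@cubes)) {
    cb <- object@cubes[[nm]]
    if (!is(cb, "GridCube")) return(sprintf("'%s' is not a GridCube", nm))
    if (!identical(cb@time, ref@time) || !identical(cb@lat, ref@lat) ||
        !identical(cb@lon, ref@lon))
      return(sprintf("cube '%s' is not aligned with the stack", nm))
  }
  TRUE
})

#' @export
GridStack <- function(cubes) new("GridStack", cubes = cubes)

setMethod("show", "GridStack", function(object) {
  cat(sprintf("GridStack: %d cubes [%s] on %d h x %d x %d\n",
              length(object@cubes),
              paste(names(object@cubes), collapse = ", "),
              length(object@cubes[[1]]@time),
              length(object@cubes[[1]]@lat), length(object@cubes[[1]]@lon)))
})

## ---------------------------------------------------------------------------
## ImputeConfig
## ---------------------------------------------------------------------------

#' ImputeConfig: settings of the spatiotemporal convolution imputer
#'
#' The defaults reproduce the 3 x 3 x 3 sliding kernel: half-width 1 in the
#' temporal dimension and 1 in each spatial dimension, a single pass in which
#' only originally valid values feed the neighborhood means, and a minimum of
#' one valid neighbor.
#'
#' @slot temporalHalfWidth,spatialHalfWidth kernel half-widths (default 1).
#' @slot passes number of filling passes (default 1); values filled in an
#'   earlier pass count as valid in later passes.
#' @slot minValidNeighbors minimum valid neighbors required to fill (>= 1).
#' @export
setClass("ImputeConfig",
  representation(temporalHalfWidth = "integer", spatialHalfWidth = "integer",
                 passes = "integer", minValidNeighbors = "integer"))

setValidity("ImputeConfig", function(object) {
  if (object@temporalHalfWidth < 1L || object@spatialHalfWidth < 1L)
    return("kernel half-widths must be positive")
  if (object@passes < 1L) return("passes must be positive")
  if (object@minValidNeighbors < 1L)
    return("minValidNeighbors must be at least 1")
  TRUE
})

#' Construct an ImputeConfig
#' @param temporalHalfWidth,spatialHalfWidth,passes,minValidNeighbors see
#'   \linkS4class{ImputeConfig}.
#' @return an \linkS4class{ImputeConfig}.
#' @export
imputeConfig <- function(temporalHalfWidth = 1, spatialHalfWidth = 1,
                         passes = 1, minValidNeighbors = 1) {
  new("ImputeConfig",
      temporalHalfWidth = as.integer(temporalHalfWidth),
      spatialHalfWidth = as.integer(spatialHalfWidth),
      passes = as.integer(passes),
      minValidNeighbors = as.integer(minValidNeighbors))
}

## ---------------------------------------------------------------------------
## FeatureTable
## ---------------------------------------------------------------------------

#' FeatureTable: matched station-hour training rows
#'
#' One row per retained station-hour, projected to the predictor set of the
#' chosen mode. TOAR mode carries the three reflectance bands, coordinates,
#' the month/day/hour dummies, the four observation angles, NDVI and the
#' eight meteorological fields (21 predictors); AOD mode carries AOD,
#' coordinates, the time dummies and the meteorology (14 predictors). The
#' target column is \code{pm25}. No entry is ever missing: validity is
#' enforced upstream by the matching gate.
#'
#' @slot mode \code{"TOAR"} or \code{"AOD"}.
#' @slot data data.frame of predictors + \code{pm25}, plus bookkeeping
#'   columns \code{station_id} and \code{time} (not predictors).
#' @export
setClass("FeatureTable",
  representation(mode = "character", data = "data.frame"))

setValidity("FeatureTable", function(object) {
  if (!object@mode %in% c("TOAR", "AOD")) return("mode must be TOAR or AOD")
  need <- c(featureColumns(object@mode), "pm25")
  miss <- setdiff(need, names(object@data))
  if (length(miss))
    return(paste("missing columns:", paste(miss, collapse = ", ")))
  if (nrow(object@data) &&
      anyNA(object@data[, need]))
    return("FeatureTable may not contain missing values")
  TRUE
})

setMethod("show", "FeatureTable", function(object) {
  cat(sprintf("FeatureTable (%s mode): %d rows, %d predictors + pm25\n",
              object@mode, nrow(object@data),
              length(featureColumns(object@mode))))
})

## ---------------------------------------------------------------------------
## FittedModel / CVResult
## ---------------------------------------------------------------------------

#' FittedModel: a trained PM2.5 learner
#'
#' @slot algorithm one of \code{"RF"}, \code{"GBR"}, \code{"XGBoost"},
#'   \code{"SVR"}.
#' @slot mode \code{"TOAR"} or \code{"AOD"}.
#' @slot hyper named list of hyperparameters used.
#' @slot featureNames predictor columns in training order.
#' @slot fit the backend model object.
#' @slot seed integer seed the fit was made reproducible with.
#' @export
setClass("FittedModel",
  representation(algorithm = "character", mode = "character",
                 hyper = "list", featureNames = "character",
                 fit = "ANY", seed = "integer"))

setMethod("show", "FittedModel", function(object) {
  cat(sprintf("FittedModel: %s (%s mode), %d predictors\n  hyper: %s\n",
              object@algorithm, object@mode, length(object@featureNames),
              paste(sprintf("%s=%s", names(object@hyper),
                            unlist(object@hyper)), collapse = ", ")))
})

#' CVResult: pooled out-of-fold cross-validation predictions
#'
#' @slot data data.frame with \code{station_id, time, fold, observed,
#'   predicted}; every row sits in exactly one validation fold.
#' @slot metrics list with pooled \code{r2} (squared Pearson correlation),
#'   \code{r2_ss} (1 - SSres/SStot), \code{rmse} (ug/m3) and \code{slope}
#'   (OLS slope of predicted on observed).
#' @slot bySeason data.frame of the same metrics per season.
#' @slot algorithm,mode,hyper,seed provenance of the winning configuration.
#' @export
setClass("CVResult",
  representation(data = "data.frame", metrics = "list",
                 bySeason = "data.frame", algorithm = "character",
                 mode = "character", hyper = "list", seed = "integer"))

setMethod("show", "CVResult", function(object) {
  m <- object@metrics
  cat(sprintf(
    "CVResult: %s (%s), %d rows, %d folds\n  R2 = %.3f, RMSE = %.2f ug/m3, slope = %.3f\n",
    object@algorithm, object@mode, nrow(object@data),
    length(unique(object@data$fold)), m$r2, m$rmse, m$slope))
})

## ---------------------------------------------------------------------------
## ExposureSummary
## ---------------------------------------------------------------------------

#' ExposureSummary: population-weighted exposure assessment
#'
#' @slot weightedMean population-weighted mean PM2.5 (ug/m3).
#' @slot cdf data.frame \code{(threshold, population)}: resident population
#'   in cells whose annual mean is at or above each threshold.
#' @slot standard the applied standard (ug/m3).
#' @slot attainFraction,nonAttainFraction population fractions below /
#'   strictly above the standard, over covered cells; they sum to 1.
#' @slot totalPopulation population in cells with a valid annual mean.
#' @slot uncoveredPopulation population in cells without a valid annual mean
#'   (excluded from the fractions rather than silently assumed attaining).
#' @export
setClass("ExposureSummary",
  representation(weightedMean = "numeric", cdf = "data.frame",
                 standard = "numeric", attainFraction = "numeric",
                 nonAttainFraction = "numeric", totalPopulation = "numeric",
                 uncoveredPopulation = "numeric"))

setMethod("show", "ExposureSummary", function(object) {
  cat(sprintf("ExposureSummary (standard %.0f ug/m3)\n", object@standard))
  cat(sprintf("  population-weighted mean: %.1f ug/m3\n", object@weightedMean))
  cat(sprintf("  non-attainment: %.1f%% of %.3g covered persons (%.3g uncovered)\n",
              100 * object@nonAttainFraction, object@totalPopulation,
              object@uncoveredPopulation))
})
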