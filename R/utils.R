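## Accessors and small shared helpers.

#' Cube accessors
#'
#' Read-only access to \linkS4class{GridCube} components. \code{cubeValues}
#' returns the value array with \code{NA} at invalid cells, so downstream
#' arithmetic can never pick up a sentinel.
#'
#' @param x a \linkS4class{GridCube}.
#' @return \code{cubeValues}: numeric array; \code{validMask}: logical array;
#'   \code{timeAxis}/\code{latAxis}/\code{lonAxis}: the axes;
#'   \code{nValid}: integer count of valid cells.
#' @export
cubeValues <- function(x) x@values

#' @rdname cubeValues
#' @export
validMask <- function(x) x@valid

#' @rdname cubeValues
#' @export
timeAxis <- function(x) x@time

#' @rdname cubeValues
#' @export
latAxis <- function(x) x@lat

#' @rdname cubeValues
#' @export
lonAxis <- function(x) x@lon

#' @rdname cubeValues
#' @export
nValid <- function(x) sum(x@valid)

#' StationSeries accessors
#' @param x a \linkS4class{StationSeries}.
#' @return \code{stationSites}: the site table; \code{stationRecords}: the
#'   record table.
#' @export
stationSites <- function(x) x@sites

#' @rdname stationSites
#' @export
stationRecords <- function(x) x@records

#' Meteorological season of a timestamp
#'
#' Maps calendar months to DJF (12, 1, 2), MAM (3-5), JJA (6-8), SON (9-11).
#' Within a single analysis year DJF combines that year's January, February
#' and December.
#'
#' @param time a \code{POSIXct} vector.
#' @return character vector of season labels.
#' @export
seasonOf <- function(time) {
  m <- as.integer(format(time, "%m"))
  c("DJF", "DJF", "MAM", "MAM", "MAM", "JJA",
    "JJA", "JJA", "SON", "SON", "SON", "DJF")[m]
}

## Order used for all per-season reporting.
SEASONS <- c("DJF", "MAM", "JJA", "SON")

#' Predictor column sets of the two model modes
#'
#' TOAR mode: the three reflectance bands, coordinates, the month/day/hour
#' dummies, four observation angles, NDVI and eight meteorological fields.
#' AOD mode: AOD, coordinates, time dummies and the meteorology.
#'
#' @param mode \code{"TOAR"} or \code{"AOD"}.
#' @return character vector of predictor column names.
#' @export
featureColumns <- function(mode = c("TOAR", "AOD")) {
  mode <- match.arg(mode)
  met <- c("RH", "SP", "TCW", "U10", "V10", "T", "TCO", "PBLH")
  tim <- c("month", "day", "hour")
  if (mode == "TOAR")
    c("R1", "R3", "R6", "Lat", "Lon", tim,
      "SensorZenith", "SensorAzimuth", "SolarZenith", "SolarAzimuth",
      "NDVI", met)
  else
    c("AOD", "Lat", "Lon", tim, met)
}

## -- internal helpers -------------------------------------------------------

## Gaussian-smoothed standard-normal random field (nLat x nLon).
## Separable smoothing of white noise; renormalized to unit marginal sd so
## thresholding at qnorm(f) yields an expected exceedance fraction f.
smoothField <- function(nLat, nLon, corrLength) {
  z <- matrix(rnorm(nLat * nLon), nLat, nLon)
  if (corrLength <= 0) return(z)
  half <- max(1L, ceiling(3 * corrLength))
  k <- exp(-0.5 * ((-half:half) / corrLength)^2)
  k <- k / sum(k)
  convRows <- function(m) {
    idx <- outer(seq_len(nrow(m)), -half:half, "+")
    idx <- pmin(pmax(idx, 1L), nrow(m))   # clamp at edges
    out <- matrix(0, nrow(m), ncol(m))
    for (d in seq_along(k))
      out <- out + k[d] * m[idx[, d], , drop = FALSE]
    out
  }
  z <- convRows(z)
  z <- t(convRows(t(z)))
  if (length(z) > 1) {
    z <- z - mean(z)          # anomalies carry no regional-mean signal
    z <- z / sd(as.vector(z))
  }
  z
}

## AR(1)-in-time stack of smoothed fields with unit marginal variance.
## Returns an array (nT, nLat, nLon).
ar1FieldStack <- function(nT, nLat, nLon, corrLength, rho) {
  out <- array(0, c(nT, nLat, nLon))
  z <- smoothField(nLat, nLon, corrLength)
  out[1, , ] <- z
  if (nT > 1) {
    innov <- sqrt(1 - rho^2)
    for (t in 2:nT) {
      z <- rho * z + innov * smoothField(nLat, nLon, corrLength)
      out[t, , ] <- z
    }
  }
  out
}

## Shared axis check for binary cube operations.
stopIfMisaligned <- function(a, b, what = "cubes") {
  if (!identical(a@time, b@time) || !identical(a@lat, b@lat) ||
      !identical(a@lon, b@lon))
    stop(sprintf("%s are not on the same grid", what), call. = FALSE)
  invisible(TRUE)
}
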