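## Gridding: hourly averaging of sub-hourly satellite samples, NDVI, bilinear
## meteorological interpolation, temporal-nearest assignment, station QC and
## station-to-cell matching.

#' Hourly mean of sub-hourly cloud-free samples
#'
#' A geostationary imager revisits each cell several times per hour (up to
#' six at a 10-minute cadence); the hourly grid value is the arithmetic mean
#' of the cloud-free samples, or missing when none are cloud-free.
#'
#' @param values numeric vector of sub-hourly samples for one cell-hour
#'   (at most 6).
#' @param cloudFree logical vector marking the cloud-free samples.
#' @return the mean of the cloud-free values, or \code{NA} if there is none.
#' @examples
#' hourlyAverage(c(0.2, 0.4, 0.9), c(TRUE, TRUE, FALSE))  # 0.3
#' @export
hourlyAverage <- function(values, cloudFree = !is.na(values)) {
  if (length(values) > 6)
    stop("more than 6 sub-hourly samples in one hour: unexpected cadence")
  if (length(values) != length(cloudFree))
    stop("values and cloudFree lengths differ")
  v <- values[cloudFree & !is.na(values)]
  if (length(v) == 0) NA_real_ else mean(v)
}

#' Aggregate a sub-hourly cube to hourly means
#'
#' Applies \code{\link{hourlyAverage}} cellwise: samples are grouped by the
#' hour their timestamp falls in; a cell-hour is valid when at least one
#' sample in the group is valid (cloud-free).
#'
#' @param cube \linkS4class{GridCube} at sub-hourly cadence; invalid cells
#'   are the cloudy samples.
#' @return an hourly \linkS4class{GridCube}.
#' @export
hourlyAverageCube <- function(cube) {
  hour <- as.POSIXct(trunc(cube@time, "hours"), tz = "UTC")
  groups <- split(seq_along(cube@time), format(hour, "%Y-%m-%d %H"))
  if (any(lengths(groups) > 6))
    stop("more than 6 sub-hourly samples in one hour: unexpected cadence")
  hTimes <- as.POSIXct(names(groups), format = "%Y-%m-%d %H", tz = "UTC")
  ord <- order(hTimes)
  groups <- groups[ord]; hTimes <- hTimes[ord]
  nla <- length(cube@lat); nlo <- length(cube@lon)
  out <- array(NA_real_, c(length(groups), nla, nlo))
  for (g in seq_along(groups)) {
    sub <- cube@values[groups[[g]], , , drop = FALSE]
    cnt <- colSums(!is.na(sub), dims = 1)
    sm <- colSums(sub, dims = 1, na.rm = TRUE)
    out[g, , ] <- ifelse(cnt > 0, sm / cnt, NA_real_)
  }
  GridCube(cube@variable, out, hTimes, cube@lat, cube@lon, units = cube@units)
}

#' Normalized difference vegetation index
#'
#' NDVI = (rho086 - rho226) / (rho086 + rho226), computed where both input
#' reflectances are valid; missing propagates and a zero denominator yields
#' missing.
#'
#' @param rho086,rho226 aligned reflectance \linkS4class{GridCube}s at 0.86
#'   and 2.26 um.
#' @return an NDVI \linkS4class{GridCube} (unitless).
#' @export
computeNDVI <- function(rho086, rho226) {
  stopIfMisaligned(rho086, rho226, "reflectance cubes")
  a <- cubeValues(rho086); b <- cubeValues(rho226)
  denom <- a + b
  vals <- ifelse(!is.na(denom) & denom != 0, (a - b) / denom, NA_real_)
  GridCube("NDVI", vals, rho086@time, rho086@lat, rho086@lon)
}

#' Bilinear interpolation of a coarse field to a target grid
#'
#' Interpolates each time slice linearly in latitude and longitude; exact at
#' coarse nodes and exact for any field affine in (lat, lon). Target points
#' outside the coarse hull raise an error rather than being clamped.
#'
#' @param coarse a \linkS4class{GridCube} on the coarse grid (fully valid).
#' @param lat,lon target cell-center axes.
#' @return a \linkS4class{GridCube} on the target grid.
#' @export
interpolateMet <- function(coarse, lat, lon) {
  if (min(lat) < min(coarse@lat) || max(lat) > max(coarse@lat) ||
      min(lon) < min(coarse@lon) || max(lon) > max(coarse@lon))
    stop(sprintf("target grid outside the coarse hull for '%s'",
                 coarse@variable))
  iy <- findInterval(lat, coarse@lat, rightmost.closed = TRUE,
                     all.inside = TRUE)
  ix <- findInterval(lon, coarse@lon, rightmost.closed = TRUE,
                     all.inside = TRUE)
  wy <- (lat - coarse@lat[iy]) / (coarse@lat[iy + 1] - coarse@lat[iy])
  wx <- (lon - coarse@lon[ix]) / (coarse@lon[ix + 1] - coarse@lon[ix])
  nT <- length(coarse@time)
  out <- array(NA_real_, c(nT, length(lat), length(lon)))
  v <- coarse@values
  W00 <- outer(1 - wy, 1 - wx); W01 <- outer(1 - wy, wx)
  W10 <- outer(wy, 1 - wx);     W11 <- outer(wy, wx)
  for (t in seq_len(nT)) {
    sl <- v[t, , ]
    out[t, , ] <- sl[iy, ix] * W00 + sl[iy, ix + 1] * W01 +
      sl[iy + 1, ix] * W10 + sl[iy + 1, ix + 1] * W11
  }
  GridCube(coarse@variable, out, coarse@time, lat, lon, units = coarse@units)
}

#' Assign each hour its temporally nearest slice
#'
#' For fields provided at a sparser cadence than hourly (PBLH is twice
#' daily), each hourly timestamp receives the value of the nearest-in-time
#' available slice; exact midpoints resolve toward the earlier slice.
#'
#' @param sparse a \linkS4class{GridCube} with at least one time slice.
#' @param hours target hourly \code{POSIXct} axis.
#' @return a \linkS4class{GridCube} on the hourly axis, same spatial grid.
#' @export
assignTemporalNearest <- function(sparse, hours) {
  if (length(sparse@time) == 0) stop("sparse cube has no time slices")
  st <- as.numeric(sparse@time)
  ht <- as.numeric(as.POSIXct(hours, tz = "UTC"))
  lo <- findInterval(ht, st)            # index of latest slice <= hour
  lo[lo == 0L] <- 1L
  hi <- pmin(lo + 1L, length(st))
  ## strict '<' keeps ties on the earlier slice
  pick <- ifelse(abs(ht - st[hi]) < abs(ht - st[lo]), hi, lo)
  GridCube(sparse@variable, sparse@values[pick, , , drop = FALSE],
           as.POSIXct(hours, tz = "UTC"), sparse@lat, sparse@lon,
           units = sparse@units)
}

#' Quality-control station PM2.5 records
#'
#' Drops hourly measurements below 1 ug/m3 (under the monitoring
#' instruments' limit of detection); values exactly at 1 are retained. The
#' number of dropped records is reported via \code{message}, and a warning
#' is raised if any station loses all of its records.
#'
#' @param series a \linkS4class{StationSeries}.
#' @param threshold detection limit (ug/m3, default 1).
#' @return the filtered \linkS4class{StationSeries}.
#' @export
qcFilterPM25 <- function(series, threshold = 1) {
  rec <- series@records
  drop <- rec$pm25 < threshold
  message(sprintf("qcFilterPM25: dropped %d of %d records (< %g ug/m3)",
                  sum(drop), nrow(rec), threshold))
  kept <- rec[!drop, , drop = FALSE]
  kept$qc_pass <- TRUE
  emptied <- setdiff(unique(rec$station_id), unique(kept$station_id))
  if (length(emptied))
    warning(sprintf("stations with no remaining records: %s",
                    paste(emptied, collapse = ", ")))
  StationSeries(series@sites, kept)
}

#' Host grid cell of each station
#'
#' @param series a \linkS4class{StationSeries}.
#' @param lat,lon cell-center axes of the analysis grid.
#' @return data.frame \code{(station_id, row, col)}; nearest-center
#'   assignment, error if a station lies outside the grid bounds (half a
#'   cell beyond the outer centers).
#' @export
stationCells <- function(series, lat, lon) {
  dlat <- if (length(lat) > 1) diff(lat[1:2]) else 1
  dlon <- if (length(lon) > 1) diff(lon[1:2]) else 1
  s <- series@sites
  bad <- s$lat < min(lat) - dlat / 2 | s$lat > max(lat) + dlat / 2 |
    s$lon < min(lon) - dlon / 2 | s$lon > max(lon) + dlon / 2
  if (any(bad))
    stop(sprintf("stations outside the grid: %s",
                 paste(s$station_id[bad], collapse = ", ")))
  data.frame(
    station_id = s$station_id,
    row = vapply(s$lat, function(y) which.min(abs(lat - y)), integer(1)),
    col = vapply(s$lon, function(x) which.min(abs(lon - x)), integer(1)))
}

#' Match stations to grid cells and hours
#'
#' Produces one candidate row per QC-passed station-hour at the station's
#' host cell, retained only when the mode's required satellite predictors
#' are valid there: TOAR mode requires the three bands, the four angles and
#' NDVI; AOD mode requires AOD. Meteorology is always present (it is gap
#' free by construction). Rows are ordered by station then time.
#'
#' @param series a QC-filtered \linkS4class{StationSeries}.
#' @param stack a \linkS4class{GridStack} holding the mode's predictor cubes.
#' @param mode \code{"TOAR"} or \code{"AOD"}.
#' @return data.frame of matched samples: \code{station_id, time, row, col,
#'   month, day, hour, Lat, Lon}, one column per predictor, and \code{pm25}.
#' @export
matchStations <- function(series, stack, mode = c("TOAR", "AOD")) {
  mode <- match.arg(mode)
  cubes <- stack@cubes
  ref <- cubes[[1]]
  cells <- stationCells(series, ref@lat, ref@lon)
  rec <- series@records[series@records$qc_pass, , drop = FALSE]
  rec <- rec[order(rec$station_id, rec$time), , drop = FALSE]
  tIdx <- match(as.numeric(rec$time), as.numeric(ref@time))
  keep <- !is.na(tIdx)
  rec <- rec[keep, , drop = FALSE]; tIdx <- tIdx[keep]
  m <- match(rec$station_id, cells$station_id)
  ri <- cells$row[m]; ci <- cells$col[m]
  flat <- cbind(tIdx, ri, ci)

  gate <- if (mode == "TOAR")
    c("R1", "R3", "R6", "SensorZenith", "SensorAzimuth",
      "SolarZenith", "SolarAzimuth", "NDVI")
  else "AOD"
  required <- c(gate, c("RH", "SP", "TCW", "U10", "V10", "T", "TCO", "PBLH"))
  miss <- setdiff(required, names(cubes))
  if (length(miss))
    stop(sprintf("stack is missing predictor cubes: %s",
                 paste(miss, collapse = ", ")))
  ok <- rep(TRUE, nrow(rec))
  for (nm in gate) ok <- ok & cubes[[nm]]@valid[flat]
  for (nm in setdiff(required, gate)) ok <- ok & cubes[[nm]]@valid[flat]

  rec <- rec[ok, , drop = FALSE]; flat <- flat[ok, , drop = FALSE]
  out <- data.frame(
    station_id = rec$station_id,
    time = rec$time,
    row = flat[, 2], col = flat[, 3],
    month = as.integer(format(rec$time, "%m")),
    day = as.integer(format(rec$time, "%d")),
    hour = as.integer(format(rec$time, "%H")),
    Lat = ref@lat[flat[, 2]],
    Lon = ref@lon[flat[, 3]])
  for (nm in required) out[[nm]] <- cubes[[nm]]@values[flat]
  out$pm25 <- rec$pm25
  rownames(out) <- NULL
  out
}

#' Build the aligned hourly predictor stack of a scene
#'
#' Runs the full gridding stage: optionally gap-fills every satellite-derived
#' cube with the spatiotemporal convolution imputer, computes NDVI from the
#' (possibly gap-filled) reflectances, interpolates the hourly meteorology
#' bilinearly to the fine grid, and brings the twice-daily PBLH to the hourly
#' axis by temporal-nearest assignment.
#'
#' @param scene a \linkS4class{SceneBundle}.
#' @param gapFilled logical: apply \code{\link{imputeCube}} to the satellite
#'   cubes first?
#' @param config an \linkS4class{ImputeConfig} (used when
#'   \code{gapFilled = TRUE}).
#' @return a \linkS4class{GridStack}.
#' @export
buildGridStack <- function(scene, gapFilled = TRUE, config = imputeConfig()) {
  sat <- scene@satellite
  if (gapFilled)
    sat <- lapply(sat, function(cb) imputeCube(cb, config)$cube)
  sat$NDVI <- computeNDVI(sat$rho086, sat$rho226)
  tm <- scene@truth@time
  lat <- scene@truth@lat; lon <- scene@truth@lon
  met <- list()
  for (nm in c("RH", "SP", "TCW", "U10", "V10", "T", "TCO"))
    met[[nm]] <- interpolateMet(scene@met[[nm]], lat, lon)
  met$PBLH <- interpolateMet(assignTemporalNearest(scene@met$PBLH, tm),
                             lat, lon)
  GridStack(c(sat, met))
}
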