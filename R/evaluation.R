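## Evaluation surfaces: site-specific metrics, temporal aggregation,
## predictor correlations.

#' Per-station cross-validation metrics
#'
#' Computes R-squared and RMSE per station from the pooled out-of-fold
#' predictions of a \linkS4class{CVResult}. Stations with fewer than
#' \code{minPairs} prediction pairs are skipped with a log line rather than
#' reported on thin evidence.
#'
#' @param cv a \linkS4class{CVResult}.
#' @param sites data.frame \code{(station_id, lat, lon)} for coordinates.
#' @param minPairs minimum pairs per station (default 30).
#' @return data.frame \code{(station_id, lat, lon, n, r2, rmse)}.
#' @export
siteMetrics <- function(cv, sites, minPairs = 30) {
  d <- cv@data
  out <- lapply(split(d, d$station_id), function(g) {
    if (nrow(g) < minPairs) {
      message(sprintf("siteMetrics: skipping %s (%d < %d pairs)",
                      g$station_id[1], nrow(g), minPairs))
      return(NULL)
    }
    m <- regressionMetrics(g$observed, g$predicted)
    data.frame(station_id = g$station_id[1], n = nrow(g),
               r2 = m$r2, rmse = m$rmse)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    return(data.frame(station_id = character(0), lat = numeric(0),
                      lon = numeric(0), n = integer(0), r2 = numeric(0),
                      rmse = numeric(0)))
  i <- match(out$station_id, sites$station_id)
  out$lat <- sites$lat[i]; out$lon <- sites$lon[i]
  rownames(out) <- NULL
  out[, c("station_id", "lat", "lon", "n", "r2", "rmse")]
}

#' Aggregate a cube in time
#'
#' Mask-aware means over valid values only. \code{"annual"} yields one
#' per-cell mean map; \code{"season"} one map per season; \code{"diurnal"}
#' a regional mean series by hour of day, annually and per season. A cell
#' enters a map only when at least \code{minCoverage} of the scheme's hours
#' are valid there, so sparsely observed cells do not masquerade as means.
#'
#' @param cube a \linkS4class{GridCube}.
#' @param scheme \code{"annual"}, \code{"season"} or \code{"diurnal"}.
#' @param minCoverage minimum valid fraction per cell (default 0.1).
#' @return \code{"annual"}: lat x lon matrix; \code{"season"}: named list
#'   of matrices; \code{"diurnal"}: data.frame
#'   \code{(season, hour, mean, nCells)} including season \code{"annual"}.
#' @export
temporalAggregate <- function(cube, scheme = c("annual", "season", "diurnal"),
                              minCoverage = 0.1) {
  scheme <- match.arg(scheme)
  if (length(cube@time) == 0) stop("empty cube")
  seas <- seasonOf(cube@time)
  cellMean <- function(sel) {
    v <- cube@values[sel, , , drop = FALSE]
    ok <- cube@valid[sel, , , drop = FALSE]
    cnt <- colSums(ok, dims = 1)
    sm <- colSums(ifelse(ok, v, 0), dims = 1)
    res <- ifelse(cnt >= max(1, minCoverage * sum(sel)), sm / cnt, NA_real_)
    res
  }
  if (scheme == "annual")
    return(cellMean(rep(TRUE, length(cube@time))))
  if (scheme == "season") {
    out <- lapply(SEASONS[SEASONS %in% seas], function(s) cellMean(seas == s))
    names(out) <- SEASONS[SEASONS %in% seas]
    return(out)
  }
  ## diurnal: regional mean over valid cells per hour of day
  hr <- as.integer(format(cube@time, "%H"))
  groups <- c(list(annual = rep(TRUE, length(seas))),
              setNames(lapply(SEASONS[SEASONS %in% seas],
                              function(s) seas == s),
                       SEASONS[SEASONS %in% seas]))
  out <- do.call(rbind, lapply(names(groups), function(g) {
    sel <- groups[[g]]
    do.call(rbind, lapply(sort(unique(hr[sel])), function(h) {
      s2 <- sel & hr == h
      v <- cube@values[s2, , , drop = FALSE]
      ok <- cube@valid[s2, , , drop = FALSE]
      data.frame(season = g, hour = h,
                 mean = if (any(ok)) mean(v[ok]) else NA_real_,
                 nCells = sum(ok))
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Regional mean series of per-season maps
#'
#' Convenience: mean of each seasonal map over its reported cells.
#'
#' @param cube a \linkS4class{GridCube}.
#' @param minCoverage see \code{\link{temporalAggregate}}.
#' @return named numeric vector of regional seasonal means.
#' @export
seasonalRegionalMeans <- function(cube, minCoverage = 0.1) {
  maps <- temporalAggregate(cube, "season", minCoverage)
  vapply(maps, function(m) mean(m, na.rm = TRUE), numeric(1))
}

#' Pairwise Pearson correlations of a feature table
#'
#' Correlations over complete rows of all predictors plus the target;
#' symmetric with unit diagonal. Zero-variance columns yield \code{NA}
#' entries (undefined, not zero) with a warning.
#'
#' @param table a \linkS4class{FeatureTable} with at least 2 rows.
#' @return symmetric correlation matrix.
#' @export
correlationMatrix <- function(table) {
  d <- table@data[, c(featureColumns(table@mode), "pm25"), drop = FALSE]
  if (nrow(d) < 2) stop("need at least 2 rows")
  d <- d[complete.cases(d), , drop = FALSE]
  sds <- vapply(d, sd, numeric(1))
  if (any(sds == 0))
    warning(sprintf("zero-variance column(s): %s (correlations undefined)",
                    paste(names(d)[sds == 0], collapse = ", ")))
  suppressWarnings(m <- cor(d))
  m[, sds == 0] <- NA_real_; m[sds == 0, ] <- NA_real_
  diag(m) <- ifelse(sds == 0, NA_real_, 1)
  m
}
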