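## Spatiotemporal convolutional gap filling: each missing cell receives the
## mean of the valid values in its 3 x 3 x 3 (time x lat x lon) neighborhood.

## Temporal neighbor bookkeeping: a slice offset l only counts as a temporal
## neighbor when the timestamps are exactly l hours apart, so across the
## overnight gap of a daytime-only axis the next day's first hour is NOT a
## neighbor of the previous day's last hour.
.temporalPairs <- function(time, l) {
  tn <- round(as.numeric(time) / 3600)   # whole hours by construction
  src <- match(tn + l, tn)               # slice exactly l hours away, if any
  dst <- which(!is.na(src))
  list(dst = dst, src = src[dst])
}

#' Fill satellite retrieval gaps with a spatiotemporal convolution kernel
#'
#' For every missing cell the imputer computes the ratio of the sum of valid
#' values to the count of valid values inside the
#' \eqn{(2h_t+1) \times (2h_s+1) \times (2h_s+1)} neighborhood centered on
#' it (default 3 x 3 x 3). Cells with fewer than \code{minValidNeighbors}
#' valid neighbors stay missing. Originally valid cells pass through
#' bit-identically, and within one pass only values valid at the start of
#' the pass feed the sums (no cascade); additional passes, in which
#' previously filled values count as valid, are opt-in via \code{passes}.
#' Neighborhoods truncate at the domain boundaries, and temporal adjacency
#' follows real timestamps (see Details in the vignette for the overnight
#' gap of a daytime-only axis).
#'
#' @param cube a \linkS4class{GridCube}.
#' @param config an \linkS4class{ImputeConfig}.
#' @return list with elements \code{cube} (the filled
#'   \linkS4class{GridCube}) and \code{report} (data.frame with
#'   \code{pass, validBefore, validAfter, imputed}).
#' @examples
#' tm <- as.POSIXct("2016-01-01 09:00", tz = "UTC") + 3600 * (0:2)
#' v <- array(10, c(3, 3, 3)); v[2, 2, 2] <- NA
#' filled <- imputeCube(GridCube("x", v, tm, 1:3, 1:3), imputeConfig())
#' filled$cube@values[2, 2, 2]  # 10
#' @export
imputeCube <- function(cube, config = imputeConfig()) {
  validObject(config)
  nT <- length(cube@time)
  if (nT < 1) stop("cube has no time slices")
  ht <- config@temporalHalfWidth
  hs <- config@spatialHalfWidth
  nla <- length(cube@lat); nlo <- length(cube@lon)
  vals <- cube@values
  valid <- cube@valid
  report <- data.frame()

  for (pass in seq_len(config@passes)) {
    before <- sum(valid)
    vals0 <- vals; vals0[!valid] <- 0
    cnt0 <- array(as.numeric(valid), dim(valid))
    S <- array(0, dim(vals)); C <- array(0, dim(vals))
    for (l in -ht:ht) {
      tp <- .temporalPairs(cube@time, l)
      if (!length(tp$dst)) next
      for (m in -hs:hs) {
        di <- seq_len(nla); si <- di + m
        okI <- si >= 1L & si <= nla
        di <- di[okI]; si <- si[okI]
        if (!length(di)) next
        for (n in -hs:hs) {
          dj <- seq_len(nlo); sj <- dj + n
          okJ <- sj >= 1L & sj <= nlo
          dj <- dj[okJ]; sj <- sj[okJ]
          if (!length(dj)) next
          S[tp$dst, di, dj] <- S[tp$dst, di, dj] + vals0[tp$src, si, sj]
          C[tp$dst, di, dj] <- C[tp$dst, di, dj] + cnt0[tp$src, si, sj]
        }
      }
    }
    ## the center cell sits inside the kernel sum but is missing by
    ## construction at every fill site, so it contributes nothing
    fill <- !valid & C >= config@minValidNeighbors
    vals[fill] <- S[fill] / C[fill]
    valid <- valid | fill
    report <- rbind(report, data.frame(
      pass = pass, validBefore = before, validAfter = sum(valid),
      imputed = sum(fill)))
    if (sum(fill) == 0) break
  }
  out <- GridCube(cube@variable, vals, cube@time, cube@lat, cube@lon,
                  units = cube@units, valid = valid)
  list(cube = out, report = report)
}

#' Reference implementation of the convolution imputer
#'
#' Direct triple-nested-loop evaluation of the neighborhood-mean rule, used
#' as an independent check of \code{\link{imputeCube}} on small cubes.
#'
#' @inheritParams imputeCube
#' @return the filled \linkS4class{GridCube}.
#' @export
imputeOracle <- function(cube, config = imputeConfig()) {
  validObject(config)
  ht <- config@temporalHalfWidth; hs <- config@spatialHalfWidth
  nT <- length(cube@time); nla <- length(cube@lat); nlo <- length(cube@lon)
  vals <- cube@values; valid <- cube@valid
  tnum <- round(as.numeric(cube@time) / 3600)
  for (pass in seq_len(config@passes)) {
    v0 <- vals; m0 <- valid
    newVals <- vals; newValid <- valid
    for (t in seq_len(nT)) {
      ## temporal neighbors by actual hour distance, not slice offset
      tNb <- lapply(-ht:ht, function(l) which(tnum == tnum[t] + l))
      for (i in seq_len(nla)) {
        for (j in seq_len(nlo)) {
          if (m0[t, i, j]) next
          acc <- 0; cnt <- 0L
          for (tl in tNb) {
            if (!length(tl)) next
            for (m in -hs:hs) {
              im <- i + m
              if (im < 1L || im > nla) next
              for (n in -hs:hs) {
                jn <- j + n
                if (jn < 1L || jn > nlo) next
                if (m0[tl, im, jn]) {
                  acc <- acc + v0[tl, im, jn]
                  cnt <- cnt + 1L
                }
              }
            }
          }
          if (cnt >= config@minValidNeighbors) {
            newVals[t, i, j] <- acc / cnt
            newValid[t, i, j] <- TRUE
          }
        }
      }
    }
    vals <- newVals; valid <- newValid
  }
  GridCube(cube@variable, vals, cube@time, cube@lat, cube@lon,
           units = cube@units, valid = valid)
}

#' Valid-pixel coverage of a cube
#'
#' Coverage diagnostics used to compare products (TOAR vs AOD) and the
#' effect of gap filling: per-cell valid-pixel counts annually and per
#' season, and valid-cell counts per hourly slice.
#'
#' @param cube a \linkS4class{GridCube}.
#' @param seasons season label per time slice (defaults to the calendar
#'   season of each timestamp).
#' @return list with \code{annual} (lat x lon count matrix),
#'   \code{bySeason} (named list of count matrices) and \code{byHour}
#'   (data.frame \code{time, validCells}).
#' @export
coverageStats <- function(cube, seasons = seasonOf(cube@time)) {
  v <- cube@valid
  annual <- colSums(v, dims = 1)
  bySeason <- lapply(SEASONS[SEASONS %in% seasons], function(s)
    colSums(v[seasons == s, , , drop = FALSE], dims = 1))
  names(bySeason) <- SEASONS[SEASONS %in% seasons]
  byHour <- data.frame(time = cube@time,
                       validCells = apply(v, 1, sum))
  list(annual = annual, bySeason = bySeason, byHour = byHour)
}

#' Coverage difference between two products
#'
#' @param a,b aligned \linkS4class{GridCube}s (e.g. TOAR band and AOD).
#' @param seasons season label per slice.
#' @return as \code{\link{coverageStats}}, with counts of \code{a} minus
#'   counts of \code{b}.
#' @export
coverageDifference <- function(a, b, seasons = seasonOf(a@time)) {
  stopIfMisaligned(a, b, "coverage cubes")
  ca <- coverageStats(a, seasons); cb <- coverageStats(b, seasons)
  list(annual = ca$annual - cb$annual,
       bySeason = Map(function(x, y) x - y, ca$bySeason, cb$bySeason),
       byHour = data.frame(time = ca$byHour$time,
                           validCells = ca$byHour$validCells -
                             cb$byHour$validCells))
}
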