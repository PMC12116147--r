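## Population-weighted exposure assessment.

#' Annual air-quality standards (ug/m3)
#'
#' Annual mean PM2.5 limits: WHO guideline 15, United States 12, European
#' Union 20, China 35.
#'
#' @return named numeric vector.
#' @export
airQualityStandards <- function() c(WHO = 15, US = 12, EU = 20, CN = 35)

#' Interpolate census populations to a target year
#'
#' Per-cell linear trend through the 2000 and 2010 estimates evaluated at
#' \code{targetYear}, floored at zero. For years past 2010 (such as 2016)
#' this is arithmetically an extrapolation of the 2000-2010 line.
#'
#' @param p2000,p2010 aligned non-negative population rasters (matrices).
#' @param targetYear the year to evaluate at.
#' @return population matrix.
#' @examples
#' interpolatePopulation(matrix(100), matrix(150), 2016)  # 180
#' @export
interpolatePopulation <- function(p2000, p2010, targetYear) {
  if (!identical(dim(p2000), dim(p2010)))
    stop("population rasters are not aligned")
  if (any(p2000 < 0, na.rm = TRUE) || any(p2010 < 0, na.rm = TRUE))
    stop("negative population input")
  pmax(p2000 + (targetYear - 2000) / 10 * (p2010 - p2000), 0)
}

#' Population-weighted mean concentration
#'
#' \eqn{\sum pop \cdot pm / \sum pop} over cells where both the annual mean
#' and the population are valid.
#'
#' @param pm matrix of annual mean PM2.5 (\code{NA} = no coverage).
#' @param pop aligned population matrix.
#' @return scalar (ug/m3).
#' @export
populationWeightedMean <- function(pm, pop) {
  if (!identical(dim(pm), dim(pop))) stop("rasters are not aligned")
  ok <- !is.na(pm) & !is.na(pop)
  tot <- sum(pop[ok])
  if (tot <= 0) stop("zero total population over covered cells")
  sum(pop[ok] * pm[ok]) / tot
}

#' Cumulative population at or above concentration thresholds
#'
#' For each threshold, the resident population of cells whose annual mean
#' is at or above it (the "equal to or exceeding" rule); non-increasing in
#' the threshold, equal to the covered population at threshold 0.
#'
#' @param pm,pop aligned matrices as in
#'   \code{\link{populationWeightedMean}}.
#' @param thresholds ascending thresholds (ug/m3).
#' @return data.frame \code{(threshold, population)}.
#' @export
exposureCDF <- function(pm, pop, thresholds = seq(0, 150, by = 1)) {
  if (!identical(dim(pm), dim(pop))) stop("rasters are not aligned")
  if (is.unsorted(thresholds)) stop("thresholds must be ascending")
  ok <- !is.na(pm) & !is.na(pop)
  data.frame(threshold = thresholds,
             population = vapply(thresholds, function(tau)
               sum(pop[ok & pm >= tau]), numeric(1)))
}

#' Attainment and non-attainment population fractions
#'
#' Non-attainment is the population fraction in cells whose annual mean
#' strictly exceeds the standard ("exceed"); attainment is its complement.
#' Cells with population but no valid annual mean are excluded from the
#' fractions and reported separately - silently assuming they attain would
#' bias the headline figure.
#'
#' @param pm,pop aligned matrices.
#' @param standard annual standard (ug/m3; default China's 35).
#' @return list \code{(attain, nonAttain, totalPopulation,
#'   uncoveredPopulation)}.
#' @export
attainmentFraction <- function(pm, pop, standard = 35) {
  if (!identical(dim(pm), dim(pop))) stop("rasters are not aligned")
  ok <- !is.na(pm) & !is.na(pop)
  tot <- sum(pop[ok])
  if (tot <= 0) stop("zero total population over covered cells")
  nonAttain <- sum(pop[ok & pm > standard]) / tot
  list(attain = 1 - nonAttain, nonAttain = nonAttain,
       totalPopulation = tot,
       uncoveredPopulation = sum(pop[!is.na(pop) & is.na(pm)]))
}

#' Full exposure summary
#'
#' Bundles the population-weighted mean, the cumulative
#' population-vs-threshold curve and the attainment split under one
#' standard into an \linkS4class{ExposureSummary}.
#'
#' @param pm annual mean PM2.5 matrix (e.g.
#'   \code{temporalAggregate(cube, "annual")}).
#' @param pop aligned population matrix.
#' @param standard annual standard (ug/m3).
#' @param thresholds CDF thresholds.
#' @return an \linkS4class{ExposureSummary}.
#' @export
exposureSummary <- function(pm, pop, standard = 35,
                            thresholds = seq(0, 150, by = 1)) {
  att <- attainmentFraction(pm, pop, standard)
  new("ExposureSummary",
      weightedMean = populationWeightedMean(pm, pop),
      cdf = exposureCDF(pm, pop, thresholds),
      standard = standard,
      attainFraction = att$attain, nonAttainFraction = att$nonAttain,
      totalPopulation = att$totalPopulation,
      uncoveredPopulation = att$uncoveredPopulation)
}
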