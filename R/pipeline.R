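## End-to-end convenience wrappers used by the vignette, the tests and the
## acceptance script.

#' Build a training table from a scene
#'
#' QC-filters the station records, builds the aligned predictor stack
#' (optionally gap-filled), matches stations to cells and hours, and
#' assembles the mode's feature table.
#'
#' @param scene a \linkS4class{SceneBundle}.
#' @param mode \code{"TOAR"} or \code{"AOD"}.
#' @param gapFilled apply the convolution imputer to the satellite cubes?
#' @param config an \linkS4class{ImputeConfig}.
#' @param stack optional pre-built \linkS4class{GridStack} (skips gridding).
#' @return list with \code{table} (a \linkS4class{FeatureTable}),
#'   \code{stack} (the \linkS4class{GridStack}) and \code{stations} (the
#'   QC-filtered \linkS4class{StationSeries}).
#' @export
buildTrainingTable <- function(scene, mode = c("TOAR", "AOD"),
                               gapFilled = TRUE, config = imputeConfig(),
                               stack = NULL) {
  mode <- match.arg(mode)
  stations <- suppressMessages(qcFilterPM25(scene@stations))
  if (is.null(stack)) stack <- buildGridStack(scene, gapFilled, config)
  samples <- matchStations(stations, stack, mode)
  list(table = assembleFeatures(samples, mode), stack = stack,
       stations = stations)
}

#' Run the full estimation pipeline on a scene
#'
#' Gridding (optionally gap-filled), cross-validated training, final fit,
#' grid prediction, annual aggregation and population-weighted exposure in
#' one call.
#'
#' @param scene a \linkS4class{SceneBundle}.
#' @param mode \code{"TOAR"} or \code{"AOD"}.
#' @param algorithm learner name (default \code{"RF"}).
#' @param hyper hyperparameters for the single evaluated configuration;
#'   default \code{\link{defaultHyperparameters}}.
#' @param gapFilled use gap-filled satellite cubes?
#' @param cvFolds number of CV folds.
#' @param seed integer seed for folds and fits.
#' @param standard exposure standard (ug/m3).
#' @return list with \code{table}, \code{cv} (\linkS4class{CVResult}),
#'   \code{model} (\linkS4class{FittedModel}), \code{pm25}
#'   (predicted \linkS4class{GridCube}), \code{annual} (per-cell annual
#'   mean matrix), \code{exposure} (\linkS4class{ExposureSummary}) and
#'   \code{stack}.
#' @export
runScenePipeline <- function(scene, mode = c("TOAR", "AOD"),
                             algorithm = "RF", hyper = NULL,
                             gapFilled = TRUE, cvFolds = 10, seed = 1,
                             standard = 35) {
  mode <- match.arg(mode)
  built <- buildTrainingTable(scene, mode, gapFilled)
  if (is.null(hyper)) hyper <- defaultHyperparameters(algorithm, mode)
  gs <- gridSearchCV(built$table, algorithm,
                     grid = as.data.frame(hyper), cvFolds = cvFolds,
                     seed = seed)
  model <- fitModel(built$table, algorithm, hyper, seed = seed)
  pm25 <- predictGrid(model, built$stack)
  annual <- temporalAggregate(pm25, "annual")
  expo <- exposureSummary(annual, scene@population, standard = standard)
  list(table = built$table, cv = gs$cv, model = model, pm25 = pm25,
       annual = annual, exposure = expo, stack = built$stack)
}

#' Write pipeline outputs as text files
#'
#' Writes the out-of-fold CV table, the site metrics and the exposure CDF
#' as CSV into a directory; used to demonstrate byte-reproducible runs.
#'
#' @param result list from \code{\link{runScenePipeline}}.
#' @param sites station site table for \code{\link{siteMetrics}}.
#' @param dir output directory (created if absent).
#' @return invisibly, the written file paths.
#' @export
writePipelineOutputs <- function(result, sites, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(cv = file.path(dir, "cv_predictions.csv"),
             site = file.path(dir, "site_metrics.csv"),
             cdf = file.path(dir, "exposure_cdf.csv"))
  cvd <- result$cv@data
  cvd$time <- format(cvd$time, "%Y-%m-%dT%H:%M:%SZ")
  utils::write.csv(cvd, paths["cv"], row.names = FALSE)
  sm <- suppressMessages(siteMetrics(result$cv, sites))
  utils::write.csv(sm, paths["site"], row.names = FALSE)
  utils::write.csv(result$exposure@cdf, paths["cdf"], row.names = FALSE)
  invisible(paths)
}
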