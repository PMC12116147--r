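## Estimation: feature-table assembly, the four learners, grid-searched
## 10-fold cross-validation, and grid prediction.

#' Assemble a feature table from matched samples
#'
#' Projects matched station-hour rows to the exact predictor contract of the
#' chosen mode (see \code{\link{featureColumns}}) plus the \code{pm25}
#' target, keeping \code{station_id} and \code{time} as bookkeeping columns.
#' Rows are ordered by station then time. Any residual missing value is an
#' error naming the offending column: validity must be enforced upstream by
#' the matching gate.
#'
#' @param samples data.frame from \code{\link{matchStations}}.
#' @param mode \code{"TOAR"} or \code{"AOD"}.
#' @return a \linkS4class{FeatureTable}.
#' @export
assembleFeatures <- function(samples, mode = c("TOAR", "AOD")) {
  mode <- match.arg(mode)
  cols <- featureColumns(mode)
  keep <- c("station_id", "time", cols, "pm25")
  miss <- setdiff(keep, names(samples))
  if (nrow(samples) == 0) {
    empty <- as.data.frame(setNames(rep(list(numeric(0)), length(keep)), keep))
    empty$station_id <- character(0)
    empty$time <- as.POSIXct(character(0), tz = "UTC")
    return(new("FeatureTable", mode = mode, data = empty[keep]))
  }
  if (length(miss))
    stop(sprintf("samples lack required columns: %s",
                 paste(miss, collapse = ", ")))
  d <- samples[order(samples$station_id, samples$time), keep, drop = FALSE]
  for (cl in c(cols, "pm25"))
    if (anyNA(d[[cl]]))
      stop(sprintf("missing values in column '%s': validity gate violated", cl))
  rownames(d) <- NULL
  new("FeatureTable", mode = mode, data = d)
}

#' Tuned default hyperparameters per learner and mode
#'
#' The shipped defaults are the grid-search winners for each learner: random
#' forest (n_tree, m_try) = (600, 9) TOAR / (800, 5) AOD; gradient boosting
#' (n_estimators, max_depth, subsample, learning_rate) =
#' (900, 7, 0.5, 0.1) TOAR / (800, 7, 0.5, 0.05) AOD; XGBoost additionally
#' (colsample_bytree, min_child_weight) = (800, 9, 0.9, 0.05, 0.7, 5) TOAR /
#' (900, 9, 0.7, 0.05, 0.7, 1) AOD; SVR with radial basis kernel
#' (gamma, C) = (0.5, 1) TOAR / (0.7, 3) AOD.
#'
#' @param algorithm one of \code{"RF"}, \code{"GBR"}, \code{"XGBoost"},
#'   \code{"SVR"}.
#' @param mode \code{"TOAR"} or \code{"AOD"}.
#' @return named list of hyperparameters.
#' @export
defaultHyperparameters <- function(algorithm = c("RF", "GBR", "XGBoost", "SVR"),
                                   mode = c("TOAR", "AOD")) {
  algorithm <- match.arg(algorithm); mode <- match.arg(mode)
  switch(algorithm,
    RF = if (mode == "TOAR") list(n_tree = 600, m_try = 9)
         else list(n_tree = 800, m_try = 5),
    GBR = if (mode == "TOAR")
      list(n_estimators = 900, max_depth = 7, subsample = 0.5,
           learning_rate = 0.1)
    else
      list(n_estimators = 800, max_depth = 7, subsample = 0.5,
           learning_rate = 0.05),
    XGBoost = if (mode == "TOAR")
      list(n_estimators = 800, max_depth = 9, subsample = 0.9,
           learning_rate = 0.05, colsample_bytree = 0.7,
           min_child_weight = 5)
    else
      list(n_estimators = 900, max_depth = 9, subsample = 0.7,
           learning_rate = 0.05, colsample_bytree = 0.7,
           min_child_weight = 1),
    SVR = if (mode == "TOAR") list(gamma = 0.5, C = 1)
          else list(gamma = 0.7, C = 3))
}

#' Small search grid around the tuned defaults
#'
#' One step down and one step up per axis around the tuned values, so the
#' grid search is exercisable at desk scale; pass your own data.frame of
#' combinations for a wider search.
#'
#' @inheritParams defaultHyperparameters
#' @return data.frame of hyperparameter combinations.
#' @export
defaultGrid <- function(algorithm = c("RF", "GBR", "XGBoost", "SVR"),
                        mode = c("TOAR", "AOD")) {
  algorithm <- match.arg(algorithm); mode <- match.arg(mode)
  h <- defaultHyperparameters(algorithm, mode)
  switch(algorithm,
    RF = expand.grid(n_tree = h$n_tree + c(-200, 0, 200),
                     m_try = h$m_try + c(-2, 0, 2)),
    GBR = expand.grid(n_estimators = h$n_estimators + c(-100, 0, 100),
                      max_depth = h$max_depth + c(-2, 0, 2),
                      subsample = h$subsample, learning_rate = h$learning_rate),
    XGBoost = expand.grid(n_estimators = h$n_estimators + c(-100, 0, 100),
                          max_depth = h$max_depth + c(-2, 0, 2),
                          subsample = h$subsample,
                          learning_rate = h$learning_rate,
                          colsample_bytree = h$colsample_bytree,
                          min_child_weight = h$min_child_weight),
    SVR = expand.grid(gamma = pmax(h$gamma + c(-0.2, 0, 0.2), 0.05),
                      C = pmax(h$C + c(-0.5, 0, 0.5), 0.1)))
}

## xgboost parameter translation shared by the two boosting learners.
.xgbParams <- function(hyper, seed, plain = FALSE) {
  list(max_depth = hyper$max_depth,
       eta = hyper$learning_rate,
       subsample = hyper$subsample,
       colsample_bytree = if (plain) 1 else hyper$colsample_bytree,
       min_child_weight = if (plain) 1 else hyper$min_child_weight,
       objective = "reg:squarederror", nthread = 1, seed = seed)
}

.xgbFit <- function(x, y, hyper, seed, plain = FALSE) {
  dtrain <- xgboost::xgb.DMatrix(as.matrix(x), label = y, nthread = 1)
  xgboost::xgb.train(params = .xgbParams(hyper, seed, plain), data = dtrain,
                     nrounds = hyper$n_estimators, verbose = 0)
}

#' Fit a PM2.5 learner
#'
#' Trains one of the four supported algorithms on a feature table:
#' \itemize{
#'   \item \code{RF}: random forest (ranger backend), predictions averaged
#'     over \code{n_tree} trees with \code{m_try} candidate predictors per
#'     split;
#'   \item \code{GBR}: least-squares stochastic gradient boosting (xgboost
#'     backend restricted to plain boosting: no column subsampling, unit
#'     minimum child weight);
#'   \item \code{XGBoost}: gradient boosting with the two extra
#'     regularization parameters \code{colsample_bytree} and
#'     \code{min_child_weight};
#'   \item \code{SVR}: support vector regression with a radial basis
#'     kernel; inputs are standardized internally on the training data
#'     (an RBF kernel is meaningless on unscaled features).
#' }
#' Fits are deterministic given \code{seed}.
#'
#' @param table a \linkS4class{FeatureTable}.
#' @param algorithm learner name.
#' @param hyper named list of hyperparameters; defaults to
#'   \code{\link{defaultHyperparameters}}.
#' @param seed integer seed.
#' @return a \linkS4class{FittedModel}.
#' @export
fitModel <- function(table, algorithm = c("RF", "GBR", "XGBoost", "SVR"),
                     hyper = NULL, seed = 1) {
  algorithm <- match.arg(algorithm)
  if (nrow(table@data) == 0) stop("empty feature table")
  if (is.null(hyper)) hyper <- defaultHyperparameters(algorithm, table@mode)
  cols <- featureColumns(table@mode)
  x <- table@data[, cols, drop = FALSE]
  y <- table@data$pm25
  set.seed(seed)
  fit <- switch(algorithm,
    RF = ranger::ranger(x = x, y = y, num.trees = hyper$n_tree,
                        mtry = min(hyper$m_try, ncol(x)),
                        seed = seed, num.threads = 1),
    GBR = .xgbFit(x, y, hyper, seed, plain = TRUE),
    XGBoost = .xgbFit(x, y, hyper, seed),
    SVR = e1071::svm(x = as.matrix(x), y = y, kernel = "radial",
                     gamma = hyper$gamma, cost = hyper$C, scale = TRUE))
  new("FittedModel", algorithm = algorithm, mode = table@mode,
      hyper = hyper, featureNames = cols, fit = fit,
      seed = as.integer(seed))
}

#' Predict PM2.5 for new rows
#'
#' @param object a \linkS4class{FittedModel}.
#' @param newdata data.frame containing the model's predictor columns.
#' @param ... unused.
#' @return numeric vector of predicted PM2.5 (ug/m3).
#' @export
setMethod("predict", "FittedModel", function(object, newdata, ...) {
  x <- newdata[, object@featureNames, drop = FALSE]
  switch(object@algorithm,
    RF = predict(object@fit, data = x, num.threads = 1)$predictions,
    GBR = ,
    XGBoost = predict(object@fit, as.matrix(x)),
    SVR = as.numeric(predict(object@fit, as.matrix(x))))
})

#' Regression accuracy metrics
#'
#' R-squared is the squared Pearson correlation of predicted and observed
#' (the scatter-plot definition); \code{r2_ss} additionally reports
#' 1 - SSres/SStot. RMSE is the root mean squared error and the slope is
#' the ordinary least-squares slope of predicted regressed on observed
#' (with intercept).
#'
#' @param observed,predicted equal-length numeric vectors, n >= 2.
#' @return list \code{(r2, r2_ss, rmse, slope)}.
#' @examples
#' regressionMetrics(c(1, 2, 3, 4), c(1.1, 1.9, 3.2, 3.8))
#' @export
regressionMetrics <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("observed and predicted lengths differ")
  if (length(observed) < 2) stop("need at least 2 pairs")
  if (sd(observed) == 0 || sd(predicted) == 0)
    stop("zero variance: correlation-based metrics undefined")
  r <- cor(predicted, observed)
  list(r2 = r^2,
       r2_ss = 1 - sum((observed - predicted)^2) /
         sum((observed - mean(observed))^2),
       rmse = sqrt(mean((predicted - observed)^2)),
       slope = unname(coef(lm(predicted ~ observed))[2]))
}

## Seeded fold assignment: random row partition (default) or site-blocked.
.assignFolds <- function(table, cvFolds, seed, scheme = c("random", "site")) {
  scheme <- match.arg(scheme)
  n <- nrow(table@data)
  set.seed(seed)
  if (scheme == "random") {
    sample(rep(seq_len(cvFolds), length.out = n))
  } else {
    st <- unique(table@data$station_id)
    sf <- sample(rep(seq_len(cvFolds), length.out = length(st)))
    sf[match(table@data$station_id, st)]
  }
}

#' Grid-searched k-fold cross-validation
#'
#' Evaluates every hyperparameter combination by pooled out-of-fold
#' prediction over a seeded random partition of the rows into
#' \code{cvFolds} folds (sizes within one row of each other). The winner
#' maximizes pooled R-squared, with ties broken by lower RMSE and then by
#' lexicographic order of the hyperparameter values. Out-of-fold
#' predictions never use a row's own training fit.
#'
#' @param table a \linkS4class{FeatureTable} with at least \code{cvFolds}
#'   rows.
#' @param algorithm learner name.
#' @param grid data.frame of hyperparameter combinations; default is the
#'   single tuned combination from \code{\link{defaultHyperparameters}}
#'   (use \code{\link{defaultGrid}} for a small search).
#' @param cvFolds number of folds (default 10).
#' @param seed integer seed controlling the fold partition and the fits.
#' @param foldScheme \code{"random"} rows (default) or \code{"site"}-blocked
#'   folds, which avoid spatial leakage between folds.
#' @return list with \code{best} (named hyperparameter list), \code{cv}
#'   (the winning \linkS4class{CVResult}) and \code{search} (data.frame of
#'   all combinations with their pooled metrics).
#' @export
gridSearchCV <- function(table, algorithm = c("RF", "GBR", "XGBoost", "SVR"),
                         grid = NULL, cvFolds = 10, seed = 1,
                         foldScheme = c("random", "site")) {
  algorithm <- match.arg(algorithm)
  foldScheme <- match.arg(foldScheme)
  n <- nrow(table@data)
  if (n < cvFolds)
    stop(sprintf("only %d rows for %d folds", n, cvFolds))
  if (is.null(grid))
    grid <- as.data.frame(defaultHyperparameters(algorithm, table@mode))
  folds <- .assignFolds(table, cvFolds, seed, foldScheme)

  evalCombo <- function(hyper) {
    pred <- numeric(n)
    for (f in seq_len(cvFolds)) {
      tr <- new("FeatureTable", mode = table@mode,
                data = table@data[folds != f, , drop = FALSE])
      m <- fitModel(tr, algorithm, hyper, seed = seed + f)
      pred[folds == f] <- predict(m, table@data[folds == f, , drop = FALSE])
    }
    pred
  }

  search <- grid
  search$r2 <- NA_real_; search$rmse <- NA_real_
  preds <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    hyper <- as.list(grid[g, , drop = FALSE])
    preds[[g]] <- evalCombo(hyper)
    mt <- regressionMetrics(table@data$pm25, preds[[g]])
    search$r2[g] <- mt$r2; search$rmse[g] <- mt$rmse
  }
  ord <- do.call(order, c(list(-search$r2, search$rmse),
                          unname(as.list(grid))))
  bestIdx <- ord[1]
  best <- as.list(grid[bestIdx, , drop = FALSE])
  attr(best, "out.attrs") <- NULL

  cvData <- data.frame(
    station_id = table@data$station_id,
    time = table@data$time,
    fold = folds,
    observed = table@data$pm25,
    predicted = preds[[bestIdx]])
  pooled <- regressionMetrics(cvData$observed, cvData$predicted)
  seas <- seasonOf(cvData$time)
  bySeason <- do.call(rbind, lapply(unique(seas), function(s) {
    m <- regressionMetrics(cvData$observed[seas == s],
                           cvData$predicted[seas == s])
    data.frame(season = s, r2 = m$r2, rmse = m$rmse, slope = m$slope)
  }))
  cv <- new("CVResult", data = cvData, metrics = pooled,
            bySeason = bySeason, algorithm = algorithm,
            mode = table@mode, hyper = best, seed = as.integer(seed))
  list(best = best, cv = cv, search = search)
}

#' Predict a PM2.5 cube over the analysis grid
#'
#' Applies a fitted model at every cell-hour where all of the mode's
#' predictors are valid; cells with any invalid predictor stay missing, so
#' prediction coverage mirrors (gap-filled) satellite coverage.
#'
#' @param model a \linkS4class{FittedModel}.
#' @param stack a \linkS4class{GridStack} with the mode's predictor cubes.
#' @return a PM2.5 \linkS4class{GridCube} (ug/m3).
#' @export
predictGrid <- function(model, stack) {
  cubes <- stack@cubes
  satCols <- setdiff(model@featureNames,
                     c("Lat", "Lon", "month", "day", "hour"))
  miss <- setdiff(satCols, names(cubes))
  if (length(miss))
    stop(sprintf("stack is missing predictor cube(s): %s",
                 paste(miss, collapse = ", ")))
  ref <- cubes[[satCols[1]]]
  nT <- length(ref@time); nla <- length(ref@lat); nlo <- length(ref@lon)
  ok <- array(TRUE, c(nT, nla, nlo))
  for (nm in satCols) ok <- ok & cubes[[nm]]@valid
  idx <- which(ok)
  out <- array(NA_real_, c(nT, nla, nlo))
  if (length(idx)) {
    tIdx <- (idx - 1L) %% nT + 1L
    rIdx <- ((idx - 1L) %/% nT) %% nla + 1L
    cIdx <- (idx - 1L) %/% (nT * nla) + 1L
    newdata <- data.frame(
      Lat = ref@lat[rIdx], Lon = ref@lon[cIdx],
      month = as.integer(format(ref@time[tIdx], "%m")),
      day = as.integer(format(ref@time[tIdx], "%d")),
      hour = as.integer(format(ref@time[tIdx], "%H")))
    for (nm in satCols) newdata[[nm]] <- cubes[[nm]]@values[idx]
    out[idx] <- predict(model, newdata)
  }
  GridCube("pm25", out, ref@time, ref@lat, ref@lon, units = "ug/m3")
}
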