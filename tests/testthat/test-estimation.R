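## Small cached training tables for learner tests.
toarTable <- function() {
  if (is.null(.fixtureCache$toar))
    .fixtureCache$toar <- buildTrainingTable(tinyScene(), "TOAR")$table
  .fixtureCache$toar
}
smallTable <- function(n = 400) {
  tab <- toarTable()
  new("FeatureTable", mode = tab@mode, data = tab@data[seq_len(n), ])
}

test_that("feature tables carry the exact predictor contracts", {
  expect_length(featureColumns("TOAR"), 21)
  expect_length(featureColumns("AOD"), 14)
  expect_true(all(c("R1", "R3", "R6", "NDVI", "SolarZenith") %in%
                    featureColumns("TOAR")))
  expect_false(any(c("R1", "NDVI") %in% featureColumns("AOD")))
  expect_true(all(c("month", "day", "hour", "Lat", "Lon", "PBLH") %in%
                    featureColumns("AOD")))

  tab <- toarTable()
  expect_s4_class(tab, "FeatureTable")
  expect_false(anyNA(tab@data))
  ## deterministic row order: sorted by station then time
  expect_false(is.unsorted(order(tab@data$station_id, tab@data$time)))

  ## empty input yields an empty table with a valid schema
  empty <- assembleFeatures(data.frame(), "AOD")
  expect_equal(nrow(empty@data), 0)
  expect_true(all(featureColumns("AOD") %in% names(empty@data)))

  ## residual missing values are refused by column name
  bad <- toarTable()@data[1:5, ]
  bad$NDVI[3] <- NA
  expect_error(assembleFeatures(bad, "TOAR"), "NDVI")
})

test_that("regression metrics match their closed forms", {
  m <- regressionMetrics(1:4, 1:4)
  expect_equal(c(m$r2, m$rmse, m$slope), c(1, 0, 1))

  ## constant shift: correlation-based R2 stays 1, RMSE is the shift
  m <- regressionMetrics(c(1, 2, 3, 4), c(1, 2, 3, 4) + 5)
  expect_equal(c(m$r2, m$rmse, m$slope), c(1, 5, 1))
  expect_lt(m$r2_ss, 0)   # the SS-based alternative reports the bias

  ## hand-computed: obs (1,2,3,4), pred (1.1,1.9,3.2,3.8); deviations
  ## (-1.5,-.5,.5,1.5) and (-1.4,-.6,.7,1.3) give Sxy = 4.7, Sxx = 5,
  ## Syy = 4.5 -> r2 = 4.7^2/(5*4.5); slope = 4.7/5; mse = .1/4
  m <- regressionMetrics(c(1, 2, 3, 4), c(1.1, 1.9, 3.2, 3.8))
  expect_equal(m$r2, 22.09 / 22.5)
  expect_equal(m$rmse, sqrt(0.025))
  expect_equal(m$slope, 0.94)

  expect_error(regressionMetrics(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_error(regressionMetrics(1, 2), "at least 2")
  ## metrics are invariant under row duplication
  obs <- c(1, 2, 3, 4); pred <- c(1.1, 1.9, 3.2, 3.8)
  m1 <- regressionMetrics(obs, pred)
  m3 <- regressionMetrics(rep(obs, 3), rep(pred, 3))
  expect_equal(m1$r2, m3$r2)
  expect_equal(m1$rmse, m3$rmse)
  expect_equal(m1$slope, m3$slope)
})

test_that("tuned defaults are shipped per learner and mode", {
  expect_equal(defaultHyperparameters("RF", "TOAR"),
               list(n_tree = 600, m_try = 9))
  expect_equal(defaultHyperparameters("RF", "AOD"),
               list(n_tree = 800, m_try = 5))
  expect_equal(defaultHyperparameters("GBR", "TOAR")$learning_rate, 0.1)
  expect_equal(defaultHyperparameters("XGBoost", "AOD")$min_child_weight, 1)
  expect_equal(defaultHyperparameters("SVR", "AOD"), list(gamma = 0.7, C = 3))
  expect_true(nrow(defaultGrid("RF", "TOAR")) == 9)
})

test_that("all four learners fit deterministically and predict sensibly", {
  tab <- smallTable(300)
  hy <- list(RF = list(n_tree = 40, m_try = 9),
             GBR = list(n_estimators = 30, max_depth = 4, subsample = 0.7,
                        learning_rate = 0.2),
             XGBoost = list(n_estimators = 30, max_depth = 4,
                            subsample = 0.7, learning_rate = 0.2,
                            colsample_bytree = 0.8, min_child_weight = 2),
             SVR = list(gamma = 0.5, C = 1))
  for (alg in names(hy)) {
    m1 <- fitModel(tab, alg, hy[[alg]], seed = 4)
    m2 <- fitModel(tab, alg, hy[[alg]], seed = 4)
    p1 <- predict(m1, tab@data)
    p2 <- predict(m2, tab@data)
    expect_identical(p1, p2)
    expect_length(p1, nrow(tab@data))
    ## in-sample fit beats the mean predictor for every learner
    expect_gt(regressionMetrics(tab@data$pm25, p1)$r2, 0.3)
  }
  expect_error(fitModel(tab, "nonsense"), "arg")
})

test_that("a deep random forest interpolates its training data", {
  tab <- smallTable(300)
  m <- fitModel(tab, "RF", list(n_tree = 100, m_try = 15), seed = 1)
  expect_gt(regressionMetrics(tab@data$pm25, predict(m, tab@data))$r2, 0.85)

  ## constant target -> constant prediction
  cdat <- tab@data; cdat$pm25 <- 42
  ctab <- new("FeatureTable", mode = "TOAR", data = cdat)
  mc <- fitModel(ctab, "RF", list(n_tree = 20, m_try = 5), seed = 1)
  expect_equal(unique(predict(mc, cdat)), 42)
})

test_that("cross-validation partitions rows exactly and reproducibly", {
  tab <- smallTable(203)
  gs <- gridSearchCV(tab, "RF", grid = data.frame(n_tree = 30, m_try = 5),
                     cvFolds = 10, seed = 2)
  folds <- gs$cv@data$fold
  expect_length(folds, 203)
  sizes <- table(folds)
  expect_length(sizes, 10)
  expect_lte(diff(range(sizes)), 1)      # sizes within one row
  ## reproducible partition and predictions
  gs2 <- gridSearchCV(tab, "RF", grid = data.frame(n_tree = 30, m_try = 5),
                      cvFolds = 10, seed = 2)
  expect_identical(gs$cv@data, gs2$cv@data)
  ## a single-combination grid returns that combination, CV still executed
  expect_equal(gs$best, list(n_tree = 30, m_try = 5))
  expect_equal(nrow(gs$search), 1)
  expect_false(anyNA(gs$search$r2))

  expect_error(gridSearchCV(smallTable(5), "RF", cvFolds = 10), "folds")
})

test_that("site-blocked folds keep each station in one fold", {
  tab <- smallTable(400)
  gs <- gridSearchCV(tab, "RF", grid = data.frame(n_tree = 20, m_try = 5),
                     cvFolds = 5, seed = 3, foldScheme = "site")
  spread <- tapply(gs$cv@data$fold, gs$cv@data$station_id,
                   function(f) length(unique(f)))
  expect_true(all(spread == 1))
})

test_that("grid search selects the best combination by R2 then RMSE", {
  tab <- smallTable(350)
  grid <- data.frame(n_tree = c(5, 60), m_try = c(1, 9))
  gs <- gridSearchCV(tab, "RF", grid = grid, cvFolds = 5, seed = 1)
  ## the stronger configuration must win on pooled R2
  expect_equal(gs$best$n_tree, gs$search$n_tree[which.max(gs$search$r2)])
  expect_equal(gs$cv@hyper, gs$best)
})

test_that("grid prediction respects predictor validity", {
  sc <- tinyScene()
  built <- buildTrainingTable(sc, "AOD", gapFilled = FALSE)
  m <- fitModel(built$table, "RF", list(n_tree = 30, m_try = 5), seed = 1)
  pred <- predictGrid(m, built$stack)
  ## prediction valid exactly where AOD is valid (met is gap free)
  expect_identical(pred@valid, built$stack@cubes$AOD@valid)
  expect_true(all(pred@values[pred@valid] >= 0))

  ## gap-filled inputs strictly enlarge prediction coverage
  gf <- buildTrainingTable(sc, "AOD", gapFilled = TRUE)
  predGf <- predictGrid(m, gf$stack)
  expect_gt(nValid(predGf), nValid(pred))

  ## a missing predictor cube is named
  broken <- GridStack(built$stack@cubes[setdiff(names(built$stack@cubes),
                                                "AOD")])
  expect_error(predictGrid(m, broken), "AOD")
})
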