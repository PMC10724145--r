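test_that("Min-Max bounds come from complete records only", {
  rec <- make_records(3)
  rec$elevation <- c(2000, 3000, 4000)
  tab <- measurementTable(rec)
  b <- fitMinmaxBounds(tab, lai = c(1, 2, 3))
  expect_equal(b@elevation, c(2000, 4000))
  expect_equal(b@lai, c(1, 3))

  # fixture elevations span the printed range
  fix <- readMeasurements(fixture_path())
  bf <- fitMinmaxBounds(fix, lai = seq(0.5, 3, length.out = 13))
  expect_equal(bf@elevation, c(2294, 3831))

  expect_error(fitMinmaxBounds(measurementTable(make_records(1)), lai = 1),
               ">= 2 records")
  rec$elevation <- 3000
  expect_error(fitMinmaxBounds(measurementTable(rec), lai = c(1, 2, 3)),
               "degenerate.*elevation")
})

test_that("normalization maps endpoints, midpoints and clamps", {
  b <- normalizationBounds(c(0, 10), c(0, 10), c(0, 10))
  expect_equal(minmaxNormalize(0, b, "elevation"), 0)
  expect_equal(minmaxNormalize(10, b, "elevation"), 1)
  expect_equal(minmaxNormalize(5, b, "elevation"), 0.5)
  expect_equal(minmaxNormalize(12, b, "elevation"), 1)        # clamped
  expect_equal(minmaxNormalize(12, b, "elevation", clamp = FALSE), 1.2)
  expect_equal(minmaxNormalize(-3, b, "temperature"), 0)
  expect_true(is.na(minmaxNormalize(NA_real_, b, "lai")))
  expect_error(normalizationBounds(c(5, 5), c(0, 1), c(0, 1)),
               "degenerate")
})

test_that("the composite index applies the signed contribution weights", {
  expect_equal(compositeIndex(1, 0, 0), -0.3958)
  expect_equal(compositeIndex(0, 1, 0), 0.3550)
  expect_equal(compositeIndex(0, 0, 1), 0.2492)
  expect_equal(compositeIndex(0, 0, 0), 0)
  expect_equal(compositeIndex(0.5, 0.5, 0.5), 0.1042, tolerance = 1e-12)
  # weight magnitudes sum to one
  w <- contributionWeights()
  expect_equal(abs(w@w_elevation) + w@w_temperature + w@w_lai, 1,
               tolerance = 1e-6)
  expect_error(contributionWeights(w_elevation = 0.4), "negative")
})

test_that("composite index is linear and matches a dot-product oracle", {
  set.seed(31)
  w <- contributionWeights()
  wv <- c(w@w_elevation, w@w_temperature, w@w_lai)
  for (i in 1:25) {
    p <- runif(3)
    a <- runif(1, -2, 2)
    expect_equal(compositeIndex(p[1], p[2], p[3]), sum(wv * p),
                 tolerance = 1e-14)
    expect_equal(compositeIndex(a * p[1], a * p[2], a * p[3]),
                 a * compositeIndex(p[1], p[2], p[3]), tolerance = 1e-13)
  }
})

test_that("predictions follow the linear model", {
  expect_equal(predictOxygen(0), 20.2509)
  expect_equal(predictOxygen(1), 21.2792)
  expect_equal(predictOxygen(0, linearModel(0, 0)), 0)
})

test_that("index and prediction ranges follow from interval arithmetic", {
  set.seed(13)
  p <- matrix(runif(300), ncol = 3)
  tmp <- compositeIndex(p[, 1], p[, 2], p[, 3])
  expect_true(all(tmp >= -0.3958 - 1e-12 & tmp <= 0.6042 + 1e-12))
  oc <- predictOxygen(tmp)
  expect_true(all(oc >= 19.8439 - 1e-10 & oc <= 20.8722 + 1e-10))
  # holding temperature and LAI fixed, OC strictly decreases in N_E
  ne <- seq(0, 1, by = 0.1)
  oc_ne <- predictOxygen(compositeIndex(ne, 0.5, 0.5))
  expect_true(all(diff(oc_ne) < 0))
  # and strictly increases in the index when the slope is positive
  expect_true(all(diff(predictOxygen(sort(tmp))) >= 0))
})

test_that("cross-validation is exact on noise-free linear data", {
  set.seed(17)
  x <- runif(40, -0.4, 0.6)
  y <- 1.0283 * x + 20.2509
  cv <- crossValidate(x, y, m_values = c(5, 20), n_reps = 50, seed = 1)
  expect_equal(cv$rmse_mean, c(0, 0), tolerance = 1e-10)
  expect_equal(cv$mean_slope, c(1.0283, 1.0283), tolerance = 1e-9)
  expect_equal(cv$mean_intercept, c(20.2509, 20.2509), tolerance = 1e-9)
})

test_that("cross-validation is bit-identical under a fixed seed", {
  set.seed(23)
  x <- runif(50, -0.4, 0.6)
  y <- 1.0283 * x + 20.2509 + rnorm(50, sd = 0.1)
  a <- crossValidate(x, y, m_values = c(10, 25), n_reps = 300, seed = 99)
  b <- crossValidate(x, y, m_values = c(10, 25), n_reps = 300, seed = 99)
  expect_identical(a, b)
  # and does not disturb the caller's RNG stream
  set.seed(7); before <- runif(3)
  set.seed(7); invisible(crossValidate(x, y, 10, n_reps = 10, seed = 1))
  expect_identical(runif(3), before)
})

test_that("cross-validation rejects bad parameters and degenerate data", {
  x <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  y <- 20 + x
  expect_error(crossValidate(x, y, m_values = 2, n_reps = 10, seed = 1),
               "3 <= m")
  expect_error(crossValidate(x, y, m_values = 5, n_reps = 10, seed = 1),
               "3 <= m")
  expect_error(crossValidate(x, y, m_values = 3, n_reps = 1, seed = 1),
               "n_reps")
  expect_error(crossValidate(x[1:3], y[1:3], 3, n_reps = 10, seed = 1),
               "at least 4")
  expect_error(crossValidate(rep(0.2, 6), 20 + rnorm(6), 4, n_reps = 5,
                             seed = 1),
               "degenerate")
})

test_that("the per-split OLS equals lm()", {
  set.seed(41)
  x <- runif(15); y <- 2 * x + 1 + rnorm(15, sd = 0.2)
  cf <- oxymap:::.ols(x, y)
  ref <- coef(lm(y ~ x))
  expect_equal(unname(cf["slope"]), unname(ref[2]), tolerance = 1e-12)
  expect_equal(unname(cf["intercept"]), unname(ref[1]), tolerance = 1e-12)
})

test_that("held-out RMSE estimates the generating noise level", {
  pts <- generatePoints(syntheticConfig(n_points = 200), seed = 6)
  y <- records(pts$table)$oxygen_concentration
  cv <- crossValidate(pts$truth$tmp, y, m_values = 60, n_reps = 400,
                      seed = 3)
  expect_equal(cv$rmse_mean, 0.0952, tolerance = 0.1)
})

test_that("RMSE decreases then plateaus in m; its spread grows near n", {
  pts <- generatePoints(syntheticConfig(n_points = 120), seed = 14)
  y <- records(pts$table)$oxygen_concentration
  cv <- crossValidate(pts$truth$tmp, y, m_values = c(5, 40, 80, 115),
                      n_reps = 400, seed = 8)
  expect_gt(cv$rmse_mean[1], cv$rmse_mean[2])            # early descent
  expect_lt(abs(cv$rmse_mean[3] - cv$rmse_mean[2]),
            cv$rmse_mean[1] - cv$rmse_mean[2])           # plateau
  expect_gt(cv$rmse_std[4], cv$rmse_std[2])              # tiny test sets
})

test_that("model selection minimizes rmse_std with deterministic ties", {
  base <- data.frame(n_reps = 100, mean_slope = 1, mean_intercept = 20,
                     rmse_mean = 0.1)
  res <- cbind(m = c(10, 76, 150), base,
               row.names = NULL)
  res$rmse_std <- c(0.005, 0.0019, 0.003)
  sel <- selectRobustModel(res)
  expect_equal(sel$result$m, 76)
  expect_equal(sel$result$rmse_std, 0.0019)

  res$rmse_std <- c(0.002, 0.002, 0.003)   # tie -> smaller m
  expect_equal(selectRobustModel(res)$result$m, 10)

  expect_equal(selectRobustModel(res[2, ])$result$m, 76)  # singleton
  expect_error(selectRobustModel(res[0, ]), "non-empty")
  expect_s4_class(sel$model, "LinearModel")
  expect_equal(sel$model@slope, sel$result$mean_slope)
})
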