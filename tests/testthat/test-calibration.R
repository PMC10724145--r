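make_sessions <- function(source_vals, slope = 1, intercept = 0,
                          source = "A", target = "B") {
  df <- data.frame(point_id = sprintf("P-%02d", seq_along(source_vals)))
  df[[source]] <- source_vals
  df[[target]] <- slope * source_vals + intercept
  df
}

test_that("identity sessions give the identity fit", {
  sess <- make_sessions(c(20.1, 20.4, 19.8, 20.6, 20.2))
  fit <- fitPairwiseCalibration(sess, "A", "B")
  expect_equal(fit@slope, 1, tolerance = 1e-12)
  expect_equal(fit@intercept, 0, tolerance = 1e-10)
  expect_equal(fit@r_squared, 1, tolerance = 1e-12)
  expect_equal(fit@n, 5L)
})

test_that("exact linear sessions recover slope and intercept", {
  sess <- make_sessions(c(19.9, 20.2, 20.5, 20.8), slope = 0.9,
                        intercept = 2.0)
  fit <- fitPairwiseCalibration(sess, "A", "B")
  expect_equal(fit@slope, 0.9, tolerance = 1e-12)
  expect_equal(fit@intercept, 2.0, tolerance = 1e-10)
  expect_equal(fit@r_squared, 1, tolerance = 1e-12)
})

test_that("fits agree with lm() on noisy data and need >= 3 complete pairs", {
  set.seed(11)
  x <- runif(12, 19.5, 21)
  y <- 0.95 * x + 1.1 + rnorm(12, sd = 0.05)
  sess <- data.frame(point_id = sprintf("P-%02d", 1:12), A = x, B = y)
  fit <- fitPairwiseCalibration(sess, "A", "B")
  ref <- lm(y ~ x)
  expect_equal(fit@slope, unname(coef(ref)[2]), tolerance = 1e-12)
  expect_equal(fit@intercept, unname(coef(ref)[1]), tolerance = 1e-12)
  expect_equal(fit@r_squared, summary(ref)$r.squared, tolerance = 1e-12)
  expect_equal(fit@p_value, summary(ref)$coefficients[2, 4],
               tolerance = 1e-12)

  sess$B[3:12] <- NA   # only two complete pairs left
  expect_error(fitPairwiseCalibration(sess, "A", "B"), "insufficient")
})

test_that("calibration sessions assemble from long format", {
  long <- generateCalibrationSessions(n_sessions = 10, seed = 5)
  wide <- calibrationSessions(long)
  expect_setequal(names(wide), c("point_id", "A", "B", "C", "D"))
  expect_equal(nrow(wide), 10L)
  # repeated meter rows per group are averaged
  dup <- rbind(long, long)
  expect_equal(calibrationSessions(dup)[, c("A", "B", "C", "D")],
               wide[, c("A", "B", "C", "D")])
  expect_error(calibrationSessions(transform(long, group = "X")),
               "unknown instrument group")
})

test_that("generated group offsets are recovered exactly at zero noise", {
  offs <- list(A = c(0.93, 1.3), B = c(1, 0))
  long <- generateCalibrationSessions(n_sessions = 15, group_offsets = offs,
                                      noise_sd = 0, seed = 2)
  fit <- fitPairwiseCalibration(calibrationSessions(long), "A", "B")
  # truth: B = t, A = 0.93 t + 1.3  =>  B = (A - 1.3) / 0.93
  expect_equal(fit@slope, 1 / 0.93, tolerance = 1e-6)
  expect_equal(fit@intercept, -1.3 / 0.93, tolerance = 1e-6)
  expect_equal(fit@r_squared, 1, tolerance = 1e-10)
})

test_that("same-model meter groups agree nearly perfectly", {
  long <- generateCalibrationSessions(n_sessions = 40, seed = 8)
  fit <- fitPairwiseCalibration(calibrationSessions(long), "B", "C")
  expect_gte(fit@r_squared, 0.999)
})

test_that("applyCalibration converts, relabels and records provenance", {
  rec <- make_records(4, year = 2017)   # inferred group A
  tab <- measurementTable(rec)
  fit <- new("CalibrationFit", source_group = "A", target_group = "B",
             slope = 0.9, intercept = 2.0, r_squared = 1, n = 5L,
             p_value = numeric())
  out <- applyCalibration(tab, list(fit), target = "B")
  expect_equal(records(out)$oxygen_concentration,
               0.9 * rec$oxygen_concentration + 2.0)
  expect_true(all(records(out)$instrument_group == "B"))
  expect_true(all(records(out)$calibrated_from == "A"))
  # the specific hand-checked point: 0.9 * 20 + 2 = 20
  tab20 <- measurementTable(transform(rec, oxygen_concentration = 20))
  expect_equal(records(applyCalibration(tab20, list(fit)))$
                 oxygen_concentration, rep(20, 4))
})

test_that("applyCalibration is a no-op on target-group tables", {
  tab <- measurementTable(make_records(5, year = 2019))  # group B
  out <- applyCalibration(tab, list(), target = "B")
  expect_equal(records(out)$oxygen_concentration,
               records(tab)$oxygen_concentration)
})

test_that("a group without a fit is a configuration error naming it", {
  tab <- measurementTable(make_records(3, year = 2021))  # group C
  expect_error(applyCalibration(tab, list(), target = "B"), "C")
})

test_that("identity fits relabel groups without changing values", {
  rec <- make_records(6)
  rec$instrument_group <- rep(c("A", "B", "C"), 2)
  tab <- measurementTable(rec)
  idfit <- function(g) new("CalibrationFit", source_group = g,
                           target_group = "B", slope = 1, intercept = 0,
                           r_squared = 1, n = 3L, p_value = numeric())
  out <- applyCalibration(tab, list(idfit("A"), idfit("C")), target = "B")
  expect_equal(records(out)$oxygen_concentration,
               rec$oxygen_concentration)
  expect_true(all(records(out)$instrument_group == "B"))
})

test_that("applying a fit then its inverse is the identity", {
  set.seed(21)
  for (i in 1:20) {
    fit <- new("CalibrationFit", source_group = "A", target_group = "B",
               slope = runif(1, 0.7, 1.3), intercept = runif(1, -2, 2),
               r_squared = 1, n = 5L, p_value = numeric())
    inv <- invertCalibration(fit)
    oc <- runif(5, 19, 21)
    expect_equal(inv@slope * (fit@slope * oc + fit@intercept) +
                   inv@intercept, oc, tolerance = 1e-10)
  }
})
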