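# Shared fixtures and independent oracles.

fixture_path <- function() {
  system.file("extdata", "table3_qinghai_lake.csv", package = "oxymap")
}

# Oxygen concentrations printed in the published partial table (13 rows
# around Qinghai Lake, August 2018).
TABLE3_OC <- c(20.35, 20.28, 20.30, 20.43, 20.36, 20.31, 20.38, 20.41,
               20.52, 20.42, 20.49, 20.37, 20.59)

# Closed-form one-sample t-test: the independent oracle for the
# stats::t.test-backed implementation.
ttest_oracle <- function(values, mu0) {
  n <- length(values)
  m <- mean(values)
  s <- sqrt(sum((values - m)^2) / (n - 1))
  se <- s / sqrt(n)
  t_stat <- (m - mu0) / se
  q <- qt(0.975, df = n - 1)
  list(t_statistic = t_stat,
       p_value = 2 * pt(-abs(t_stat), df = n - 1),
       ci_low = m - q * se, ci_high = m + q * se)
}

# Scalar-path oracle for the gridded estimator: normalize -> composite
# index -> linear model, applied cell by cell in explicit loops.
scalar_map_oracle <- function(stack, weights, bounds, model) {
  ev <- gridValues(stack@elevation)
  tv <- gridValues(stack@temperature)
  lv <- gridValues(stack@lai)
  out <- ev * NA_real_
  for (i in seq_len(nrow(ev))) {
    for (j in seq_len(ncol(ev))) {
      if (is.na(ev[i, j]) || is.na(tv[i, j]) || is.na(lv[i, j])) next
      tmp <- compositeIndex(
        minmaxNormalize(ev[i, j], bounds, "elevation"),
        minmaxNormalize(tv[i, j], bounds, "temperature"),
        minmaxNormalize(lv[i, j], bounds, "lai"),
        weights)
      out[i, j] <- predictOxygen(tmp, model)
    }
  }
  out
}

# A small valid measurement data.frame for constructor tests.
make_records <- function(n = 5, year = 2019) {
  data.frame(
    tid = sprintf("T-%03d", seq_len(n)),
    fid = sprintf("F-%03d", seq_len(n)),
    timestamp = as.POSIXct(sprintf("%d-08-01 10:00:00", year), tz = "UTC") +
      seq_len(n) * 3600,
    longitude = seq(90, 100, length.out = n),
    latitude = seq(30, 36, length.out = n),
    elevation = seq(2500, 4500, length.out = n),
    temperature = seq(18, 5, length.out = n),
    pressure = seq(750, 580, length.out = n),
    oxygen_concentration = seq(20.5, 20.1, length.out = n))
}
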