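# Statistical validation of field data: one-sample t-tests of measured
# oxygen concentration against the conventional well-mixed-atmosphere
# constant 20.946%, stratified summary tables, and the measured-vs-remote
# vegetation regression check.

#' Reference oxygen concentration of well-mixed dry air
#'
#' The conventional constant 20.946% by volume, against which measured
#' plateau concentrations are tested.
#' @export
REFERENCE_OC <- 20.946

#' One-sample t-test against a reference concentration
#'
#' Two-sided t-test of a sample mean against `mu0`, with the t-based 95%
#' confidence interval for the mean.
#'
#' @param values oxygen concentrations (%), n >= 2, finite.
#' @param mu0 reference value (default [REFERENCE_OC]).
#' @param conf_level confidence level for the interval (default 0.95).
#' @return List with `n`, `mean`, `sd` (sample, n-1 denominator),
#'   `t_statistic`, `p_value`, `ci_low`, `ci_high`.
#' @examples
#' oneSampleTTest(c(20.35, 20.28, 20.30, 20.43))
#' @export
oneSampleTTest <- function(values, mu0 = REFERENCE_OC, conf_level = 0.95) {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("insufficient data: a t-test needs n >= 2", call. = FALSE)
  if (any(!is.finite(values)))
    stop("values must be finite", call. = FALSE)
  s <- stats::sd(values)
  if (s == 0) {
    # a constant sample: the t statistic is 0/0 when the mean equals mu0
    # (no evidence of a difference, t = 0, p = 1) and +-Inf otherwise
    m <- mean(values)
    t_stat <- if (m == mu0) 0 else sign(m - mu0) * Inf
    return(list(n = length(values), mean = m, sd = 0, t_statistic = t_stat,
                p_value = if (m == mu0) 1 else 0, ci_low = m, ci_high = m))
  }
  tt <- stats::t.test(values, mu = mu0, conf.level = conf_level)
  list(n = length(values), mean = unname(tt$estimate),
       sd = s, t_statistic = unname(tt$statistic),
       p_value = tt$p.value, ci_low = tt$conf.int[1],
       ci_high = tt$conf.int[2])
}

# Season rule: months 6-8 summer, months 11-2 winter; other months do not
# enter the two-season table.
.season_of <- function(timestamp) {
  mon <- as.integer(format(timestamp, "%m"))
  ifelse(mon %in% 6:8, "summer",
         ifelse(mon %in% c(11L, 12L, 1L, 2L), "winter", NA_character_))
}

#' Stratified summary statistics with reference t-tests
#'
#' Groups records by (season, calendar year) — months 6-8 are summer,
#' months 11-2 winter, other months are excluded — and reports per
#' stratum the sample size, mean, sample standard deviation, t-test
#' against `mu0` and the 95% confidence interval for the mean. Strata with
#' a single record appear with the dispersion and test fields `NA`.
#'
#' @param table a [MeasurementTable-class] with timestamps.
#' @param mu0 reference concentration (default [REFERENCE_OC]).
#' @return data.frame sorted by season (summer first) then year, columns
#'   `season`, `year`, `n`, `mean`, `sd`, `t_statistic`, `p_value`,
#'   `ci_low`, `ci_high`. Empty input gives an empty frame.
#' @export
summarizeByStratum <- function(table, mu0 = REFERENCE_OC) {
  stopifnot(is(table, "MeasurementTable"))
  rec <- table@records
  empty <- data.frame(season = character(), year = integer(),
                      n = integer(), mean = numeric(), sd = numeric(),
                      t_statistic = numeric(), p_value = numeric(),
                      ci_low = numeric(), ci_high = numeric())
  if (!nrow(rec)) return(empty)
  season <- .season_of(rec$timestamp)
  year <- as.integer(format(rec$timestamp, "%Y"))
  keep <- !is.na(season) & !is.na(year) & !is.na(rec$oxygen_concentration)
  if (!any(keep)) return(empty)
  oc <- rec$oxygen_concentration[keep]
  key <- interaction(season[keep], year[keep], drop = TRUE)
  rows <- lapply(split(oc, key), function(v) {
    if (length(v) >= 2L) {
      tt <- oneSampleTTest(v, mu0 = mu0)
      data.frame(n = tt$n, mean = tt$mean, sd = tt$sd,
                 t_statistic = tt$t_statistic, p_value = tt$p_value,
                 ci_low = tt$ci_low, ci_high = tt$ci_high)
    } else {
      data.frame(n = 1L, mean = v, sd = NA_real_, t_statistic = NA_real_,
                 p_value = NA_real_, ci_low = NA_real_, ci_high = NA_real_)
    }
  })
  parts <- strsplit(names(rows), ".", fixed = TRUE)
  out <- cbind(data.frame(season = vapply(parts, `[`, "", 1L),
                          year = as.integer(vapply(parts, `[`, "", 2L))),
               do.call(rbind, rows))
  out <- out[order(match(out$season, c("summer", "winter")), out$year), ]
  rownames(out) <- NULL
  out
}

#' Regression check of measured against reference values
#'
#' Ordinary least-squares regression of field-measured values on
#' co-located reference values (e.g. measured fractional vegetation
#' coverage against the remote-sensing product), reporting slope,
#' intercept, R-squared and the two-sided slope-test p-value.
#'
#' @param measured,reference numeric vectors of equal length >= 3.
#' @return A [CalibrationFit-class] with `source_group = "reference"` and
#'   `target_group = "measured"`.
#' @export
regressValidation <- function(measured, reference) {
  if (length(measured) != length(reference))
    stop("'measured' and 'reference' must have equal length", call. = FALSE)
  if (length(measured) < 3L)
    stop("need at least 3 pairs", call. = FALSE)
  fit <- stats::lm(measured ~ reference)
  cf <- unname(stats::coef(fit))
  sm <- suppressWarnings(summary(fit))   # exact fits are legitimate input
  p <- tryCatch(sm$coefficients[2, 4], error = function(e) NA_real_)
  new("CalibrationFit", source_group = "reference",
      target_group = "measured", slope = cf[2], intercept = cf[1],
      r_squared = min(max(sm$r.squared, 0), 1), n = length(measured),
      p_value = if (is.na(p)) numeric() else p)
}
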