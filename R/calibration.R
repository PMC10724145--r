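# Instrument cross-calibration: pairwise OLS harmonization between the
# four meter groups (A: 2017 electrochemical meters; B: 2018-2020; C:
# 2021; D: 2022 replacements), fitted from sessions in which several
# groups read the same point simultaneously.

#' Assemble calibration sessions from a long-format table
#'
#' A calibration session is one field point at which two or more
#' instrument groups measured oxygen concentration simultaneously; the
#' per-group reading is the mean of that group's meters. Input is long
#' format with columns `point_id`, `group`, `oxygen_concentration`
#' (several rows per point/group are averaged).
#'
#' @param x data.frame with columns `point_id`, `group`,
#'   `oxygen_concentration`.
#' @return A wide data.frame, one row per session: `point_id` plus one
#'   numeric column per instrument group present (NA where a group did
#'   not read that point). Sessions with fewer than two groups are
#'   dropped with a warning.
#' @export
calibrationSessions <- function(x) {
  stopifnot(is.data.frame(x),
            all(c("point_id", "group", "oxygen_concentration") %in% names(x)))
  if (any(!x$group %in% .INSTRUMENT_GROUPS))
    stop("unknown instrument group(s): ",
         paste(unique(setdiff(x$group, .INSTRUMENT_GROUPS)), collapse = ", "),
         call. = FALSE)
  agg <- stats::aggregate(oxygen_concentration ~ point_id + group, data = x,
                          FUN = mean)
  wide <- stats::reshape(agg, idvar = "point_id", timevar = "group",
                         direction = "wide")
  names(wide) <- sub("^oxygen_concentration\\.", "", names(wide))
  rownames(wide) <- NULL
  n_groups <- rowSums(!is.na(wide[, -1, drop = FALSE]))
  if (any(n_groups < 2)) {
    warning(sum(n_groups < 2),
            " session(s) with fewer than two groups dropped", call. = FALSE)
    wide <- wide[n_groups >= 2, , drop = FALSE]
  }
  wide[order(wide$point_id), , drop = FALSE]
}

#' Fit a pairwise instrument calibration
#'
#' Ordinary least-squares regression of target-group readings on
#' source-group readings, restricted to sessions in which both groups are
#' present. Source values are later substituted as the independent
#' variable when converting measurements to the target standard.
#'
#' @param sessions wide session table from [calibrationSessions()] (or any
#'   data.frame with one numeric column per group).
#' @param source,target instrument group labels (`"A"`-`"D"`).
#' @return A [CalibrationFit-class] with slope, intercept, R-squared,
#'   slope-test p-value and the number of complete sessions used.
#' @examples
#' long <- data.frame(point_id = rep(sprintf("P%d", 1:5), each = 2),
#'                    group = rep(c("A", "B"), 5),
#'                    oxygen_concentration = c(20.1, 20.3, 20.4, 20.6,
#'                                             19.8, 20.0, 20.6, 20.8,
#'                                             20.2, 20.4))
#' fitPairwiseCalibration(calibrationSessions(long), "A", "B")
#' @export
fitPairwiseCalibration <- function(sessions, source, target) {
  stopifnot(is.data.frame(sessions))
  for (g in c(source, target))
    if (!g %in% names(sessions))
      stop("no readings for group '", g, "' in the sessions", call. = FALSE)
  x <- sessions[[source]]
  y <- sessions[[target]]
  both <- !is.na(x) & !is.na(y)
  if (sum(both) < 3L)
    stop("insufficient data: need >= 3 sessions with both groups '",
         source, "' and '", target, "', got ", sum(both), call. = FALSE)
  fit <- stats::lm(y[both] ~ x[both])
  cf <- unname(stats::coef(fit))
  # exact linear sessions are a legitimate input; silence summary.lm's
  # "essentially perfect fit" warning
  sm <- suppressWarnings(summary(fit))
  p <- tryCatch(sm$coefficients[2, 4], error = function(e) NA_real_)
  new("CalibrationFit", source_group = source, target_group = target,
      slope = cf[2], intercept = cf[1],
      r_squared = min(max(sm$r.squared, 0), 1), n = sum(both),
      p_value = if (is.na(p)) numeric() else p)
}

#' Harmonize a measurement table to one instrument standard
#'
#' Converts oxygen concentrations measured by other instrument groups to
#' the target group's standard using pairwise calibration fits
#' (`OC_target = slope * OC_source + intercept`). Records already in the
#' target group pass through unchanged; all output records are re-labeled
#' to the target group, and a `calibrated_from` provenance column records
#' each record's original group.
#'
#' @param table a [MeasurementTable-class]; every record needs an
#'   instrument group.
#' @param fits list of [CalibrationFit-class] objects, one per non-target
#'   group present, each with `target_group` equal to `target`.
#' @param target harmonization target group (default `"B"`, the group
#'   with the largest measurement campaign).
#' @return The harmonized [MeasurementTable-class].
#' @seealso [fitPairwiseCalibration()], [invertCalibration()]
#' @export
applyCalibration <- function(table, fits, target = "B") {
  stopifnot(is(table, "MeasurementTable"))
  if (is(fits, "CalibrationFit")) fits <- list(fits)
  for (f in fits) {
    stopifnot(is(f, "CalibrationFit"))
    if (f@target_group != target)
      stop("fit ", f@source_group, " -> ", f@target_group,
           " does not target group '", target, "'", call. = FALSE)
  }
  fit_for <- structure(fits, names = vapply(fits, slot, "", "source_group"))
  rec <- table@records
  grp <- rec$instrument_group
  if (anyNA(grp))
    stop("records without an instrument group cannot be calibrated",
         call. = FALSE)
  need <- setdiff(unique(grp), target)
  missing_fit <- setdiff(need, names(fit_for))
  if (length(missing_fit))
    stop("configuration error: no calibration fit to '", target,
         "' for group(s): ", paste(missing_fit, collapse = ", "),
         call. = FALSE)
  oc <- rec$oxygen_concentration
  for (g in need) {
    f <- fit_for[[g]]
    sel <- grp == g
    oc[sel] <- f@slope * oc[sel] + f@intercept
  }
  rec$oxygen_concentration <- oc
  rec$calibrated_from <- grp
  rec$instrument_group <- target
  out <- table
  out@records <- rec
  validObject(out)
  out
}

#' Invert a calibration fit
#'
#' Returns the algebraic inverse mapping target-standard values back to
#' the source standard: `OC_source = (OC_target - intercept) / slope`.
#' Applying a fit and then its inverse is the identity up to floating
#' tolerance.
#'
#' @param fit a [CalibrationFit-class] with nonzero slope.
#' @return A [CalibrationFit-class] with source and target swapped.
#' @export
invertCalibration <- function(fit) {
  stopifnot(is(fit, "CalibrationFit"))
  if (abs(fit@slope) < .Machine$double.eps)
    stop("cannot invert a fit with zero slope", call. = FALSE)
  new("CalibrationFit", source_group = fit@target_group,
      target_group = fit@source_group, slope = 1 / fit@slope,
      intercept = -fit@intercept / fit@slope, r_squared = fit@r_squared,
      n = fit@n, p_value = fit@p_value)
}
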