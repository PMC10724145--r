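# Composite-index oxygen-concentration model:
#   Tmp = w_E * N_E + w_T * N_T + w_L * N_L      (N_* Min-Max normalized)
#   OC  = slope * Tmp + intercept
# The slope/intercept are fitted by repeated random-subsampling
# cross-validation; the training-set size whose held-out RMSE has the
# smallest standard deviation across draws gives the "most robust" model.

#' Min-Max normalization bounds from point data
#'
#' Computes the observed minimum and maximum of elevation, temperature and
#' LAI over the records for which all three predictors are present. These
#' bounds are later reused when the model is applied to raster grids
#' (values beyond them are clamped).
#'
#' @param table a [MeasurementTable-class].
#' @param lai numeric vector of per-record LAI values (same length as the
#'   table; remote-sensing LAI is not part of the field schema).
#' @return A [NormalizationBounds-class].
#' @examples
#' tab <- measurementTable(data.frame(
#'   longitude = c(95, 96, 97), latitude = c(30, 31, 32),
#'   elevation = c(2000, 3000, 4000), temperature = c(15, 10, 5),
#'   oxygen_concentration = c(20.5, 20.4, 20.3)))
#' fitMinmaxBounds(tab, lai = c(2.5, 1.5, 0.5))
#' @export
fitMinmaxBounds <- function(table, lai) {
  stopifnot(is(table, "MeasurementTable"))
  rec <- table@records
  if (length(lai) != nrow(rec))
    stop("'lai' must supply one value per record", call. = FALSE)
  ok <- !is.na(rec$elevation) & !is.na(rec$temperature) & !is.na(lai)
  if (sum(ok) < 2L)
    stop("need >= 2 records with elevation, temperature and LAI present",
         call. = FALSE)
  rng <- function(x, what) {
    r <- range(x)
    if (r[2] <= r[1])
      stop("degenerate bounds: '", what, "' is constant", call. = FALSE)
    r
  }
  normalizationBounds(elevation = rng(rec$elevation[ok], "elevation"),
                      temperature = rng(rec$temperature[ok], "temperature"),
                      lai = rng(lai[ok], "lai"))
}

#' Min-Max normalize values against fitted bounds
#'
#' `(x - min) / (max - min)`, vectorized. Values outside the bounds — which
#' arise when training-point bounds are applied to raster grids — are
#' clamped to `[0, 1]` by default so predictions stay within the
#' calibrated index range.
#'
#' @param x numeric vector in native units (`NA` passes through).
#' @param bounds a [NormalizationBounds-class].
#' @param variable which bounds to use: `"elevation"`, `"temperature"` or
#'   `"lai"`.
#' @param clamp clamp out-of-range results to `[0, 1]` (default `TRUE`);
#'   `FALSE` extrapolates linearly.
#' @return Dimensionless numeric vector.
#' @examples
#' b <- normalizationBounds(c(2000, 4000), c(0, 20), c(0, 4))
#' minmaxNormalize(c(2000, 3000, 4000, 5000), b, "elevation")
#' @export
minmaxNormalize <- function(x, bounds,
                            variable = c("elevation", "temperature", "lai"),
                            clamp = TRUE) {
  stopifnot(is(bounds, "NormalizationBounds"))
  variable <- match.arg(variable)
  b <- slot(bounds, variable)
  out <- (x - b[1]) / (b[2] - b[1])
  if (clamp) out <- pmin(pmax(out, 0), 1)
  out
}

#' Composite index from normalized predictors
#'
#' The contribution-weighted sum `Tmp = w_E * N_E + w_T * N_T + w_L * N_L`.
#' The elevation weight carries the minus sign, so with the default
#' weights and predictors in `[0, 1]` the index lies in
#' `[-0.3958, 0.6042]`.
#'
#' @param n_elevation,n_temperature,n_lai dimensionless normalized
#'   predictors (vectors recycle as usual).
#' @param weights a [ContributionWeights-class].
#' @return Numeric vector of composite-index values.
#' @examples
#' compositeIndex(1, 0, 0)   # the elevation weight, -0.3958
#' compositeIndex(0.5, 0.5, 0.5)
#' @export
compositeIndex <- function(n_elevation, n_temperature, n_lai,
                           weights = contributionWeights()) {
  stopifnot(is(weights, "ContributionWeights"))
  weights@w_elevation * n_elevation +
    weights@w_temperature * n_temperature +
    weights@w_lai * n_lai
}

#' Predict oxygen concentration from the composite index
#'
#' `OC = slope * Tmp + intercept`; with the default published model,
#' `OC = 1.0283 * Tmp + 20.2509` (%).
#'
#' @param tmp composite-index values (numeric vector).
#' @param model a [LinearModel-class].
#' @return Oxygen concentration in percent by volume.
#' @examples
#' predictOxygen(0)    # the model intercept
#' @export
predictOxygen <- function(tmp, model = linearModel()) {
  stopifnot(is(model, "LinearModel"))
  model@slope * tmp + model@intercept
}

# Closed-form simple OLS used inside the CV loop (called 1e4-1e5 times;
# equivalent to lm(y ~ x), checked against it in the unit tests).
.ols <- function(x, y) {
  xbar <- mean(x); ybar <- mean(y)
  sxx <- sum((x - xbar)^2)
  slope <- sum((x - xbar) * (y - ybar)) / sxx
  c(slope = slope, intercept = ybar - slope * xbar)
}

#' Repeated random-subsampling cross-validation
#'
#' For each training-set size `m`, draws `n_reps` uniform
#' without-replacement training subsets, fits the simple linear regression
#' of oxygen concentration on the composite index on each, and evaluates
#' the RMSE on the held-out records. Reported per `m` are the mean slope,
#' mean intercept, mean RMSE and the standard deviation of RMSE across
#' draws (population formula, denominator `n_reps`).
#'
#' Training draws whose composite-index values are all equal cannot be
#' fitted; such a draw is redrawn, up to 100 times, before a
#' degenerate-data error is raised.
#'
#' @param x composite-index values (numeric).
#' @param y oxygen concentrations (%), same length as `x`, length >= 4.
#' @param m_values training-set sizes; each must satisfy
#'   `3 <= m <= length(x) - 1`.
#' @param n_reps random draws per `m` (>= 2). The full-scale protocol uses
#'   50,000; test suites typically use 2,000.
#' @param seed integer seed; identical seeds give bit-identical results.
#' @return data.frame with one row per `m`: `m`, `n_reps`, `mean_slope`,
#'   `mean_intercept`, `rmse_mean`, `rmse_std`.
#' @seealso [selectRobustModel()]
#' @examples
#' set.seed(7)
#' x <- runif(60, -0.4, 0.6)
#' y <- 1.0283 * x + 20.2509 + rnorm(60, sd = 0.1)
#' crossValidate(x, y, m_values = c(10, 30), n_reps = 200, seed = 1)
#' @export
crossValidate <- function(x, y, m_values, n_reps = 50000L, seed) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 4L) stop("need at least 4 observations", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("x and y must be finite", call. = FALSE)
  m_values <- as.integer(m_values)
  if (any(m_values < 3L | m_values > n - 1L))
    stop("every m must satisfy 3 <= m <= n - 1 (n = ", n, ")",
         call. = FALSE)
  n_reps <- as.integer(n_reps)
  if (n_reps < 2L) stop("n_reps must be >= 2", call. = FALSE)
  if (missing(seed)) stop("a seed is required for reproducibility",
                          call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(as.integer(seed))

  res <- lapply(m_values, function(m) {
    slopes <- numeric(n_reps)
    intercepts <- numeric(n_reps)
    rmses <- numeric(n_reps)
    for (r in seq_len(n_reps)) {
      for (attempt in 1:100) {
        idx <- sample.int(n, m)
        xt <- x[idx]
        if (max(xt) > min(xt)) break
        if (attempt == 100L)
          stop("degenerate data: training composite index constant in 100 ",
               "consecutive draws (m = ", m, ")", call. = FALSE)
      }
      cf <- .ols(xt, y[idx])
      resid <- y[-idx] - (cf[1] * x[-idx] + cf[2])
      slopes[r] <- cf[1]
      intercepts[r] <- cf[2]
      rmses[r] <- sqrt(mean(resid^2))
    }
    mu <- mean(rmses)
    data.frame(m = m, n_reps = n_reps,
               mean_slope = mean(slopes),
               mean_intercept = mean(intercepts),
               rmse_mean = mu,
               rmse_std = sqrt(mean((rmses - mu)^2)))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Select the most robust cross-validated model
#'
#' Picks the training-set size whose held-out RMSE has the smallest
#' standard deviation across random draws; ties break toward smaller `m`,
#' then smaller mean RMSE. The returned model uses the mean slope and
#' intercept from that configuration.
#'
#' @param results data.frame from [crossValidate()] (non-empty).
#' @return List with `result` (the chosen one-row data.frame) and `model`
#'   (a [LinearModel-class]).
#' @export
selectRobustModel <- function(results) {
  if (!is.data.frame(results) || nrow(results) == 0L)
    stop("'results' must be a non-empty cross-validation table",
         call. = FALSE)
  needed <- c("m", "mean_slope", "mean_intercept", "rmse_mean", "rmse_std")
  stopifnot(all(needed %in% names(results)))
  ord <- order(results$rmse_std, results$m, results$rmse_mean)
  chosen <- results[ord[1L], , drop = FALSE]
  rownames(chosen) <- NULL
  list(result = chosen,
       model = linearModel(slope = chosen$mean_slope,
                           intercept = chosen$mean_intercept))
}
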