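.check_coregistered <- function(a, b, what = "rasters") {
  if (!identical(dim(a@values), dim(b@values)) ||
      !isTRUE(all.equal(a@extent, b@extent, tolerance = 1e-9)) ||
      !identical(a@crs, b@crs))
    stop("co-registration error: ", what,
         " differ in shape, extent or crs", call. = FALSE)
  invisible(NULL)
}

# Composite index of a stack: normalize each layer against the fitted
# bounds (clamped), then weight. NA in any input layer propagates.
.stack_index <- function(stack, weights, bounds, clamp = TRUE) {
  compositeIndex(
    minmaxNormalize(stack@elevation@values, bounds, "elevation", clamp),
    minmaxNormalize(stack@temperature@values, bounds, "temperature", clamp),
    minmaxNormalize(stack@lai@values, bounds, "lai", clamp),
    weights)
}

#' Grid-by-grid oxygen-concentration estimation
#'
#' Applies the fitted model to a co-registered elevation/temperature/LAI
#' stack: each layer is Min-Max normalized against the training bounds
#' (out-of-range cells clamped to `[0, 1]`), the composite index is formed
#' cell-wise, and the linear model maps it to oxygen concentration. A cell
#' is nodata whenever any input layer is nodata. The output inherits the
#' stack's extent, CRS and nodata sentinel.
#'
#' @param stack a [RasterStack-class].
#' @param weights a [ContributionWeights-class].
#' @param bounds a [NormalizationBounds-class] (normally from
#'   [fitMinmaxBounds()] on the training points).
#' @param model a [LinearModel-class].
#' @param clamp clamp normalized values to `[0, 1]` (default `TRUE`).
#' @return A [RasterGrid-class] of oxygen concentration (%).
#' @seealso [uncertaintyMap()], [differenceMap()]
#' @export
estimateMap <- function(stack, weights = contributionWeights(), bounds,
                        model = linearModel(), clamp = TRUE) {
  stopifnot(is(stack, "RasterStack"), is(bounds, "NormalizationBounds"),
            is(model, "LinearModel"))
  tmp <- .stack_index(stack, weights, bounds, clamp)
  ref <- stack@elevation
  rasterGrid(predictOxygen(tmp, model), extent = ref@extent, crs = ref@crs,
             nodata = ref@nodata)
}

#' Seasonal difference map
#'
#' Cell-wise `july - january`. The convention is July minus January, so a
#' warmer, leafier July yields positive differences. Nodata propagates.
#'
#' @param july,january co-registered [RasterGrid-class] maps (%).
#' @return A [RasterGrid-class] of concentration differences (%).
#' @export
differenceMap <- function(july, january) {
  stopifnot(is(july, "RasterGrid"), is(january, "RasterGrid"))
  .check_coregistered(july, january, "difference-map inputs")
  rasterGrid(july@values - january@values, extent = july@extent,
             crs = july@crs, nodata = july@nodata)
}

#' Ensemble standard-deviation uncertainty map
#'
#' Per-cell standard deviation of the predicted oxygen concentration
#' across an ensemble of fitted models (population formula, denominator =
#' ensemble size — so two models differing only by an intercept shift `d`
#' give a constant `d/2`). The natural ensemble is the set of averaged
#' models produced by the cross-validation sweep, one per training-set
#' size. Nodata propagates from the input stack.
#'
#' @param stack a [RasterStack-class].
#' @param weights a [ContributionWeights-class].
#' @param bounds a [NormalizationBounds-class].
#' @param models list of at least two [LinearModel-class] objects.
#' @param clamp clamp normalized values to `[0, 1]` (default `TRUE`).
#' @return A [RasterGrid-class] of standard deviations (%), non-negative
#'   everywhere and invariant under model reordering.
#' @export
uncertaintyMap <- function(stack, weights = contributionWeights(), bounds,
                           models, clamp = TRUE) {
  stopifnot(is(stack, "RasterStack"), is(bounds, "NormalizationBounds"))
  if (!is.list(models) || length(models) < 2L)
    stop("need an ensemble of >= 2 models", call. = FALSE)
  for (m in models) stopifnot(is(m, "LinearModel"))
  tmp <- .stack_index(stack, weights, bounds, clamp)
  k <- length(models)
  slopes <- vapply(models, slot, numeric(1), "slope")
  intercepts <- vapply(models, slot, numeric(1), "intercept")
  # centered (two-pass) variance: deviations from the ensemble-mean model
  # avoid the cancellation a raw sum-of-squares suffers around ~20%
  v <- tmp * 0          # keeps the NA pattern
  for (i in seq_len(k)) {
    dev <- (slopes[i] - mean(slopes)) * tmp +
      (intercepts[i] - mean(intercepts))
    v <- v + dev * dev
  }
  v <- v / k
  ref <- stack@elevation
  rasterGrid(sqrt(v), extent = ref@extent, crs = ref@crs,
             nodata = ref@nodata)
}
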