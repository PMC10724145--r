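#' @import methods
NULL

## ---------------------------------------------------------------------------
## Measurement tables
## ---------------------------------------------------------------------------

# Canonical column order of a measurement table. Optional columns hold NA
# where a value is absent ("/" or empty in the source file).
.MEASUREMENT_COLUMNS <- c(
  "tid", "fid", "timestamp", "longitude", "latitude", "elevation",
  "temperature", "relative_humidity", "pressure", "oxygen_concentration",
  "fvc", "geomorph_type", "vegetation_type", "instrument_group"
)

.MANDATORY_COLUMNS <- c("longitude", "latitude", "elevation",
                        "oxygen_concentration")

.INSTRUMENT_GROUPS <- c("A", "B", "C", "D")

# Geographic extent of the plateau study area (degrees, WGS-84):
# xmin, xmax, ymin, ymax. Points outside only warn (off-plateau records
# are legal), hard physical ranges error.
.PLATEAU_EXTENT <- c(73.50, 104.67, 26.05, 39.91)

#' MeasurementTable: a table of field oxygen-concentration measurements
#'
#' An ordered collection of point measurements in the 13-column field schema:
#' identifiers (`tid`, `fid`), timestamp, position (decimal degrees, WGS-84),
#' elevation (m), meteorology (temperature degC, relative humidity %,
#' pressure hPa), oxygen concentration (% by volume), optional fractional
#' vegetation coverage (%), map-derived geomorphologic and vegetation type
#' labels, and the instrument group (A-D) that produced the record.
#'
#' @slot records data.frame with the canonical columns (see
#'   [measurementTable()]); optional fields are `NA` where absent.
#' @slot source character scalar, the file the table was read from or
#'   `"synthetic"`.
#' @exportClass MeasurementTable
setClass("MeasurementTable",
  representation(records = "data.frame", source = "character"))

setValidity("MeasurementTable", function(object) {
  rec <- object@records
  msgs <- character()
  missing_cols <- setdiff(.MEASUREMENT_COLUMNS, names(rec))
  if (length(missing_cols))
    msgs <- c(msgs, paste0("missing columns: ",
                           paste(missing_cols, collapse = ", ")))
  if (length(object@source) != 1L)
    msgs <- c(msgs, "'source' must be a single string")
  if (!length(msgs) && nrow(rec)) {
    if (anyDuplicated(rec$tid))
      msgs <- c(msgs, "tid values must be unique within a table")
    oc <- rec$oxygen_concentration
    if (any(!is.na(oc) & (oc <= 0 | oc > 30)))
      msgs <- c(msgs, "oxygen_concentration must lie in (0, 30]")
    el <- rec$elevation
    if (any(!is.na(el) & (el < -500 | el > 9000)))
      msgs <- c(msgs, "elevation must lie in [-500, 9000]")
    pr <- rec$pressure
    if (any(!is.na(pr) & (pr <= 300 | pr >= 1100)))
      msgs <- c(msgs, "pressure must lie in (300, 1100)")
    grp <- rec$instrument_group
    if (any(!is.na(grp) & !grp %in% .INSTRUMENT_GROUPS))
      msgs <- c(msgs, "instrument_group must be one of A, B, C, D")
  }
  if (length(msgs)) msgs else TRUE
})

## ---------------------------------------------------------------------------
## Model parameter objects
## ---------------------------------------------------------------------------

#' ContributionWeights: fixed relative contributions of the three predictors
#'
#' The composite index weighs normalized elevation, temperature and leaf
#' area index by their relative contributions to oxygen concentration.
#' Elevation contributes negatively, temperature and LAI positively; the
#' default weights are -0.3958, 0.3550 and 0.2492, whose absolute values
#' sum to one.
#'
#' @slot w_elevation,w_temperature,w_lai numeric scalars.
#' @exportClass ContributionWeights
setClass("ContributionWeights",
  representation(w_elevation = "numeric", w_temperature = "numeric",
                 w_lai = "numeric"))

setValidity("ContributionWeights", function(object) {
  w <- c(object@w_elevation, object@w_temperature, object@w_lai)
  if (length(w) != 3L || !all(is.finite(w)))
    return("weights must be three finite numeric scalars")
  msgs <- character()
  if (object@w_elevation >= 0)
    msgs <- c(msgs, "w_elevation must be negative")
  if (object@w_temperature <= 0 || object@w_lai <= 0)
    msgs <- c(msgs, "w_temperature and w_lai must be positive")
  if (length(msgs)) msgs else TRUE
})

#' NormalizationBounds: Min-Max ranges for the three predictors
#'
#' Observed minimum and maximum, in native units, used to rescale
#' elevation (m), temperature (degC) and LAI (dimensionless) to `[0, 1]`.
#'
#' @slot elevation,temperature,lai numeric length-2 `(min, max)` with
#'   `max > min`.
#' @exportClass NormalizationBounds
setClass("NormalizationBounds",
  representation(elevation = "numeric", temperature = "numeric",
                 lai = "numeric"))

setValidity("NormalizationBounds", function(object) {
  for (v in c("elevation", "temperature", "lai")) {
    b <- slot(object, v)
    if (length(b) != 2L || !all(is.finite(b)))
      return(sprintf("'%s' bounds must be two finite numbers", v))
    if (b[2] <= b[1])
      return(sprintf("degenerate bounds for '%s': max must exceed min", v))
  }
  TRUE
})

#' LinearModel: slope-intercept oxygen-concentration model
#'
#' The linear map from composite index to oxygen concentration,
#' `OC = slope * Tmp + intercept`, with an optional in-sample R-squared.
#'
#' @slot slope percent per unit composite index.
#' @slot intercept percent.
#' @slot r_squared numeric scalar in `[0, 1]` or length-0 when unknown.
#' @exportClass LinearModel
setClass("LinearModel",
  representation(slope = "numeric", intercept = "numeric",
                 r_squared = "numeric"))

setValidity("LinearModel", function(object) {
  if (length(object@slope) != 1L || length(object@intercept) != 1L ||
      !is.finite(object@slope) || !is.finite(object@intercept))
    return("slope and intercept must be finite scalars")
  r2 <- object@r_squared
  if (length(r2) > 1L || (length(r2) == 1L && (r2 < 0 || r2 > 1)))
    return("r_squared must be absent or a scalar in [0, 1]")
  TRUE
})

#' CalibrationFit: pairwise linear harmonization between instrument groups
#'
#' Ordinary least-squares fit of target-group readings on source-group
#' readings across simultaneous calibration sessions, used to convert
#' measurements to a common instrument standard.
#'
#' @slot source_group,target_group character labels (instrument groups
#'   `A`-`D`, or descriptive labels for generic regressions).
#' @slot slope dimensionless; @slot intercept percent.
#' @slot r_squared in `[0, 1]`; @slot n sessions used (>= 3).
#' @slot p_value two-sided p-value of the slope test (length 0 when not
#'   computed).
#' @exportClass CalibrationFit
setClass("CalibrationFit",
  representation(source_group = "character", target_group = "character",
                 slope = "numeric", intercept = "numeric",
                 r_squared = "numeric", n = "integer", p_value = "numeric"))

setValidity("CalibrationFit", function(object) {
  if (object@n < 3L) return("a calibration fit needs n >= 3 sessions")
  if (!is.finite(object@r_squared) ||
      object@r_squared < -1e-12 || object@r_squared > 1 + 1e-12)
    return("r_squared must lie in [0, 1]")
  TRUE
})

## ---------------------------------------------------------------------------
## Rasters
## ---------------------------------------------------------------------------

.WGS84 <- "GEOGCS[\"GCS_WGS_1984\",DATUM[\"D_WGS_1984\",SPHEROID[\"WGS_1984\",6378137.0,298.257223563]],PRIMEM[\"Greenwich\",0.0],UNIT[\"Degree\",0.0174532925199433]]"

#' RasterGrid: a georeferenced single-band grid
#'
#' Values are stored row-major from the north-west corner (pixel-is-area
#' registration); missing cells are `NA` in memory and written as the
#' nodata sentinel on disk.
#'
#' @slot values numeric matrix, row 1 = northernmost row.
#' @slot extent numeric length-4 `(xmin, xmax, ymin, ymax)` in CRS units.
#' @slot crs character, coordinate reference text (WKT); defaults to
#'   geographic WGS-84.
#' @slot nodata numeric scalar sentinel used on disk (default -9999).
#' @exportClass RasterGrid
setClass("RasterGrid",
  representation(values = "matrix", extent = "numeric", crs = "character",
                 nodata = "numeric"))

setValidity("RasterGrid", function(object) {
  v <- object@values
  if (!is.numeric(v) || nrow(v) < 1L || ncol(v) < 1L)
    return("values must be a numeric matrix with at least one cell")
  e <- object@extent
  if (length(e) != 4L || !all(is.finite(e)))
    return("extent must be finite (xmin, xmax, ymin, ymax)")
  if (e[2] <= e[1] || e[4] <= e[3])
    return("extent must have xmax > xmin and ymax > ymin")
  if (any(is.infinite(v)))
    return("grid values must be finite or NA")
  if (length(object@nodata) != 1L || !is.finite(object@nodata))
    return("nodata must be a single finite sentinel value")
  TRUE
})

#' RasterStack: co-registered elevation, temperature and LAI grids
#'
#' The three predictor layers of the oxygen-concentration model; identical
#' shape, extent and CRS are enforced.
#'
#' @slot elevation,temperature,lai [RasterGrid-class] layers.
#' @exportClass RasterStack
setClass("RasterStack",
  representation(elevation = "RasterGrid", temperature = "RasterGrid",
                 lai = "RasterGrid"))

setValidity("RasterStack", function(object) {
  ref <- object@elevation
  for (v in c("temperature", "lai")) {
    g <- slot(object, v)
    if (!identical(dim(g@values), dim(ref@values)))
      return(sprintf("layer '%s' is not co-registered: shape differs", v))
    if (!isTRUE(all.equal(g@extent, ref@extent, tolerance = 1e-9)))
      return(sprintf("layer '%s' is not co-registered: extent differs", v))
    if (!identical(g@crs, ref@crs))
      return(sprintf("layer '%s' is not co-registered: crs differs", v))
  }
  TRUE
})

## ---------------------------------------------------------------------------
## Constructors
## ---------------------------------------------------------------------------

#' Construct a MeasurementTable
#'
#' Builds a [MeasurementTable-class] from a data.frame, filling absent
#' optional columns with `NA`, validating physical ranges, and inferring
#' the instrument group from the record year when it is not given
#' (2017 -> A, 2018-2020 -> B, 2021 -> C, 2022 -> D). Records outside the
#' plateau longitude/latitude extent raise a warning, not an error.
#'
#' @param records data.frame; must contain `longitude`, `latitude`,
#'   `elevation` and `oxygen_concentration`; other schema columns optional.
#' @param source character scalar provenance label.
#' @return A [MeasurementTable-class].
#' @examples
#' tab <- measurementTable(data.frame(
#'   longitude = 92.1, latitude = 31.5, elevation = 4500,
#'   oxygen_concentration = 20.1))
#' nRecords(tab)
#' @export
measurementTable <- function(records, source = "synthetic") {
  stopifnot(is.data.frame(records))
  missing_mand <- setdiff(.MANDATORY_COLUMNS, names(records))
  if (length(missing_mand))
    stop("missing mandatory column(s): ",
         paste(missing_mand, collapse = ", "), call. = FALSE)
  n <- nrow(records)
  for (col in .MEASUREMENT_COLUMNS) {
    if (!col %in% names(records)) {
      records[[col]] <- if (col == "timestamp") as.POSIXct(rep(NA, n))
                        else if (col %in% c("tid", "fid", "geomorph_type",
                                            "vegetation_type",
                                            "instrument_group"))
                          rep(NA_character_, n)
                        else rep(NA_real_, n)
    }
  }
  if (n && all(is.na(records$tid)))
    records$tid <- sprintf("R-%04d", seq_len(n))
  records$instrument_group <- .infer_instrument_group(
    records$instrument_group, records$timestamp)
  records <- records[, .MEASUREMENT_COLUMNS]
  rownames(records) <- NULL
  .warn_off_plateau(records)
  new("MeasurementTable", records = records, source = source)
}

# Instrument-group inference from the measurement year (see constructor
# docs); an explicit group always wins.
.infer_instrument_group <- function(group, timestamp) {
  group <- as.character(group)
  needs <- is.na(group) & !is.na(timestamp)
  if (any(needs)) {
    yr <- as.integer(format(timestamp[needs], "%Y"))
    group[needs] <- ifelse(yr <= 2017, "A",
                    ifelse(yr <= 2020, "B",
                    ifelse(yr == 2021, "C", "D")))
  }
  group
}

.warn_off_plateau <- function(records) {
  lon <- records$longitude; lat <- records$latitude
  off <- (!is.na(lon) & (lon < .PLATEAU_EXTENT[1] | lon > .PLATEAU_EXTENT[2])) |
         (!is.na(lat) & (lat < .PLATEAU_EXTENT[3] | lat > .PLATEAU_EXTENT[4]))
  if (any(off))
    warning(sum(off), " record(s) fall outside the plateau extent (",
            paste(.PLATEAU_EXTENT, collapse = ", "), ")", call. = FALSE)
  invisible(NULL)
}

#' Construct contribution weights
#'
#' Defaults are the relative contributions of elevation, temperature and
#' LAI to oxygen concentration: -0.3958, 0.3550, 0.2492 (absolute values
#' sum to 1).
#'
#' @param w_elevation,w_temperature,w_lai numeric scalars; elevation must
#'   be negative, the other two positive.
#' @return A [ContributionWeights-class].
#' @examples
#' contributionWeights()
#' @export
contributionWeights <- function(w_elevation = -0.3958,
                                w_temperature = 0.3550,
                                w_lai = 0.2492) {
  new("ContributionWeights", w_elevation = w_elevation,
      w_temperature = w_temperature, w_lai = w_lai)
}

#' Construct normalization bounds
#'
#' @param elevation,temperature,lai numeric length-2 `(min, max)` in native
#'   units (m, degC, dimensionless).
#' @return A [NormalizationBounds-class].
#' @examples
#' normalizationBounds(c(2000, 5500), c(-10, 25), c(0, 4))
#' @export
normalizationBounds <- function(elevation, temperature, lai) {
  new("NormalizationBounds", elevation = as.numeric(elevation),
      temperature = as.numeric(temperature), lai = as.numeric(lai))
}

#' Construct a linear oxygen-concentration model
#'
#' Defaults are the published plateau-wide model `OC = 1.0283 * Tmp +
#' 20.2509` (%, per unit composite index).
#'
#' @param slope,intercept numeric scalars.
#' @param r_squared optional scalar in `[0, 1]`.
#' @return A [LinearModel-class].
#' @examples
#' linearModel()
#' @export
linearModel <- function(slope = 1.0283, intercept = 20.2509,
                        r_squared = numeric()) {
  new("LinearModel", slope = slope, intercept = intercept,
      r_squared = as.numeric(r_squared))
}

#' Construct a RasterGrid
#'
#' @param values numeric matrix, row 1 northernmost; `NA` marks nodata.
#' @param extent numeric `(xmin, xmax, ymin, ymax)`.
#' @param crs coordinate reference text; defaults to geographic WGS-84.
#' @param nodata sentinel written to disk for `NA` cells.
#' @return A [RasterGrid-class].
#' @examples
#' g <- rasterGrid(matrix(1:12, 3, 4), extent = c(0, 4, 0, 3))
#' res(g)
#' @export
rasterGrid <- function(values, extent, crs = .WGS84, nodata = -9999) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  new("RasterGrid", values = values, extent = as.numeric(extent),
      crs = crs, nodata = nodata)
}

#' Construct a co-registered RasterStack
#'
#' @param elevation,temperature,lai [RasterGrid-class] layers sharing
#'   shape, extent and CRS.
#' @return A [RasterStack-class].
#' @export
rasterStack <- function(elevation, temperature, lai) {
  new("RasterStack", elevation = elevation, temperature = temperature,
      lai = lai)
}

## ---------------------------------------------------------------------------
## Accessors and show methods
## ---------------------------------------------------------------------------

#' @describeIn measurementTable Records of a table as a data.frame.
#' @param x,object a `MeasurementTable`.
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' @rdname measurementTable
#' @export
setMethod("records", "MeasurementTable", function(x) x@records)

#' @describeIn measurementTable Number of records.
#' @export
setGeneric("nRecords", function(x) standardGeneric("nRecords"))

#' @rdname measurementTable
#' @export
setMethod("nRecords", "MeasurementTable", function(x) nrow(x@records))

#' @rdname measurementTable
#' @export
setMethod("show", "MeasurementTable", function(object) {
  cat("MeasurementTable with", nrow(object@records), "record(s)\n")
  cat("  source:", object@source, "\n")
  grp <- table(object@records$instrument_group, useNA = "ifany")
  if (length(grp))
    cat("  instrument groups:",
        paste(sprintf("%s=%d", names(grp), grp), collapse = ", "), "\n")
  invisible(NULL)
})

#' @describeIn rasterGrid Grid values (matrix, `NA` = nodata).
#' @param x,object a `RasterGrid`.
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))

#' @rdname rasterGrid
#' @export
setMethod("gridValues", "RasterGrid", function(x) x@values)

#' @describeIn rasterGrid Extent `(xmin, xmax, ymin, ymax)`.
#' @export
setGeneric("extent", function(x) standardGeneric("extent"))

#' @rdname rasterGrid
#' @export
setMethod("extent", "RasterGrid", function(x) x@extent)

#' @describeIn rasterGrid Pixel size `(xres, yres)` in CRS units.
#' @export
setGeneric("res", function(x) standardGeneric("res"))

#' @rdname rasterGrid
#' @export
setMethod("res", "RasterGrid", function(x) {
  e <- x@extent; d <- dim(x@values)
  c((e[2] - e[1]) / d[2], (e[4] - e[3]) / d[1])
})

#' @describeIn rasterGrid Coordinate reference text.
#' @export
setGeneric("crs", function(x) standardGeneric("crs"))

#' @rdname rasterGrid
#' @export
setMethod("crs", "RasterGrid", function(x) x@crs)

#' @rdname rasterGrid
#' @export
setMethod("show", "RasterGrid", function(object) {
  d <- dim(object@values); e <- object@extent
  cat(sprintf("RasterGrid %d x %d (rows x cols)\n", d[1], d[2]))
  cat(sprintf("  extent : %g, %g, %g, %g (xmin, xmax, ymin, ymax)\n",
              e[1], e[2], e[3], e[4]))
  cat(sprintf("  res    : %g, %g\n", res(object)[1], res(object)[2]))
  cat(sprintf("  nodata : %g (%d cell(s) NA)\n", object@nodata,
              sum(is.na(object@values))))
  rng <- suppressWarnings(range(object@values, na.rm = TRUE))
  if (all(is.finite(rng)))
    cat(sprintf("  values : %g .. %g\n", rng[1], rng[2]))
  invisible(NULL)
})

#' @rdname rasterStack
#' @param object a `RasterStack`.
#' @export
setMethod("show", "RasterStack", function(object) {
  d <- dim(object@elevation@values)
  cat(sprintf("RasterStack (elevation, temperature, lai), %d x %d\n",
              d[1], d[2]))
  invisible(NULL)
})

#' @rdname contributionWeights
#' @param object a `ContributionWeights`.
#' @export
setMethod("show", "ContributionWeights", function(object) {
  cat(sprintf(
    "ContributionWeights: elevation %+.4f, temperature %+.4f, LAI %+.4f\n",
    object@w_elevation, object@w_temperature, object@w_lai))
  invisible(NULL)
})

#' @rdname linearModel
#' @param object a `LinearModel`.
#' @export
setMethod("show", "LinearModel", function(object) {
  cat(sprintf("LinearModel: OC = %.6g * Tmp + %.6g", object@slope,
              object@intercept))
  if (length(object@r_squared))
    cat(sprintf("  (R^2 = %.3f)", object@r_squared))
  cat("\n")
  invisible(NULL)
})

#' @rdname fitPairwiseCalibration
#' @param object a `CalibrationFit`.
#' @export
setMethod("show", "CalibrationFit", function(object) {
  cat(sprintf(
    "CalibrationFit %s -> %s: target = %.6g * source %+.6g  (R^2 = %.4f, n = %d)\n",
    object@source_group, object@target_group, object@slope,
    object@intercept, object@r_squared, object@n))
  invisible(NULL)
})

#' Coefficients and summaries of fitted objects
#'
#' @param object a [LinearModel-class] or [CalibrationFit-class].
#' @param ... ignored.
#' @return Named numeric vector `(intercept, slope)`.
#' @export
setMethod("coef", "LinearModel", function(object, ...)
  c(intercept = object@intercept, slope = object@slope))

#' @rdname coef-LinearModel-method
#' @export
setMethod("coef", "CalibrationFit", function(object, ...)
  c(intercept = object@intercept, slope = object@slope))
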