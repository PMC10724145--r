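# Seeded synthetic-data generators. They emulate the statistical
# structure the estimation pipeline assumes — a plateau-like negative
# elevation-temperature coupling (standard lapse rate), vegetation
# decreasing with elevation and increasing eastward, and oxygen
# concentration linear in the composite index plus Gaussian noise at the
# scale of the field campaign's held-out RMSE (0.0952%). They make no
# attempt to reproduce the true geography of the plateau.

.with_seed <- function(seed, expr) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  force(expr)
}

#' Synthetic-data configuration
#'
#' Collects the knobs of the synthetic generators. Defaults describe the
#' study conditions: 422 field points, elevations 2000-5500 m, a
#' -6 degC/km lapse rate from a 25 degC sea-level baseline, the published
#' contribution weights and oxygen model as generating truth, and
#' observation noise with sd 0.0952% (the held-out RMSE scale of the
#' full-size campaign).
#'
#' @param n_points number of field points (>= 4).
#' @param elevation_range meters, `(min, max)`.
#' @param sea_level_temp degC at sea level.
#' @param lapse_rate degC per km of elevation (negative).
#' @param temp_sd degC, scatter of temperature around the lapse line.
#' @param lai_max dimensionless, LAI of low warm eastern terrain.
#' @param noise_sd percent, observation noise on oxygen concentration.
#' @param weights generating [ContributionWeights-class].
#' @param model generating [LinearModel-class].
#' @param raster_shape `(rows, cols)` of generated grids, each >= 2.
#' @param extent geographic bounding box `(xmin, xmax, ymin, ymax)`,
#'   default the plateau extent 73.50-104.67 degE, 26.05-39.91 degN.
#' @param nodata_margin cells of nodata border on generated grids.
#' @return A list of class `"syntheticConfig"`.
#' @export
syntheticConfig <- function(n_points = 422L,
                            elevation_range = c(2000, 5500),
                            sea_level_temp = 25, lapse_rate = -6,
                            temp_sd = 1.5, lai_max = 4,
                            noise_sd = 0.0952,
                            weights = contributionWeights(),
                            model = linearModel(),
                            raster_shape = c(40L, 60L),
                            extent = .PLATEAU_EXTENT,
                            nodata_margin = 2L) {
  stopifnot(n_points >= 4L, noise_sd >= 0, all(raster_shape >= 2L),
            elevation_range[2] > elevation_range[1],
            is(weights, "ContributionWeights"), is(model, "LinearModel"))
  structure(list(n_points = as.integer(n_points),
                 elevation_range = elevation_range,
                 sea_level_temp = sea_level_temp, lapse_rate = lapse_rate,
                 temp_sd = temp_sd, lai_max = lai_max, noise_sd = noise_sd,
                 weights = weights, model = model,
                 raster_shape = as.integer(raster_shape), extent = extent,
                 nodata_margin = as.integer(nodata_margin)),
            class = "syntheticConfig")
}

# LAI surface shared by the point and raster generators: decreases with
# elevation, increases eastward, never negative.
.lai_surface <- function(elev, lon, cfg, scale = 1) {
  er <- range(c(cfg$elevation_range, 500, 6500))
  relief <- 1 - pmin(pmax((elev - er[1]) / (er[2] - er[1]), 0), 1)
  east <- (lon - cfg$extent[1]) / (cfg$extent[2] - cfg$extent[1])
  pmax(scale * cfg$lai_max * relief * (0.3 + 0.7 * east), 0)
}

#' Generate a synthetic field-measurement table
#'
#' Samples point positions and elevations, derives temperature from the
#' lapse-rate model and LAI from an elevation/longitude surface, and sets
#' oxygen concentration to `slope * Tmp + intercept + N(0, noise_sd)`
#' where `Tmp` is the composite index of the Min-Max-normalized
#' predictors (bounds = observed ranges of the generated sample).
#'
#' @param cfg a [syntheticConfig()].
#' @param seed integer seed (mandatory; identical seeds give identical
#'   tables).
#' @return List with `table` (a [MeasurementTable-class]), `lai`
#'   (per-record LAI), and `truth` (generating weights, model, bounds,
#'   composite index and noise sd).
#' @examples
#' pts <- generatePoints(syntheticConfig(n_points = 50), seed = 1)
#' nRecords(pts$table)
#' @export
generatePoints <- function(cfg = syntheticConfig(), seed) {
  stopifnot(inherits(cfg, "syntheticConfig"))
  .with_seed(seed, {
    n <- cfg$n_points
    e <- cfg$extent
    lon <- stats::runif(n, e[1], e[2])
    lat <- stats::runif(n, e[3], e[4])
    elev <- stats::runif(n, cfg$elevation_range[1], cfg$elevation_range[2])
    temp <- cfg$sea_level_temp + cfg$lapse_rate * elev / 1000 +
      stats::rnorm(n, sd = cfg$temp_sd)
    lai <- .lai_surface(elev, lon, cfg) *
      stats::runif(n, 0.85, 1.15)
    bounds <- normalizationBounds(range(elev), range(temp), range(lai))
    tmp <- compositeIndex(minmaxNormalize(elev, bounds, "elevation"),
                          minmaxNormalize(temp, bounds, "temperature"),
                          minmaxNormalize(lai, bounds, "lai"),
                          cfg$weights)
    oc <- predictOxygen(tmp, cfg$model) + stats::rnorm(n, sd = cfg$noise_sd)
    stamp <- as.POSIXct("2019-08-01 08:00:00", tz = "UTC") +
      (seq_len(n) - 1L) * 600
    rec <- data.frame(tid = sprintf("SYN-%04d", seq_len(n)),
                      fid = sprintf("PT-%04d", seq_len(n)),
                      timestamp = stamp, longitude = lon, latitude = lat,
                      elevation = elev, temperature = temp,
                      relative_humidity = stats::runif(n, 20, 80),
                      pressure = 1013.25 * exp(-elev / 8434),
                      oxygen_concentration = oc,
                      instrument_group = "B")
    list(table = measurementTable(rec, source = "synthetic"), lai = lai,
         truth = list(weights = cfg$weights, model = cfg$model,
                      bounds = bounds, tmp = tmp,
                      noise_sd = cfg$noise_sd))
  })
}

# Seasonal baselines for the raster generator; July is warmer and leafier
# than January everywhere by construction.
.SEASON_PARAMS <- list(annual  = list(t0 = 19, lai_scale = 0.55),
                       january = list(t0 = 10, lai_scale = 0.25),
                       july    = list(t0 = 28, lai_scale = 1.00))

#' Generate a co-registered synthetic raster stack
#'
#' Builds stylized plateau-like elevation (a central massif rising
#' westward, plus smooth seeded relief), temperature from the lapse-rate
#' model with a seasonal sea-level baseline, and an LAI surface that
#' decreases with elevation, increases eastward and scales with season.
#' The monthly layers are deterministic functions of the (seeded)
#' elevation surface, so for a fixed seed the July stack is cell-wise
#' warmer and leafier than January. The outer `nodata_margin` cells are
#' nodata in all three layers.
#'
#' @param cfg a [syntheticConfig()].
#' @param month `"annual"`, `"january"` or `"july"`.
#' @param seed integer seed.
#' @return A [RasterStack-class] on the configured extent.
#' @export
generateRasters <- function(cfg = syntheticConfig(),
                            month = c("annual", "january", "july"), seed) {
  stopifnot(inherits(cfg, "syntheticConfig"))
  month <- match.arg(month)
  par <- .SEASON_PARAMS[[month]]
  .with_seed(seed, {
    nr <- cfg$raster_shape[1]; nc <- cfg$raster_shape[2]
    e <- cfg$extent
    xres <- (e[2] - e[1]) / nc
    yres <- (e[4] - e[3]) / nr
    lon <- matrix(e[1] + (seq_len(nc) - 0.5) * xres, nr, nc, byrow = TRUE)
    lat <- matrix(e[4] - (seq_len(nr) - 0.5) * yres, nr, nc)
    u <- (lon - e[1]) / (e[2] - e[1])          # 0 west .. 1 east
    v <- (lat - e[3]) / (e[4] - e[3])          # 0 south .. 1 north
    massif <- exp(-((v - 0.5) / 0.35)^2)       # central east-west belt
    relief <- matrix(stats::rnorm(nr * nc, sd = 120), nr, nc)
    elev <- 1500 + 3500 * massif * (1 - 0.45 * u) + 600 * (1 - u) + relief
    elev <- pmin(pmax(elev, 500), 8800)
    temp <- par$t0 + cfg$lapse_rate * elev / 1000
    lai <- .lai_surface(elev, lon, cfg, scale = par$lai_scale)
    m <- cfg$nodata_margin
    if (m > 0L) {
      mask <- matrix(FALSE, nr, nc)
      mask[c(seq_len(m), nr - seq_len(m) + 1L), ] <- TRUE
      mask[, c(seq_len(m), nc - seq_len(m) + 1L)] <- TRUE
      elev[mask] <- NA; temp[mask] <- NA; lai[mask] <- NA
    }
    g <- function(x) rasterGrid(x, extent = e)
    rasterStack(g(elev), g(temp), g(lai))
  })
}

#' Generate synthetic instrument-calibration sessions
#'
#' Draws a latent true oxygen concentration per session and produces each
#' group's reading as `slope * truth + intercept + N(0, noise)`, with
#' group B the identity by default. The defaults emulate the field
#' cross-calibration campaign: the three same-model meter groups (B, C,
#' D) agree almost perfectly, while the older electrochemical group A
#' shows a looser linear relationship.
#'
#' @param n_sessions number of simultaneous-measurement points (>= 3).
#' @param group_offsets named list `group -> c(slope, intercept)`.
#' @param noise_sd named per-group reading noise (%), or a single scalar.
#' @param truth_range latent concentration range (%) sessions are drawn
#'   from.
#' @param seed integer seed.
#' @return Long data.frame with columns `point_id`, `group`,
#'   `oxygen_concentration`, plus a `"truth"` attribute carrying the
#'   latent values and offsets; feed to [calibrationSessions()].
#' @export
generateCalibrationSessions <- function(n_sessions = 25L,
                                        group_offsets = list(
                                          A = c(0.94, 1.1), B = c(1, 0),
                                          C = c(1.002, -0.03),
                                          D = c(0.998, 0.05)),
                                        noise_sd = c(A = 0.08, B = 0.005,
                                                     C = 0.005, D = 0.005),
                                        truth_range = c(19.5, 21.0),
                                        seed) {
  stopifnot(n_sessions >= 3L)
  groups <- names(group_offsets)
  if (length(noise_sd) == 1L && is.null(names(noise_sd)))
    noise_sd <- structure(rep(noise_sd, length(groups)), names = groups)
  .with_seed(seed, {
    truth <- stats::runif(n_sessions, truth_range[1], truth_range[2])
    out <- do.call(rbind, lapply(groups, function(g) {
      off <- group_offsets[[g]]
      data.frame(point_id = sprintf("CAL-%03d", seq_len(n_sessions)),
                 group = g,
                 oxygen_concentration = off[1] * truth + off[2] +
                   stats::rnorm(n_sessions, sd = noise_sd[[g]]))
    }))
    rownames(out) <- NULL
    attr(out, "truth") <- list(latent = truth, offsets = group_offsets)
    out
  })
}
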