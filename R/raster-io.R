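# Native raster format: ESRI ASCII grid (.asc), a plain-text
# georeferenced single-band raster — header (ncols/nrows/corner/cell
# size/NODATA_value) followed by rows north to south. Non-square pixels
# use the dx/dy header variant. The CRS travels in a sidecar .prj file
# holding the coordinate-reference text, the usual ESRI convention.

.prj_path <- function(path) sub("\\.[^.]*$", "", path) |> paste0(".prj")

#' Read a georeferenced raster from an ASCII grid
#'
#' Reads a single-band ESRI ASCII grid (`cellsize` or `dx`/`dy` header
#' variants). Nodata cells become `NA`; a sidecar `.prj` file, when
#' present, supplies the coordinate reference text (otherwise geographic
#' WGS-84 is assumed).
#'
#' @param path `.asc` file to read.
#' @return A [RasterGrid-class].
#' @seealso [writeRaster()]
#' @export
readRaster <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, n = 8L, warn = FALSE)
  header <- list()
  n_header <- 0L
  for (ln in lines) {
    tok <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    if (length(tok) == 2L &&
        tolower(tok[1]) %in% c("ncols", "nrows", "xllcorner", "yllcorner",
                               "xllcenter", "yllcenter", "cellsize", "dx",
                               "dy", "nodata_value")) {
      header[[tolower(tok[1])]] <- as.numeric(tok[2])
      n_header <- n_header + 1L
    } else break
  }
  req <- c("ncols", "nrows")
  if (!all(req %in% names(header)))
    stop("unsupported format: '", path,
         "' is not a single-band ASCII grid (ncols/nrows header missing)",
         call. = FALSE)
  if (!"cellsize" %in% names(header) &&
      !all(c("dx", "dy") %in% names(header)))
    stop("missing georeference: no cellsize (or dx/dy) in '", path, "'",
         call. = FALSE)
  if (!any(c("xllcorner", "xllcenter") %in% names(header)) ||
      !any(c("yllcorner", "yllcenter") %in% names(header)))
    stop("missing georeference: no corner coordinates in '", path, "'",
         call. = FALSE)
  nc <- as.integer(header$ncols); nr <- as.integer(header$nrows)
  dx <- if (!is.null(header$cellsize)) header$cellsize else header$dx
  dy <- if (!is.null(header$cellsize)) header$cellsize else header$dy
  xmin <- if (!is.null(header$xllcorner)) header$xllcorner
          else header$xllcenter - dx / 2
  ymin <- if (!is.null(header$yllcorner)) header$yllcorner
          else header$yllcenter - dy / 2
  nodata <- if (!is.null(header$nodata_value)) header$nodata_value else -9999
  vals <- scan(path, what = double(), skip = n_header, quiet = TRUE)
  if (length(vals) != nr * nc)
    stop("corrupt grid: expected ", nr * nc, " values, found ",
         length(vals), call. = FALSE)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  prj <- .prj_path(path)
  crs <- if (file.exists(prj))
    paste(readLines(prj, warn = FALSE), collapse = "") else .WGS84
  rasterGrid(m, extent = c(xmin, xmin + nc * dx, ymin, ymin + nr * dy),
             crs = crs, nodata = nodata)
}

#' Write a raster to an ASCII grid
#'
#' Writes the grid with 17-significant-digit values so that
#' `readRaster(writeRaster(g, f))` reproduces values, extent, CRS and
#' nodata exactly. `NA` cells are written as the grid's nodata sentinel;
#' the CRS goes to a sidecar `.prj` file.
#'
#' @param grid a [RasterGrid-class].
#' @param path destination `.asc` file.
#' @return `path`, invisibly.
#' @export
writeRaster <- function(grid, path) {
  stopifnot(is(grid, "RasterGrid"))
  v <- grid@values
  d <- dim(v); e <- grid@extent
  dx <- (e[2] - e[1]) / d[2]
  dy <- (e[4] - e[3]) / d[1]
  header <- c(sprintf("ncols %d", d[2]),
              sprintf("nrows %d", d[1]),
              sprintf("xllcorner %.17g", e[1]),
              sprintf("yllcorner %.17g", e[3]),
              if (isTRUE(all.equal(dx, dy)))
                sprintf("cellsize %.17g", dx)
              else c(sprintf("dx %.17g", dx), sprintf("dy %.17g", dy)),
              sprintf("NODATA_value %.17g", grid@nodata))
  v[is.na(v)] <- grid@nodata
  body <- apply(v, 1L, function(row)
    paste(sprintf("%.17g", row), collapse = " "))
  ok <- try(writeLines(c(header, body), path), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("cannot write raster to ", path, call. = FALSE)
  writeLines(grid@crs, .prj_path(path))
  invisible(path)
}

#' Crop a raster to a cell window
#'
#' Extracts the sub-grid covering the given row and column ranges
#' (1-based, row 1 is the northernmost) and shrinks the extent to match,
#' so cell centres are preserved exactly.
#'
#' @param x a [RasterGrid-class] or [RasterStack-class].
#' @param rows,cols integer ranges of rows/columns to keep.
#' @return The cropped object, same class as `x`.
#' @export
cropRaster <- function(x, rows, cols) {
  if (is(x, "RasterStack"))
    return(rasterStack(cropRaster(x@elevation, rows, cols),
                       cropRaster(x@temperature, rows, cols),
                       cropRaster(x@lai, rows, cols)))
  stopifnot(is(x, "RasterGrid"))
  d <- dim(x@values)
  rows <- sort(unique(as.integer(rows)))
  cols <- sort(unique(as.integer(cols)))
  stopifnot(all(rows >= 1L & rows <= d[1]), all(cols >= 1L & cols <= d[2]),
            identical(rows, rows[1]:rows[length(rows)]),
            identical(cols, cols[1]:cols[length(cols)]))
  r <- res(x); e <- x@extent
  rasterGrid(x@values[rows, cols, drop = FALSE],
             extent = c(e[1] + (cols[1] - 1L) * r[1],
                        e[1] + cols[length(cols)] * r[1],
                        e[4] - rows[length(rows)] * r[2],
                        e[4] - (rows[1] - 1L) * r[2]),
             crs = x@crs, nodata = x@nodata)
}
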