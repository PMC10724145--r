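# Header aliases: published spreadsheet headers (units stripped,
# case-insensitive) -> canonical column names.
.HEADER_ALIASES <- c(
  tid = "tid", fid = "fid", time = "timestamp", timestamp = "timestamp",
  longitude = "longitude", latitude = "latitude", elevation = "elevation",
  temperature = "temperature", relativehumidity = "relative_humidity",
  atmosphericpressure = "pressure", pressure = "pressure",
  oxygenconcentration = "oxygen_concentration", fvc = "fvc",
  geomorphologictype = "geomorph_type", geomorphtype = "geomorph_type",
  vegetationtype = "vegetation_type", instrumentgroup = "instrument_group"
)

.NUMERIC_COLUMNS <- c("longitude", "latitude", "elevation", "temperature",
                      "relative_humidity", "pressure",
                      "oxygen_concentration", "fvc")

.normalize_header <- function(h) {
  h <- sub("\\(.*$", "", h)              # strip unit suffixes like "(m)"
  gsub("[^a-z]", "", tolower(h))
}

# Timestamps are timezone-naive local times; parsed in UTC so arithmetic
# and formatting are DST-free. Accepts the field dialect "YYYY/M/D H:MM"
# and ISO-8601 variants.
.parse_timestamp <- function(x) {
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01",
                    tz = "UTC")
  todo <- !is.na(x) & nzchar(trimws(x)) & trimws(x) != "/"
  fmts <- c("%Y/%m/%d %H:%M:%S", "%Y/%m/%d %H:%M", "%Y/%m/%d",
            "%Y-%m-%d %H:%M:%S", "%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M",
            "%Y-%m-%d")
  for (fmt in fmts) {
    if (!any(todo)) break
    parsed <- as.POSIXct(trimws(x[todo]), format = fmt, tz = "UTC")
    hit <- !is.na(parsed)
    out[which(todo)[hit]] <- parsed[hit]
    todo[todo] <- !hit
  }
  if (any(todo))
    stop("unparseable timestamp(s) at row(s): ",
         paste(which(todo), collapse = ", "), call. = FALSE)
  out
}

# Strict numeric parsing: "/" and "" are absent; anything else must be a
# plain decimal (no thousands separators, "." decimal point only).
.parse_numeric <- function(x, column) {
  x <- trimws(x)
  absent <- is.na(x) | x == "" | x == "/"
  ok <- grepl("^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$", x)
  bad <- which(!absent & !ok)
  if (length(bad))
    stop(sprintf("unparseable numeric value in column '%s' at row(s): %s",
                 column, paste(bad, collapse = ", ")), call. = FALSE)
  out <- rep(NA_real_, length(x))
  out[!absent] <- as.numeric(x[!absent])
  out
}

.parse_character <- function(x) {
  x <- trimws(as.character(x))
  x[is.na(x) | x == "" | x == "/"] <- NA_character_
  x
}

#' Read a measurement table from CSV or spreadsheet
#'
#' Parses a point-measurement file in the 13-column field schema (plus an
#' optional instrument-group column). Headers are matched
#' case-insensitively with unit suffixes ignored, so both the published
#' spreadsheet headers (`"Oxygen concentration (%)"`) and snake_case names
#' are accepted. The cells `"/"` and `""` mark absent optional values.
#'
#' @param path file to read.
#' @param dialect `"csv"` (comma-separated UTF-8) or `"xlsx"` (requires the
#'   readxl package). Guessed from the file extension by default.
#' @return A [MeasurementTable-class]. Mandatory columns are `longitude`,
#'   `latitude`, `elevation`, `oxygen_concentration`; a missing one is a
#'   schema error naming the column. Unparseable numeric cells raise a
#'   row-indexed error.
#' @examples
#' f <- system.file("extdata", "table3_qinghai_lake.csv", package = "oxymap")
#' tab <- readMeasurements(f)
#' nRecords(tab)
#' @seealso [writeMeasurements()]
#' @export
readMeasurements <- function(path, dialect = c("auto", "csv", "xlsx")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) "xlsx"
               else "csv"
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- switch(dialect,
    csv = utils::read.csv(path, colClasses = "character",
                          check.names = FALSE, fileEncoding = "UTF-8"),
    xlsx = {
      if (!requireNamespace("readxl", quietly = TRUE))
        stop("reading xlsx requires the 'readxl' package", call. = FALSE)
      as.data.frame(readxl::read_excel(path), check.names = FALSE)
    })
  canon <- .HEADER_ALIASES[.normalize_header(names(raw))]
  keep <- !is.na(canon)
  raw <- raw[, keep, drop = FALSE]
  names(raw) <- canon[keep]
  missing_mand <- setdiff(.MANDATORY_COLUMNS, names(raw))
  if (length(missing_mand))
    stop("schema error: missing mandatory column(s): ",
         paste(missing_mand, collapse = ", "), call. = FALSE)

  n <- nrow(raw)
  rec <- data.frame(row.names = seq_len(max(n, 0L)))
  for (col in .MEASUREMENT_COLUMNS) {
    x <- if (col %in% names(raw)) raw[[col]] else rep(NA_character_, n)
    rec[[col]] <- if (col == "timestamp") {
      if (inherits(x, "POSIXct")) as.POSIXct(format(x), tz = "UTC")
      else .parse_timestamp(as.character(x))
    } else if (col %in% .NUMERIC_COLUMNS) {
      if (is.numeric(x)) as.numeric(x) else .parse_numeric(x, col)
    } else {
      .parse_character(x)
    }
  }
  measurementTable(rec, source = path)
}

#' Write a measurement table to CSV
#'
#' Writes the canonical 14 columns (schema plus `instrument_group`) as
#' comma-separated UTF-8. Absent values are written as `"/"`; numeric
#' fields are written with 17 significant digits so that
#' `readMeasurements(writeMeasurements(tab))` reproduces every field
#' exactly.
#'
#' @param table a [MeasurementTable-class].
#' @param path destination file.
#' @return `path`, invisibly.
#' @seealso [readMeasurements()]
#' @export
writeMeasurements <- function(table, path) {
  stopifnot(is(table, "MeasurementTable"))
  if (grepl("\\.xlsx?$", path, ignore.case = TRUE))
    stop("writing xlsx is not supported; write csv instead", call. = FALSE)
  rec <- table@records
  out <- rec
  for (col in names(out)) {
    x <- rec[[col]]
    out[[col]] <- if (inherits(x, "POSIXct"))
      ifelse(is.na(x), "/", format(x, "%Y-%m-%d %H:%M:%S", tz = "UTC"))
    else if (is.numeric(x)) ifelse(is.na(x), "/", sprintf("%.17g", x))
    else ifelse(is.na(x), "/", as.character(x))
  }
  ok <- try(utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                             fileEncoding = "UTF-8"), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("cannot write measurements to ", path, call. = FALSE)
  invisible(path)
}
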