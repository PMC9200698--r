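#' Write a DEM as an Esri ASCII grid
#'
#' Plain-text `.asc` raster with the grid's lower-left origin and cell size;
#' a format every GIS reads and that keeps the repository text-only.
#'
#' @param dem a [dem_grid()].
#' @param path output file.
#' @export
write_dem_asc <- function(dem, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(dem$z)),
    sprintf("nrows %d", nrow(dem$z)),
    sprintf("xllcorner %.6f", dem$xll),
    sprintf("yllcorner %.6f", dem$yll),
    sprintf("cellsize %.6f", dem$cellsize),
    "NODATA_value -9999"), con)
  utils::write.table(format(dem$z, trim = TRUE, digits = 10), con,
                     row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read an Esri ASCII grid DEM
#' @param path `.asc` file.
#' @return A [dem_grid()].
#' @export
read_dem_asc <- function(path) {
  hdr <- readLines(path, n = 6)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  get <- function(k) as.numeric(kv[tolower(kv[, 1]) == tolower(k), 2])
  z <- as.matrix(utils::read.table(path, skip = 6))
  dimnames(z) <- NULL
  stopifnot(nrow(z) == get("nrows"), ncol(z) == get("ncols"))
  dem_grid(z, get("cellsize"), get("xllcorner"), get("yllcorner"))
}

#' Write point/line/polygon layers as GeoJSON
#'
#' Coordinates are in the catchment's planar metric frame (metres); the CRS
#' is recorded as a `crs` member naming a planar engineering frame.
#'
#' @param features list of features; each a list with `geometry` (matrix of
#'   coordinates), `type` (`"Point"`, `"LineString"` or `"Polygon"`) and
#'   `properties` (named list).
#' @param path output file.
#' @export
write_geojson <- function(features, path) {
  fjson <- lapply(features, function(f) {
    coords <- switch(f$type,
      Point = as.numeric(f$geometry[1, ]),
      LineString = unname(apply(f$geometry, 1, as.numeric,
                                simplify = FALSE)),
      Polygon = list(unname(apply(close_ring(f$geometry), 1, as.numeric,
                                  simplify = FALSE))),
      stop("unsupported geometry type: ", f$type))
    list(type = "Feature",
         geometry = list(type = f$type, coordinates = coords),
         properties = f$properties)
  })
  obj <- list(type = "FeatureCollection",
              crs = list(type = "name",
                         properties = list(name = "urn:local:planar-metric")),
              features = fjson)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  invisible(path)
}

#' Read a GeoJSON layer written by [write_geojson()]
#' @param path GeoJSON file.
#' @return List of features (geometry matrix, type, properties).
#' @export
read_geojson <- function(path) {
  obj <- jsonlite::read_json(path)
  lapply(obj$features, function(f) {
    g <- f$geometry
    coords <- switch(g$type,
      Point = matrix(unlist(g$coordinates), nrow = 1),
      LineString = do.call(rbind, lapply(g$coordinates, unlist)),
      Polygon = do.call(rbind, lapply(g$coordinates[[1]], unlist)),
      stop("unsupported geometry type: ", g$type))
    list(geometry = coords, type = g$type, properties = f$properties)
  })
}

#' Write a time series as CSV with ISO-8601 UTC timestamps
#' @param x data frame whose `time` column is `POSIXct`.
#' @param path output file.
#' @export
write_timeseries_csv <- function(x, path) {
  x$time <- format(x$time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a time-series CSV with ISO-8601 timestamps
#' @param path CSV file with a `time` column.
#' @return Data frame with `time` parsed as `POSIXct` (UTC).
#' @export
read_timeseries_csv <- function(path) {
  x <- utils::read.csv(path)
  x$time <- as.POSIXct(x$time, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  x
}

#' Export a synthetic catchment to disk
#'
#' Writes the DEM (`dem.asc`), plots/roads/inlets (GeoJSON) and stream cells
#' (CSV) into a directory.
#'
#' @param catchment a [generate_catchment()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_catchment <- function(catchment, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_dem_asc(catchment$dem, file.path(dir, "dem.asc"))
  write_geojson(lapply(names(catchment$plots), function(id) list(
    geometry = catchment$plots[[id]], type = "Polygon",
    properties = as.list(
      catchment$plots_df[catchment$plots_df$plot_id == id, ]))),
    file.path(dir, "plots.geojson"))
  write_geojson(lapply(seq_len(nrow(catchment$roads)), function(i) {
    r <- catchment$roads[i, ]
    list(geometry = cbind(c(r$x0, r$x1), c(r$y0, r$y1)),
         type = "LineString",
         properties = list(road_id = r$road_id, surface = r$surface))
  }), file.path(dir, "roads.geojson"))
  write_geojson(lapply(seq_len(nrow(catchment$inlets)), function(i) {
    s <- catchment$inlets[i, ]
    list(geometry = cbind(s$x, s$y), type = "Point",
         properties = list(site = s$site, threshold_m = s$threshold_m,
                           activation_mm = s$activation_mm,
                           via_cs = s$via_cs))
  }), file.path(dir, "inlets.geojson"))
  utils::write.csv(as.data.frame(catchment$stream_cells),
                   file.path(dir, "stream_cells.csv"), row.names = FALSE)
  invisible(dir)
}

#' Validate and read a directory of catchment layers
#'
#' Reads the layers written by [write_catchment()] plus optional tabular
#' observation files, collecting all schema violations before failing, so a
#' broken dataset is reported exhaustively rather than one error at a time.
#'
#' @param dir directory with `dem.asc`, `plots.geojson`, `roads.geojson`,
#'   `inlets.geojson`, `stream_cells.csv`, and optionally `rainfall.csv`
#'   (columns `time`, `depth_mm`) and `concentrations.csv` (columns `site`,
#'   `event`, `substance`, `value`, `loq`, `censored`).
#' @param substances substance table used to cross-validate concentration
#'   records.
#' @return List of parsed layers.
#' @export
read_layers <- function(dir, substances = default_substances()) {
  problems <- character(0)
  need <- c("dem.asc", "plots.geojson", "roads.geojson", "inlets.geojson",
            "stream_cells.csv")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing) > 0)
    stop("missing layer files: ", paste(missing, collapse = ", "))
  dem <- read_dem_asc(file.path(dir, "dem.asc"))
  plots <- read_geojson(file.path(dir, "plots.geojson"))
  roads <- read_geojson(file.path(dir, "roads.geojson"))
  inlets <- read_geojson(file.path(dir, "inlets.geojson"))
  stream <- utils::read.csv(file.path(dir, "stream_cells.csv"))
  if (!all(c("row", "col") %in% names(stream)))
    problems <- c(problems, "stream_cells.csv: needs columns row, col")

  rainfall <- NULL
  rf <- file.path(dir, "rainfall.csv")
  if (file.exists(rf)) {
    rainfall <- read_timeseries_csv(rf)
    if (nrow(rainfall) == 0)
      problems <- c(problems, "rainfall.csv: empty rainfall file")
    if (!all(c("time", "depth_mm") %in% names(rainfall)))
      problems <- c(problems, "rainfall.csv: needs columns time, depth_mm")
  }
  conc <- NULL
  cf <- file.path(dir, "concentrations.csv")
  if (file.exists(cf)) {
    conc <- utils::read.csv(cf)
    needc <- c("site", "event", "substance", "value", "loq", "censored")
    miss <- needc[!needc %in% names(conc)]
    if (length(miss) > 0)
      problems <- c(problems, paste0("concentrations.csv: missing columns ",
                                     paste(miss, collapse = ", ")))
    if ("substance" %in% names(conc)) {
      unknown <- setdiff(unique(conc$substance), substances$name)
      if (length(unknown) > 0)
        problems <- c(problems,
                      paste0("concentrations.csv: unknown substance(s) in ",
                             "column substance: ",
                             paste(unknown, collapse = ", ")))
    }
  }
  if (length(problems) > 0)
    stop("schema violations:\n  ", paste(problems, collapse = "\n  "))
  list(dem = dem, plots = plots, roads = roads, inlets = inlets,
       stream_cells = as.matrix(stream), rainfall = rainfall,
       concentrations = conc)
}

# Polynomial rolling hash of an R object's serialisation, as hex. Used for
# manifest config hashes without external dependencies.
config_hash <- function(object) {
  raw <- serialize(object, NULL, version = 2)
  h <- 0
  for (b in as.integer(raw)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}
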