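# Interchange formats: GeoJSON points/polygons (RFC 7946 structure,
# planar coordinates), CSV tables with schema checks, ESRI ASCII
# population grids, and the YAML pipeline configuration.

#' Write shoreline points to GeoJSON
#'
#' Emits a FeatureCollection of Point features; every non-coordinate
#' column of `points` becomes a feature property (extra columns are
#' preserved).
#'
#' @param points shoreline point data.frame (`x`, `y`, plus attributes).
#' @param path output file path.
#' @return invisibly `path`.
#' @export
write_points_geojson <- function(points, path) {
  props <- setdiff(names(points), c("x", "y"))
  features <- lapply(seq_len(nrow(points)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(points$x[i], points$y[i])),
         properties = as.list(points[i, props, drop = FALSE]))
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = FALSE)
  invisible(path)
}

#' Read shoreline points from GeoJSON
#'
#' @param path GeoJSON FeatureCollection of Point features.
#' @return data.frame with `x`, `y` and one column per property.
#' @export
read_points_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  if (is.null(fc$features)) stop("not a FeatureCollection: ", path)
  rows <- lapply(seq_along(fc$features), function(i) {
    f <- fc$features[[i]]
    if (is.null(f$geometry) || !identical(f$geometry$type, "Point"))
      stop("feature ", i, ": malformed or non-Point geometry")
    co <- unlist(f$geometry$coordinates)
    props <- lapply(f$properties, function(v) if (is.null(v)) NA else v)
    c(list(x = co[1], y = co[2]), props)
  })
  nm <- names(rows[[1]])
  out <- as.data.frame(lapply(stats::setNames(nm, nm), function(col) {
    unlist(lapply(rows, function(r) if (is.null(r[[col]])) NA else r[[col]]))
  }))
  out
}

#' Write admin polygons to GeoJSON
#'
#' @param polygons list of `list(unit_id, coords)` polygons.
#' @param path output path.
#' @return invisibly `path`.
#' @export
write_polygons_geojson <- function(polygons, path) {
  features <- lapply(polygons, function(p) {
    ring <- p$coords
    if (!all(ring[1, ] == ring[nrow(ring), ]))
      ring <- rbind(ring, ring[1, ])
    list(type = "Feature",
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(i) ring[i, ]))),
         properties = list(unit_id = p$unit_id))
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  invisible(path)
}

#' Read admin polygons from GeoJSON
#'
#' @param path GeoJSON FeatureCollection of Polygon features with a
#'   `unit_id` property.
#' @return list of `list(unit_id, coords)`.
#' @export
read_polygons_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  if (is.null(fc$features)) stop("not a FeatureCollection: ", path)
  lapply(seq_along(fc$features), function(i) {
    f <- fc$features[[i]]
    if (is.null(f$geometry) || !identical(f$geometry$type, "Polygon"))
      stop("feature ", i, ": malformed or non-Polygon geometry")
    ring <- f$geometry$coordinates[[1]]
    coords <- do.call(rbind, lapply(ring, function(v) unlist(v)[1:2]))
    colnames(coords) <- c("x", "y")
    if (is.null(f$properties$unit_id))
      stop("feature ", i, ": missing required property 'unit_id'")
    list(unit_id = f$properties$unit_id, coords = coords)
  })
}

#' @keywords internal
#' @noRd
read_csv_schema <- function(path, required) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(basename(path), " missing required column(s): ",
         paste(miss, collapse = ", "))
  df
}

#' Read a district census table
#'
#' @param path CSV with `district_id` and the eight [svi_indicators()]
#'   columns; extra columns pass through.
#' @return data.frame.
#' @export
read_census_csv <- function(path) {
  read_csv_schema(path, c("district_id", svi_indicators()))
}

#' Read a hazard-event count table
#'
#' @param path CSV with `district_id` (or `unit_id`), `n_events`,
#'   `n_fatal_events`, in disaster-inventory export shape.
#' @return data.frame with `unit_id`, `n_events`, `n_fatal_events`.
#' @export
read_events_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("district_id" %in% names(df) && !"unit_id" %in% names(df))
    names(df)[names(df) == "district_id"] <- "unit_id"
  miss <- setdiff(c("unit_id", "n_events", "n_fatal_events"), names(df))
  if (length(miss))
    stop(basename(path), " missing required column(s): ",
         paste(miss, collapse = ", "))
  df
}

#' Read an admin hierarchy table
#'
#' @param path CSV with `unit_id`, `parent_id`, `level`, `name`.
#' @return data.frame, validated with [check_hierarchy()].
#' @export
read_hierarchy_csv <- function(path) {
  df <- read_csv_schema(path, c("unit_id", "parent_id", "level", "name"))
  check_hierarchy(df)
  df
}

#' Write a population grid as ESRI ASCII
#'
#' @param grid a [population_grid()].
#' @param path output `.asc` path.
#' @return invisibly `path`.
#' @export
write_ascii_grid <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(grid$counts)),
    paste("nrows", nrow(grid$counts)),
    paste("xllcorner", grid$origin_x),
    paste("yllcorner", grid$origin_y),
    paste("cellsize", grid$cell_size_m),
    paste("NODATA_value", -9999)
  ), con)
  utils::write.table(grid$counts, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a population grid from ESRI ASCII
#'
#' NODATA cells are treated as zero population; a message reports how many
#' were replaced.
#'
#' @param path `.asc` file path.
#' @return a [population_grid()].
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 0L
  while (i < length(lines)) {
    parts <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1]]
    if (suppressWarnings(!is.na(as.numeric(parts[1])))) break
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  for (k in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize"))
    if (is.null(hdr[[k]])) stop("ASCII grid header missing: ", k)
  vals <- scan(text = paste(lines[-seq_len(i)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("ASCII grid: expected ", hdr$ncols * hdr$nrows, " cells, got ",
         length(vals))
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  n_no <- sum(m == nodata)
  if (n_no > 0) {
    message(n_no, " NODATA cell(s) treated as zero population")
    m[m == nodata] <- 0
  }
  population_grid(m, hdr$xllcorner, hdr$yllcorner, hdr$cellsize)
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML configuration and checks types and ranges, naming the
#' offending key in every error. Recognised keys (all optional, with
#' package defaults): `seed`, `buffer_km`, `point_spacing_km`,
#' `missing_change_rank`, `ie_class_rule`, `thresholds`,
#' `protective_distances` (named map), `log_offset`, `scenarios`.
#'
#' @param path YAML file path, or `NULL` for all defaults.
#' @return named list of configuration values.
#' @export
load_config <- function(path = NULL) {
  cfg <- list(seed = 1L, buffer_km = 5, point_spacing_km = 1,
              missing_change_rank = 3L, ie_class_rule = "round",
              thresholds = c(20, 25, 30, 50),
              protective_distances = list(coral_reef = 2000, mangrove = 1000,
                                          seagrass = 500),
              log_offset = 1,
              scenarios = names(scenario_presets()))
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  bad <- setdiff(names(user), names(cfg))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  for (k in names(user)) cfg[[k]] <- user[[k]]
  if (cfg$buffer_km <= 0) stop("config key 'buffer_km' must be > 0")
  if (cfg$point_spacing_km <= 0)
    stop("config key 'point_spacing_km' must be > 0")
  if (!cfg$ie_class_rule %in% c("round", "quantile"))
    stop("config key 'ie_class_rule' must be 'round' or 'quantile'")
  if (any(cfg$thresholds <= 0 | cfg$thresholds >= 100))
    stop("config key 'thresholds' must lie strictly between 0 and 100")
  if (!all(cfg$scenarios %in% names(scenario_presets())))
    stop("config key 'scenarios' contains unknown scenario name(s)")
  cfg
}
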