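# Shoreline model: sampled coastline points, administrative attribution,
# and point-count based coastline lengths.

#' Sample a coastline polyline at fixed spacing
#'
#' Places shoreline points along a polyline at arc-length multiples of
#' `spacing_km`, starting at the first vertex. Each point represents
#' `spacing_km` of coastline; all downstream length statistics are point
#' counts times spacing, mirroring point-based reporting of shoreline
#' exposure at (typically) 1-km resolution.
#'
#' @param polyline two-column matrix (or data.frame) of planar vertex
#'   coordinates in metres, ordered along the coast.
#' @param spacing_km spacing between sampled points, km (> 0). Default 1.
#' @return data.frame with columns `point_id`, `x`, `y`, `spacing_km`.
#'   The number of points is `floor(total_length / spacing) + 1`.
#' @examples
#' line <- cbind(x = c(0, 10000), y = c(0, 0))
#' nrow(sample_coastline(line))  # 11 points along 10 km at 1-km spacing
#' @export
sample_coastline <- function(polyline, spacing_km = 1) {
  coords <- as.matrix(polyline)[, 1:2, drop = FALSE]
  storage.mode(coords) <- "double"
  if (nrow(coords) < 2L) stop("polyline must have at least 2 vertices")
  if (!is.numeric(spacing_km) || length(spacing_km) != 1L || spacing_km <= 0)
    stop("spacing_km must be a single positive number")
  total_m <- arc_length(coords)[nrow(coords)]
  if (total_m <= 0) stop("degenerate polyline: zero total length")
  spacing_m <- spacing_km * 1000
  s <- seq(0, total_m, by = spacing_m)
  pts <- interp_along(coords, s)
  data.frame(
    point_id = seq_along(s),
    x = pts[, 1], y = pts[, 2],
    spacing_km = spacing_km
  )
}

#' Attribute shoreline points to administrative units
#'
#' Assigns each point to a district by point-in-polygon and joins the
#' province and country through the admin hierarchy. Points on a shared
#' boundary go to the polygon with the smaller `unit_id` (deterministic
#' tie-break; polygons are visited in increasing `unit_id` order).
#'
#' @param points data.frame from [sample_coastline()].
#' @param district_polygons list of polygons, each a list with `unit_id` and
#'   `coords` (two-column ring matrix), as read by
#'   [read_polygons_geojson()].
#' @param hierarchy admin hierarchy data.frame with columns `unit_id`,
#'   `parent_id`, `level` (`"district"`, `"province"`, `"country"`), `name`.
#' @return `points` with `district_id`, `province_id`, `country_id` added.
#' @export
attribute_points <- function(points, district_polygons, hierarchy) {
  ids <- vapply(district_polygons, function(p) p$unit_id, character(1))
  ord <- order(ids)
  assigned <- rep(NA_character_, nrow(points))
  for (k in ord) {
    poly <- district_polygons[[k]]
    todo <- is.na(assigned)
    if (!any(todo)) break
    hit <- point_in_ring(points$x[todo], points$y[todo], poly$coords)
    assigned[todo][hit] <- poly$unit_id
  }
  if (anyNA(assigned)) {
    bad <- points$point_id[is.na(assigned)]
    stop("points not contained in any district polygon: point_id ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) sprintf(" (and %d more)", length(bad) - 10))
  }
  points$district_id <- assigned
  points$province_id <- admin_parent(assigned, hierarchy)
  points$country_id <- admin_parent(points$province_id, hierarchy)
  points
}

#' Look up parent unit ids in the hierarchy
#' @keywords internal
#' @noRd
admin_parent <- function(unit_ids, hierarchy) {
  hierarchy$parent_id[match(unit_ids, hierarchy$unit_id)]
}

#' Coastline length represented by a subset of points
#'
#' Length is point-count based: the sum of `spacing_km` over the points
#' satisfying `subset`, so 22,112 points at 1-km spacing represent
#' 22,112 km of coastline.
#'
#' @param points shoreline point data.frame.
#' @param subset logical vector (recycled `TRUE` if omitted) selecting points.
#' @return total length in km.
#' @export
coastline_length <- function(points, subset = TRUE) {
  keep <- rep_len(subset, nrow(points))
  sum(points$spacing_km[keep & !is.na(keep)])
}

#' Validate an admin hierarchy table
#'
#' Checks the district -> province -> country tree: every district has a
#' province parent, every province a country parent.
#'
#' @param hierarchy hierarchy data.frame (`unit_id`, `parent_id`, `level`,
#'   `name`).
#' @return invisibly `TRUE`; stops with a message naming offending units.
#' @export
check_hierarchy <- function(hierarchy) {
  req <- c("unit_id", "parent_id", "level", "name")
  miss <- setdiff(req, names(hierarchy))
  if (length(miss)) stop("hierarchy missing column(s): ",
                         paste(miss, collapse = ", "))
  for (lv in c("district", "province")) {
    parent_lv <- if (lv == "district") "province" else "country"
    units <- hierarchy[hierarchy$level == lv, ]
    par <- hierarchy[match(units$parent_id, hierarchy$unit_id), ]
    bad <- units$unit_id[is.na(par$unit_id) | par$level != parent_lv]
    if (length(bad))
      stop(lv, " unit(s) without a ", parent_lv, " parent: ",
           paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}
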