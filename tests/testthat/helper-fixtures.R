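# Shared fixtures and independent oracles, all built in code.

# square-wave coastline, total arc length 5.5 km
square_wave_polyline <- function() {
  cbind(x = c(0, 0, 1000, 1000, 2000, 2000, 2500),
        y = c(0, 1000, 1000, 0, 0, 1000, 1000))
}

# winding-number point-in-polygon oracle (independent of the package's
# ray-casting implementation); boundary points handled by caller
pip_winding <- function(px, py, ring) {
  n <- nrow(ring)
  if (all(ring[1, ] == ring[n, ])) ring <- ring[-n, , drop = FALSE]
  n <- nrow(ring)
  total <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    a1 <- atan2(ring[i, 2] - py, ring[i, 1] - px)
    a2 <- atan2(ring[j, 2] - py, ring[j, 1] - px)
    d <- a2 - a1
    if (d > pi) d <- d - 2 * pi
    if (d < -pi) d <- d + 2 * pi
    total <- total + d
  }
  abs(total) > pi
}

# three vertical-slab districts over x in [0, 30 km], two provinces,
# one country
three_district_region <- function() {
  slab <- function(id, x0, x1) {
    list(unit_id = id,
         coords = cbind(x = c(x0, x1, x1, x0), y = c(-5e4, -5e4, 5e4, 5e4)))
  }
  polygons <- list(slab("D1", 0, 1e4), slab("D2", 1e4, 2e4),
                   slab("D3", 2e4, 3e4))
  hierarchy <- data.frame(
    unit_id = c("D1", "D2", "D3", "P1", "P2", "C1"),
    parent_id = c("P1", "P1", "P2", "C1", "C1", "region"),
    level = c("district", "district", "district", "province", "province",
              "country"),
    name = c("d1", "d2", "d3", "p1", "p2", "c1"))
  list(polygons = polygons, hierarchy = hierarchy)
}

# points with constant mid-rank variables; ranks (3,3,w,s,h,3) by default
flat_points <- function(n, x = seq(0, by = 1000, length.out = n), y = 0) {
  data.frame(point_id = seq_len(n), x = x, y = y, spacing_km = 1,
             relief_m = 5, wave_power = 10,
             wind_exposure = seq_len(n), shelf_distance_m = seq_len(n),
             shoreline_change_rate = 0)
}

# independent quintile oracle: sort-and-cut with ties to the lower class
quintile_oracle <- function(values) {
  br <- stats::quantile(values, c(.2, .4, .6, .8), names = FALSE, type = 7)
  vapply(values, function(v) 1L + sum(v > br), integer(1))
}

# small census table where only pct_illiterate varies
census_one_var <- function(varying) {
  n <- length(varying)
  df <- data.frame(district_id = sprintf("D%02d", seq_len(n)))
  for (v in svi_indicators()) df[[v]] <- 10
  df$pct_illiterate <- varying
  df
}

small_region_spec <- function(seed = 3, ...) {
  region_spec(seed = seed, coast_length_km = 150, n_countries = 2,
              provinces_per_country = 2, districts_per_province = 2, ...)
}
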