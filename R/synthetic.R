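# Synthetic coastal regions: seeded generation of coastline, biophysical
# fields, admin units, habitats, population, census and hazard events with
# the statistical structure the pipeline assumes, so every stage runs
# without external data.

#' Specification of a synthetic coastal region
#'
#' Defaults describe a mid-sized coastal region: a 600-km coastline sampled
#' at 1-km spacing, three countries of two provinces with three districts
#' each, spatially smooth biophysical fields (25-km correlation length),
#' habitat coverages near the regional shares reported for East African
#' coasts (mangrove ~60%, coral ~34%, seagrass ~8% of coastline), two
#' million people clustered within a few km of the coast, correlated
#' lognormal census indicators, and district hazard-event counts whose
#' log-rate rises with the district's true share of higher-exposure
#' coastline (`n_events ~ Poisson(exp(baseline + slope * pct_higher/100))`).
#'
#' @param seed integer RNG seed; fully determines the region.
#' @param n_countries,provinces_per_country,districts_per_province admin
#'   tree shape.
#' @param coast_length_km total coastline length (km).
#' @param point_spacing_km shoreline sampling interval (km).
#' @param field_correlation_km correlation length of the smooth fields (km).
#' @param habitat_coverage named fractions of coastline within protective
#'   range per habitat class.
#' @param population_total total population on the grid.
#' @param population_decay_km e-folding distance of population density away
#'   from the coast (km).
#' @param pop_cell_km population grid cell size (km).
#' @param sandy_fraction fraction of coastline with shoreline-change
#'   estimates (contiguous sandy stretches; other points are missing).
#' @param census_rho common-factor correlation between census indicators.
#' @param event_baseline,event_slope log-rate intercept and exposure slope
#'   of the district hazard-event model.
#' @return list of class `region_spec`.
#' @export
region_spec <- function(seed = 1L,
                        n_countries = 3L,
                        provinces_per_country = 2L,
                        districts_per_province = 3L,
                        coast_length_km = 600,
                        point_spacing_km = 1,
                        field_correlation_km = 25,
                        habitat_coverage = c(coral_reef = 0.34,
                                             mangrove = 0.60,
                                             seagrass = 0.08),
                        population_total = 2e6,
                        population_decay_km = 3,
                        pop_cell_km = 2,
                        sandy_fraction = 0.6,
                        census_rho = 0.5,
                        event_baseline = 0.5,
                        event_slope = 2) {
  if (point_spacing_km <= 0 || coast_length_km <= point_spacing_km)
    stop("infeasible spec: need 0 < point_spacing_km < coast_length_km")
  if (any(habitat_coverage < 0 | habitat_coverage > 1))
    stop("habitat_coverage fractions must lie in [0, 1]")
  if (sandy_fraction < 0 || sandy_fraction > 1)
    stop("sandy_fraction must lie in [0, 1]")
  structure(as.list(environment()), class = "region_spec")
}

#' Moving-average smoothed standard-normal field
#' @keywords internal
#' @noRd
smooth_field <- function(n, window) {
  w <- max(1L, as.integer(window))
  z <- stats::rnorm(n + 2L * w)
  k <- rep(1 / (2 * w + 1), 2 * w + 1)
  s <- stats::filter(z, k, sides = 2)
  s <- as.numeric(s)[(w + 1L):(w + n)]
  if (stats::sd(s) == 0) return(rep(0, n))
  (s - mean(s)) / stats::sd(s)
}

#' Contiguous runs where a smooth field exceeds its coverage quantile
#' @keywords internal
#' @noRd
coverage_runs <- function(n, window, coverage) {
  if (coverage <= 0) return(rep(FALSE, n))
  if (coverage >= 1) return(rep(TRUE, n))
  f <- smooth_field(n, window)
  f >= stats::quantile(f, 1 - coverage, names = FALSE)
}

#' Generate a complete synthetic coastal region
#'
#' Builds, from the seed alone: a smooth x-monotone coastline polyline
#' sampled into shoreline points; positive spatially autocorrelated
#' relief/wave/wind/shelf-distance fields; shoreline-change rates on
#' contiguous sandy stretches (missing elsewhere); district slab polygons
#' partitioning the coastal strip with a province/country hierarchy;
#' habitat ribbon polygons offshore with the specified coastline coverage;
#' a coast-clustered population grid; correlated lognormal census
#' indicators per district; and district hazard-event counts drawn from a
#' Poisson model whose log-rate increases with the district's true
#' percentage of higher-exposure coastline (scenario S1, default
#' configuration).
#'
#' @param spec a [region_spec()].
#' @return list with `points` (attributed, with all variables), `polygons`
#'   (district slabs), `hierarchy`, `habitats` (list of
#'   [habitat_layer()]), `grid` ([population_grid()]), `census`, `events`,
#'   and the `spec`.
#' @export
generate_region <- function(spec = region_spec()) {
  if (!inherits(spec, "region_spec")) stop("spec must be a region_spec")
  set.seed(spec$seed)

  ## coastline: 0.5-km steps, heading within +/-60 degrees of east so x is
  ## strictly monotone (lets district polygons be exact vertical slabs)
  step_m <- 500
  n_seg <- ceiling(spec$coast_length_km * 1000 / step_m)
  heading <- smooth_field(n_seg, window = 40) * (pi / 4)
  heading <- pmax(pmin(heading, pi / 3), -pi / 3)
  dx <- step_m * cos(heading); dy <- step_m * sin(heading)
  polyline <- cbind(x = c(0, cumsum(dx)), y = c(0, cumsum(dy)))
  points <- sample_coastline(polyline, spec$point_spacing_km)
  n <- nrow(points)

  ## smooth biophysical fields (lognormal marginals, realistic spreads).
  ## A shared latent "openness" field couples the variables the way open
  ## vs sheltered coasts do: open stretches pair high wave and wind energy
  ## with low-lying shores, wide shallow shelves and faster erosion.
  w <- spec$field_correlation_km / spec$point_spacing_km
  expo <- smooth_field(n, w)
  mix <- function(a) a * expo + sqrt(1 - a^2) * smooth_field(n, w)
  points$relief_m <- exp(1.5 - 1.1 * mix(0.7))
  points$wave_power <- exp(1.5 + 1.6 * mix(0.7))
  points$wind_exposure <- exp(2.0 + 0.8 * mix(0.6))
  points$shelf_distance_m <- exp(9.0 + 1.0 * mix(0.5))
  rate <- -1.0 * expo + 1.8 * smooth_field(n, w / 2)
  sandy <- coverage_runs(n, w, spec$sandy_fraction)
  points$shoreline_change_rate <- ifelse(sandy, rate, NA_real_)

  ## admin hierarchy and slab polygons partitioning the coastal strip
  n_prov <- spec$n_countries * spec$provinces_per_country
  n_dist <- n_prov * spec$districts_per_province
  if (n_dist > n) stop("infeasible spec: more districts than shoreline points")
  dist_idx <- as.integer(cut(seq_len(n), breaks = n_dist, labels = FALSE))
  district_ids <- sprintf("D%03d", seq_len(n_dist))
  province_ids <- sprintf("P%02d", seq_len(n_prov))
  country_ids <- sprintf("C%d", seq_len(spec$n_countries))
  hierarchy <- rbind(
    data.frame(unit_id = district_ids,
               parent_id = province_ids[(seq_len(n_dist) - 1L) %/%
                                          spec$districts_per_province + 1L],
               level = "district",
               name = paste("District", seq_len(n_dist))),
    data.frame(unit_id = province_ids,
               parent_id = country_ids[(seq_len(n_prov) - 1L) %/%
                                         spec$provinces_per_country + 1L],
               level = "province",
               name = paste("Province", seq_len(n_prov))),
    data.frame(unit_id = country_ids, parent_id = "region",
               level = "country",
               name = paste("Country", seq_len(spec$n_countries)))
  )
  ## slab edges midway between adjacent districts' boundary points
  pad <- 50000
  xmax_by_d <- tapply(points$x, dist_idx, max)
  xmin_by_d <- tapply(points$x, dist_idx, min)
  cuts <- (xmax_by_d[-n_dist] + xmin_by_d[-1]) / 2
  edges <- c(min(points$x) - pad, cuts, max(points$x) + pad)
  ylo <- min(points$y) - pad; yhi <- max(points$y) + pad
  polygons <- lapply(seq_len(n_dist), function(i) {
    list(unit_id = district_ids[i],
         coords = cbind(x = c(edges[i], edges[i + 1], edges[i + 1], edges[i]),
                        y = c(ylo, ylo, yhi, yhi)))
  })
  points <- attribute_points(points, polygons, hierarchy)

  ## habitat ribbons offshore (negative-y side), following covered points;
  ## mangroves and seagrasses develop preferentially on sheltered coast
  habitats <- lapply(names(spec$habitat_coverage), function(cls) {
    layer <- habitat_layer(cls)
    cov_frac <- spec$habitat_coverage[[cls]]
    covered <- if (cls == "coral_reef") {
      coverage_runs(n, w, cov_frac)
    } else {
      g <- -0.5 * expo + sqrt(1 - 0.25) * smooth_field(n, w)
      if (cov_frac <= 0) rep(FALSE, n)
      else g >= stats::quantile(g, 1 - cov_frac, names = FALSE)
    }
    runs <- rle(covered)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    polys <- list()
    for (k in which(runs$values & runs$lengths >= 2L)) {
      i <- starts[k]:ends[k]
      near <- layer$protective_distance_m * 0.1
      far <- layer$protective_distance_m * 0.5
      polys[[length(polys) + 1L]] <- cbind(
        x = c(points$x[i], rev(points$x[i])),
        y = c(points$y[i] - near, rev(points$y[i]) - far))
    }
    layer$polygons <- polys
    layer
  })

  ## population grid clustered near the coast
  cs <- spec$pop_cell_km * 1000
  gx0 <- min(points$x) - 10000; gy0 <- min(points$y) - 10000
  ncx <- ceiling((max(points$x) + 10000 - gx0) / cs)
  ncy <- ceiling((max(points$y) + 10000 - gy0) / cs)
  cx <- gx0 + (seq_len(ncx) - 0.5) * cs
  cy <- gy0 + (ncy - seq_len(ncy) + 0.5) * cs
  xm <- matrix(cx, ncy, ncx, byrow = TRUE)
  ym <- matrix(cy, ncy, ncx)
  dmin <- matrix(Inf, ncy, ncx)
  for (i in seq_len(n)) {
    dmin <- pmin(dmin, sqrt((xm - points$x[i])^2 + (ym - points$y[i])^2))
  }
  wgt <- exp(-(dmin / 1000) / spec$population_decay_km)
  counts <- spec$population_total * wgt / sum(wgt)
  grid <- population_grid(counts, gx0, gy0, cs)

  ## census: correlated lognormal indicators per district
  mu <- c(pct_under4 = log(15), pct_over65 = log(3.5),
          pct_annual_growth = log(2.5), density_per_km2 = log(100),
          pct_illiterate = log(30), pct_natural_housing = log(70),
          pct_unimproved_water = log(40), pct_unimproved_waste = log(58))
  sdev <- c(0.25, 0.35, 0.4, 1.0, 0.5, 0.3, 0.5, 0.4)
  common <- stats::rnorm(n_dist)
  census <- data.frame(district_id = district_ids)
  for (j in seq_along(mu)) {
    lat <- spec$census_rho * common +
      sqrt(1 - spec$census_rho^2) * stats::rnorm(n_dist)
    v <- exp(mu[j] + sdev[j] * lat)
    if (startsWith(names(mu)[j], "pct")) v <- pmin(v, 100)
    census[[names(mu)[j]]] <- v
  }

  ## hazard events: Poisson log-rate rising with true district exposure
  exposure <- run_scenarios(points, habitats, scenarios = "S1_all")
  summ <- summarize_admin(exposure, points, level = "district")
  pct <- summ$pct_higher[match(district_ids, summ$unit_id)]
  events <- draw_events(district_ids, pct,
                        baseline = spec$event_baseline,
                        slope = spec$event_slope)

  list(points = points, polygons = polygons, hierarchy = hierarchy,
       habitats = habitats, grid = grid, census = census, events = events,
       spec = spec)
}

#' Draw hazard-event counts from the exposure-linked Poisson model
#'
#' Per-unit coastal hazard events are Poisson with
#' `log(rate) = baseline + slope * pct_higher / 100`; fatal events are a
#' binomial thinning of the events. `slope = 0` gives the
#' exposure-independent null model used for type-I calibration.
#'
#' @param unit_ids unit identifiers.
#' @param pct_higher percent of each unit's coastline at higher exposure
#'   (0-100).
#' @param baseline,slope log-rate intercept and exposure slope.
#' @param fatal_prob probability an event causes fatalities (default 0.4).
#' @return data.frame `unit_id`, `n_events`, `n_fatal_events`.
#' @export
draw_events <- function(unit_ids, pct_higher, baseline = 0.5, slope = 2,
                        fatal_prob = 0.4) {
  lambda <- exp(baseline + slope * pct_higher / 100)
  n_events <- stats::rpois(length(unit_ids), lambda)
  data.frame(unit_id = unit_ids, n_events = n_events,
             n_fatal_events = stats::rbinom(length(unit_ids), n_events,
                                            fatal_prob))
}

#' Worked-example fixtures: printed regional summary marginals
#'
#' Returns the per-unit shoreline point counts (1 point = 1 km) and
#' higher-exposure counts under the all-habitats (S1) and no-habitats (S5)
#' scenarios, plus population at higher exposure (thousands), for the East
#' African region, its four countries and their most exposed provinces, as
#' printed in the source regional assessment's summary table. Used by the
#' worked-example tests and the acceptance script to exercise the
#' summarisation/reporting arithmetic.
#'
#' @return data.frame with `unit`, `level`, `parent`, `n_points`, `h_s1`,
#'   `h_s5`, `pop_s1_thousands`, `pop_s5_thousands`.
#' @export
fixture_table4 <- function() {
  data.frame(
    unit = c("East Africa", "Kenya", "Tana River", "Tanzania", "Pwani",
             "Mozambique", "Gaza", "Madagascar", "Androy"),
    level = c("region", "country", "province", "country", "province",
              "country", "province", "country", "province"),
    parent = c(NA, "East Africa", "Kenya", "East Africa", "Tanzania",
               "East Africa", "Mozambique", "East Africa", "Madagascar"),
    n_points = c(22112L, 1591L, 99L, 3138L, 636L, 7146L, 202L, 10237L, 211L),
    h_s1 = c(4827L, 228L, 64L, 309L, 159L, 1670L, 154L, 2620L, 172L),
    h_s5 = c(8603L, 581L, 76L, 1039L, 339L, 2500L, 154L, 4483L, 187L),
    pop_s1_thousands = c(3536.8, 314.6, 15.2, 405.1, 53.6, 1660.4, 76.3,
                         1156.8, 71.8),
    pop_s5_thousands = c(6898.8, 1298.5, 15.6, 2204.7, 80.8, 1899.9, 76.3,
                         1495.7, 72.1)
  )
}
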