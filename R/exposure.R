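# Exposure engine: per-variable 1-5 ranking, habitat protection under
# scenarios, the geometric-mean index of exposure (IE), and the collapse of
# the five IE classes to lower/moderate/higher (L/M/H).

#' Ranking scheme for one exposure variable
#'
#' Fixed-bin schemes carry four interior class edges (five classes);
#' quantile schemes cut at the 20/40/60/80th percentiles of the observed
#' values. `rank_order = "asc"` means larger raw values are more exposed
#' (rank 5 at the top); `"desc"` the opposite (e.g. relief: high ground is
#' least exposed). Intervals are closed at the lower edge, open at the
#' upper; values outside the stated range clamp to the extreme class.
#'
#' @param variable variable name (e.g. `"relief"`, `"wave"`).
#' @param method `"fixed_bins"` or `"quantile"`.
#' @param edges ascending numeric vector of 4 interior edges
#'   (fixed_bins only).
#' @param rank_order `"asc"` or `"desc"`.
#' @return an object of class `ranking_scheme`.
#' @export
ranking_scheme <- function(variable, method = c("fixed_bins", "quantile"),
                           edges = NULL, rank_order = c("asc", "desc")) {
  method <- match.arg(method)
  rank_order <- match.arg(rank_order)
  if (method == "fixed_bins") {
    if (is.null(edges) || length(edges) != 4L || is.unsorted(edges, strictly = TRUE))
      stop("fixed_bins scheme needs exactly 4 strictly ascending edges")
  }
  structure(list(variable = variable, method = method,
                 edges = edges, rank_order = rank_order),
            class = "ranking_scheme")
}

#' Default ranking schemes for the four scalar variables
#'
#' Relief (m) is ranked descending on fixed bins with edges 2, 4, 8, 12
#' (flat coasts most exposed); wave exposure ascending on fixed bins with
#' edges 0.75, 3, 18.75, 48 (model units of weighted-average wave power);
#' wind exposure and surge potential are ranked by region-wide quintiles.
#'
#' @return named list of [ranking_scheme()] objects.
#' @export
default_schemes <- function() {
  list(
    relief = ranking_scheme("relief", "fixed_bins",
                            edges = c(2, 4, 8, 12), rank_order = "desc"),
    wave = ranking_scheme("wave", "fixed_bins",
                          edges = c(0.75, 3, 18.75, 48), rank_order = "asc"),
    wind = ranking_scheme("wind", "quantile", rank_order = "asc"),
    surge = ranking_scheme("surge", "quantile", rank_order = "asc")
  )
}

#' Rank values on a fixed-bin scheme
#'
#' @param values numeric vector, finite.
#' @param scheme a fixed-bin [ranking_scheme()].
#' @return integer ranks 1-5.
#' @examples
#' sch <- default_schemes()
#' rank_fixed_bins(c(1, 15), sch$relief)  # 5 (flat), 1 (high ground)
#' rank_fixed_bins(100, sch$wave)         # 5
#' @export
rank_fixed_bins <- function(values, scheme) {
  if (!inherits(scheme, "ranking_scheme") || scheme$method != "fixed_bins")
    stop("scheme must be a fixed_bins ranking_scheme")
  if (any(!is.finite(values)))
    stop("rank_fixed_bins: non-finite value(s)")
  bin <- findInterval(values, scheme$edges) + 1L  # 1..5, lower-closed
  if (scheme$rank_order == "desc") bin <- 6L - bin
  as.integer(bin)
}

#' Rank values by region-wide quintiles
#'
#' Breakpoints are the 20/40/60/80th percentiles (type-7 linear
#' interpolation). A value equal to a breakpoint goes to the lower class;
#' a constant vector gets rank 1 everywhere.
#'
#' @param values numeric vector over all points (length >= 5).
#' @return integer ranks 1-5, same length as `values`.
#' @export
rank_quantile <- function(values) {
  if (length(values) < 5L) stop("rank_quantile needs at least 5 values")
  if (any(!is.finite(values))) stop("rank_quantile: non-finite value(s)")
  br <- stats::quantile(values, probs = c(.2, .4, .6, .8),
                        names = FALSE, type = 7)
  ranks <- rep(1L, length(values))
  for (b in br) ranks <- ranks + (values > b)
  as.integer(ranks)
}

#' Habitat scenario presets
#'
#' Five scenarios covering the presence or absence of mangroves, coral
#' reefs and seagrasses: S1 keeps all habitats ("current" conditions); S2,
#' S3 and S4 drop corals, mangroves and seagrasses respectively; S5 drops
#' all habitats, forcing the habitat rank to 5 everywhere.
#'
#' @return named list mapping scenario name to the included habitat classes.
#' @export
scenario_presets <- function() {
  all3 <- c("coral_reef", "mangrove", "seagrass")
  list(
    S1_all = all3,
    S2_no_corals = setdiff(all3, "coral_reef"),
    S3_no_mangrove = setdiff(all3, "mangrove"),
    S4_no_seagrasses = setdiff(all3, "seagrass"),
    S5_no_habitats = character(0)
  )
}

#' Construct a habitat layer
#'
#' Coral reefs and mangroves carry protection rank 1 (most protective),
#' seagrass rank 4; shoreline with no habitat in range is rank 5. The
#' protective distance is the radius within which a polygon confers its
#' rank on a shoreline point. The defaults (coral 2,000 m, mangrove
#' 1,000 m, seagrass 500 m) are package assumptions, configurable per layer.
#'
#' @param habitat_class `"coral_reef"`, `"mangrove"` or `"seagrass"`.
#' @param polygons list of two-column ring matrices (projected metres).
#' @param protective_distance_m protection radius in metres (> 0);
#'   `NULL` for the class default.
#' @return an object of class `habitat_layer`.
#' @export
habitat_layer <- function(habitat_class = c("coral_reef", "mangrove", "seagrass"),
                          polygons = list(), protective_distance_m = NULL) {
  habitat_class <- match.arg(habitat_class)
  defaults <- c(coral_reef = 2000, mangrove = 1000, seagrass = 500)
  if (is.null(protective_distance_m))
    protective_distance_m <- unname(defaults[habitat_class])
  if (protective_distance_m <= 0) stop("protective_distance_m must be > 0")
  rank <- if (habitat_class == "seagrass") 4L else 1L
  structure(list(habitat_class = habitat_class,
                 protection_rank = rank,
                 protective_distance_m = protective_distance_m,
                 polygons = polygons),
            class = "habitat_layer")
}

#' Habitat protection rank for shoreline points under a scenario
#'
#' For every habitat class included in the scenario, a point within the
#' class's protective distance of any of its polygons is protected at that
#' class's rank; the most protective (minimum) rank wins. Points with no
#' habitat in range get rank 5.
#'
#' @param points shoreline point data.frame (`x`, `y`).
#' @param habitat_layers list of [habitat_layer()] objects.
#' @param scenario scenario name (see [scenario_presets()]) or a character
#'   vector of included habitat classes.
#' @return integer vector of ranks in \{1, 4, 5\}.
#' @export
habitat_rank <- function(points, habitat_layers, scenario = "S1_all") {
  included <- resolve_scenario(scenario)
  rank <- rep(5L, nrow(points))
  for (layer in habitat_layers) {
    if (!layer$habitat_class %in% included) next
    if (all(rank <= layer$protection_rank)) next
    in_range <- rep(FALSE, nrow(points))
    for (ring in layer$polygons) {
      todo <- !in_range
      if (!any(todo)) break
      d <- dist_point_ring(points$x[todo], points$y[todo], ring)
      in_range[todo] <- d <= layer$protective_distance_m
    }
    rank[in_range] <- pmin(rank[in_range], layer$protection_rank)
  }
  rank
}

#' @keywords internal
#' @noRd
resolve_scenario <- function(scenario) {
  presets <- scenario_presets()
  if (length(scenario) == 1L && scenario %in% names(presets))
    return(presets[[scenario]])
  known <- c("coral_reef", "mangrove", "seagrass")
  if (all(scenario %in% known)) return(scenario)
  if (length(scenario) == 0L) return(character(0))
  stop("unknown scenario: ", paste(scenario, collapse = ", "),
       " (presets: ", paste(names(presets), collapse = ", "), ")")
}

#' Rank shoreline change rates
#'
#' Accretion above +2 m/yr ranks 1 (least exposed); rates in (+1, +2] rank
#' 2; stable shores in [-1, +1] rank 3; erosion in [-2, -1) ranks 4; below
#' -2 m/yr ranks 5. Rates are only observed on sandy shores; missing rates
#' get `missing_rank` (default 3, neutral).
#'
#' @param rates numeric vector of shoreline change rates in m/yr, `NA` where
#'   unobserved.
#' @param missing_rank rank assigned to missing rates (default 3).
#' @return integer ranks 1-5.
#' @export
shoreline_change_rank <- function(rates, missing_rank = 3L) {
  rank <- rep(NA_integer_, length(rates))
  rank[rates > 2] <- 1L
  rank[rates > 1 & rates <= 2] <- 2L
  rank[rates >= -1 & rates <= 1] <- 3L
  rank[rates >= -2 & rates < -1] <- 4L
  rank[rates < -2] <- 5L
  rank[is.na(rates)] <- as.integer(missing_rank)
  rank
}

#' Geometric-mean index of exposure
#'
#' IE is the geometric mean of the six variable ranks
#' (relief, waves, wind, surge, habitats, shoreline change):
#' \deqn{IE = (R_{relief} R_{waves} R_{wind} R_{surge} R_{habitats}
#'       R_{shoreline\,change})^{1/6}}
#'
#' @param ranks numeric vector of six ranks in 1-5, or an n x 6 matrix
#'   (one row per point).
#' @return IE value(s) in \[1, 5\].
#' @examples
#' compute_ie(c(1, 2, 3, 4, 5, 5))  # 600^(1/6) = 2.9045
#' @export
compute_ie <- function(ranks) {
  m <- if (is.matrix(ranks)) ranks else matrix(ranks, nrow = 1)
  if (ncol(m) != 6L) stop("compute_ie expects six ranks per point")
  if (any(m < 1 | m > 5 | m != round(m)))
    stop("ranks must be integers in 1..5")
  exp(rowMeans(log(m)))
}

#' Collapse continuous IE to discrete classes and L/M/H
#'
#' The default rule maps IE to its nearest integer class (half rounds up,
#' so H starts at IE >= 3.5) and collapses classes 1-2 to lower (L), 3 to
#' moderate (M) and 4-5 to higher (H). `rule = "quantile"` instead cuts
#' the IE distribution at region-wide quintiles.
#'
#' @param ie numeric IE values in \[1, 5\].
#' @param rule `"round"` (default) or `"quantile"`.
#' @return data.frame with `ie_class` (integer 1-5) and `lmh`
#'   (`"L"`, `"M"`, `"H"`).
#' @export
classify_ie <- function(ie, rule = c("round", "quantile")) {
  rule <- match.arg(rule)
  if (any(ie < 1 - 1e-9 | ie > 5 + 1e-9)) stop("ie values must lie in [1, 5]")
  cls <- if (rule == "round") {
    pmin(as.integer(floor(ie + 0.5)), 5L)  # half-up
  } else {
    rank_quantile(ie)
  }
  lmh <- c("L", "L", "M", "H", "H")[cls]
  data.frame(ie_class = cls, lmh = lmh)
}

#' Exposure configuration
#'
#' @param schemes named list of ranking schemes ([default_schemes()]).
#' @param missing_change_rank rank for missing shoreline-change rates.
#' @param ie_class_rule `"round"` or `"quantile"` (see [classify_ie()]).
#' @return list of class `exposure_config`.
#' @export
exposure_config <- function(schemes = default_schemes(),
                            missing_change_rank = 3L,
                            ie_class_rule = "round") {
  structure(list(schemes = schemes,
                 missing_change_rank = missing_change_rank,
                 ie_class_rule = ie_class_rule),
            class = "exposure_config")
}

#' Run the exposure model across habitat scenarios
#'
#' Ranks the five non-habitat variables once (they are scenario-invariant),
#' then recomputes the habitat rank and IE for each scenario. Only
#' `r_habitat` differs between scenarios; S5 forces `r_habitat = 5`
#' everywhere.
#'
#' @param points attributed shoreline points carrying `relief_m`,
#'   `wave_power`, `wind_exposure`, `shelf_distance_m`,
#'   `shoreline_change_rate`.
#' @param habitat_layers list of [habitat_layer()] objects.
#' @param scenarios character vector of scenario names
#'   (default all five presets).
#' @param config an [exposure_config()].
#' @return data.frame with one row per point per scenario: `point_id`,
#'   `scenario`, the six ranks, `ie`, `ie_class`, `lmh`.
#' @export
run_scenarios <- function(points, habitat_layers,
                          scenarios = names(scenario_presets()),
                          config = exposure_config()) {
  schemes <- config$schemes
  base <- data.frame(
    point_id = points$point_id,
    r_relief = rank_fixed_bins(points$relief_m, schemes$relief),
    r_wave = rank_fixed_bins(points$wave_power, schemes$wave),
    r_wind = rank_quantile(points$wind_exposure),
    r_surge = rank_quantile(points$shelf_distance_m),
    r_shoreline_change = shoreline_change_rank(points$shoreline_change_rate,
                                               config$missing_change_rank)
  )
  out <- lapply(scenarios, function(sc) {
    res <- base
    res$scenario <- sc
    res$r_habitat <- habitat_rank(points, habitat_layers, sc)
    res$ie <- compute_ie(as.matrix(res[, c("r_relief", "r_wave", "r_wind",
                                           "r_surge", "r_habitat",
                                           "r_shoreline_change")]))
    cls <- classify_ie(res$ie, config$ie_class_rule)
    res$ie_class <- cls$ie_class
    res$lmh <- cls$lmh
    res
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[, c("point_id", "scenario", "r_relief", "r_wave", "r_wind", "r_surge",
          "r_habitat", "r_shoreline_change", "ie", "ie_class", "lmh")]
}
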