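# Integration: per-unit exposure summaries, the IVCC (SVI + mean IE), and
# priority/critical classification.

#' Summarise exposure per administrative unit
#'
#' For each unit at the requested level: number of points, represented
#' coastline length (km), arithmetic mean IE, count and percentage of
#' points at higher exposure (L/M/H class H). Units with zero points are
#' excluded with a warning.
#'
#' @param exposure result of [run_scenarios()] (one or more scenarios).
#' @param points attributed shoreline points.
#' @param level `"district"`, `"province"`, `"country"` or `"region"`
#'   (region = all points as one unit).
#' @param scenario scenario name; default summarises every scenario
#'   present in `exposure`.
#' @return data.frame `unit_id`, `level`, `scenario`, `n_points`,
#'   `coast_km`, `mean_ie`, `n_higher`, `pct_higher`.
#' @export
summarize_admin <- function(exposure, points,
                            level = c("district", "province", "country",
                                      "region"),
                            scenario = NULL) {
  level <- match.arg(level)
  scenarios <- if (is.null(scenario)) unique(exposure$scenario) else scenario
  unit_of <- if (level == "region") {
    rep("region", nrow(points))
  } else {
    points[[paste0(level, "_id")]]
  }
  out <- lapply(scenarios, function(sc) {
    ex <- exposure[exposure$scenario == sc, ]
    m <- match(ex$point_id, points$point_id)
    u <- unit_of[m]
    spl <- split(seq_len(nrow(ex)), u)
    res <- lapply(names(spl), function(uid) {
      i <- spl[[uid]]
      data.frame(
        unit_id = uid, level = level, scenario = sc,
        n_points = length(i),
        coast_km = sum(points$spacing_km[m[i]]),
        mean_ie = mean(ex$ie[i]),
        n_higher = sum(ex$lmh[i] == "H"),
        pct_higher = 100 * sum(ex$lmh[i] == "H") / length(i)
      )
    })
    do.call(rbind, res)
  })
  out <- do.call(rbind, out)
  empty <- setdiff(unique(unit_of), out$unit_id)
  if (length(empty))
    warning("unit(s) with zero points excluded: ",
            paste(empty, collapse = ", "))
  rownames(out) <- NULL
  out
}

#' Index of vulnerability to coastal change
#'
#' The IVCC is the sum of the SVI and the mean IE of all shoreline points
#' within the unit. At district level the SVI is the district's quintile
#' rank (1-5); at province level it is the mean of the district ranks and
#' the mean IE averages all points in the province. The result lies in
#' \[2, 10\]. A missing SVI yields a missing IVCC (never imputed), as for
#' units without comparable census data.
#'
#' @param svi_value SVI in \[1, 5\] (may be `NA`).
#' @param mean_ie mean IE in \[1, 5\].
#' @return numeric IVCC value(s); `NA` where the SVI is missing.
#' @examples
#' compute_ivcc(5, 3.75)  # 8.75
#' @export
compute_ivcc <- function(svi_value, mean_ie) {
  ok <- !is.na(svi_value)
  if (any(svi_value[ok] < 1 | svi_value[ok] > 5))
    stop("svi_value must lie in [1, 5]")
  if (any(mean_ie < 1 - 1e-9 | mean_ie > 5 + 1e-9, na.rm = TRUE))
    stop("mean_ie must lie in [1, 5]")
  svi_value + mean_ie
}

#' Classify districts into priority-concern and critical areas
#'
#' A unit with IVCC strictly above 7 is an area of priority concern; a
#' priority-concern unit with strictly more than 90% of its coastline at
#' higher exposure under the all-habitats scenario is a critical area.
#'
#' @param ivcc IVCC value(s), `NA` allowed.
#' @param pct_higher_s1 percent of coastline at higher exposure under
#'   scenario S1 (0-100).
#' @return character vector: `"none"`, `"priority_concern"` or
#'   `"critical"` (`NA` where IVCC is missing).
#' @export
classify_priority <- function(ivcc, pct_higher_s1) {
  if (any(pct_higher_s1 < 0 | pct_higher_s1 > 100, na.rm = TRUE))
    stop("pct_higher_s1 must lie in [0, 100]")
  out <- ifelse(is.na(ivcc), NA_character_,
         ifelse(ivcc > 7,
                ifelse(pct_higher_s1 > 90, "critical", "priority_concern"),
                "none"))
  out
}

#' Full per-unit summary table with SVI, IVCC and priority class
#'
#' Joins the exposure summary, population at higher exposure and the SVI
#' into one table per unit and scenario, computing the IVCC and the
#' priority classification (against scenario S1's percent higher).
#'
#' @param summaries output of [summarize_admin()] at one level.
#' @param svi_table data.frame `unit_id`, `svi` (district ranks or
#'   province means); may omit units (their IVCC is `NA`).
#' @param population optional data.frame from [population_by_admin()]
#'   (matched on `unit_id` and `scenario`).
#' @param s1 name of the all-habitats scenario (default `"S1_all"`).
#' @return `summaries` with `population_higher`, `svi`, `ivcc`,
#'   `priority` columns added.
#' @export
admin_summary <- function(summaries, svi_table = NULL, population = NULL,
                          s1 = "S1_all") {
  out <- summaries
  out$population_higher <- if (!is.null(population)) {
    population$population_higher[match(paste(out$unit_id, out$scenario),
                                       paste(population$unit_id,
                                             population$scenario))]
  } else NA_real_
  out$svi <- if (!is.null(svi_table)) {
    svi_table$svi[match(out$unit_id, svi_table$unit_id)]
  } else NA_real_
  out$ivcc <- compute_ivcc(out$svi, out$mean_ie)
  ref <- out[out$scenario == s1, ]
  out$priority <- classify_priority(
    out$ivcc, ref$pct_higher[match(out$unit_id, ref$unit_id)])
  out
}
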