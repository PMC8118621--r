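# Social vulnerability index: eight census indicators per district,
# ln-transformed, z-scored, direction-weighted sum, quintile-ranked 1-5.

#' Names of the eight SVI census indicators
#' @return character vector of the indicator column names.
#' @export
svi_indicators <- function() {
  c("pct_under4", "pct_over65", "pct_annual_growth", "density_per_km2",
    "pct_illiterate", "pct_natural_housing", "pct_unimproved_water",
    "pct_unimproved_waste")
}

#' Indicator direction specification
#'
#' Direction +1 means larger values increase social vulnerability (the
#' default for all eight indicators: young/elderly population shares,
#' growth, density, illiteracy, natural-material housing, unimproved water
#' and waste); -1 reverses the contribution.
#'
#' @param directions named numeric vector of +1/-1 overriding defaults.
#' @return named vector over [svi_indicators()].
#' @export
indicator_directions <- function(directions = NULL) {
  dir <- stats::setNames(rep(1, 8), svi_indicators())
  if (!is.null(directions)) {
    bad <- setdiff(names(directions), svi_indicators())
    if (length(bad)) stop("unknown indicator(s): ", paste(bad, collapse = ", "))
    if (!all(directions %in% c(-1, 1))) stop("directions must be +1 or -1")
    dir[names(directions)] <- directions
  }
  dir
}

#' Log-transform and z-score one indicator across districts
#'
#' Computes `z = (ln(v + offset) - mean) / sd` over the included districts,
#' with the sample (n-1) standard deviation. The default offset 1 admits
#' zero-valued percentages; set `offset = 0` for strictly positive data.
#' A constant column yields z = 0 everywhere.
#'
#' @param values non-negative numeric vector, one value per district.
#' @param offset added inside the logarithm (default 1).
#' @return numeric vector of z-scores.
#' @export
transform_indicator <- function(values, offset = 1) {
  if (any(values < 0, na.rm = TRUE))
    stop("indicator values must be non-negative")
  if (length(values) < 2L) stop("need at least 2 districts")
  lv <- log(values + offset)
  s <- stats::sd(lv)
  if (!is.finite(s) || s == 0) return(rep(0, length(values)))
  (lv - mean(lv)) / s
}

#' Compute the social vulnerability index per district
#'
#' Each of the eight indicators is ln-transformed and z-scored across the
#' complete districts, the z-scores are summed with their direction signs,
#' and the scores are ranked 1 (very low social vulnerability, first
#' quintile) to 5 (very high, fifth quintile) with the same quintile rule
#' as [rank_quantile()]. Districts with any missing indicator are excluded
#' (reported in the `excluded` attribute), not failed.
#'
#' @param census data.frame with `district_id` and the eight
#'   [svi_indicators()] columns.
#' @param directions named +1/-1 vector from [indicator_directions()].
#' @param offset log offset passed to [transform_indicator()].
#' @return data.frame `district_id`, the eight z-score columns (prefixed
#'   `z_`), `score`, `rank`; attribute `excluded` lists dropped districts.
#' @export
compute_svi <- function(census, directions = indicator_directions(),
                        offset = 1) {
  ind <- svi_indicators()
  miss <- setdiff(c("district_id", ind), names(census))
  if (length(miss)) stop("census table missing column(s): ",
                         paste(miss, collapse = ", "))
  complete <- stats::complete.cases(census[, ind])
  excluded <- census$district_id[!complete]
  cen <- census[complete, ]
  if (nrow(cen) < 5L)
    stop("compute_svi needs at least 5 complete districts, got ", nrow(cen))
  z <- vapply(ind, function(v) transform_indicator(cen[[v]], offset),
              numeric(nrow(cen)))
  score <- as.numeric(z %*% directions[ind])
  out <- data.frame(district_id = cen$district_id)
  out[paste0("z_", ind)] <- as.data.frame(z)
  out$score <- score
  out$rank <- rank_quantile(score)
  attr(out, "excluded") <- excluded
  out
}

#' Province-level SVI as the mean district rank
#'
#' Averages the district SVI ranks (1-5), not the raw scores, within each
#' province. Provinces with no scored district (e.g. all districts lacked
#' census data) are absent from the output rather than carrying NA.
#'
#' @param svi district SVI table from [compute_svi()].
#' @param hierarchy admin hierarchy data.frame.
#' @return data.frame `province_id`, `svi` (mean district rank),
#'   `n_districts`.
#' @export
province_svi <- function(svi, hierarchy) {
  prov <- admin_parent(svi$district_id, hierarchy)
  keep <- !is.na(prov)
  agg <- stats::aggregate(list(svi = svi$rank[keep]),
                          by = list(province_id = prov[keep]), FUN = mean)
  n <- stats::aggregate(list(n_districts = svi$rank[keep]),
                        by = list(province_id = prov[keep]), FUN = length)
  merge(agg, n, by = "province_id")
}
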