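# Validation protocol: exposed/less-exposed classification at several
# thresholds, Mann-Whitney U comparison of hazard-event counts, and
# Spearman rank correlations of exposure and IVCC against events.

#' Classify units as exposed at a percent-higher threshold
#'
#' A unit is "exposed" when the percentage of its shoreline points at
#' higher exposure (under current conditions, scenario S1) meets the
#' threshold, inclusively (`>=`).
#'
#' @param pct_higher numeric percentages (0-100).
#' @param threshold_pct threshold in percent, strictly inside (0, 100);
#'   typical values 20, 25, 30, 50.
#' @return logical vector.
#' @export
classify_exposed <- function(pct_higher, threshold_pct) {
  if (length(threshold_pct) != 1L || threshold_pct <= 0 || threshold_pct >= 100)
    stop("threshold_pct must lie strictly between 0 and 100")
  pct_higher >= threshold_pct
}

#' Mann-Whitney U test (midranks, tie-corrected)
#'
#' U is computed from midranks; `U + U' = n_a * n_b` always holds. The
#' two-sided p-value is obtained by exact enumeration of all rank
#' assignments when `n_a * n_b <= 20` (valid with ties, since midranks are
#' enumerated), and otherwise from the normal approximation with tie
#' correction and continuity correction.
#'
#' @param a,b numeric vectors (both non-empty).
#' @return list with `u` (U for group `a`), `p` (two-sided), `method`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mann_whitney_u <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("both groups must be non-empty")
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))  # midranks
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  if (na * nb <= 20) {
    # exact: enumerate which positions get group a's ranks
    combos <- utils::combn(n, na)
    us <- apply(combos, 2, function(idx) {
      sum(r[idx]) - na * (na + 1) / 2
    })
    # two-sided: double the smaller tail (capped at 1)
    p <- 2 * min(mean(us <= u + 1e-9), mean(us >= u - 1e-9))
    p <- min(p, 1)
    list(u = u, p = p, method = "exact")
  } else {
    mu <- na * nb / 2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- na * nb / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) return(list(u = u, p = 1, method = "normal"))
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
    list(u = u, p = 2 * stats::pnorm(-abs(z)), method = "normal")
  }
}

#' Spearman rank correlation (midranks, t approximation)
#'
#' rho is the product-moment correlation of the midranks (tie-safe; for
#' untied data it equals `1 - 6*sum(d^2)/(n*(n^2-1))`). The two-sided
#' p-value uses the t approximation with n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `rho`, `p`; both `NA` (with `degenerate = TRUE`) if
#'   either vector has zero rank variance.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    return(list(rho = NA_real_, p = NA_real_, degenerate = TRUE))
  rho <- stats::cor(rx, ry)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, degenerate = FALSE)
}

#' Run the full validation protocol
#'
#' Joins per-unit exposure summaries with hazard-event records, then for
#' each threshold splits units into exposed/less-exposed and compares
#' their event and fatal-event counts with Mann-Whitney U tests; and
#' correlates (Spearman) the percent of shoreline at higher exposure, and
#' optionally the IVCC, against both outcomes.
#'
#' @param summaries [summarize_admin()] output for scenario S1 at the
#'   validation level (must carry `unit_id`, `pct_higher`).
#' @param events data.frame `unit_id`, `n_events`, `n_fatal_events`.
#' @param thresholds percent thresholds (default `c(20, 25, 30, 50)`).
#' @param ivcc optional data.frame `unit_id`, `ivcc`.
#' @return list with `tests` (one row per threshold x outcome:
#'   `threshold_pct`, `outcome`, `n_exposed`, `n_less`, `u`, `p`),
#'   `correlations` (`predictor`, `outcome`, `rho`, `p`, `n`), and
#'   `n_dropped` (units without events or vice versa).
#' @export
run_validation <- function(summaries, events,
                           thresholds = c(20, 25, 30, 50), ivcc = NULL) {
  if (any(events$n_fatal_events > events$n_events))
    stop("n_fatal_events cannot exceed n_events")
  m <- merge(summaries[, c("unit_id", "pct_higher")],
             events[, c("unit_id", "n_events", "n_fatal_events")],
             by = "unit_id")
  n_dropped <- length(union(summaries$unit_id, events$unit_id)) - nrow(m)
  if (nrow(m) == 0L) stop("no overlapping units between summaries and events")
  if (n_dropped > 0)
    message(n_dropped, " unit(s) without matching records dropped")

  outcomes <- c("n_events", "n_fatal_events")
  tests <- do.call(rbind, lapply(thresholds, function(th) {
    exposed <- classify_exposed(m$pct_higher, th)
    do.call(rbind, lapply(outcomes, function(oc) {
      if (all(exposed) || !any(exposed)) {
        return(data.frame(threshold_pct = th, outcome = oc,
                          n_exposed = sum(exposed), n_less = sum(!exposed),
                          u = NA_real_, p = NA_real_))
      }
      mw <- mann_whitney_u(m[[oc]][exposed], m[[oc]][!exposed])
      data.frame(threshold_pct = th, outcome = oc,
                 n_exposed = sum(exposed), n_less = sum(!exposed),
                 u = mw$u, p = mw$p)
    }))
  }))

  predictors <- list(pct_higher = m$pct_higher)
  if (!is.null(ivcc)) {
    iv <- ivcc$ivcc[match(m$unit_id, ivcc$unit_id)]
    predictors$ivcc <- iv
  }
  correlations <- do.call(rbind, lapply(names(predictors), function(pv) {
    do.call(rbind, lapply(outcomes, function(oc) {
      ok <- !is.na(predictors[[pv]])
      sp <- if (sum(ok) < 3L) {
        list(rho = NA_real_, p = NA_real_)
      } else {
        spearman_rho(predictors[[pv]][ok], m[[oc]][ok])
      }
      data.frame(predictor = pv, outcome = oc,
                 rho = sp$rho, p = sp$p, n = sum(ok))
    }))
  }))
  list(tests = tests, correlations = correlations, n_dropped = n_dropped)
}
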