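test_that("fixed-bin ranking follows the class table with clamping", {
  sch <- default_schemes()
  # relief: flat coast very exposed, high ground barely
  expect_equal(rank_fixed_bins(c(1, 15), sch$relief), c(5L, 1L))
  # wave: high wave power very exposed
  expect_equal(rank_fixed_bins(100, sch$wave), 5L)
  # boundary values fall in the lower-closed interval
  expect_equal(rank_fixed_bins(4, sch$relief), 3L)
  expect_equal(rank_fixed_bins(c(2, 8, 12), sch$relief), c(4L, 2L, 1L))
  expect_equal(rank_fixed_bins(c(0.75, 3, 18.75, 48), sch$wave),
               c(2L, 3L, 4L, 5L))
  # out-of-range values clamp to the extreme classes
  expect_equal(rank_fixed_bins(c(-1, 30), sch$relief), c(5L, 1L))
  expect_equal(rank_fixed_bins(c(-5, 300), sch$wave), c(1L, 5L))
  expect_error(rank_fixed_bins(NaN, sch$wave), "non-finite")
})

test_that("fixed-bin ranking is a monotone step function", {
  sch <- default_schemes()
  grid <- seq(-2, 30, by = 0.25)
  expect_true(all(diff(rank_fixed_bins(grid, sch$relief)) <= 0))
  expect_true(all(diff(rank_fixed_bins(grid, sch$wave)) >= 0))
})

test_that("quantile ranking cuts at the 20/40/60/80 percentiles, ties to lower", {
  r <- rank_quantile(1:100)
  expect_equal(r[c(10, 50, 95)], c(1L, 3L, 5L))
  expect_equal(rank_quantile(rep(7, 10)), rep(1L, 10))
  expect_error(rank_quantile(1:4), "at least 5")
  # heavy ties: agree with the sort-and-cut oracle
  v <- c(rep(1, 50), rep(2, 50))
  expect_equal(rank_quantile(v), quintile_oracle(v))
})

test_that("quantile rank classes match the oracle and stay near n/5", {
  set.seed(11)
  for (n in c(5, 23, 60, 200)) {
    v <- round(rnorm(n, 50, 20), 1)
    r <- rank_quantile(v)
    expect_equal(r, quintile_oracle(v))
    if (!anyDuplicated(v)) {
      expect_true(all(abs(table(factor(r, 1:5)) - n / 5) <= 1))
    }
  }
})

test_that("habitat rank takes the most protective habitat within range", {
  pt <- data.frame(point_id = 1L, x = 0, y = 0)
  ring_at <- function(d) cbind(x = c(d, d + 1000, d + 1000, d),
                               y = c(-500, -500, 500, 500))
  coral <- habitat_layer("coral_reef", list(ring_at(500)))
  sea <- habitat_layer("seagrass", list(ring_at(200)))
  expect_equal(habitat_rank(pt, list(coral), "S1_all"), 1L)
  expect_equal(habitat_rank(pt, list(sea), "S1_all"), 4L)
  expect_equal(habitat_rank(pt, list(coral, sea), "S1_all"), 1L)
  # coral out of its protective distance (2,000 m)
  far_coral <- habitat_layer("coral_reef", list(ring_at(2500)))
  expect_equal(habitat_rank(pt, list(far_coral), "S1_all"), 5L)
  # losing the only in-range habitat drops protection entirely
  expect_equal(habitat_rank(pt, list(coral), "S2_no_corals"), 5L)
  expect_equal(habitat_rank(pt, list(coral, sea), "S5_no_habitats"), 5L)
  expect_error(habitat_rank(pt, list(coral), "S9"), "unknown scenario")
})

test_that("shoreline change ranking maps accretion to low and erosion to high", {
  rates <- c(3, 2, 1.5, 1, 0, -1, -1.5, -2, -2.5, NA)
  expect_equal(shoreline_change_rank(rates),
               c(1L, 2L, 2L, 3L, 3L, 3L, 4L, 4L, 5L, 3L))
  expect_equal(shoreline_change_rank(NA_real_, missing_rank = 5L), 5L)
})

test_that("IE is the geometric mean of the six ranks", {
  expect_equal(compute_ie(rep(1L, 6)), 1)
  expect_equal(compute_ie(rep(5L, 6)), 5)
  expect_equal(compute_ie(c(1, 2, 3, 4, 5, 5)), 600^(1/6))
  expect_error(compute_ie(c(0, 1, 1, 1, 1, 1)), "1..5")
  expect_error(compute_ie(c(1, 2, 3)), "six ranks")

  set.seed(21)
  m <- matrix(sample(1:5, 600, replace = TRUE), ncol = 6)
  ie <- compute_ie(m)
  # oracle: exponent of the mean log rank
  expect_equal(ie, exp(rowMeans(log(m))), tolerance = 1e-12)
  expect_true(all(ie >= apply(m, 1, min) & ie <= apply(m, 1, max)))
  # permutation invariance
  expect_equal(compute_ie(m[, c(4, 2, 6, 1, 5, 3)]), ie)
})

test_that("IE classes round half-up and collapse to L/M/H", {
  out <- classify_ie(c(1.2, 3.5, 3.49, 1, 5, 4.5))
  expect_equal(out$ie_class, c(1L, 4L, 3L, 1L, 5L, 5L))
  expect_equal(out$lmh, c("L", "H", "M", "L", "H", "H"))
  expect_error(classify_ie(5.2), "\\[1, 5\\]")
})

test_that("only the habitat rank varies across scenarios", {
  pts <- flat_points(10)
  ring <- cbind(x = c(0, 3000, 3000, 0), y = c(-600, -600, -300, -300))
  coral <- habitat_layer("coral_reef", list(ring))
  res <- run_scenarios(pts, list(coral))
  wide <- split(res, res$scenario)
  for (sc in names(wide)) {
    expect_equal(wide[[sc]][, c("r_relief", "r_wave", "r_wind", "r_surge",
                                "r_shoreline_change")],
                 wide$S1_all[, c("r_relief", "r_wave", "r_wind", "r_surge",
                                 "r_shoreline_change")],
                 ignore_attr = TRUE)
  }
  expect_true(all(wide$S5_no_habitats$r_habitat == 5L))
  # points protected by coral only: S2 = S5 > S1 = S3 = S4
  prot <- wide$S1_all$r_habitat == 1L
  expect_true(any(prot))
  expect_equal(wide$S2_no_corals$ie[prot], wide$S5_no_habitats$ie[prot])
  expect_equal(wide$S1_all$ie[prot], wide$S3_no_mangrove$ie[prot])
  expect_equal(wide$S1_all$ie[prot], wide$S4_no_seagrasses$ie[prot])
  expect_true(all(wide$S2_no_corals$ie[prot] > wide$S1_all$ie[prot]))
  # unprotected points identical everywhere
  expect_equal(wide$S1_all$ie[!prot], wide$S5_no_habitats$ie[!prot])
})
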