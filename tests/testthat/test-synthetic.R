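test_that("regions are reproducible under seed and distinct across seeds", {
  a <- generate_region(small_region_spec(seed = 21))
  b <- generate_region(small_region_spec(seed = 21))
  expect_identical(a$points, b$points)
  expect_identical(a$census, b$census)
  expect_identical(a$events, b$events)
  expect_identical(a$grid, b$grid)
  c_ <- generate_region(small_region_spec(seed = 22))
  expect_false(identical(a$points$relief_m, c_$points$relief_m))
  expect_false(identical(a$census, c_$census))
})

test_that("region spec validates feasibility", {
  expect_error(region_spec(coast_length_km = 0.5, point_spacing_km = 1),
               "infeasible")
  expect_error(region_spec(habitat_coverage = c(coral_reef = 1.5,
                                                mangrove = 0, seagrass = 0)),
               "habitat_coverage")
  expect_error(generate_region(list()), "region_spec")
})

test_that("generated structure matches the spec: partition, fields, sandy runs", {
  spec <- small_region_spec(seed = 23)
  reg <- generate_region(spec)
  pts <- reg$points
  n_dist <- with(spec, n_countries * provinces_per_country *
                   districts_per_province)
  expect_equal(length(unique(pts$district_id)), n_dist)
  expect_true(all(table(pts$district_id) >= 1))
  expect_true(all(pts$relief_m > 0 & pts$wave_power > 0 &
                    pts$shelf_distance_m > 0))
  # sandy stretches: missing-rate fraction near 1 - sandy_fraction,
  # and contiguous (few runs relative to points)
  miss <- is.na(pts$shoreline_change_rate)
  expect_lt(abs(mean(miss) - (1 - spec$sandy_fraction)), 0.15)
  expect_lt(sum(rle(miss)$values), nrow(pts) / 8)
  # population grid: positive total, clustered toward the coast
  expect_gt(sum(reg$grid$counts), 0.99 * spec$population_total)
  expect_true(check_hierarchy(reg$hierarchy))
})

test_that("habitat coverage fractions are honoured within tolerance", {
  spec <- region_spec(seed = 24, coast_length_km = 500)
  reg <- generate_region(spec)
  for (layer in reg$habitats) {
    rank <- habitat_rank(reg$points, list(layer), layer$habitat_class)
    got <- mean(rank < 5L)
    expect_lt(abs(got - spec$habitat_coverage[[layer$habitat_class]]), 0.1)
  }
})

test_that("zero habitat coverage makes all scenarios identical", {
  spec <- small_region_spec(seed = 25,
                            habitat_coverage = c(coral_reef = 0, mangrove = 0,
                                                 seagrass = 0))
  reg <- generate_region(spec)
  ex <- run_scenarios(reg$points, reg$habitats)
  s1 <- ex[ex$scenario == "S1_all", -2]
  s5 <- ex[ex$scenario == "S5_no_habitats", -2]
  expect_equal(s1, s5, ignore_attr = TRUE)
})

test_that("event counts rise with true district exposure when slope > 0", {
  spec <- region_spec(seed = 26, coast_length_km = 1000, n_countries = 4,
                      provinces_per_country = 5, districts_per_province = 5)
  reg <- generate_region(spec)
  ex <- run_scenarios(reg$points, reg$habitats, scenarios = "S1_all")
  su <- summarize_admin(ex, reg$points, level = "district")
  m <- merge(su, reg$events, by = "unit_id")
  expect_gt(spearman_rho(m$pct_higher, m$n_events)$rho, 0)
})

test_that("worked-example fixtures are internally consistent", {
  fx <- fixture_table4()
  countries <- fx[fx$level == "country", ]
  region <- fx[fx$level == "region", ]
  expect_equal(sum(countries$n_points), region$n_points)
  expect_equal(sum(countries$h_s1), region$h_s1)
  expect_equal(sum(countries$h_s5), region$h_s5)
  expect_true(all(fx$h_s1 <= fx$h_s5))
  expect_true(all(fx$h_s5 <= fx$n_points))
  # each listed province nested in its country
  prov <- fx[fx$level == "province", ]
  par <- fx[match(prov$parent, fx$unit), ]
  expect_true(all(prov$n_points < par$n_points))
})
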