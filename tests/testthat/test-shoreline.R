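test_that("sample_coastline places points at arc-length multiples of the spacing", {
  straight <- cbind(x = c(0, 10000), y = c(0, 0))
  pts <- sample_coastline(straight, 1)
  expect_equal(nrow(pts), 11L)
  expect_equal(pts$x, seq(0, 10000, by = 1000))
  expect_equal(pts$y, rep(0, 11))

  # square-wave coast, 5.5 km total: 6 points, last at arc position 5.0 km
  sq <- square_wave_polyline()
  pts <- sample_coastline(sq, 1)
  expect_equal(nrow(pts), 6L)
  # cumulative arc-length oracle: 5 km along lands on vertex (2000, 1000)
  expect_equal(c(pts$x[6], pts$y[6]), c(2000, 1000))
  # spacing longer than the coast: single point at the start
  pts1 <- sample_coastline(sq, 10)
  expect_equal(nrow(pts1), 1L)
  expect_equal(c(pts1$x, pts1$y), c(0, 0))
})

test_that("sample_coastline rejects degenerate input", {
  expect_error(sample_coastline(cbind(0, 0)), "2 vertices")
  expect_error(sample_coastline(cbind(c(0, 0), c(0, 0))), "zero total length")
  expect_error(sample_coastline(cbind(c(0, 1), c(0, 1)), spacing_km = 0),
               "positive")
})

test_that("sample_coastline is invariant to vertex densification", {
  set.seed(4)
  x <- cumsum(runif(20, 500, 2000))
  y <- cumsum(rnorm(20, 0, 300))
  line <- cbind(x = c(0, x), y = c(0, y))
  dense <- matrix(nrow = 0, ncol = 2)
  for (i in seq_len(nrow(line) - 1)) {
    mid <- (line[i, ] + line[i + 1, ]) / 2
    dense <- rbind(dense, line[i, ], mid)
  }
  dense <- rbind(dense, line[nrow(line), ])
  a <- sample_coastline(line, 1)
  b <- sample_coastline(dense, 1)
  expect_equal(nrow(a), nrow(b))
  expect_lt(max(abs(a$x - b$x), abs(a$y - b$y)), 1e-3)  # 1e-6 km
})

test_that("attribute_points matches a winding-number oracle and tie-breaks by id", {
  reg <- three_district_region()
  set.seed(7)
  pts <- data.frame(point_id = 1:60,
                    x = runif(60, 0, 3e4), y = runif(60, -4e4, 4e4),
                    spacing_km = 1)
  out <- attribute_points(pts, reg$polygons, reg$hierarchy)
  for (i in seq_len(nrow(out))) {
    oracle <- NA_character_
    for (p in reg$polygons) {
      if (pip_winding(out$x[i], out$y[i], p$coords)) { oracle <- p$unit_id; break }
    }
    expect_equal(out$district_id[i], oracle)
  }
  expect_equal(out$province_id[out$district_id == "D1"][1], "P1")
  expect_equal(out$country_id[1], "C1")

  # boundary point: shared edge of D1|D2 at x = 10 km -> smaller unit id
  bpt <- data.frame(point_id = 1L, x = 1e4, y = 0, spacing_km = 1)
  expect_equal(attribute_points(bpt, reg$polygons, reg$hierarchy)$district_id,
               "D1")
  # a point in no polygon errors, naming the point
  off <- data.frame(point_id = 99L, x = 9e5, y = 0, spacing_km = 1)
  expect_error(attribute_points(off, reg$polygons, reg$hierarchy), "99")
})

test_that("coastline_length sums spacing over the selected points", {
  pts <- data.frame(point_id = 1:10, spacing_km = 1)
  expect_equal(coastline_length(pts, c(rep(TRUE, 2), rep(FALSE, 8))), 2)
  expect_equal(coastline_length(pts, rep(FALSE, 10)), 0)
  expect_equal(coastline_length(pts), 10)
})

test_that("coastline length is conserved across admin levels", {
  reg <- generate_region(small_region_spec())
  pts <- reg$points
  total <- coastline_length(pts)
  by_d <- tapply(pts$spacing_km, pts$district_id, sum)
  by_p <- tapply(pts$spacing_km, pts$province_id, sum)
  by_c <- tapply(pts$spacing_km, pts$country_id, sum)
  expect_equal(sum(by_d), total)
  expect_equal(sum(by_p), total)
  expect_equal(sum(by_c), total)
})

test_that("check_hierarchy flags broken trees", {
  reg <- three_district_region()
  expect_true(check_hierarchy(reg$hierarchy))
  broken <- reg$hierarchy
  broken$parent_id[broken$unit_id == "D3"] <- "NOPE"
  expect_error(check_hierarchy(broken), "D3")
})
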