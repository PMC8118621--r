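test_that("exposed classification is inclusive at the threshold", {
  expect_true(classify_exposed(55, 50))
  expect_false(classify_exposed(10, 20))
  expect_true(classify_exposed(50, 50))
  expect_error(classify_exposed(50, 0), "strictly between")
  expect_error(classify_exposed(50, 100), "strictly between")
})

test_that("Mann-Whitney U: exact small-sample p by enumeration", {
  mw <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$u, 0)
  expect_equal(mw$p, 0.1)  # 2 * 1/20 over all C(6,3) rank assignments
  expect_equal(mw$method, "exact")
  # oracle: base wilcox.test exact two-sided p
  w <- wilcox.test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$p, w$p.value)
  expect_equal(mw$u, unname(w$statistic))

  tied <- mann_whitney_u(c(1, 2), c(1, 2))
  expect_equal(tied$u, 2)  # = n_a * n_b / 2 by symmetry
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})

test_that("Mann-Whitney U + U' = n_a * n_b on arbitrary inputs", {
  set.seed(41)
  for (i in 1:20) {
    na <- sample(2:12, 1); nb <- sample(2:12, 1)
    a <- rpois(na, 3); b <- rpois(nb, 5)
    u_ab <- mann_whitney_u(a, b)$u
    u_ba <- mann_whitney_u(b, a)$u
    expect_equal(u_ab + u_ba, na * nb)
  }
})

test_that("Mann-Whitney normal approximation matches the reference test", {
  set.seed(42)
  a <- rnorm(30, 0, 1); b <- rnorm(30, 0.6, 1)  # untied
  mw <- mann_whitney_u(a, b)
  w <- wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(mw$method, "normal")
  expect_equal(mw$u, unname(w$statistic))
  expect_equal(mw$p, w$p.value, tolerance = 1e-6)
  # tied count data against the same tie-corrected reference
  a <- rpois(25, 2); b <- rpois(35, 3)
  mw <- mann_whitney_u(a, b)
  w <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
  expect_equal(mw$p, w$p.value, tolerance = 1e-6)
})

test_that("Spearman rho: midranks, closed form when untied, t-approx p", {
  expect_equal(spearman_rho(1:3, c(1, 4, 9))$rho, 1)
  expect_equal(spearman_rho(1:3, c(3, 2, 1))$rho, -1)
  set.seed(43)
  x <- sample(1:50); y <- sample(1:50)  # untied
  sp <- spearman_rho(x, y)
  d <- rank(x) - rank(y)
  expect_equal(sp$rho, 1 - 6 * sum(d^2) / (50 * (50^2 - 1)))
  ct <- cor.test(x, y, method = "spearman", exact = FALSE)
  expect_equal(sp$rho, unname(ct$estimate))
  expect_equal(sp$p, ct$p.value, tolerance = 1e-9)
  # ties: rho equals Pearson on midranks
  xt <- rpois(40, 2); yt <- rpois(40, 3)
  expect_equal(spearman_rho(xt, yt)$rho, cor(rank(xt), rank(yt)))
  # degenerate input flagged rather than erroring
  dg <- spearman_rho(rep(1, 5), 1:5)
  expect_true(dg$degenerate)
  expect_true(is.na(dg$rho))
  expect_error(spearman_rho(1:3, 1:4), "equal length")
})

test_that("run_validation tests events across thresholds and correlates indices", {
  set.seed(44)
  n <- 40
  su <- data.frame(unit_id = sprintf("D%02d", 1:n),
                   pct_higher = runif(n, 0, 100))
  ev <- draw_events(su$unit_id, su$pct_higher)
  iv <- data.frame(unit_id = su$unit_id,
                   ivcc = 2 + 8 * su$pct_higher / 100)
  out <- run_validation(su, ev, ivcc = iv)
  expect_equal(nrow(out$tests), 8L)  # 4 thresholds x 2 outcomes
  expect_equal(sort(unique(out$tests$threshold_pct)), c(20, 25, 30, 50))
  expect_equal(out$tests$n_exposed + out$tests$n_less, rep(n, 8))
  expect_equal(nrow(out$correlations), 4L)
  expect_true(all(abs(out$correlations$rho) <= 1))

  # unmatched units dropped with a message
  ev2 <- rbind(ev, data.frame(unit_id = "ZZZ", n_events = 1,
                              n_fatal_events = 0))
  expect_message(out2 <- run_validation(su, ev2), "dropped")
  expect_equal(out2$n_dropped, 1L)
  expect_error(run_validation(su, ev[0, ]), "no overlapping units")
  bad <- ev; bad$n_fatal_events <- bad$n_events + 1
  expect_error(run_validation(su, bad), "cannot exceed")
})

test_that("degenerate two-unit validation still returns a defined wide p", {
  su <- data.frame(unit_id = c("A", "B"), pct_higher = c(10, 80))
  ev <- data.frame(unit_id = c("A", "B"), n_events = c(1, 5),
                   n_fatal_events = c(0, 2))
  out <- run_validation(su, ev, thresholds = 50, ivcc = NULL)
  expect_equal(out$tests$n_exposed, rep(1L, 2))
  expect_true(all(out$tests$p >= 0.5))  # n = 1 per group cannot be significant
})
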