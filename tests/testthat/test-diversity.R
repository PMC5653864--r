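ts5 <- sim_timescale(100, 0, 5)

test_that("range-through counts match hand enumeration", {
  r <- strat_ranges(c("a", "b", "c", "d", "e"),
                    first_bin = c(1, 1, 2, 4, 5),
                    last_bin = c(3, 2, 4, 4, 5), ts = ts5)
  counts <- range_through_counts(r, ts5)
  expect_equal(unname(counts), c(2, 3, 2, 2, 1))
  one <- strat_ranges("a", 1, 3)
  expect_equal(unname(range_through_counts(one, ts5)), c(1, 1, 1, 0, 0))
  bad <- strat_ranges("x", 1, 9)
  expect_error(range_through_counts(bad, ts5), "outside")
})

test_that("widening a range never decreases any count", {
  set.seed(13)
  for (i in 1:10) {
    f <- sample(1:4, 8, TRUE)
    l <- pmin(f + sample(0:3, 8, TRUE), 5)
    r <- strat_ranges(paste0("t", 1:8), f, l)
    c1 <- range_through_counts(r, ts5)
    j <- sample(8, 1)
    r$first_bin[j] <- max(1L, r$first_bin[j] - 1L)
    r$last_bin[j] <- min(5L, r$last_bin[j] + 1L)
    c2 <- range_through_counts(r, ts5)
    expect_true(all(c2 >= c1))
  }
})

test_that("bootstrap count intervals are seeded and contain the bulk", {
  r <- strat_ranges(paste0("t", 1:12), sample(1:3, 12, TRUE),
                    rep(5, 12))
  b1 <- bootstrap_counts(r, ts5, n_boot = 300, seed = 5)
  b2 <- bootstrap_counts(r, ts5, n_boot = 300, seed = 5)
  expect_identical(b1, b2)
  expect_true(all(b1$lo <= b1$hi))
  expect_true(all(b1$count >= 0))
  # dominant bin: the point estimate sits inside its interval
  expect_true(all(b1$count[5] >= b1$lo[5] & b1$count[5] <= b1$hi[5]))
})

test_that("bootstrap coverage of the true count is near nominal", {
  # simulate range sets, check the 95% interval covers the full-data count
  set.seed(14)
  hits <- 0; tries <- 0
  for (i in 1:40) {
    f <- sample(1:4, 20, TRUE)
    r <- strat_ranges(paste0("t", 1:20), f, pmin(f + sample(0:2, 20, TRUE), 5))
    truth <- range_through_counts(r, ts5)
    b <- bootstrap_counts(r, ts5, n_boot = 200, seed = i)
    for (bin in 1:5) {
      if (truth[bin] == 0) next
      tries <- tries + 1
      if (truth[bin] >= b$lo[bin] && truth[bin] <= b$hi[bin])
        hits <- hits + 1
    }
  }
  expect_gt(hits / tries, 0.9)
})

test_that("range standardization maps the series onto [0, 1] exactly", {
  expect_equal(range_standardize(c(1, 2, 4)), c(0, 1 / 3, 1))
  expect_equal(range_standardize(c(0, 0.4, 1)), c(0, 0.4, 1))
  set.seed(15)
  x <- rnorm(20)
  z <- range_standardize(x)
  expect_equal(min(z), 0)
  expect_equal(max(z), 1)
  expect_error(range_standardize(rep(2, 4)), "constant")
})

test_that("the trajectory identifies on-line, above and below bins", {
  counts <- setNames(c(2, 5, 10, 20, 40), ts5$name)
  disp <- data.frame(bin = ts5$name,
                     disparity = range_standardize(log(counts)))
  tr <- dd_trajectory(counts, disp)
  expect_equal(tr$deviation, rep(0, 5))
  expect_true(all(tr$position == "on"))
  # doubling disparity in one interior bin raises that deviation
  disp2 <- disp
  disp2$disparity[3] <- disp2$disparity[3] * 2
  tr2 <- dd_trajectory(counts, disp2)
  expect_gt(tr2$deviation[3], tr$deviation[3])
  # invariance to multiplying all diversities by a constant
  tr3 <- dd_trajectory(counts * 7, disp)
  expect_equal(tr3$deviation, tr$deviation)
})

test_that("bins without usable data are excluded and reported", {
  counts <- setNames(c(0, 5, 10, 20, 40), ts5$name)
  disp <- data.frame(bin = ts5$name, disparity = c(0.1, NA, 0.3, 0.5, 0.9))
  tr <- dd_trajectory(counts, disp)
  expect_equal(attr(tr, "excluded_bins"), c("bin01", "bin02"))
  expect_equal(nrow(tr), 3L)
})

test_that("paired bootstrap deviations are seeded and ordered", {
  m <- rand_matrix(14, 12, p_miss = 0.1, seed = 16)
  g <- gower_distance(m)
  f <- sample(1:3, 14, TRUE)
  r <- strat_ranges(rownames(m), f, pmin(f + 2, 5), ts = ts5)
  mem <- bin_membership(r, ts5)
  div <- bootstrap_counts(r, ts5, n_boot = 100, seed = 2)
  disp <- disparity_series(g, mem, n_boot = 100, seed = 3)
  t1 <- dd_trajectory(div, disp, ranges = r, ts = ts5, d = g,
                      membership = mem, n_boot = 150, seed = 4)
  t2 <- dd_trajectory(div, disp, ranges = r, ts = ts5, d = g,
                      membership = mem, n_boot = 150, seed = 4)
  expect_identical(t1, t2)
  expect_true(all(t1$dev_lo <= t1$dev_hi))
  expect_true(all(t1$position %in% c("above", "on", "below")))
})
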