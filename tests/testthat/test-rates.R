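test_that("branch changes follow the endpoint-comparison rules", {
  # char 1 changes somewhere along the tree; char 2 is missing at tip B,
  # so it is comparable on every branch except B's terminal branch
  m <- character_matrix(rbind(A = c("0", "0"), B = c("1", NA),
                              Z = c("0", "1")))
  t3 <- time_tree(ape::read.tree(text = "((A:1,B:1):1,Z:2);"),
                  youngest_tip_age = 0)
  asr <- fit_mk_asr(t3, m)
  bc <- count_branch_changes(t3, m, asr)
  term_B <- which(bc$child == which(t3$phy$tip.label == "B"))
  expect_equal(bc$n_comparable[term_B], 1)  # char 2 missing at B
  expect_equal(bc$p_comp[term_B], 0.5)
  internal <- bc$child > length(t3$phy$tip.label)
  expect_true(all(bc$n_comparable[internal] == 2))  # internals always scored
})

test_that("branch rates implement changes / (time x comparable characters)", {
  bc <- data.frame(parent = 1, child = 2, duration = 5, n_comparable = 6,
                   changes = 3, p_comp = 0.6)
  r <- branch_rates(bc)
  # per-matrix units: rate x n_characters = C / (duration x p)
  expect_equal(as.numeric(r) * 10, 3 / (5 * 0.6))
  bc0 <- data.frame(duration = c(0, 4), n_comparable = c(5, 0),
                    changes = c(1, 0))
  r0 <- branch_rates(bc0)
  expect_true(all(is.na(r0)))
  expect_equal(attr(r0, "n_undefined"), 2L)
  # algebraic inversion on random tables
  set.seed(40)
  bc2 <- data.frame(duration = runif(50, 0.1, 10),
                    n_comparable = sample(1:20, 50, TRUE),
                    changes = rpois(50, 2))
  r2 <- branch_rates(bc2)
  expect_equal(as.numeric(r2) * bc2$duration * bc2$n_comparable,
               as.numeric(bc2$changes))
})

test_that("bin allocation conserves changes and opportunity", {
  for (seed in 1:5) {
    t <- rand_ttree(12, seed = seed)
    m <- rand_matrix(12, 8, p_miss = 0.2, seed = seed + 50)
    asr <- fit_mk_asr(t, m)
    bc <- count_branch_changes(t, m, asr)
    ra <- root_age(t)
    ts <- timescale(letters[1:4], ra * c(4, 3, 2, 1) / 4, ra * c(3, 2, 1, 0) / 4)
    for (alloc in c("proportional", "midpoint")) {
      seg <- partition_by_bins(t, bc, ts, allocation = alloc)
      expect_equal(sum(seg$changes) + attr(seg, "dropped_changes"),
                   sum(bc$changes), tolerance = 1e-9)
      expect_equal(sum(seg$opportunity),
                   sum(bc$duration * bc$n_comparable), tolerance = 1e-9)
    }
  }
})

test_that("proportional allocation splits changes by segment duration", {
  phy <- ape::read.tree(text = "(A:10,B:10);")
  t <- time_tree(phy, youngest_tip_age = 0)
  ts <- timescale(c("old", "young"), c(10, 5), c(5, 0))
  bc <- data.frame(parent = c(3, 3), child = c(1, 2), duration = c(10, 10),
                   n_comparable = c(4, 4), changes = c(2, 0))
  seg <- partition_by_bins(t, bc, ts, allocation = "proportional")
  expect_equal(seg$changes, c(1, 1))  # 50/50 straddle
  # fully contained branch: everything to its bin
  ts2 <- timescale(c("all"), 10, 0)
  seg2 <- partition_by_bins(t, bc, ts2)
  expect_equal(seg2$changes, 2)
  expect_equal(seg2$opportunity, 2 * 10 * 4)
})

test_that("the bin LRT matches brute-force likelihood maximisation", {
  # null identity: equal empirical rates
  eq <- bin_lrt(5, 10, 15, 30)
  expect_equal(eq$statistic, 0, tolerance = 1e-12)
  expect_equal(eq$p, 1)
  # the spec-style instance and 100 random ones, fractional counts included
  set.seed(60)
  inst <- rbind(c(20, 10, 10, 10),
                cbind(runif(100, 0.5, 40), runif(100, 1, 20),
                      runif(100, 0.5, 80), runif(100, 1, 40)))
  for (i in seq_len(nrow(inst))) {
    z <- inst[i, ]
    got <- bin_lrt(z[1], z[2], z[3], z[4])
    expect_equal(got$statistic, oracle_lrt(z[1], z[2], z[3], z[4]),
                 tolerance = 1e-6)
  }
  # direction reflects the rate comparison
  expect_equal(bin_lrt(20, 10, 10, 10)$direction, "high")
  expect_equal(bin_lrt(1, 10, 10, 10)$direction, "low")
  # undefined opportunity is NA, never dropped silently
  expect_true(is.na(bin_lrt(0, 0, 10, 10)$p))
})

test_that("the LRT statistic grows with the focal count at fixed opportunity", {
  stats <- vapply(seq(10, 40, by = 2), function(C)
    bin_lrt(C, 10, 10, 10)$statistic, numeric(1))
  expect_true(all(diff(stats) > 0))
})

test_that("Benjamini-Hochberg follows the step-up rule", {
  expect_equal(bh_adjust(0.03)$p_adj, 0.03)
  r <- bh_adjust(c(0.001, 0.02, 0.03), alpha = 0.01)
  expect_equal(sum(r$reject), 1L)
  expect_equal(r$p_adj[1], 0.003)
  tie <- bh_adjust(rep(0.02, 4), alpha = 0.05)
  expect_true(all(tie$p_adj == 0.02))
  expect_true(all(tie$reject))
})

test_that("aggregation applies the strict >threshold rule per direction", {
  fake <- function(n_high, n_low, n = 100) {
    data.frame(bin = "b1", tree = seq_len(n),
               rate = runif(n), p = 0.5,
               p_adj = 0.5, direction = rep(c("high", "low"),
                                            c(n_high, n - n_high)),
               significant = seq_len(n) <= n_high | seq_len(n) >
                 (n - n_low))
  }
  expect_equal(aggregate_over_trees(fake(60, 0))$class, "HIGH")
  expect_equal(aggregate_over_trees(fake(55, 0))$class, "BACKGROUND")
  d <- fake(30, 30)
  expect_equal(aggregate_over_trees(d)$class, "BACKGROUND")
  s <- aggregate_over_trees(fake(60, 0))
  expect_equal(s$frac_high, 0.6)
  expect_true(s$lo95 <= s$median_rate && s$median_rate <= s$hi95)
})

test_that("rate trends recover monotone series and match the rank formula", {
  mids <- c(90, 70, 50, 30, 10)
  tr <- rate_trend(c(5, 4, 3, 2, 1), mids)
  expect_equal(tr$rho, -1)
  expect_lt(tr$p, 0.05)
  set.seed(70)
  for (i in 1:5) {
    y <- sample(seq(0.1, 0.9, length.out = 7))
    tr2 <- rate_trend(y, seq(70, 10, by = -10))
    expect_equal(tr2$rho, oracle_spearman(-seq(70, 10, by = -10), y),
                 tolerance = 1e-12)
  }
  expect_true(is.na(rate_trend(rep(1, 5), mids)$rho))
  expect_error(rate_trend(c(1, 2, NA, NA, NA), mids), "at least 4")
})

test_that("inferred total changes bound parsimony steps from below", {
  skip_if_not_installed("phangorn")
  t <- rand_ttree(10, seed = 80)
  m <- rand_matrix(10, 12, k_range = 2, p_miss = 0, seed = 81)
  asr <- fit_mk_asr(t, m)
  bc <- count_branch_changes(t, m, asr)
  dat <- lapply(seq_len(nrow(m)), function(i) unclass(m)[i, asr$characters])
  names(dat) <- rownames(m)
  pd <- phangorn::phyDat(do.call(rbind, dat), type = "USER",
                         levels = c("0", "1"))
  steps <- phangorn::fitch(t$phy, pd)
  expect_gte(sum(bc$changes), steps)
})

test_that("rate_analysis aggregates per-tree tables deterministically", {
  s <- sim_scenario(birth = 0.08, death = 0.02, origin_ma = 80,
                    timescale = sim_timescale(80, 20, 4), n_characters = 12,
                    min_tips = 8, max_tips = 30, multipliers = rep(1, 4),
                    max_retries = 500)
  cl <- simulate_clade(s, n_trees = 4, age_jitter_sd = 1, seed = 90)
  r1 <- rate_analysis(cl$trees, cl$matrix, s$timescale)
  r2 <- rate_analysis(cl$trees, cl$matrix, s$timescale)
  expect_identical(r1$summary, r2$summary)
  expect_equal(nrow(r1$summary), 4L)
  # bins the tree sample never reaches stay NA rather than being dropped
  expect_true(all(is.na(r1$summary$class) |
                    r1$summary$class %in% c("HIGH", "LOW", "BACKGROUND")))
  expect_true(all(r1$per_tree$p_adj >= r1$per_tree$p - 1e-12, na.rm = TRUE))
})
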