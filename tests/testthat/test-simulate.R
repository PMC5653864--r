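small_scenario <- function(...) {
  args <- list(birth = 0.1, death = 0.03,
               origin_ma = 100, timescale = sim_timescale(100, 20, 4),
               n_characters = 10, min_tips = 5, max_tips = 60,
               target_changes_per_character = 2, multipliers = rep(1, 4),
               max_retries = 500)
  args[names(list(...))] <- list(...)
  do.call(sim_scenario, args)
}

test_that("pure-birth clades stopped at the present are ultrametric", {
  s <- small_scenario(death = 0, birth = 0.05)
  t <- simulate_tree(s, seed = 4)
  expect_true(all(abs(tip_ages(t) - 20) < 1e-9))
})

test_that("tree simulation is reproducible and respects the size window", {
  s <- small_scenario(min_tips = 6, max_tips = 25)
  t1 <- simulate_tree(s, seed = 10)
  t2 <- simulate_tree(s, seed = 10)
  expect_identical(ape::write.tree(t1$phy), ape::write.tree(t2$phy))
  expect_identical(t1$ages, t2$ages)
  for (seed in 1:5) {
    t <- simulate_tree(s, seed = seed)
    expect_gte(n_tips(t), 6)
    expect_lte(n_tips(t), 25)
    # survival conditioning: the clade reaches the end of the timescale
    expect_lt(min(tip_ages(t)), 20 + 1e-9)
    expect_true(all(branch_durations(t) >= 0))
  }
})

test_that("mean tip count agrees with an independent naive birth-death simulator", {
  # no conditioning beyond >= 2 tips so the two simulators are comparable
  s <- small_scenario(birth = 0.2, death = 0.1, origin_ma = 60,
                      timescale = sim_timescale(60, 0, 2),
                      multipliers = c(1, 1),
                      min_tips = 4, max_tips = 10000)
  naive_tips <- function(b, d, T) {
    # event-by-event simulation tracking only lineage birth times
    tips <- 0; survivors <- 0
    stack <- c(0)
    while (length(stack)) {
      t0 <- stack[1]; stack <- stack[-1]
      w <- rexp(1, b + d)
      if (t0 + w >= T) { tips <- tips + 1; survivors <- survivors + 1; next }
      if (runif(1) < b / (b + d)) stack <- c(stack, t0 + w, t0 + w)
      else tips <- tips + 1
    }
    c(tips, survivors)
  }
  set.seed(77)
  ref <- replicate(800, naive_tips(0.2, 0.1, 60))
  # match the package's acceptance rule: >= 4 tips and clade survival
  ref <- ref[1, ref[1, ] >= 4 & ref[2, ] > 0]
  pkg <- vapply(1:250, function(i) {
    n_tips(simulate_tree(s, seed = 5000 + i))
  }, numeric(1))
  se <- sqrt(var(ref) / length(ref) + var(pkg) / length(pkg))
  expect_lt(abs(mean(pkg) - mean(ref)), 3 * se)
})

test_that("a zero base rate leaves every tip in the root state", {
  s <- small_scenario(r0 = 0)
  t <- simulate_tree(s, seed = 2)
  sim <- simulate_characters(t, s, seed = 3)
  expect_equal(sim$ledger$total_changes, 0)
  expect_true(all(apply(unclass(sim$matrix), 2,
                        function(col) length(unique(col)) == 1L)))
})

test_that("the truth ledger conserves change counts exactly", {
  s <- small_scenario()
  t <- simulate_tree(s, seed = 6)
  sim <- simulate_characters(t, s, seed = 7)
  led <- sim$ledger
  expect_identical(sum(led$per_branch), led$total_changes)
  expect_identical(sum(led$per_bin$changes), led$total_changes)
  expect_equal(sum(led$per_bin$branch_time_myr), sum(branch_durations(t)),
               tolerance = 1e-9)
  # bit-reproducible under the seed
  sim2 <- simulate_characters(t, s, seed = 7)
  expect_identical(unclass(sim2$matrix)[, ], unclass(sim$matrix)[, ])
  expect_identical(sim2$ledger$per_branch, led$per_branch)
})

test_that("realized change totals match the Poisson expectation", {
  s <- small_scenario(r0 = 0.004, n_characters = 20)
  t <- simulate_tree(s, seed = 8)
  expected <- 0.004 * 20 * sum(branch_durations(t))
  tot <- vapply(1:120, function(i)
    simulate_characters(t, s, seed = 100 + i)$ledger$total_changes,
    numeric(1))
  se <- sd(tot) / sqrt(length(tot))
  expect_lt(abs(mean(tot) - expected), 3 * se)
})

test_that("per-bin multipliers scale realized per-bin rates", {
  s <- small_scenario(multipliers = c(1, 1, 3, 1), r0 = 0.004,
                      n_characters = 30)
  t <- simulate_tree(s, seed = 12)
  tot <- Reduce(`+`, lapply(1:60, function(i) {
    led <- simulate_characters(t, s, seed = 200 + i)$ledger
    cbind(led$per_bin$changes, led$per_bin$opportunity)
  }))
  focal <- tot[3, 1] / tot[3, 2]
  rest <- sum(tot[-3, 1]) / sum(tot[-3, 2])
  ratio <- focal / rest
  expect_gt(ratio, 2.4)
  expect_lt(ratio, 3.6)
})

test_that("single-branch transition frequencies match the closed form", {
  # two tips, one informative branch of duration d; the zero-length tip
  # pins the root state
  phy <- ape::read.tree(text = "(A:0,B:12);")
  t <- time_tree(phy, youngest_tip_age = 0)
  k <- 3; r <- 0.05; d <- 12
  s <- sim_scenario(birth = 0.1, death = 0, origin_ma = 100,
                    timescale = sim_timescale(100, 0, 2),
                    n_characters = 400, state_range = k, r0 = r,
                    multipliers = c(1, 1), min_tips = 4)
  same <- unlist(lapply(1:25, function(i) {
    m <- simulate_characters(t, s, seed = 300 + i)$matrix
    unclass(m)["A", ] == unclass(m)["B", ]
  }))
  p_hat <- mean(same)
  p_exp <- 1 / k + (k - 1) / k * exp(-k * r * d / (k - 1))
  se <- sqrt(p_exp * (1 - p_exp) / length(same))
  expect_lt(abs(p_hat - p_exp), 3 * se)
})

test_that("missing-data injection hits its target rate", {
  m <- rand_matrix(92, 82, p_miss = 0, seed = 1)
  expect_identical(inject_missing(m, 0, seed = 1)[, ], m[, ])
  expect_true(all(is.na(inject_missing(m, 1, seed = 1))))
  m2 <- inject_missing(m, 0.2, seed = 2)
  frac <- mean(is.na(m2))
  bounds <- qbinom(c(0.005, 0.995), length(m), 0.2) / length(m)
  expect_gte(frac, bounds[1])
  expect_lte(frac, bounds[2])
})

test_that("posterior-like jitter preserves topology, monotonicity and tip ages", {
  s <- small_scenario()
  t <- simulate_tree(s, seed = 20)
  same <- make_posterior_like(t, 3, age_jitter_sd = 0, seed = 1)
  expect_identical(same[[1]]$ages, t$ages)
  expect_identical(same[[3]]$ages, t$ages)
  jit <- make_posterior_like(t, 50, age_jitter_sd = 3, seed = 2,
                             max_root_age = s$origin_ma)
  for (tt in jit[1:10]) {
    e <- tt$phy$edge
    expect_true(all(tt$ages[e[, 1]] - tt$ages[e[, 2]] >= -1e-9))
    expect_identical(tt$phy$edge, t$phy$edge)
  }
  ntip <- n_tips(t)
  expect_equal(unique(lapply(jit, function(tt) tt$ages[seq_len(ntip)])),
               list(t$ages[seq_len(ntip)]))
})

test_that("jittered root ages are unbiased when truncation rarely binds", {
  s <- small_scenario()
  t <- simulate_tree(s, seed = 21)
  jit <- make_posterior_like(t, 1000, age_jitter_sd = 1, seed = 3)
  roots <- vapply(jit, root_age, numeric(1))
  se <- sd(roots) / sqrt(length(roots))
  expect_lt(abs(mean(roots) - root_age(t)), 3 * se)
})

test_that("simulated ranges reference bins covered by the terminal branch", {
  s <- small_scenario()
  t <- simulate_tree(s, seed = 22)
  r <- sim_ranges(t, s$timescale)
  expect_true(all(r$first_bin <= r$last_bin))
  expect_equal(r$last_bin, unname(bin_index(s$timescale, tip_ages(t))))
})
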