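test_that("item selection obeys dominance and breaks ties by index", {
  # two identical items: the lower index wins
  d <- c(1, 0, -1)
  bk <- item_bank(c(1.5, 1.5), rbind(d, d), si_item = NA)
  expect_equal(select_next_item(bk, 1:2, theta = 0, rule = "MI"), 1)
  g <- quad_grid(1)
  post <- prior_weights(g, diag(1))
  expect_equal(select_next_item(bk, 1:2, posterior = post, rule = "MPWI",
                                grid = g), 1)

  # a uniformly dominating item is selected under every rule
  dom <- item_bank(c(0.5, 3, 0.7),
                   rbind(c(1, 0, -1), c(1, 0, -1), c(1.2, 0, -1.3)),
                   si_item = NA)
  expect_equal(select_next_item(dom, 1:3, theta = 0.4, rule = "MI"), 2)
  expect_equal(select_next_item(dom, 1:3, theta = -1, rule = "trace"), 2)
  expect_equal(select_next_item(dom, 1:3, posterior = post, rule = "MPWI",
                                grid = g), 2)
  expect_error(select_next_item(dom, integer(0)), "available")
})

test_that("MPWI matches brute-force posterior-weighted integration", {
  bk <- toy_bank()
  g <- quad_grid(1)
  # posterior after observing item 2 answered in category 3
  x <- seq(-6, 6, length.out = 20001)
  w <- dnorm(x) * vapply(x, function(xx)
    oracle_cat_probs(bk$slopes[2], bk$intercepts[2, ], xx)[4], 0)
  w <- w / sum(w)
  crit <- vapply(c(1, 3), function(i)
    sum(w * vapply(x, function(xx)
      oracle_info(bk$slopes[i], bk$intercepts[i, ], xx), 0)), 0)
  brute_choice <- c(1, 3)[which.max(crit)]

  pre <- cat_precompute(bk, diag(1), g)
  post <- pre$prior * pre$pnode[[2]][, 4]
  got <- select_next_item(bk, c(1, 3), posterior = post, rule = "MPWI",
                          grid = g, info_grid = pre$info_grid)
  expect_equal(got, brute_choice)
})

test_that("termination rule compares successive trait estimates to delta", {
  cfg <- cat_config(delta = 0.05)
  expect_true(check_termination(rbind(0.30, 0.27), cfg, 8))   # |d| = 0.03
  expect_false(check_termination(rbind(0.5, 0.6), cfg, 8))    # |d| = 0.10
  expect_true(check_termination(matrix(rnorm(10), 10, 1),
                                cat_config(max_items = 10), 0))
  expect_false(check_termination(matrix(0.3, 1, 1), cfg, 9))  # < min_items
  # multi-factor max norm
  traj <- rbind(c(0.2, 0.5), c(0.23, 0.58))
  expect_false(check_termination(traj, cfg, 5))
  expect_true(check_termination(traj, cat_config(delta = 0.09), 5))
})

test_that("delta = Inf administers exactly min_items", {
  bank <- generate_item_bank(factors = 1, seed = 31)
  tab <- generate_cohort(cohort_spec(n = 40, seed = 32), bank)
  it <- as.matrix(tab[paste0("item", 1:10)])
  sim <- simulate_cat(it, bank, config = cat_config(delta = Inf))
  expect_true(all(sim$results$n_items == 2))
  sim3 <- simulate_cat(it, bank,
                       config = cat_config(delta = Inf, min_items = 3))
  expect_true(all(sim3$results$n_items == 3))
})

test_that("administering the full bank reproduces the full-test EAP exactly", {
  bank <- generate_item_bank(factors = 1, seed = 33)
  tab <- generate_cohort(cohort_spec(n = 25, seed = 34), bank)
  it <- as.matrix(tab[paste0("item", 1:10)])
  cfg <- cat_config(delta = 1e-12, min_items = 10)
  full <- eap_score(bank, it)
  for (j in c(1, 7, 25)) {
    r <- run_cat(it[j, ], bank, config = cfg)
    expect_equal(r$n_administered, 10)
    expect_equal(r$theta, full$theta[j, 1], tolerance = 1e-12)
    expect_equal(r$se, full$se[j, 1], tolerance = 1e-12)
  }
})

test_that("runs are deterministic, never repeat items or alter responses", {
  bank <- generate_item_bank(factors = 1, seed = 35)
  tab <- generate_cohort(cohort_spec(n = 30, seed = 36), bank)
  it <- as.matrix(tab[paste0("item", 1:10)])
  for (j in c(2, 9, 30)) {
    r1 <- run_cat(it[j, ], bank)
    r2 <- run_cat(it[j, ], bank)
    expect_identical(r1, r2)
    expect_equal(anyDuplicated(r1$administered), 0)
    expect_identical(r1$responses_seen, unname(it[j, r1$administered]))
    expect_gte(r1$n_administered, 2)
    expect_true(r1$expected_total >= 0 && r1$expected_total <= 30)
  }
  # identical records give identical results
  two <- rbind(it[5, ], it[5, ])
  sim <- simulate_cat(two, bank)
  expect_equal(sim$results$theta1[1], sim$results$theta1[2])
  expect_equal(sim$administered[[1]], sim$administered[[2]])
})

test_that("lowering delta never decreases a patient's item count", {
  bank <- generate_item_bank(factors = 1, seed = 37)
  tab <- generate_cohort(cohort_spec(n = 15, seed = 38), bank)
  it <- as.matrix(tab[paste0("item", 1:10)])
  deltas <- c(0.4, 0.1, 0.05, 0.01)
  counts <- sapply(deltas, function(d)
    simulate_cat(it, bank,
                 config = cat_config(delta = d))$results$n_items)
  for (j in seq_len(nrow(counts)))
    expect_true(all(diff(counts[j, ]) >= 0))
})

test_that("forcing the suicidal-ideation item administers it", {
  bank <- generate_item_bank(factors = 1, seed = 39)
  tab <- generate_cohort(cohort_spec(n = 40, seed = 40), bank)
  it <- as.matrix(tab[paste0("item", 1:10)])
  sim_def <- simulate_cat(it, bank)
  skipped_si <- !vapply(sim_def$administered, function(a) 10 %in% a, TRUE)
  expect_true(any(skipped_si))  # the default simulation may skip item 10
  sim_si <- simulate_cat(it, bank, config = cat_config(force_si = TRUE))
  expect_true(all(vapply(sim_si$administered, function(a) 10 %in% a, TRUE)))
})

test_that("multi-factor CAT uses the trace rule and terminates", {
  bank <- generate_item_bank(factors = 2, seed = 41)
  tab <- generate_cohort(cohort_spec(n = 30, factors = 2, seed = 42), bank)
  it <- as.matrix(tab[paste0("item", 1:10)])
  sim <- simulate_cat(it, bank, Sigma = cohort_spec(2, factors = 2)$Sigma)
  expect_true(all(sim$results$n_items >= 2 & sim$results$n_items <= 10))
  # first item is the trace-rule argmax at the origin
  first <- select_next_item(bank, 1:10, theta = c(0, 0), rule = "trace")
  expect_true(all(vapply(sim$administered, `[`, 0L, 1) == first))
})
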