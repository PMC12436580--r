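test_that("information criteria follow their defining formulas", {
  expect_equal(information_criteria(0, 0, 10), c(AIC = 0, BIC = 0))
  expect_equal(information_criteria(-100, 40, 8750),
               c(AIC = 280, BIC = 200 + 40 * log(8750)))
})

test_that("free-parameter count and AIC/BIC wiring on a one-factor fit", {
  bank <- generate_item_bank(factors = 1, seed = 2,
                             si_b1_range = c(0.65, 1.45))
  tab <- generate_cohort(cohort_spec(n = 400, seed = 3), bank)
  fit <- grm(tab[paste0("item", 1:10)], factors = 1, min_n = 100)
  expect_equal(fit$npar, 40)
  expect_equal(fit$AIC - fit$BIC, 2 * 40 - 40 * log(fit$N))
  expect_equal(AIC(fit), fit$AIC)
  expect_equal(BIC(fit), fit$BIC)
  expect_equal(unname(attr(logLik(fit), "df")), 40)
})

test_that("EM log-likelihood is monotone and parameters are recovered", {
  bank <- generate_item_bank(factors = 1, seed = 17,
                             si_b1_range = c(0.65, 1.45))
  tab <- generate_cohort(cohort_spec(n = 1500, seed = 18), bank)
  fit <- grm(tab[paste0("item", 1:10)], factors = 1)
  expect_true(fit$converged)
  expect_true(all(diff(fit$loglik_trace) > -1e-8))
  co <- coef(fit)
  expect_lt(sqrt(mean((co[, "a"] - bank$slopes)^2)), 0.25)
  expect_lt(sqrt(mean((co[, c("d1", "d2", "d3")] - bank$intercepts)^2)),
            0.3)
  # fitted intercepts keep their ordering
  expect_true(all(apply(co[, c("d1", "d2", "d3")], 1, diff) < 0))
})

test_that("model nesting: richer factor structures fit no worse", {
  bank <- generate_item_bank(factors = 3, seed = 21,
                             si_b1_range = c(0.65, 1.45))
  tab <- generate_cohort(cohort_spec(n = 1200, factors = 3, seed = 22),
                         bank)
  it <- tab[paste0("item", 1:10)]
  f1 <- grm(it, factors = 1, collapse = TRUE)
  f2 <- grm(it, factors = 2, collapse = TRUE)
  f3 <- grm(it, factors = 3, collapse = TRUE)
  # rescaling identification makes the Sigma update approximate, so allow
  # a small numerical slack
  tol <- 1e-3 * abs(f1$loglik)
  expect_gte(f2$loglik, f1$loglik - tol)
  expect_gte(f3$loglik, f2$loglik - tol)
  expect_equal(f2$npar, 41)
  expect_equal(f3$npar, 43)
  # Sigma stays a unit-diagonal correlation matrix
  expect_equal(diag(f3$Sigma), rep(1, 3))
  expect_true(all(eigen(f3$Sigma, only.values = TRUE)$values > 0))
  # generating correlations (0.6) recovered reasonably at this N
  expect_true(all(abs(f3$Sigma[upper.tri(f3$Sigma)] - 0.6) < 0.15))
})

test_that("the fitted model predicts and simulates coherently", {
  bank <- generate_item_bank(factors = 1, seed = 2,
                             si_b1_range = c(0.65, 1.45))
  tab <- generate_cohort(cohort_spec(n = 600, seed = 5), bank)
  it <- tab[paste0("item", 1:10)]
  fit <- grm(it, factors = 1, min_n = 100)
  pr <- predict(fit, it)
  expect_equal(dim(pr$theta), c(600, 1))
  # EAP estimates track the hidden generating traits
  expect_gt(cor(pr$theta[, 1], attr(tab, "theta")[, 1]), 0.8)
  tot <- predict(fit, it, type = "total", correct = TRUE)
  expect_true(all(tot >= 0 & tot <= 30))
  expect_gt(cor(tot, rowSums(it)), 0.9)
  sim <- simulate(fit, seed = 1, n = 50)
  expect_equal(dim(sim), c(50, 10))
  expect_true(all(sim %in% 0:3))
})

test_that("degenerate inputs are refused with informative errors", {
  bank <- generate_item_bank(factors = 1, seed = 1)
  tab <- generate_cohort(cohort_spec(n = 300, seed = 2), bank)
  it <- as.matrix(tab[paste0("item", 1:10)])
  expect_error(grm(it, factors = 1, min_n = 1000), "at least 1000")
  it2 <- it; it2[, 4] <- ifelse(it2[, 4] > 1, 1L, it2[, 4])
  it2[, 4] <- pmin(it2[, 4], 1L)
  expect_error(grm(it2, factors = 1, min_n = 100, collapse = FALSE),
               "unobserved")
  fit <- grm(it2, factors = 1, min_n = 100, collapse = TRUE)
  expect_equal(fit$bank$n_cat_item[4], 2L)
  expect_lt(fit$npar, 40)
})
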