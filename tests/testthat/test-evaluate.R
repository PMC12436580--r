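test_that("full-test classification applies cutoffs and the SI override", {
  got <- classify_full_test(c(13, 8, 5, 5, 12, 30), c(0, 0, 0, 2, 0, 0))
  expect_equal(as.character(got$tier),
               c("high", "moderate", "low", "high", "moderate", "high"))
  expect_equal(got$positive, c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE))
  expect_error(classify_full_test(31, 0), "0..30")
  expect_error(classify_full_test(7.5, 0), "integers")
})

test_that("CAT-implied classification uses expected total >= 8 or SI", {
  expect_true(classify_cat_result(8.0, 0))
  expect_true(classify_cat_result(7.99, 1))   # override by recorded SI
  expect_false(classify_cat_result(7.99, 0))
  expect_equal(classify_cat_result(c(0, 29.9), c(0, 0)), c(FALSE, TRUE))
  expect_error(classify_cat_result(-1, 0), "0, 30")
})

test_that("diagnostic metrics satisfy their defining identities", {
  # perfect agreement
  m <- diagnostic_metrics(c(TRUE, FALSE, TRUE), c(TRUE, FALSE, TRUE))
  expect_equal(m$npv, 1); expect_equal(m$ppv, 1); expect_equal(m$fnr, 0)

  # TN = 988, FN = 12 -> NPV 98.8%
  truth <- c(rep(TRUE, 12), rep(FALSE, 988))
  pred <- rep(FALSE, 1000)
  m2 <- diagnostic_metrics(truth, pred)
  expect_equal(m2$npv, 0.988)
  expect_true(is.na(m2$ppv))  # empty denominator reported as undefined

  # exhaustive check against the brute-force definition for all
  # confusion tables with n <= 20
  for (tp in 0:3) for (fp in 0:3) for (tn in 0:3) for (fn in 0:3) {
    truth <- c(rep(TRUE, tp), rep(FALSE, fp), rep(FALSE, tn),
               rep(TRUE, fn))
    pred <- c(rep(TRUE, tp), rep(TRUE, fp), rep(FALSE, tn),
              rep(FALSE, fn))
    if (!length(truth)) next
    m <- diagnostic_metrics(truth, pred)
    expect_equal(unname(m$counts),
                 c(tp, fp, tn, fn))
    if (tn + fn > 0) expect_equal(m$npv, tn / (tn + fn))
    if (tp + fp > 0) expect_equal(m$ppv, tp / (tp + fp))
    if (tp + fn > 0) expect_equal(m$fnr, fn / (fn + tp))
  }
})

test_that("Wilson intervals bracket the point estimate inside [0, 1]", {
  for (x in c(0, 3, 10)) {
    ci <- epdscat:::wilson_ci(x, 10)
    expect_true(ci[1] >= 0 && ci[2] <= 1)
    expect_true(ci[1] <= x / 10 && x / 10 <= ci[2])
  }
})

test_that("FNR parity audit matches hand-computed chi-square", {
  # identical FN/TP proportions: chi-square 0, all parity ratios 1
  truth <- rep(TRUE, 100)
  pred <- rep(c(rep(FALSE, 5), rep(TRUE, 45)), 2)
  grp <- rep(c("White", "B"), each = 50)
  fp0 <- fnr_parity(truth, pred, grp)
  expect_equal(fp0$chisq$statistic, 0)
  expect_equal(fp0$table$parity_ratio, c(1, 1))

  # two groups 5/45 and 10/40: Pearson statistic on the 2x2 table
  truth <- rep(TRUE, 100)
  pred <- c(rep(FALSE, 5), rep(TRUE, 45), rep(FALSE, 10), rep(TRUE, 40))
  grp <- rep(c("White", "B"), each = 50)
  got <- fnr_parity(truth, pred, grp)
  tab <- rbind(c(5, 45), c(10, 40))
  e <- outer(rowSums(tab), colSums(tab)) / 100
  expect_equal(got$chisq$statistic, sum((tab - e)^2 / e))
  expect_equal(got$chisq$df, 1)
  expect_equal(got$overall_fnr, 0.15)
  b_fnr <- got$table$FNR[got$table$group == "B"]
  w_fnr <- got$table$FNR[got$table$group == "White"]
  expect_equal(got$table$parity_ratio[got$table$group == "B"],
               b_fnr / w_fnr)

  expect_error(fnr_parity(truth, pred, grp, reference_group = "Z"),
               "absent")
  # groups without full-test positives are dropped with a warning
  truth2 <- c(truth, FALSE, FALSE)
  pred2 <- c(pred, FALSE, TRUE)
  grp2 <- c(grp, "C", "C")
  expect_warning(out <- fnr_parity(truth2, pred2, grp2), "no full-test")
  expect_equal(sort(out$table$group), c("B", "White"))
})

test_that("Cronbach's alpha has its closed-form extremes", {
  set.seed(12)
  x <- rnorm(100)
  same <- cbind(x, x, x)
  expect_equal(cronbach_alpha(same)$alpha, 1)
  indep <- cbind(rnorm(4000), rnorm(4000))
  expect_lt(abs(cronbach_alpha(indep)$alpha), 0.1)
  a <- cronbach_alpha(cbind(x, x + rnorm(100, sd = 0.5)))
  expect_true(a$ci[1] < a$alpha && a$alpha < a$ci[2])
  expect_error(cronbach_alpha(matrix(1, 10, 3)), "variance")
})

test_that("score agreement wraps the Pearson correlation", {
  x <- c(1, 4, 2, 8, 5)
  expect_equal(score_agreement(x, x)$r, 1)
  expect_equal(score_agreement(-x, x)$r, -1)
  expect_error(score_agreement(rep(1, 5), x), "constant")
  set.seed(3)
  y <- x + rnorm(5, sd = 0.5)
  ag <- score_agreement(x, y)
  expect_equal(ag$r, cor(x, y))
  expect_length(ag$ci, 2)
})
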