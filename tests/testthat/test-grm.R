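test_that("category probabilities match direct logistic evaluation", {
  # a = 1, d = 0, theta = 0: cumulative = logistic(0) = 0.5
  b <- item_bank(1, matrix(0, 1, 1), si_item = NA)
  expect_equal(item_response_probs(b, 1, 0)$cumulative, 0.5)

  # a = 1.5, thresholds b = (-1, 0, 1) i.e. d = -a*b, theta = 0.5
  a <- 1.5; d <- -a * c(-1, 0, 1)
  bk <- item_bank(a, matrix(d, 1), si_item = NA)
  got <- item_response_probs(bk, 1, 0.5)
  expect_equal(got$category, oracle_cat_probs(a, d, 0.5),
               tolerance = 1e-12)
  expect_equal(sum(got$category), 1, tolerance = 1e-12)

  # zero slope: probabilities independent of theta
  b0 <- item_bank(0, matrix(c(1, -1), 1), si_item = NA)
  expect_equal(item_response_probs(b0, 1, -3)$category,
               item_response_probs(b0, 1, 3)$category)

  # dimension mismatch errors
  expect_error(item_response_probs(b, 1, c(0, 0)), "length")
})

test_that("probabilities form a simplex and cumulative curves are monotone", {
  for (s in 1:20) {
    bk <- random_bank(4, seed = s)
    th <- runif(1, -4, 4)
    for (i in 1:4) {
      pr <- item_response_probs(bk, i, th)
      expect_true(all(pr$category >= 0))
      expect_equal(sum(pr$category), 1, tolerance = 1e-12)
      expect_true(all(diff(pr$cumulative) < 0))
      # cumulative increasing in theta when slope > 0
      pr2 <- item_response_probs(bk, i, th + 0.5)
      expect_true(all(pr2$cumulative > pr$cumulative))
    }
  }
})

test_that("item information matches a numeric differentiation oracle", {
  bk <- toy_bank()
  for (i in 1:3) for (th in c(-2.5, -0.7, 0, 1.3, 3)) {
    expect_equal(item_information(bk, i, th)[1, 1],
                 oracle_info(bk$slopes[i], bk$intercepts[i, ], th),
                 tolerance = 1e-6)
  }
})

test_that("dichotomous items reduce to the 2PL", {
  # K = 2: information a^2 P*(1-P*), equal to a^2/4 at theta = b
  a <- 1.8; b <- 0.6
  bk <- item_bank(a, matrix(-a * b, 1), si_item = NA)
  expect_equal(item_information(bk, 1, b)[1, 1], a^2 / 4,
               tolerance = 1e-10)
  p <- item_response_probs(bk, 1, 1.1)
  expect_equal(p$cumulative, plogis(a * (1.1 - b)), tolerance = 1e-12)
  th <- 0.4
  pstar <- plogis(a * (th - b))
  expect_equal(item_information(bk, 1, th)[1, 1],
               a^2 * pstar * (1 - pstar), tolerance = 1e-10)
})

test_that("zero-slope items carry no information; info is PSD rank <= 1", {
  b0 <- item_bank(0, matrix(c(1, -1), 1), si_item = NA)
  expect_equal(item_information(b0, 1, 1.7), matrix(0, 1, 1))
  bank3 <- generate_item_bank(factors = 3, seed = 3)
  th <- c(0.5, -1, 0.3)
  for (i in c(1, 4, 8)) {
    I <- item_information(bank3, i, th)
    expect_equal(I, t(I))
    f <- bank3$factors[i]
    expect_true(I[f, f] > 0)
    I[f, f] <- 0
    expect_equal(I, matrix(0, 3, 3))  # only the loaded entry is nonzero
  }
})

test_that("response log-likelihood composes item log-probabilities", {
  bk <- toy_bank()
  expect_identical(response_loglik(bk, rep(NA_integer_, 3), 0.3), 0)
  b1 <- item_bank(1, matrix(0, 1, 1), si_item = NA)
  expect_equal(response_loglik(b1, 1L, 0), log(0.5))
  resp <- c(2L, 0L, 3L)
  th <- -0.4
  expected <- sum(vapply(1:3, function(i)
    log(item_response_probs(bk, i, th)$category[resp[i] + 1L]), 0))
  expect_equal(response_loglik(bk, resp, th), expected)
  expect_true(response_loglik(bk, resp, th) <= 0)
  expect_error(response_loglik(bk, c(4L, 0L, 0L), 0), "item")
})

test_that("expected total score is bounded, monotone and compositional", {
  # zero slopes with uniform 4-category probabilities: T = 10 * 1.5
  d_unif <- qlogis(c(0.75, 0.5, 0.25))
  bank <- item_bank(rep(0, 10), matrix(d_unif, 10, 3, byrow = TRUE),
                    si_item = NA)
  expect_equal(expected_total_score(bank, 0), 15, tolerance = 1e-12)

  bk <- generate_item_bank(factors = 1, seed = 9)
  expect_lt(expected_total_score(bk, -6), 0.05)
  tots <- expected_total_score(bk, matrix(seq(-6, 6, by = 0.5)))
  expect_true(all(diff(tots) >= 0))
  expect_true(all(tots >= 0 & tots <= 30))

  # compositional oracle at a fixed theta
  th <- 0.8
  direct <- sum(vapply(1:10, function(i)
    sum((0:3) * item_response_probs(bk, i, th)$category), 0))
  expect_equal(expected_total_score(bk, th), direct, tolerance = 1e-10)
})
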