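# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own kernels: probabilities by direct logistic
# evaluation, information by central differences, EAP by dense-grid
# Riemann integration.

# Direct logistic evaluation of graded category probabilities for one item.
oracle_cat_probs <- function(a, d, x) {
  cum <- c(1, 1 / (1 + exp(-(a * x + d))), 0)
  -diff(cum)
}

# Expected Fisher information by central-difference differentiation of the
# category probabilities (one latent dimension).
oracle_info <- function(a, d, x, h = 1e-5) {
  p <- oracle_cat_probs(a, d, x)
  dp <- (oracle_cat_probs(a, d, x + h) - oracle_cat_probs(a, d, x - h)) /
    (2 * h)
  sum(dp^2 / p)
}

# EAP by dense-grid integration against a standard normal prior (D = 1).
oracle_eap <- function(bank, responses, npts = 10001, bound = 6) {
  x <- seq(-bound, bound, length.out = npts)
  logpost <- stats::dnorm(x, log = TRUE)
  for (i in which(!is.na(responses))) {
    p <- vapply(x, function(xx)
      oracle_cat_probs(bank$slopes[i], bank$intercepts[i, ],
                       xx)[responses[i] + 1L], 0)
    logpost <- logpost + log(pmax(p, 1e-10))
  }
  w <- exp(logpost - max(logpost))
  w <- w / sum(w)
  mu <- sum(w * x)
  list(theta = mu, se = sqrt(sum(w * (x - mu)^2)))
}

# A small deterministic one-factor test bank used by many tests.
toy_bank <- function() {
  item_bank(slopes = c(1.5, 2.0, 1.2),
            intercepts = rbind(c(1.5, 0, -1.5),
                               c(2.0, 0.4, -1.2),
                               c(1.0, -0.5, -2.0)),
            si_item = NA)
}

# Random small bank generator for property sweeps (one factor).
random_bank <- function(n_items = 4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- runif(n_items, 0.5, 3)
  b1 <- runif(n_items, -2, 1)
  b <- cbind(b1, b1 + runif(n_items, 0.3, 1.5),
             b1 + runif(n_items, 1.8, 3))
  item_bank(a, -a * b, si_item = NA)
}
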