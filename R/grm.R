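#' Graded response model category probabilities for one item
#'
#' Cumulative curves are \eqn{P^*_k(\theta) = \mathrm{logit}^{-1}(a
#' \theta_f + d_k)} and category probabilities their adjacent differences
#' \eqn{P_k = P^*_k - P^*_{k+1}}, with \eqn{P^*_0 = 1} and
#' \eqn{P^*_K = 0}. Only the coordinate of `theta` on the item's factor
#' enters; items with zero slope have constant category probabilities.
#'
#' @param bank an [item_bank()].
#' @param item item index.
#' @param theta latent trait: a vector of length `bank$D` (or a scalar when
#'   `bank$D == 1`).
#' @return list with `cumulative` (length K-1, strictly decreasing in k)
#'   and `category` (length K, sums to 1).
#' @examples
#' b <- item_bank(1, matrix(0, 1, 1))           # dichotomous, a = 1, d = 0
#' item_response_probs(b, 1, 0)$cumulative      # 0.5
#' @export
item_response_probs <- function(bank, item, theta) {
  stopifnot(inherits(bank, "item_bank"))
  theta <- as.numeric(theta)
  if (length(theta) != bank$D)
    stop(sprintf("theta has length %d but the bank has %d factor(s)",
                 length(theta), bank$D), call. = FALSE)
  if (any(!is.finite(theta))) stop("theta must be finite", call. = FALSE)
  x <- theta[bank$factors[item]]
  cum <- stats::plogis(bank$slopes[item] * x + .item_d(bank, item))
  cat <- diff(c(1, cum, 0)) * -1
  list(cumulative = cum, category = cat)
}

# non-NA intercepts of one item
.item_d <- function(bank, i)
  bank$intercepts[i, seq_len(bank$n_cat_item[i] - 1L)]

# Category probabilities for one item at a vector of scalar positions along
# its own factor. Returns length(x) x K matrix. Kernel shared by scoring,
# estimation and the CAT engine.
.grm_cat_probs <- function(a, d, x) {
  z <- outer(x, d, function(xx, dd) stats::plogis(a * xx + dd))
  cbind(1, z) - cbind(z, 0)
}

# d/dx of the category probabilities (same shape as .grm_cat_probs).
# dP*_k/dx = a P*_k (1 - P*_k); dP_k/dx = a (W_k - W_{k+1}).
.grm_cat_dprobs <- function(a, d, x) {
  z <- outer(x, d, function(xx, dd) stats::plogis(a * xx + dd))
  w <- z * (1 - z)
  a * (cbind(w, 0) - cbind(0, w))
}

#' Fisher information matrix of one item
#'
#' Expected (Fisher) information of a graded item at `theta`:
#' \eqn{I(\theta) = \sum_k \nabla P_k \nabla P_k^\top / P_k}. Under simple
#' structure the gradient points along the loaded factor, so the matrix has
#' rank at most one with its only nonzero diagonal entry on that factor.
#' Category probabilities are floored at `floor` before dividing, to keep
#' the information finite at extreme `theta`.
#'
#' @inheritParams item_response_probs
#' @param floor lower bound applied to category probabilities.
#' @return a `D` x `D` positive semidefinite matrix.
#' @export
item_information <- function(bank, item, theta, floor = 1e-10) {
  stopifnot(inherits(bank, "item_bank"))
  theta <- as.numeric(theta)
  if (length(theta) != bank$D)
    stop("theta dimension does not match the bank", call. = FALSE)
  f <- bank$factors[item]
  info <- .grm_info_scalar(bank$slopes[item], .item_d(bank, item),
                           theta[f], floor = floor)
  out <- matrix(0, bank$D, bank$D)
  out[f, f] <- info
  out
}

# Scalar information along the loaded factor, vectorised over x.
.grm_info_scalar <- function(a, d, x, floor = 1e-10) {
  p <- pmax(.grm_cat_probs(a, d, x), floor)
  dp <- .grm_cat_dprobs(a, d, x)
  rowSums(dp^2 / p)
}

#' Log-likelihood of a response pattern
#'
#' Sum over answered items of the log category probability at `theta`.
#' `NA` responses are treated as not administered and skipped; an empty
#' pattern has log-likelihood 0.
#'
#' @inheritParams item_response_probs
#' @param responses integer vector of length `bank$n_items` with values in
#'   `0..K-1` or `NA`.
#' @param floor probability floor guarding against `-Inf` at extreme theta.
#' @return scalar log-likelihood (non-positive).
#' @export
response_loglik <- function(bank, responses, theta, floor = 1e-10) {
  stopifnot(inherits(bank, "item_bank"))
  responses <- as.integer(responses)
  if (length(responses) != bank$n_items)
    stop("need one response (or NA) per bank item", call. = FALSE)
  bad <- which(!is.na(responses) &
                 (responses < 0L | responses >= bank$n_cat_item))
  if (length(bad))
    stop("response out of range 0..", bank$n_cat - 1L, " for item(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  ll <- 0
  for (i in which(!is.na(responses))) {
    p <- item_response_probs(bank, i, theta)$category[responses[i] + 1L]
    ll <- ll + log(max(p, floor))
  }
  ll
}

#' Model-implied expected total score
#'
#' Maps a latent position back to the 0--30 EPDS raw-score scale:
#' \eqn{T(\theta) = \sum_i \sum_k k \, P_{i,k}(\theta)}. Weakly increasing
#' in every coordinate of `theta` when all slopes are non-negative, with
#' range `[0, n_items * (K-1)]` approached only in the limits.
#'
#' @param bank an [item_bank()] (the full 10-item bank; the expected total
#'   always uses every item regardless of which were administered).
#' @param theta a `D`-vector, or a matrix with `D` columns for several
#'   respondents at once.
#' @return numeric vector of expected totals.
#' @export
expected_total_score <- function(bank, theta) {
  stopifnot(inherits(bank, "item_bank"))
  theta <- if (is.matrix(theta)) theta else matrix(theta, ncol = bank$D)
  if (ncol(theta) != bank$D)
    stop("theta must have D columns", call. = FALSE)
  tot <- numeric(nrow(theta))
  for (i in seq_len(bank$n_items)) {
    p <- .grm_cat_probs(bank$slopes[i], .item_d(bank, i),
                        theta[, bank$factors[i]])
    tot <- tot + drop(p %*% (seq_len(bank$n_cat_item[i]) - 1))
  }
  tot
}
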