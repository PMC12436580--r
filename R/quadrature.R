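#' Rectangular quadrature grid for EAP scoring and MML estimation
#'
#' A tensor-product grid of equally spaced points on `[-bound, bound]` in
#' each of `d` dimensions, symmetric about zero. Prior weights are the
#' multivariate normal density with zero mean and correlation matrix
#' `Sigma` evaluated at the nodes and renormalised to sum to one.
#' Defaults follow common desk-scale practice: 61 points for one factor,
#' 31 per dimension for two, 15 for three.
#'
#' @param d number of latent dimensions.
#' @param npts points per dimension; default depends on `d`.
#' @param bound half-width of the grid.
#' @return list of class `quad_grid`: `points` (per-dimension abscissae),
#'   `nodes` (n x d matrix), `index` (n x d integer matrix locating each
#'   node on the per-dimension grid), `d`, `npts`, `bound`.
#' @export
quad_grid <- function(d, npts = c(61L, 31L, 15L)[min(d, 3L)], bound = 6) {
  d <- as.integer(d)
  stopifnot(d >= 1, npts >= 3, bound > 0)
  pts <- seq(-bound, bound, length.out = npts)
  idx <- as.matrix(do.call(expand.grid, rep(list(seq_len(npts)), d)))
  dimnames(idx) <- NULL
  structure(list(points = pts, nodes = matrix(pts[idx], ncol = d),
                 index = idx, d = d, npts = as.integer(npts),
                 bound = bound),
            class = "quad_grid")
}

# Normalised prior weights N(0, Sigma) at the grid nodes.
prior_weights <- function(grid, Sigma) {
  d <- grid$d
  Sigma <- as.matrix(Sigma)
  stopifnot(nrow(Sigma) == d, ncol(Sigma) == d)
  R <- chol(Sigma)
  z <- backsolve(R, t(grid$nodes), transpose = TRUE)
  logdens <- -0.5 * colSums(z^2)
  w <- exp(logdens - max(logdens))
  w / sum(w)
}

# Likelihood of each response row at each grid node: n_rows x n_nodes.
# Probabilities are evaluated once per item on the 1-D per-dimension grid
# and broadcast through the node index, so the cost is linear in the grid
# size even for d = 3. NA responses are skipped.
pattern_likelihood <- function(bank, responses, grid, floor = 1e-10) {
  responses <- as.matrix(responses)
  n <- nrow(responses)
  L <- matrix(1, n, nrow(grid$nodes))
  for (i in seq_len(bank$n_items)) {
    p <- pmax(.grm_cat_probs(bank$slopes[i], .item_d(bank, i),
                             grid$points), floor)
    pnode <- p[grid$index[, bank$factors[i]], , drop = FALSE]  # nodes x K
    ri <- responses[, i]
    for (k in seq_len(ncol(pnode))) {
      rows <- which(!is.na(ri) & ri == k - 1L)
      if (length(rows))
        L[rows, ] <- L[rows, ] * rep(pnode[, k], each = length(rows))
    }
  }
  L
}
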