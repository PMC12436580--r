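#' Expected a posteriori (EAP) trait estimate
#'
#' Posterior mean and SD of the latent trait given a (possibly partial)
#' response pattern, computed by numerical integration of the response
#' likelihood against a multivariate normal prior `N(0, Sigma)` over a
#' rectangular quadrature grid. With no responses the posterior is the
#' prior, so the estimate is 0 with SD 1 in every dimension.
#'
#' @param bank an [item_bank()].
#' @param responses integer vector in `0..K-1` with `NA` for items not
#'   administered, or a matrix/data frame of such rows to score a whole
#'   table at once.
#' @param Sigma factor correlation matrix (default identity).
#' @param grid a [quad_grid()] matching the bank's dimension (built on the
#'   fly if omitted).
#' @return For a single pattern, a list of class `trait_estimate` with
#'   `theta` (D-vector), `se` (posterior SDs) and `n_items_used`. For a
#'   matrix input, a list with matrices `theta` and `se` (rows =
#'   respondents) and vector `n_items_used`.
#' @examples
#' b <- item_bank(rep(1.7, 3), matrix(c(2, 0, -2), 3, 3, byrow = TRUE) +
#'                  c(0, 0, 0))
#' eap_score(b, c(2L, NA, 1L))
#' @export
eap_score <- function(bank, responses, Sigma = diag(bank$D), grid = NULL) {
  stopifnot(inherits(bank, "item_bank"))
  single <- !is.matrix(responses) && !is.data.frame(responses)
  resp <- if (single) matrix(as.integer(responses), nrow = 1)
          else as.matrix(responses)
  if (ncol(resp) != bank$n_items)
    stop("need one response column per bank item", call. = FALSE)
  storage.mode(resp) <- "integer"
  if (any(resp < 0L | resp >= bank$n_cat, na.rm = TRUE))
    stop("responses out of range 0..", bank$n_cat - 1L, call. = FALSE)
  if (is.null(grid)) grid <- quad_grid(bank$D)
  if (grid$d != bank$D) stop("grid dimension mismatch", call. = FALSE)

  w <- prior_weights(grid, Sigma)
  L <- pattern_likelihood(bank, resp, grid)
  post <- L * rep(w, each = nrow(resp))
  norm <- rowSums(post)
  post <- post / norm
  th <- post %*% grid$nodes
  m2 <- post %*% (grid$nodes^2)
  se <- sqrt(pmax(m2 - th^2, 0))
  used <- rowSums(!is.na(resp))

  edge <- grid$index == 1L | grid$index == grid$npts
  edge_mass <- rowSums(post[, rowSums(edge) > 0, drop = FALSE])
  if (any(edge_mass > 0.5))
    warning("posterior mass concentrated at the grid boundary for ",
            sum(edge_mass > 0.5), " respondent(s); estimates may be ",
            "truncated (extreme respondent)", call. = FALSE)

  if (single)
    structure(list(theta = drop(th), se = drop(se),
                   n_items_used = used[1]),
              class = "trait_estimate")
  else
    list(theta = unname(th), se = unname(se), n_items_used = unname(used))
}

#' @export
print.trait_estimate <- function(x, ...) {
  cat("EAP trait estimate (", x$n_items_used, " item(s) answered)\n",
      sep = "")
  print(round(rbind(theta = x$theta, se = x$se), 4))
  invisible(x)
}

#' Empirical reliability and shrinkage correction of EAP estimates
#'
#' EAP estimates shrink toward the prior mean; over a cohort their
#' variance understates the trait variance. The empirical (marginal)
#' reliability per dimension is
#' \eqn{\rho_d = \mathrm{Var}(\hat\theta_d) / (\mathrm{Var}(\hat\theta_d)
#' + \overline{SE_d^2})}, and the corrected estimates
#' \eqn{\hat\theta^*_d = \hat\theta_d / \sqrt{\rho_d}} restore (to first
#' order) the prior trait variance of 1.
#'
#' @param theta matrix of EAP estimates (respondents x dimensions), or the
#'   list returned by [eap_score()] on a matrix.
#' @param se matrix of posterior SDs matching `theta` (ignored when
#'   `theta` is an `eap_score` result list).
#' @return list with `rho` (per-dimension reliability), `theta_corrected`
#'   and the inputs.
#' @export
empirical_reliability <- function(theta, se = NULL) {
  if (is.list(theta) && !is.data.frame(theta)) {
    se <- theta$se
    theta <- theta$theta
  }
  theta <- as.matrix(theta); se <- as.matrix(se)
  if (nrow(theta) < 2) stop("need at least 2 respondents", call. = FALSE)
  v <- apply(theta, 2, stats::var)
  if (any(v <= 0))
    stop("zero variance in EAP estimates; shrinkage correction undefined",
         call. = FALSE)
  rho <- v / (v + colMeans(se^2))
  corrected <- sweep(theta, 2, sqrt(rho), "/")
  list(rho = rho, theta_corrected = corrected, theta = theta, se = se)
}
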