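#' Fit a graded response model by marginal maximum likelihood EM
#'
#' Fits a simple-structure graded response model (GRM) to a table of
#' polytomous responses by an EM algorithm over a fixed rectangular
#' quadrature grid. Each item loads on exactly one factor; with
#' `factors = 1` the model is the familiar unidimensional GRM, and for a
#' 10-item table `factors = 2` or `3` uses the conventional EPDS
#' assignments (see [epds_factor_structure()]). Factors are identified by
#' fixing their variances to 1; inter-factor correlations are estimated.
#'
#' The E step computes each respondent's posterior over the grid under the
#' current parameters; the M step maximises the expected complete-data
#' log-likelihood item by item (quasi-Newton on log-slope and ordered
#' intercept increments, which keeps slopes positive and intercepts
#' strictly decreasing), then updates the factor correlation matrix from
#' the average posterior second moment rescaled to unit diagonal.
#' Estimation is fully deterministic: slopes start at 1, intercepts at the
#' logits of the observed cumulative category frequencies, correlations at
#' zero.
#'
#' @param responses matrix or data frame of integer responses in
#'   `0..n_cat-1`, one row per respondent; incomplete rows are dropped
#'   with a message.
#' @param factors `1`, `2` or `3` for the standard EPDS structures, or an
#'   integer vector assigning each item to a factor.
#' @param n_cat number of ordered categories per item (4 for the EPDS).
#' @param grid a [quad_grid()]; defaults to 61/31/15 points per dimension
#'   for 1/2/3 factors on `[-6, 6]`.
#' @param tol convergence tolerance on the maximum absolute parameter
#'   change between cycles.
#' @param max_cycles maximum number of EM cycles.
#' @param min_n minimum number of complete rows required.
#' @param collapse if `TRUE`, categories never observed for an item are
#'   merged with the adjacent lower category (recoding that item's
#'   responses); if `FALSE` (default) an unobserved category is an error.
#' @param si_item suicidal-ideation item index recorded on the fitted
#'   bank (default 10 for 10-item tables, else `NA`).
#' @param verbose print the log-likelihood every 25 cycles.
#'
#' @return An object of class `grm`: a list with the fitted `bank`
#'   ([item_bank()]), `Sigma`, `loglik`, `npar`, `AIC`, `BIC`, `cycles`,
#'   `converged`, `N`, `loglik_trace`, `grid` and the matched call.
#'   Methods: `print`, `summary`, `coef`, `logLik`, `predict`,
#'   `simulate`, `plot`.
#' @examples
#' \donttest{
#' bank <- generate_item_bank(factors = 1, seed = 1)
#' tab <- generate_cohort(cohort_spec(n = 800, seed = 2), bank)
#' fit <- grm(tab[paste0("item", 1:10)], factors = 1, min_n = 100)
#' fit
#' }
#' @export
grm <- function(responses, factors = 1, n_cat = 4L, grid = NULL,
                tol = 1e-4, max_cycles = 500L, min_n = 200L,
                collapse = FALSE, si_item = NULL, verbose = FALSE) {
  cl <- match.call()
  resp <- as.matrix(responses)
  storage.mode(resp) <- "integer"
  n_items <- ncol(resp)
  if (any(resp < 0L | resp >= n_cat, na.rm = TRUE))
    stop("responses out of range 0..", n_cat - 1L, call. = FALSE)
  complete <- stats::complete.cases(resp)
  if (!all(complete)) {
    message("dropping ", sum(!complete), " incomplete row(s)")
    resp <- resp[complete, , drop = FALSE]
  }
  N <- nrow(resp)
  if (N < min_n)
    stop("need at least ", min_n, " complete rows (got ", N, ")",
         call. = FALSE)

  if (length(factors) == 1L) {
    if (n_items == 10L && factors %in% 1:3) {
      fs <- epds_factor_structure(factors)
      fac <- fs$factors; fac_names <- fs$factor_names
    } else if (factors == 1) {
      fac <- rep(1L, n_items); fac_names <- "F1"
    } else stop("multi-factor shorthand needs a 10-item table", call. = FALSE)
  } else {
    fac <- as.integer(factors); fac_names <- NULL
    if (length(fac) != n_items)
      stop("factor assignment length mismatch", call. = FALSE)
  }
  D <- max(fac)
  if (is.null(si_item)) si_item <- if (n_items == 10L) 10L else NA_integer_
  if (is.null(grid)) grid <- quad_grid(D)
  if (grid$d != D) stop("grid dimension mismatch", call. = FALSE)

  # observed category handling ------------------------------------------
  km1_max <- n_cat - 1L
  recode <- vector("list", n_items)
  for (i in seq_len(n_items)) {
    seen <- sort(unique(resp[, i]))
    if (length(seen) < 2L)
      stop("item ", i, " shows fewer than 2 observed categories",
           call. = FALSE)
    if (length(seen) < n_cat) {
      if (!collapse)
        stop("item ", i, " has unobserved categor(ies) ",
             paste(setdiff(0:km1_max, seen), collapse = ", "),
             "; rerun with collapse = TRUE to merge them", call. = FALSE)
      map <- integer(n_cat)
      map[seen + 1L] <- seq_along(seen) - 1L
      # unobserved categories inherit the next lower observed code
      for (k in seq_len(n_cat)) if (!(k - 1L) %in% seen)
        map[k] <- if (any(seen < k - 1L)) map[max(seen[seen < k - 1L]) + 1L] else 0L
      resp[, i] <- map[resp[, i] + 1L]
      recode[[i]] <- map
      message("item ", i, ": collapsed to ", length(seen), " categories")
    }
  }
  km1 <- vapply(seq_len(n_items),
                function(i) length(unique(resp[, i])) - 1L, 0L)

  # collapse to unique response patterns --------------------------------
  key <- apply(resp, 1, paste, collapse = ",")
  first <- !duplicated(key)
  pat <- resp[first, , drop = FALSE]
  counts <- as.vector(table(factor(key, levels = key[first])))

  # deterministic start values ------------------------------------------
  slopes <- rep(1, n_items)
  inter <- matrix(NA_real_, n_items, km1_max)
  for (i in seq_len(n_items)) {
    cum <- vapply(seq_len(km1[i]), function(k) mean(resp[, i] >= k), 0)
    cum <- pmin(pmax(cum, 1 / (2 * N)), 1 - 1 / (2 * N))
    inter[i, seq_len(km1[i])] <- stats::qlogis(cum)
  }
  Sigma <- diag(D)

  make_bank <- function() item_bank(slopes, inter, fac,
                                    labels = colnames(resp) %||%
                                      paste0("item", seq_len(n_items)),
                                    si_item = si_item,
                                    factor_names = fac_names)

  ll_trace <- numeric(0)
  converged <- FALSE
  cycle <- 0L
  repeat {
    cycle <- cycle + 1L
    bank <- make_bank()
    w <- prior_weights(grid, Sigma)
    L <- pattern_likelihood(bank, pat, grid)
    marg <- drop(L %*% w)
    ll <- sum(counts * log(marg))
    ll_trace <- c(ll_trace, ll)
    if (verbose && cycle %% 25L == 1L)
      cat(sprintf("cycle %4d  loglik %.4f\n", cycle, ll))

    post <- (L * rep(w, each = nrow(L))) / marg
    postc <- post * counts

    # per-dimension marginal posterior mass, aggregated over patterns later
    marg_post <- lapply(seq_len(D), function(f)
      t(rowsum(t(postc), grid$index[, f], reorder = TRUE)))

    old_slopes <- slopes; old_inter <- inter; old_Sigma <- Sigma
    for (i in seq_len(n_items)) {
      r <- rowsum(marg_post[[fac[i]]], pat[, i], reorder = TRUE)
      # r: categories x npts expected counts; some categories may be absent
      rfull <- matrix(0, km1[i] + 1L, grid$npts)
      rfull[as.integer(rownames(r)) + 1L, ] <- r
      res <- .mstep_item(slopes[i], inter[i, seq_len(km1[i])], rfull,
                         grid$points)
      slopes[i] <- res$a
      inter[i, seq_len(km1[i])] <- res$d
    }
    if (D > 1) {
      nodew <- colSums(postc)
      M <- crossprod(grid$nodes, grid$nodes * nodew) / N
      Sigma <- stats::cov2cor(M)
    }

    delta <- max(abs(slopes - old_slopes),
                 abs(inter - old_inter), na.rm = TRUE)
    if (D > 1) delta <- max(delta, abs(Sigma - old_Sigma))
    if (delta < tol) { converged <- TRUE; break }
    if (cycle >= max_cycles) break
  }

  bank <- make_bank()
  w <- prior_weights(grid, Sigma)
  ll <- sum(counts * log(drop(pattern_likelihood(bank, pat, grid) %*% w)))
  ll_trace <- c(ll_trace, ll)
  npar <- n_items + sum(km1) + D * (D - 1L) / 2L
  ic <- information_criteria(ll, npar, N)

  structure(list(bank = bank, Sigma = Sigma, loglik = ll, npar = npar,
                 AIC = ic[["AIC"]], BIC = ic[["BIC"]], cycles = cycle,
                 converged = converged, N = N, loglik_trace = ll_trace,
                 grid = grid, recode = recode, call = cl),
            class = "grm")
}

# One M-step item update: maximise sum_{k,m} r[k,m] log P_k(x_m) over
# (a, d) with a > 0 and d strictly decreasing, via BFGS on transformed
# parameters (log a, d_1, log of successive decrements). Returns the
# incumbent parameters if no improvement is found.
.mstep_item <- function(a, d, r, x, floor = 1e-10) {
  m <- length(d)
  to_par <- function(a, d)
    c(log(a), d[1], if (m > 1) log(-diff(d)))
  from_par <- function(p) {
    a <- exp(p[1])
    d <- p[2] - c(0, cumsum(exp(p[-(1:2)])))
    list(a = a, d = d)
  }
  rt <- t(r)                                   # npts x K
  negq <- function(p) {
    q <- from_par(p)
    P <- pmax(.grm_cat_probs(q$a, q$d, x), floor)
    -sum(rt * log(P))
  }
  grad <- function(p) {
    q <- from_par(p)
    a <- q$a; d <- q$d
    z <- outer(x, d, function(xx, dd) stats::plogis(a * xx + dd))
    wz <- z * (1 - z)
    P <- pmax(cbind(1, z) - cbind(z, 0), floor)
    R <- rt / P
    gd <- vapply(seq_len(m), function(j)
      -sum(wz[, j] * (R[, j + 1] - R[, j])), 0)
    ga <- -sum(R * (x * (cbind(0, wz) - cbind(wz, 0))))
    g <- numeric(length(p))
    g[1] <- a * ga
    g[2] <- sum(gd)
    if (m > 1)
      g[3:(m + 1)] <- -exp(p[3:(m + 1)]) *
        rev(cumsum(rev(gd)))[-1]
    g
  }
  p0 <- to_par(a, d)
  f0 <- negq(p0)
  fit <- try(stats::optim(p0, negq, grad, method = "BFGS",
                          control = list(maxit = 50)), silent = TRUE)
  if (inherits(fit, "try-error") || !is.finite(fit$value) ||
      fit$value > f0)
    return(list(a = a, d = d))
  from_par(fit$par)
}

#' Recode responses to a fitted model's category coding
#'
#' When [grm()] collapses unobserved categories (`collapse = TRUE`), the
#' fitted bank uses a contracted category coding for the affected items.
#' This helper maps a raw response table onto that coding so it can be
#' scored or replayed through the CAT under the fitted bank.
#'
#' @param fit a fitted [grm()].
#' @param responses raw response matrix/data frame.
#' @return integer matrix in the fitted coding.
#' @export
recode_responses <- function(fit, responses) {
  stopifnot(inherits(fit, "grm"))
  resp <- as.matrix(responses)
  storage.mode(resp) <- "integer"
  for (i in seq_along(fit$recode)) {
    map <- fit$recode[[i]]
    if (!is.null(map)) resp[, i] <- map[resp[, i] + 1L]
  }
  resp
}

#' Akaike and Bayesian information criteria
#'
#' `AIC = -2 loglik + 2 p` and `BIC = -2 loglik + p log(N)`. For the
#' simple-structure GRM with 10 four-category items the free parameter
#' count is `10 + 30 + D(D-1)/2`.
#'
#' @param loglik marginal log-likelihood.
#' @param n_free_params number of free parameters.
#' @param N number of respondents.
#' @return named numeric vector with elements `AIC` and `BIC`.
#' @export
information_criteria <- function(loglik, n_free_params, N) {
  stopifnot(N >= 1)
  c(AIC = -2 * loglik + 2 * n_free_params,
    BIC = -2 * loglik + n_free_params * log(N))
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("Graded response model (%d factor%s), N = %d\n",
              x$bank$D, if (x$bank$D > 1) "s" else "", x$N))
  cat(sprintf("  log-likelihood %.2f on %d parameters (%d EM cycles%s)\n",
              x$loglik, x$npar, x$cycles,
              if (x$converged) "" else ", NOT converged"))
  cat(sprintf("  AIC %.2f   BIC %.2f\n", x$AIC, x$BIC))
  invisible(x)
}

#' @export
summary.grm <- function(object, ...) {
  structure(list(fit = object, coef = coef(object)),
            class = "summary.grm")
}

#' @export
print.summary.grm <- function(x, ...) {
  print(x$fit)
  if (x$fit$bank$D > 1) {
    cat("\nFactor correlations:\n")
    S <- x$fit$Sigma
    dimnames(S) <- list(x$fit$bank$factor_names, x$fit$bank$factor_names)
    print(round(S, 3))
  }
  cat("\nItem parameters (slope-intercept; b = -d/a):\n")
  print(round(x$coef, 3))
  invisible(x)
}

#' @export
coef.grm <- function(object, ...) {
  b <- object$bank
  km1 <- b$n_cat - 1L
  out <- cbind(factor = b$factors, a = b$slopes, b$intercepts,
               -b$intercepts / b$slopes)
  colnames(out) <- c("factor", "a", paste0("d", seq_len(km1)),
                     paste0("b", seq_len(km1)))
  rownames(out) <- b$labels
  out
}

#' @export
logLik.grm <- function(object, ...) {
  structure(object$loglik, df = object$npar, nobs = object$N,
            class = "logLik")
}

#' Predict latent traits or expected totals from a fitted GRM
#'
#' EAP-scores a response table under the fitted item parameters and factor
#' correlations, optionally applying the empirical-reliability shrinkage
#' correction and mapping to the expected-total 0--30 scale.
#'
#' @param object a fitted [grm()].
#' @param newdata response matrix/data frame (may contain `NA` for items
#'   not administered).
#' @param type `"theta"` for EAP estimates and posterior SDs, `"total"`
#'   for expected total scores.
#' @param correct apply the shrinkage correction before reporting
#'   (and before the total-score mapping).
#' @param ... unused.
#' @return For `type = "theta"`, a list with `theta`, `se` (matrices) and,
#'   when `correct = TRUE`, `theta_corrected` and `rho`. For
#'   `type = "total"`, a numeric vector.
#' @export
predict.grm <- function(object, newdata, type = c("theta", "total"),
                        correct = FALSE, ...) {
  type <- match.arg(type)
  sc <- eap_score(object$bank, as.matrix(newdata), object$Sigma,
                  object$grid)
  if (correct) {
    rel <- empirical_reliability(sc$theta, sc$se)
    sc$theta_corrected <- rel$theta_corrected
    sc$rho <- rel$rho
  }
  if (type == "theta") return(sc)
  th <- if (correct) sc$theta_corrected else sc$theta
  expected_total_score(object$bank, th)
}

#' @export
simulate.grm <- function(object, nsim = 1, seed = NULL, n = object$N,
                         ...) {
  if (!is.null(seed)) set.seed(seed)
  out <- replicate(nsim, {
    theta <- .rmvnorm_chol(n, object$Sigma)
    .sample_responses(object$bank, theta)
  }, simplify = FALSE)
  if (nsim == 1) out[[1]] else out
}

#' @export
plot.grm <- function(x, items = seq_len(x$bank$n_items), ...) {
  b <- x$bank
  th <- seq(-4, 4, length.out = 201)
  info <- vapply(items, function(i)
    .grm_info_scalar(b$slopes[i], b$intercepts[i, !is.na(b$intercepts[i, ])],
                     th), numeric(length(th)))
  graphics::matplot(th, info, type = "l", lty = 1,
                    xlab = expression(theta),
                    ylab = "Item information",
                    main = "Item information curves", ...)
  graphics::legend("topright", legend = b$labels[items],
                   col = seq_along(items), lty = 1, cex = 0.7, bty = "n")
  invisible(x)
}
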