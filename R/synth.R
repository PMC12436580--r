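# Default demographic mix of the emulated postpartum screening cohort.
.default_group_props <- c(White = 0.54, AAPI = 0.12, Other = 0.12,
                          "Hispanic White" = 0.10, Black = 0.07,
                          Multiracial = 0.04, Unknown = 0.01)

# Default inter-factor correlation for multi-factor banks: EPDS subscales
# are strongly related facets of one syndrome.
.default_factor_cor <- 0.6

#' Generate a random graded-response item bank
#'
#' Draws a 10-item, 4-category bank with the EPDS factor assignment for
#' the requested dimension. Slopes are uniform on `slope_range`;
#' difficulties are built as an increasing sequence
#' \eqn{b_1 < b_2 < b_3} (first threshold uniform on `b1_range`, gaps
#' uniform on `gap_range`) and converted to intercepts `d = -a b`, which
#' are strictly decreasing. The suicidal-ideation item's first threshold
#' is drawn from the harder `si_b1_range`, reflecting how rarely that
#' item is endorsed relative to the others.
#'
#' @param factors 1, 2 or 3 (EPDS simple structures).
#' @param n_items number of items (10 for the EPDS).
#' @param n_cat ordered categories per item.
#' @param slope_range range of the uniform slope draw.
#' @param b1_range range of the first threshold.
#' @param gap_range range of the threshold gaps.
#' @param si_b1_range first-threshold range for the suicidal-ideation
#'   item.
#' @param seed integer seed; the same seed always yields the same bank.
#' @return an [item_bank()].
#' @export
generate_item_bank <- function(factors = 1, n_items = 10L, n_cat = 4L,
                               slope_range = c(1.3, 2.6),
                               b1_range = c(0.65, 1.45),
                               gap_range = c(0.8, 1.5),
                               si_b1_range = c(2.5, 3.1),
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_items == 10L) {
    if (!factors %in% 1:3) stop("`factors` must be 1, 2 or 3", call. = FALSE)
    fs <- epds_factor_structure(factors)
    fac <- fs$factors; fac_names <- fs$factor_names
    si <- 10L
  } else {
    fac <- rep(1L, n_items); fac_names <- NULL; si <- NA_integer_
  }
  a <- stats::runif(n_items, slope_range[1], slope_range[2])
  b1 <- stats::runif(n_items, b1_range[1], b1_range[2])
  if (!is.na(si)) b1[si] <- stats::runif(1, si_b1_range[1], si_b1_range[2])
  gaps <- matrix(stats::runif(n_items * (n_cat - 2L),
                              gap_range[1], gap_range[2]),
                 n_items, n_cat - 2L)
  b <- cbind(b1, b1 + t(apply(gaps, 1, cumsum)))
  item_bank(a, -a * b, fac, si_item = si, factor_names = fac_names)
}

#' Specification of a synthetic screening cohort
#'
#' Bundles the population parameters the generator emulates: cohort size,
#' demographic group proportions, optional per-group latent shifts
#' (zero by default -- the fairness null), the factor correlation matrix,
#' and a seed. With the default bank ranges the implied positive-screen
#' rate (total >= 8 or suicidal-ideation endorsement) sits near 11--12%.
#'
#' @param n cohort size.
#' @param factors latent dimension matching the bank (1, 2 or 3).
#' @param group_props named proportions summing to 1; defaults to
#'   White 54%, AAPI 12%, Other 12%, Hispanic White 10%, Black 7%,
#'   Multiracial 4%, Unknown 1%.
#' @param group_shifts named list/matrix of per-group mean shifts of the
#'   latent trait (D-vectors); default zero for every group.
#' @param Sigma factor correlation matrix; default 1 (one factor) or
#'   all off-diagonals 0.6.
#' @param age_mean,age_sd,age_range parameters of the truncated-normal
#'   age column (schema fidelity only; the analysis ignores age).
#' @param seed integer seed.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n, factors = 1, group_props = .default_group_props,
                        group_shifts = NULL, Sigma = NULL,
                        age_mean = 34.26, age_sd = 4.89,
                        age_range = c(18, 54), seed = NULL) {
  if (abs(sum(group_props) - 1) > 1e-8)
    stop("group proportions must sum to 1", call. = FALSE)
  if (is.null(names(group_props)))
    stop("group proportions must be named", call. = FALSE)
  D <- as.integer(factors)
  if (is.null(Sigma)) {
    Sigma <- matrix(.default_factor_cor, D, D); diag(Sigma) <- 1
  }
  if (is.null(group_shifts))
    group_shifts <- matrix(0, length(group_props), D,
                           dimnames = list(names(group_props), NULL))
  group_shifts <- as.matrix(group_shifts)
  if (!all(names(group_props) %in% rownames(group_shifts)))
    stop("group_shifts must cover every group", call. = FALSE)
  structure(list(n = as.integer(n), factors = D,
                 group_props = group_props, group_shifts = group_shifts,
                 Sigma = Sigma, age_mean = age_mean, age_sd = age_sd,
                 age_range = age_range, seed = seed),
            class = "cohort_spec")
}

# Draw n D-variate normals with covariance Sigma (mean 0) by Cholesky.
.rmvnorm_chol <- function(n, Sigma) {
  D <- nrow(as.matrix(Sigma))
  z <- matrix(stats::rnorm(n * D), n, D)
  z %*% chol(as.matrix(Sigma))
}

# Sample graded responses for rows of theta from a bank.
.sample_responses <- function(bank, theta) {
  theta <- as.matrix(theta)
  n <- nrow(theta)
  out <- matrix(0L, n, bank$n_items,
                dimnames = list(NULL, bank$labels))
  u <- matrix(stats::runif(n * bank$n_items), n, bank$n_items)
  for (i in seq_len(bank$n_items)) {
    cum <- t(apply(.grm_cat_probs(bank$slopes[i], .item_d(bank, i),
                                  theta[, bank$factors[i]]), 1, cumsum))
    out[, i] <- as.integer(rowSums(u[, i] > cum))  # inverse-CDF draw
  }
  out
}

#' Generate a synthetic response table
#'
#' Draws group labels from the spec's proportions, latent traits from
#' `N(shift_g, Sigma)`, and item responses from the bank's graded
#' response model. The generating traits are kept on the result (as the
#' `"theta"` attribute) for parameter- and score-recovery tests. Output
#' is byte-identical for a fixed seed (R's default Mersenne-Twister
#' stream).
#'
#' @param spec a [cohort_spec()].
#' @param bank an [item_bank()] with `bank$D == spec$factors`.
#' @return data frame with columns `item1..item10`, `race`, `age`, and
#'   attribute `theta` (the hidden generating traits).
#' @export
generate_cohort <- function(spec, bank) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(bank, "item_bank"))
  if (bank$D != spec$factors)
    stop("bank dimension does not match the spec", call. = FALSE)
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n
  race <- sample(names(spec$group_props), n, replace = TRUE,
                 prob = spec$group_props)
  theta <- .rmvnorm_chol(n, spec$Sigma) +
    spec$group_shifts[race, , drop = FALSE]
  resp <- .sample_responses(bank, theta)
  age <- round(stats::qnorm(
    stats::runif(n,
                 stats::pnorm(spec$age_range[1], spec$age_mean, spec$age_sd),
                 stats::pnorm(spec$age_range[2], spec$age_mean, spec$age_sd)),
    spec$age_mean, spec$age_sd))
  out <- data.frame(resp, race = race, age = age,
                    stringsAsFactors = FALSE)
  attr(out, "theta") <- unname(theta)
  out
}
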