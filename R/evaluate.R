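#' Risk classification from the full-length EPDS
#'
#' Clinical tiers used in postpartum screening: a total score of 13 or
#' more, or any endorsement of the suicidal-ideation item, indicates high
#' risk; a total between 8 and 12 indicates moderate risk; totals below 8
#' are low risk. "Positive" screens (triggering referral) are the
#' moderate and high tiers. Endorsement means a recorded response above 0.
#'
#' @param total integer total score(s) in 0..30.
#' @param si_response recorded response(s) to the suicidal-ideation item,
#'   in 0..3.
#' @param moderate_cutoff,high_cutoff classification cutoffs (defaults 8
#'   and 13).
#' @return data frame with columns `tier` (ordered factor
#'   low < moderate < high) and `positive` (logical).
#' @examples
#' classify_full_test(c(5, 8, 13, 5), c(0, 0, 0, 2))
#' @export
classify_full_test <- function(total, si_response,
                               moderate_cutoff = 8, high_cutoff = 13) {
  total <- as.numeric(total)
  if (any(total < 0 | total > 30 | total != round(total), na.rm = TRUE))
    stop("total scores must be integers in 0..30", call. = FALSE)
  stopifnot(length(si_response) == length(total))
  high <- total >= high_cutoff | si_response > 0
  mod <- !high & total >= moderate_cutoff
  tier <- factor(ifelse(high, "high", ifelse(mod, "moderate", "low")),
                 levels = c("low", "moderate", "high"), ordered = TRUE)
  data.frame(tier = tier, positive = tier != "low")
}

#' CAT-implied screening classification
#'
#' A CAT run is classified positive when its expected total score is 8 or
#' more, or when the patient's recorded suicidal-ideation response is
#' endorsed (above 0) -- the recorded answer is used whether or not the
#' CAT administered that item.
#'
#' @param expected_total expected total score(s) in `[0, 30]`.
#' @param si_response recorded suicidal-ideation response(s).
#' @param cutoff positive-screen cutoff (default 8).
#' @return logical vector: positive screen.
#' @export
classify_cat_result <- function(expected_total, si_response, cutoff = 8) {
  expected_total <- as.numeric(expected_total)
  if (any(expected_total < 0 | expected_total > 30, na.rm = TRUE))
    stop("expected totals must lie in [0, 30]", call. = FALSE)
  stopifnot(length(si_response) == length(expected_total))
  expected_total >= cutoff | si_response > 0
}

# Wilson score interval for a binomial proportion.
wilson_ci <- function(x, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = if (x == 0) 0 else max(0, ctr - hw),
    upper = if (x == n) 1 else min(1, ctr + hw))
}

#' Screening accuracy of CAT-implied classifications
#'
#' Cross-tabulates CAT-implied screens against the full-test reference
#' classification and reports the confusion counts, negative and positive
#' predictive values, false negative rate among reference positives, and
#' the predicted positive rate, each with a Wilson confidence interval.
#' A metric whose denominator is empty is reported as `NA` ("undefined")
#' rather than propagating `NaN`.
#'
#' @param truth logical vector: reference (full-test) positives.
#' @param predicted logical vector: CAT-implied positives.
#' @param conf confidence level for the Wilson intervals.
#' @return list of class `screen_metrics` with `counts` (TP, FP, TN, FN),
#'   `npv`, `ppv`, `fnr`, `positive_rate`, matching `*_ci` entries and
#'   `n`.
#' @export
diagnostic_metrics <- function(truth, predicted, conf = 0.95) {
  stopifnot(length(truth) == length(predicted))
  truth <- as.logical(truth); predicted <- as.logical(predicted)
  tp <- sum(truth & predicted); fp <- sum(!truth & predicted)
  tn <- sum(!truth & !predicted); fn <- sum(truth & !predicted)
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  structure(list(
    counts = c(TP = tp, FP = fp, TN = tn, FN = fn),
    npv = safe(tn, tn + fn), npv_ci = wilson_ci(tn, tn + fn, conf),
    ppv = safe(tp, tp + fp), ppv_ci = wilson_ci(tp, tp + fp, conf),
    fnr = safe(fn, fn + tp), fnr_ci = wilson_ci(fn, fn + tp, conf),
    positive_rate = safe(tp + fp, length(truth)),
    positive_rate_ci = wilson_ci(tp + fp, length(truth), conf),
    n = length(truth)), class = "screen_metrics")
}

#' @export
print.screen_metrics <- function(x, ...) {
  cat("Screening accuracy (n =", x$n, ")\n")
  print(x$counts)
  pct <- function(v, ci) sprintf("%.1f%% [%.1f, %.1f]", 100 * v,
                                 100 * ci[1], 100 * ci[2])
  cat("  NPV:", pct(x$npv, x$npv_ci), "\n")
  cat("  PPV:", pct(x$ppv, x$ppv_ci), "\n")
  cat("  FNR:", pct(x$fnr, x$fnr_ci), "\n")
  cat("  predicted positive rate:",
      pct(x$positive_rate, x$positive_rate_ci), "\n")
  invisible(x)
}

#' False-negative-rate parity audit across demographic groups
#'
#' Among reference (full-test) positives, tabulates false negatives and
#' true positives per group, tests homogeneity of the per-group FNRs with
#' a Pearson chi-square (no continuity correction) on the groups x
#' \{FN, TP\} table, and reports each group's FNR as a parity ratio
#' against a named reference group. Groups with no reference positives
#' are dropped with a warning (the chi-square degrees of freedom shrink
#' accordingly).
#'
#' @param truth logical: full-test positives.
#' @param predicted logical: CAT-implied positives.
#' @param groups group label per respondent.
#' @param reference_group label of the parity reference (default
#'   `"White"`).
#' @param conf confidence level for the Wilson intervals.
#' @return list of class `fnr_parity`: `table` (per-group FN, TP, FNR,
#'   CI bounds, parity ratio), `overall_fnr` with `overall_fnr_ci`,
#'   `chisq` (statistic, df, p.value), `reference_group`, `dropped`.
#' @export
fnr_parity <- function(truth, predicted, groups,
                       reference_group = "White", conf = 0.95) {
  stopifnot(length(truth) == length(predicted),
            length(groups) == length(truth))
  truth <- as.logical(truth); predicted <- as.logical(predicted)
  groups <- as.character(groups)
  if (!reference_group %in% groups)
    stop("reference group '", reference_group, "' absent", call. = FALSE)
  pos <- truth
  fn <- tapply(pos & !predicted, groups, sum)
  tp <- tapply(pos & predicted, groups, sum)
  tot <- fn + tp
  dropped <- names(tot)[tot == 0]
  if (length(dropped)) {
    warning("dropping group(s) with no full-test positives: ",
            paste(dropped, collapse = ", "), call. = FALSE)
    fn <- fn[tot > 0]; tp <- tp[tot > 0]
  }
  if (length(fn) < 2)
    stop("need at least 2 groups with full-test positives", call. = FALSE)
  if (!reference_group %in% names(fn))
    stop("reference group has no full-test positives", call. = FALSE)

  fnr <- fn / (fn + tp)
  cis <- t(mapply(wilson_ci, fn, fn + tp, MoreArgs = list(conf = conf)))
  tab <- data.frame(group = names(fn), FN = as.vector(fn),
                    TP = as.vector(tp), FNR = as.vector(fnr),
                    lower = cis[, 1], upper = cis[, 2],
                    parity_ratio = as.vector(fnr / fnr[[reference_group]]),
                    row.names = NULL)

  ctab <- cbind(FN = fn, TP = tp)
  expected <- outer(rowSums(ctab), colSums(ctab)) / sum(ctab)
  if (any(expected < 5))
    warning("some expected counts below 5; the chi-square approximation ",
            "may be poor (consider an exact test)", call. = FALSE)
  chi <- suppressWarnings(stats::chisq.test(ctab, correct = FALSE))

  structure(list(table = tab,
                 overall_fnr = sum(fn) / sum(fn + tp),
                 overall_fnr_ci = wilson_ci(sum(fn), sum(fn + tp), conf),
                 chisq = list(statistic = unname(chi$statistic),
                              df = unname(chi$parameter),
                              p.value = unname(chi$p.value)),
                 reference_group = reference_group, dropped = dropped),
            class = "fnr_parity")
}

#' @export
print.fnr_parity <- function(x, ...) {
  cat("FNR parity audit (reference:", x$reference_group, ")\n")
  tab <- x$table
  tab$FNR <- sprintf("%.1f%%", 100 * tab$FNR)
  tab$lower <- NULL; tab$upper <- NULL
  tab$parity_ratio <- round(tab$parity_ratio, 2)
  print(tab, row.names = FALSE)
  cat(sprintf("  overall FNR %.1f%% [%.1f%%, %.1f%%]\n",
              100 * x$overall_fnr, 100 * x$overall_fnr_ci[1],
              100 * x$overall_fnr_ci[2]))
  cat(sprintf("  homogeneity: chi-square(%d) = %.2f, p = %.3f\n",
              x$chisq$df, x$chisq$statistic, x$chisq$p.value))
  invisible(x)
}

#' Cronbach's alpha with a Feldt confidence interval
#'
#' Internal-consistency reliability
#' \eqn{\alpha = k/(k-1)\,(1 - \sum_i s_i^2 / s_T^2)} for a k-item table,
#' with the standard F-distribution (Feldt) interval.
#'
#' @param responses numeric matrix/data frame, items in columns;
#'   incomplete rows dropped.
#' @param conf confidence level.
#' @return list with `alpha`, `ci`, `k`, `n`.
#' @export
cronbach_alpha <- function(responses, conf = 0.95) {
  x <- as.matrix(responses)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  k <- ncol(x); n <- nrow(x)
  if (k < 2 || n < 3) stop("need >= 2 items and >= 3 respondents",
                           call. = FALSE)
  vt <- stats::var(rowSums(x))
  if (vt <= 0) stop("zero total-score variance; alpha undefined",
                    call. = FALSE)
  alpha <- k / (k - 1) * (1 - sum(apply(x, 2, stats::var)) / vt)
  a2 <- (1 - conf) / 2
  df1 <- n - 1; df2 <- (n - 1) * (k - 1)
  ci <- c(lower = 1 - (1 - alpha) * stats::qf(1 - a2, df1, df2),
          upper = 1 - (1 - alpha) * stats::qf(a2, df1, df2))
  list(alpha = alpha, ci = ci, k = k, n = n)
}

#' Agreement between predicted and observed total scores
#'
#' Pearson correlation between CAT-predicted expected totals and observed
#' full-test totals, with the Fisher-z confidence interval from
#' [stats::cor.test()].
#'
#' @param predicted_totals numeric vector of model-predicted totals.
#' @param observed_totals numeric vector of observed totals.
#' @param conf confidence level.
#' @return list with `r`, `ci`, `p.value`, `n`.
#' @export
score_agreement <- function(predicted_totals, observed_totals,
                            conf = 0.95) {
  stopifnot(length(predicted_totals) == length(observed_totals))
  if (length(predicted_totals) < 3)
    stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(predicted_totals) == 0 || stats::sd(observed_totals) == 0)
    stop("constant vector; correlation undefined", call. = FALSE)
  ct <- stats::cor.test(predicted_totals, observed_totals,
                        conf.level = conf)
  list(r = unname(ct$estimate), ci = unname(ct$conf.int),
       p.value = ct$p.value, n = length(predicted_totals))
}
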