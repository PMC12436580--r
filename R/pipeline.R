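#' Read a patient response table from CSV
#'
#' Expects a UTF-8 CSV with a header and columns `item1..item10`, an
#' optional `race` column (missing values mapped to `"Unknown"`) and an
#' optional `age` column. Item responses must be integers in 0..3. In
#' strict mode (default) any out-of-range or missing response is an error
#' naming the row and item; in lenient mode offending rows are dropped
#' with a message.
#'
#' @param path CSV path.
#' @param n_items expected number of item columns.
#' @param strict error (default) or drop invalid rows.
#' @return validated data frame with columns `item1..itemN`, `race`,
#'   and `age` when present.
#' @export
read_epds_responses <- function(path, n_items = 10L, strict = TRUE) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  cols <- paste0("item", seq_len(n_items))
  missing_cols <- setdiff(cols, names(tab))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  items <- as.matrix(tab[cols])
  if (!is.numeric(items))
    stop("item columns must be numeric", call. = FALSE)
  bad <- which(is.na(items) | items < 0 | items > 3 |
                 items != round(items), arr.ind = TRUE)
  if (nrow(bad)) {
    msg <- paste0("row ", bad[, 1], " ", cols[bad[, 2]],
                  " = ", items[bad])
    if (strict)
      stop("invalid response(s): ",
           paste(utils::head(msg, 5), collapse = "; "),
           if (nrow(bad) > 5) " ..." else "", call. = FALSE)
    drop <- unique(bad[, 1])
    message("dropping ", length(drop), " invalid row(s)")
    tab <- tab[-drop, , drop = FALSE]
  }
  if (is.null(tab$race)) tab$race <- "Unknown"
  tab$race[is.na(tab$race) | tab$race == ""] <- "Unknown"
  storage.mode(tab[cols][[1]]) <- "integer"
  for (cc in cols) tab[[cc]] <- as.integer(tab[[cc]])
  rownames(tab) <- NULL
  tab
}

#' @rdname read_epds_responses
#' @param tab response table (e.g. from [generate_cohort()]).
#' @export
write_epds_responses <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' End-to-end screening pipeline
#'
#' Runs the whole evaluation on one response table: fits the graded
#' response model, replays every patient through the CAT, applies the
#' shrinkage correction, classifies full-test and CAT-implied screens,
#' computes accuracy metrics and the FNR-parity audit, and (optionally)
#' writes the fit summary, per-patient CAT results, metrics and a
#' markdown report to an output directory. Deterministic given the input
#' table: no stage draws random numbers.
#'
#' @param responses response data frame (columns `item1..item10`, `race`)
#'   or a CSV path.
#' @param factors 1, 2 or 3.
#' @param config a [cat_config()].
#' @param reference_group parity reference group (default `"White"`).
#' @param moderate_cutoff,high_cutoff classification cutoffs.
#' @param out_dir optional output directory for the report bundle.
#' @param min_n minimum rows for the fit stage.
#' @return list of class `epds_pipeline`: `fit`, `cat` (a `cat_sim`),
#'   `alpha`, `positive_rate`, `truth`, `predicted`, `metrics`,
#'   `agreement`, `fairness`, `items_summary`.
#' @export
run_epds_pipeline <- function(responses, factors = 1,
                              config = cat_config(),
                              reference_group = "White",
                              moderate_cutoff = 8, high_cutoff = 13,
                              out_dir = NULL, min_n = 200L) {
  if (is.character(responses))
    responses <- read_epds_responses(responses)
  cols <- paste0("item", 1:10)
  if (!all(cols %in% names(responses)))
    stop("response table must have columns item1..item10", call. = FALSE)
  items <- as.matrix(responses[cols])
  race <- responses$race %||% rep("Unknown", nrow(items))
  complete <- stats::complete.cases(items)
  items <- items[complete, , drop = FALSE]
  race <- race[complete]

  fit <- grm(items, factors = factors, min_n = min_n, collapse = TRUE)
  sim <- simulate_cat(recode_responses(fit, items), fit, config = config)

  totals <- rowSums(items)
  si <- items[, 10]
  alpha <- cronbach_alpha(items)
  full_cls <- classify_full_test(totals, si, moderate_cutoff, high_cutoff)
  cat_pos <- classify_cat_result(sim$results$expected_total, si,
                                 cutoff = moderate_cutoff)
  metrics <- diagnostic_metrics(full_cls$positive, cat_pos)
  agreement <- score_agreement(sim$results$expected_total, totals)
  fairness <- fnr_parity(full_cls$positive, cat_pos, race,
                         reference_group = reference_group)
  n_adm <- sim$results$n_items

  out <- structure(list(
    fit = fit, cat = sim, alpha = alpha,
    positive_rate = mean(full_cls$positive),
    truth = full_cls$positive, predicted = cat_pos,
    metrics = metrics, agreement = agreement, fairness = fairness,
    items_summary = c(median = stats::median(n_adm),
                      min = min(n_adm), max = max(n_adm))),
    class = "epds_pipeline")
  if (!is.null(out_dir)) .write_pipeline_bundle(out, items, race, out_dir)
  out
}

#' @export
print.epds_pipeline <- function(x, ...) {
  cat("EPDS CAT pipeline (", x$fit$bank$D, "-factor model, N = ",
      x$fit$N, ")\n", sep = "")
  cat(sprintf("  Cronbach's alpha %.2f [%.2f, %.2f]; full-test positive rate %.1f%%\n",
              x$alpha$alpha, x$alpha$ci[1], x$alpha$ci[2],
              100 * x$positive_rate))
  cat(sprintf("  items administered: median %g (range %d-%d)\n",
              x$items_summary["median"], x$items_summary["min"],
              x$items_summary["max"]))
  cat(sprintf("  predicted vs observed totals: r = %.3f [%.3f, %.3f]\n",
              x$agreement$r, x$agreement$ci[1], x$agreement$ci[2]))
  cat(sprintf("  NPV %.1f%%  PPV %.1f%%  overall FNR %.1f%%\n",
              100 * x$metrics$npv, 100 * x$metrics$ppv,
              100 * x$metrics$fnr))
  cat(sprintf("  FNR homogeneity: chi-square(%d) = %.2f, p = %.3f\n",
              x$fairness$chisq$df, x$fairness$chisq$statistic,
              x$fairness$chisq$p.value))
  invisible(x)
}

# Write the report bundle: fit summary JSON, bank CSV, per-patient CAT
# CSV, metrics JSON and a markdown report. Figures are deliberately not
# the data of record; every plotted number is also in the CSV/JSON.
.write_pipeline_bundle <- function(x, items, race, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_item_bank(x$fit$bank, file.path(out_dir, "item_bank.csv"))
  jsonlite::write_json(
    list(loglik = x$fit$loglik, npar = x$fit$npar, AIC = x$fit$AIC,
         BIC = x$fit$BIC, cycles = x$fit$cycles,
         converged = x$fit$converged, Sigma = x$fit$Sigma),
    file.path(out_dir, "fit_summary.json"),
    auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  res <- x$cat$results
  res$race <- race[res$row]
  res$observed_total <- rowSums(items)[res$row]
  res$truth_positive <- x$truth[res$row]
  res$cat_positive <- x$predicted[res$row]
  utils::write.csv(res, file.path(out_dir, "cat_results.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(alpha = x$alpha$alpha, alpha_ci = unname(x$alpha$ci),
         positive_rate = x$positive_rate,
         items_median = unname(x$items_summary["median"]),
         items_range = unname(x$items_summary[c("min", "max")]),
         r_predicted_observed = x$agreement$r,
         r_ci = x$agreement$ci,
         npv = x$metrics$npv, ppv = x$metrics$ppv,
         fnr = x$metrics$fnr,
         cat_positive_rate = x$metrics$positive_rate,
         fnr_by_group = x$fairness$table,
         chisq = x$fairness$chisq),
    file.path(out_dir, "metrics.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")
  md <- c(
    "# EPDS CAT screening report", "",
    sprintf("- N = %d patients, %d-factor graded response model",
            x$fit$N, x$fit$bank$D),
    sprintf("- Cronbach's alpha %.3f [%.3f, %.3f]", x$alpha$alpha,
            x$alpha$ci[1], x$alpha$ci[2]),
    sprintf("- Full-test positive rate %.1f%%", 100 * x$positive_rate),
    sprintf("- Median items administered %g (range %d-%d)",
            x$items_summary["median"], x$items_summary["min"],
            x$items_summary["max"]),
    sprintf("- Predicted vs observed totals r = %.3f [%.3f, %.3f]",
            x$agreement$r, x$agreement$ci[1], x$agreement$ci[2]),
    sprintf("- NPV %.1f%%, PPV %.1f%%, overall FNR %.1f%% [%.1f%%, %.1f%%]",
            100 * x$metrics$npv, 100 * x$metrics$ppv,
            100 * x$metrics$fnr, 100 * x$fairness$overall_fnr_ci[1],
            100 * x$fairness$overall_fnr_ci[2]),
    sprintf("- FNR homogeneity chi-square(%d) = %.2f, p = %.3f",
            x$fairness$chisq$df, x$fairness$chisq$statistic,
            x$fairness$chisq$p.value),
    "", "## Items administered",
    knit_hist(x$cat$results$n_items),
    "", "## Observed total scores (cutoff 8)",
    knit_hist(rowSums(items)),
    "", "## Predicted expected totals",
    knit_hist(round(x$cat$results$expected_total)),
    "", "## FNR parity ratios",
    sprintf("- %s: %.2f", x$fairness$table$group,
            x$fairness$table$parity_ratio))
  writeLines(md, file.path(out_dir, "report.md"))
  invisible(out_dir)
}

# Tiny text histogram for the markdown report.
knit_hist <- function(v) {
  tb <- table(v)
  width <- 40 / max(tb)
  sprintf("    %4s | %s %d", names(tb),
          vapply(tb, function(k) strrep("#", max(1, round(k * width))), ""),
          as.integer(tb))
}
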