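#' Construct an item bank for a graded response model
#'
#' An item bank holds the parameters of a simple-structure (between-item
#' multidimensional) graded response model in slope--intercept form: each
#' item has a single positive slope \eqn{a_i} on exactly one latent factor
#' and strictly decreasing intercepts \eqn{d_{i,1} > \dots > d_{i,K-1}}.
#' The cumulative probability of responding in category \eqn{k} or above is
#' \eqn{P^*_{i,k}(\theta) = \mathrm{logit}^{-1}(a_i \theta_{f(i)} + d_{i,k})}
#' (logistic metric, no 1.7 scaling constant). For a unidimensional model
#' the familiar difficulty parameterisation is \eqn{b_{i,k} = -d_{i,k}/a_i}.
#'
#' @param slopes numeric vector, one positive slope per item (the loading on
#'   the item's factor).
#' @param intercepts numeric matrix, items in rows and the \eqn{K-1}
#'   category intercepts in columns, strictly decreasing within each row.
#' @param factors integer vector assigning each item to one factor
#'   (1-based). Default: all items on factor 1.
#' @param labels item labels; defaults to `item1..itemN`.
#' @param si_item index of the suicidal-ideation item (EPDS item 10), used
#'   by the classification rules. `NA` for banks without one.
#' @param factor_names optional names for the latent factors.
#'
#' @return An object of class `item_bank` with elements `slopes`,
#'   `intercepts`, `factors`, `n_items`, `n_cat`, `D`, `labels`,
#'   `si_item`, `factor_names`.
#' @seealso [epds_factor_structure()], [generate_item_bank()],
#'   [read_item_bank()]
#' @examples
#' bank <- item_bank(slopes = c(1.5, 2),
#'                   intercepts = rbind(c(1, 0, -1), c(2, 0.5, -1.5)))
#' bank
#' @export
item_bank <- function(slopes, intercepts, factors = NULL, labels = NULL,
                      si_item = NA_integer_, factor_names = NULL) {
  slopes <- as.numeric(slopes)
  intercepts <- as.matrix(intercepts)
  n <- length(slopes)
  if (nrow(intercepts) != n)
    stop("`intercepts` must have one row per item", call. = FALSE)
  if (any(!is.finite(slopes)) || any(slopes < 0))
    stop("slopes must be finite and non-negative", call. = FALSE)
  # trailing NA columns are allowed (items with collapsed categories);
  # the non-NA intercepts must form a strictly decreasing prefix
  for (i in seq_len(n)) {
    d <- intercepts[i, ]
    ok <- !is.na(d)
    if (!any(ok) || any(ok != (cumsum(!ok) == 0)))
      stop("intercepts for item ", i, " must be a leading run of values",
           call. = FALSE)
    if (any(diff(d[ok]) >= 0))
      stop("intercepts must be strictly decreasing within item ", i,
           call. = FALSE)
  }
  if (is.null(factors)) factors <- rep(1L, n)
  factors <- as.integer(factors)
  if (length(factors) != n || any(is.na(factors)) || any(factors < 1))
    stop("invalid factor assignment", call. = FALSE)
  D <- max(factors)
  if (is.null(labels)) labels <- paste0("item", seq_len(n))
  if (!is.na(si_item)) si_item <- as.integer(si_item)
  structure(
    list(slopes = slopes, intercepts = unname(intercepts),
         factors = factors, n_items = n, n_cat = ncol(intercepts) + 1L,
         n_cat_item = rowSums(!is.na(intercepts)) + 1L,
         D = D, labels = labels, si_item = si_item,
         factor_names = factor_names %||% paste0("F", seq_len(D))),
    class = "item_bank")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.item_bank <- function(x, ...) {
  cat(sprintf("Graded-response item bank: %d items, %d categories, %d factor%s\n",
              x$n_items, x$n_cat, x$D, if (x$D > 1) "s" else ""))
  tab <- data.frame(item = x$labels, factor = x$factor_names[x$factors],
                    a = round(x$slopes, 3),
                    round(x$intercepts, 3))
  names(tab)[-(1:3)] <- paste0("d", seq_len(x$n_cat - 1L))
  print(tab, row.names = FALSE)
  if (!is.na(x$si_item))
    cat("Suicidal-ideation item:", x$labels[x$si_item], "\n")
  invisible(x)
}

#' EPDS simple-structure factor assignments
#'
#' Returns the conventional assignment of the 10 EPDS items to latent
#' factors: a single general factor (`d = 1`); anxiety (items 3--5) versus
#' anhedonia--depression (items 1, 2, 6--10) (`d = 2`); or anhedonia
#' (items 1--2), anxiety (items 3--5) and depression (items 6--10)
#' (`d = 3`).
#'
#' @param d number of factors, 1, 2 or 3.
#' @return list with integer vector `factors` (length 10) and
#'   `factor_names`.
#' @export
epds_factor_structure <- function(d) {
  d <- as.integer(d)
  if (!d %in% 1:3) stop("`d` must be 1, 2 or 3", call. = FALSE)
  switch(d,
    list(factors = rep(1L, 10), factor_names = "depression-anxiety"),
    list(factors = c(2L, 2L, 1L, 1L, 1L, 2L, 2L, 2L, 2L, 2L),
         factor_names = c("anxiety", "anhedonia-depression")),
    list(factors = c(1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L, 3L, 3L),
         factor_names = c("anhedonia", "anxiety", "depression")))
}

#' Read or write an item bank
#'
#' Item banks are serialised as CSV (columns `item`, `factor`, `slope`,
#' `d1`, `d2`, ...) or JSON. Numbers are written in full precision so a
#' write--read cycle reproduces the bank exactly.
#'
#' @param bank an [item_bank()].
#' @param path file path; format chosen by extension (`.csv` or `.json`).
#' @return `read_item_bank()` returns an `item_bank`;
#'   `write_item_bank()` returns `path` invisibly.
#' @export
write_item_bank <- function(bank, path) {
  stopifnot(inherits(bank, "item_bank"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- list(slopes = bank$slopes, intercepts = bank$intercepts,
                factors = bank$factors, labels = bank$labels,
                si_item = bank$si_item, factor_names = bank$factor_names)
    jsonlite::write_json(obj, path, digits = I(17), auto_unbox = FALSE,
                         matrix = "rowmajor", na = "null")
  } else {
    km1 <- bank$n_cat - 1L
    num <- function(v) vapply(v, function(z) sprintf("%.17g", z), "")
    tab <- data.frame(item = bank$labels, factor = bank$factors,
                      slope = num(bank$slopes))
    for (k in seq_len(km1)) tab[[paste0("d", k)]] <- num(bank$intercepts[, k])
    utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_item_bank
#' @param si_item suicidal-ideation item index used when the CSV does not
#'   carry one (CSV stores parameters only; JSON round-trips everything).
#' @export
read_item_bank <- function(path, si_item = NA_integer_) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    si <- obj$si_item
    if (is.null(si) || length(si) == 0 || is.na(si)) si <- NA_integer_
    item_bank(obj$slopes, obj$intercepts, obj$factors, obj$labels,
              si_item = si, factor_names = obj$factor_names)
  } else {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    dcols <- grep("^d[0-9]+$", names(tab), value = TRUE)
    item_bank(tab$slope, as.matrix(tab[dcols]), tab$factor, tab$item,
              si_item = si_item)
  }
}
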