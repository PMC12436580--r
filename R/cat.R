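#' Configuration of the adaptive-testing engine
#'
#' @param delta stopping threshold on the change in estimated trait
#'   scores: the test terminates once the change between successive EAP
#'   estimates falls below `delta` (default 0.05).
#' @param min_items minimum number of items administered (default 2; a
#'   trait-change rule needs two successive estimates).
#' @param max_items maximum number of items (default: the whole bank).
#' @param delta_norm how the change is aggregated across dimensions for
#'   multi-factor models: `"max"` (default) or `"mean"` absolute change.
#' @param force_si always administer the suicidal-ideation item before
#'   finishing, even when the stopping rule would skip it. Off by
#'   default, matching a simulation in which the CAT may skip it.
#' @param correct_shrinkage apply the empirical-reliability shrinkage
#'   correction to the cohort's final trait estimates.
#' @param correct_before_total compute expected total scores from the
#'   corrected (rather than raw) estimates.
#' @return list of class `cat_config`.
#' @export
cat_config <- function(delta = 0.05, min_items = 2L, max_items = NULL,
                       delta_norm = c("max", "mean"), force_si = FALSE,
                       correct_shrinkage = TRUE,
                       correct_before_total = TRUE) {
  if (!is.numeric(delta) || delta <= 0)
    stop("`delta` must be positive", call. = FALSE)
  if (min_items < 1) stop("`min_items` must be >= 1", call. = FALSE)
  structure(list(delta = delta, min_items = as.integer(min_items),
                 max_items = max_items,
                 delta_norm = match.arg(delta_norm),
                 force_si = isTRUE(force_si),
                 correct_shrinkage = isTRUE(correct_shrinkage),
                 correct_before_total = isTRUE(correct_before_total)),
            class = "cat_config")
}

#' Select the next item to administer
#'
#' Selection criteria: `"MI"` (maximum information) and `"trace"` pick the
#' available item with the largest trace of the Fisher information matrix
#' at the current trait estimate; `"MPWI"` (maximum posterior-weighted
#' information) integrates each item's information against the current
#' trait posterior over the quadrature grid. Ties are broken by the
#' lowest item index.
#'
#' @param bank an [item_bank()].
#' @param available integer vector of item indices still available.
#' @param theta current trait estimate (used by `"MI"`/`"trace"`).
#' @param posterior current posterior weights over `grid` nodes (used by
#'   `"MPWI"`).
#' @param rule `"MI"`, `"MPWI"` or `"trace"`.
#' @param grid the [quad_grid()] the posterior lives on.
#' @param info_grid optional precomputed `n_items x n_nodes` matrix of
#'   item information traces at the grid nodes (see
#'   [cat_information_grid()]).
#' @return the selected item index.
#' @export
select_next_item <- function(bank, available, theta = rep(0, bank$D),
                             posterior = NULL,
                             rule = c("MPWI", "MI", "trace"),
                             grid = NULL, info_grid = NULL) {
  rule <- match.arg(rule)
  available <- sort(as.integer(available))
  if (!length(available)) stop("no items available", call. = FALSE)
  crit <- switch(rule,
    MI = ,
    trace = vapply(available, function(i)
      .grm_info_scalar(bank$slopes[i], .item_d(bank, i),
                       theta[bank$factors[i]]), 0),
    MPWI = {
      if (is.null(posterior)) stop("MPWI needs a posterior", call. = FALSE)
      if (is.null(info_grid)) {
        if (is.null(grid)) stop("MPWI needs the quadrature grid", call. = FALSE)
        info_grid <- cat_information_grid(bank, grid)
      }
      drop(info_grid[available, , drop = FALSE] %*%
             (posterior / sum(posterior)))
    })
  available[which.max(crit)]
}

#' Item information traces over a quadrature grid
#'
#' Precomputes `trace(I_i(theta))` for every bank item at every node of
#' `grid`, the lookup the posterior-weighted-information criterion needs.
#'
#' @inheritParams select_next_item
#' @return `n_items x n_nodes` matrix.
#' @export
cat_information_grid <- function(bank, grid) {
  t(vapply(seq_len(bank$n_items), function(i)
    .grm_info_scalar(bank$slopes[i], .item_d(bank, i),
                     grid$points)[grid$index[, bank$factors[i]]],
    numeric(nrow(grid$nodes))))
}

#' Stopping rule of the adaptive test
#'
#' The test stops when the change in estimated trait scores between the
#' two most recent estimates falls below `config$delta` (once at least
#' `min_items` items are administered), or when `max_items` is reached or
#' the bank is exhausted.
#'
#' @param trajectory matrix of EAP estimates so far (one row per
#'   administered item, `D` columns).
#' @param config a [cat_config()].
#' @param n_available number of items still available.
#' @return `TRUE` to stop, `FALSE` to continue.
#' @export
check_termination <- function(trajectory, config, n_available = 1L) {
  trajectory <- as.matrix(trajectory)
  n_done <- nrow(trajectory)
  if (n_done < 1) stop("empty trajectory", call. = FALSE)
  max_items <- config$max_items %||% (n_done + n_available)
  if (n_available < 1L || n_done >= max_items) return(TRUE)
  if (n_done < max(config$min_items, 2L)) return(FALSE)
  d <- abs(trajectory[n_done, ] - trajectory[n_done - 1L, ])
  change <- if (config$delta_norm == "max") max(d) else mean(d)
  change < config$delta
}

#' Run the adaptive test for one patient (real-data simulation)
#'
#' Replays one patient's recorded full-test responses through the CAT:
#' the first item is chosen by maximum information at the prior mean
#' (one-factor models) or by the trace rule at the origin (multi-factor
#' models); subsequent items by maximum posterior-weighted information
#' (one factor) or the trace of the information matrix at the current EAP
#' estimate (multi-factor). The "answer" to each administered item is the
#' patient's recorded response; after each answer the trait is re-scored
#' by EAP and the stopping rule checked. The run is deterministic.
#'
#' @param responses the patient's complete recorded responses (length
#'   `n_items`, values `0..K-1`).
#' @param bank an [item_bank()].
#' @param Sigma factor correlation matrix.
#' @param config a [cat_config()].
#' @param grid a [quad_grid()] (defaults to the standard grid for the
#'   bank's dimension).
#' @param precomp optional precomputation from [cat_precompute()] shared
#'   across patients.
#' @return list of class `cat_result`: `administered` (item order),
#'   `responses_seen`, `trajectory` (EAP after each item), `se_trajectory`,
#'   `theta`, `se` (final), `expected_total` (raw, from the uncorrected
#'   estimate), `n_administered`.
#' @export
run_cat <- function(responses, bank, Sigma = diag(bank$D),
                    config = cat_config(), grid = NULL, precomp = NULL) {
  responses <- as.integer(responses)
  if (length(responses) != bank$n_items || anyNA(responses))
    stop("need a complete recorded response vector", call. = FALSE)
  if (any(responses < 0L | responses >= bank$n_cat_item))
    stop("recorded response outside the bank's category range ",
         "(recode collapsed items first)", call. = FALSE)
  if (is.null(precomp)) precomp <- cat_precompute(bank, Sigma, grid)
  grid <- precomp$grid
  D <- bank$D

  max_items <- config$max_items %||% bank$n_items
  post <- precomp$prior
  available <- seq_len(bank$n_items)
  administered <- integer(0)
  seen <- integer(0)
  traj <- matrix(NA_real_, 0, D)
  setraj <- matrix(NA_real_, 0, D)
  theta <- rep(0, D)

  repeat {
    rule <- if (length(administered) == 0L) {
      if (D == 1L) "MI" else "trace"
    } else if (D == 1L) "MPWI" else "trace"
    nxt <- select_next_item(bank, available, theta = theta,
                            posterior = post, rule = rule, grid = grid,
                            info_grid = precomp$info_grid)
    r <- responses[nxt]
    post <- post * precomp$pnode[[nxt]][, r + 1L]
    post <- post / sum(post)
    theta <- drop(crossprod(post, grid$nodes))
    m2 <- drop(crossprod(post, grid$nodes^2))
    se <- sqrt(pmax(m2 - theta^2, 0))
    administered <- c(administered, nxt)
    seen <- c(seen, r)
    available <- setdiff(available, nxt)
    traj <- rbind(traj, theta)
    setraj <- rbind(setraj, se)
    stop_now <- check_termination(traj, config, length(available)) ||
      length(administered) >= max_items
    if (stop_now && config$force_si && !is.na(bank$si_item) &&
        !(bank$si_item %in% administered) && bank$si_item %in% available) {
      available <- c(bank$si_item)  # force it as the final item
      next
    }
    if (stop_now) break
  }

  structure(list(administered = administered, responses_seen = seen,
                 trajectory = unname(traj), se_trajectory = unname(setraj),
                 theta = theta, se = se,
                 expected_total = expected_total_score(bank, theta),
                 n_administered = length(administered)),
            class = "cat_result")
}

#' @rdname run_cat
#' @export
cat_precompute <- function(bank, Sigma = diag(bank$D), grid = NULL,
                           floor = 1e-10) {
  if (is.null(grid)) grid <- quad_grid(bank$D)
  pnode <- lapply(seq_len(bank$n_items), function(i) {
    p <- pmax(.grm_cat_probs(bank$slopes[i], .item_d(bank, i),
                             grid$points), floor)
    p[grid$index[, bank$factors[i]], , drop = FALSE]
  })
  list(grid = grid, prior = prior_weights(grid, Sigma),
       pnode = pnode,
       info_grid = if (bank$D == 1L) cat_information_grid(bank, grid))
}

#' @export
print.cat_result <- function(x, ...) {
  cat("CAT run:", x$n_administered, "items administered (",
      paste(x$administered, collapse = ", "), ")\n")
  cat("final theta:", paste(round(x$theta, 3), collapse = ", "),
      " expected total:", round(x$expected_total, 2), "\n")
  invisible(x)
}

#' Real-data CAT simulation over a cohort
#'
#' Runs [run_cat()] for every row of a recorded response table, then
#' applies the empirical-reliability shrinkage correction to the final
#' trait estimates across the cohort and maps them to expected total
#' scores on the 0--30 scale. Each patient's result depends only on that
#' patient's responses.
#'
#' @param responses matrix/data frame of complete recorded responses
#'   (rows = patients); incomplete rows are skipped with a message unless
#'   `strict = TRUE`, in which case they are an error.
#' @param fit a fitted [grm()] object, or an [item_bank()] (then `Sigma`
#'   may be given).
#' @param Sigma factor correlation matrix when `fit` is a bare bank.
#' @param config a [cat_config()].
#' @param strict error on incomplete rows instead of skipping.
#' @return object of class `cat_sim`: `results` data frame (one row per
#'   scored patient: `n_items`, final `theta.*`/`se.*`, corrected
#'   estimates, `expected_total`), `administered` list, `rho`
#'   (empirical reliabilities), `skipped` row indices, `config`, `bank`,
#'   `Sigma`.
#' @export
simulate_cat <- function(responses, fit, Sigma = NULL,
                         config = cat_config(), strict = FALSE) {
  if (inherits(fit, "grm")) {
    bank <- fit$bank
    Sigma <- Sigma %||% fit$Sigma
    grid <- fit$grid
  } else {
    bank <- fit
    Sigma <- Sigma %||% diag(bank$D)
    grid <- quad_grid(bank$D)
  }
  resp <- as.matrix(responses)
  storage.mode(resp) <- "integer"
  ok <- stats::complete.cases(resp)
  if (any(!ok)) {
    if (strict) stop(sum(!ok), " incomplete record(s)", call. = FALSE)
    message("skipping ", sum(!ok), " incomplete record(s): rows ",
            paste(utils::head(which(!ok), 10), collapse = ", "))
  }
  rows <- which(ok)
  if (!length(rows)) stop("no complete records to simulate", call. = FALSE)
  pre <- cat_precompute(bank, Sigma, grid)
  D <- bank$D

  runs <- vector("list", length(rows))
  for (j in seq_along(rows))
    runs[[j]] <- run_cat(resp[rows[j], ], bank, Sigma, config,
                         precomp = pre)

  theta <- do.call(rbind, lapply(runs, `[[`, "theta"))
  se <- do.call(rbind, lapply(runs, `[[`, "se"))
  n_adm <- vapply(runs, `[[`, 0L, "n_administered")

  rho <- rep(NA_real_, D)
  theta_c <- theta
  if (config$correct_shrinkage && length(rows) >= 2) {
    rel <- tryCatch(empirical_reliability(theta, se),
                    error = function(e) {
                      message("shrinkage correction skipped: ",
                              conditionMessage(e))
                      NULL
                    })
    if (!is.null(rel)) {
      rho <- rel$rho
      theta_c <- rel$theta_corrected
    }
  }
  tot <- expected_total_score(
    bank, if (config$correct_before_total) theta_c else theta)
  tot <- pmin(pmax(tot, 0), sum(bank$n_cat_item - 1L))

  res <- data.frame(row = rows, n_items = n_adm)
  for (d in seq_len(D)) res[[paste0("theta", d)]] <- theta[, d]
  for (d in seq_len(D)) res[[paste0("se", d)]] <- se[, d]
  for (d in seq_len(D)) res[[paste0("theta_corr", d)]] <- theta_c[, d]
  res$expected_total <- tot

  structure(list(results = res,
                 administered = lapply(runs, `[[`, "administered"),
                 rho = rho, skipped = which(!ok), config = config,
                 bank = bank, Sigma = Sigma),
            class = "cat_sim")
}

#' @export
print.cat_sim <- function(x, ...) {
  n <- x$results$n_items
  cat(sprintf("Real-data CAT simulation: %d patients, %d-factor bank\n",
              nrow(x$results), x$bank$D))
  cat(sprintf("  items administered: median %g, range %d-%d (full test: %d)\n",
              stats::median(n), min(n), max(n), x$bank$n_items))
  if (!anyNA(x$rho))
    cat("  empirical reliability:",
        paste(round(x$rho, 3), collapse = ", "), "\n")
  cat(sprintf("  expected totals: mean %.2f, %.1f%% at or above 8\n",
              mean(x$results$expected_total),
              100 * mean(x$results$expected_total >= 8)))
  invisible(x)
}

#' @export
summary.cat_sim <- function(object, ...) {
  n <- object$results$n_items
  list(n_patients = nrow(object$results),
       median_items = stats::median(n),
       range_items = range(n),
       mean_items = mean(n),
       rho = object$rho,
       mean_expected_total = mean(object$results$expected_total))
}
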