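#' Simulate predicted responses from a fitted model
#'
#' Draws `multiplier * N` synthetic respondents: an attribute pattern from
#' the fitted structural distribution, then one option per item from the
#' fitted conditional probabilities of the respondent's reduced pattern.
#'
#' @param fit A `gndm_fit`.
#' @param multiplier Positive integer; predicted sample size is
#'   `multiplier * N` (default 10).
#' @param seed Optional seed (caller's RNG state restored).
#' @return An `N~ x J` integer response matrix.
#' @export
simulate_predicted <- function(fit, multiplier = 10, seed = NULL) {
  stopifnot(multiplier >= 1)
  Ntil <- as.integer(multiplier * fit$N)
  with_seed(seed, {
    l <- sample.int(length(fit$structural), Ntil, replace = TRUE,
                    prob = fit$structural)
    draw_responses(l, fit$P, fit$qmatrix, fit$hmaps)
  })
}

# sample one option per item for respondents with full-pattern indices l
draw_responses <- function(l, P, qmatrix, hmaps) {
  N <- length(l)
  X <- matrix(0L, N, qmatrix$J)
  for (jj in seq_len(qmatrix$J)) {
    it <- qmatrix$items[[jj]]
    h <- hmaps[[jj]][l]
    for (hh in seq_len(it$H)) {
      idx <- which(h == hh)
      if (length(idx) == 0) next
      X[idx, jj] <- sample.int(it$C, length(idx), replace = TRUE,
                               prob = P[[jj]][hh, ])
    }
  }
  colnames(X) <- paste0("I", seq_len(qmatrix$J))
  X
}

# 0/1 indicator matrix over the dichotomized options c = 2..C_j of each item
dichotomize <- function(X, qmatrix) {
  cols <- list()
  meta <- list()
  for (jj in seq_len(qmatrix$J)) {
    it <- qmatrix$items[[jj]]
    for (c in 2:it$C) {
      cols[[length(cols) + 1L]] <- as.integer(X[, jj] == c)
      meta[[length(meta) + 1L]] <- c(jj, c)
    }
  }
  Y <- do.call(cbind, cols)
  m <- do.call(rbind, meta)
  list(Y = Y, item = m[, 1], option = m[, 2])
}

# 2x2 cell counts for every unordered column pair of indicator matrix Y,
# with a +0.5 continuity correction on every cell
pair_counts <- function(Y) {
  n <- nrow(Y)
  n11 <- crossprod(Y)
  cs <- colSums(Y)
  n10 <- outer(cs, rep(1, length(cs))) - n11   # first=1, second=0
  n01 <- outer(rep(1, length(cs)), cs) - n11
  n00 <- n - n11 - n10 - n01
  list(n11 = n11 + 0.5, n10 = n10 + 0.5, n01 = n01 + 0.5, n00 = n00 + 0.5)
}

#' Log-odds-ratio residual pairs
#'
#' For every unordered pair of dichotomized item options (`c >= 2`), the
#' absolute difference `l` between the observed and model-predicted
#' log-odds ratios of the 2x2 cross-table, its approximate standard error
#' `SE = sqrt(N~ (1/N~11 + 1/N~00 + 1/N~01 + 1/N~10) / N)` from the
#' predicted counts, and the z-score `l / SE`.  A 0.5 continuity
#' correction is added to every cell of both tables (within-item pairs
#' have structural zeros).
#'
#' @param observed N x J observed responses (matrix or data frame).
#' @param predicted Predicted responses from [simulate_predicted()].
#' @param qmatrix A `gndm_qmatrix`.
#' @param include_within_item Keep pairs of options of the same item
#'   (default TRUE, matching the `(T-J)(T-J-1)/2` pair count).
#' @return A tibble with one row per pair: `item1`, `option1`, `item2`,
#'   `option2`, `lor_obs`, `lor_pred`, `l`, `se`, `z`.
#' @export
lor_residuals <- function(observed, predicted, qmatrix,
                          include_within_item = TRUE) {
  X <- response_matrix(observed, qmatrix)
  N <- nrow(X)
  Ntil <- nrow(predicted)
  do <- dichotomize(X, qmatrix)
  dp <- dichotomize(predicted, qmatrix)
  co <- pair_counts(do$Y)
  cp <- pair_counts(dp$Y)
  lor_o <- log(co$n11 * co$n00 / (co$n01 * co$n10))
  lor_p <- log(cp$n11 * cp$n00 / (cp$n01 * cp$n10))
  se <- sqrt(Ntil * (1 / cp$n11 + 1 / cp$n00 + 1 / cp$n01 + 1 / cp$n10) / N)
  M <- length(do$item)
  pr <- which(lower.tri(matrix(0, M, M)), arr.ind = TRUE)  # row > col
  a <- pr[, 2]  # first member (lower column index)
  b <- pr[, 1]
  out <- tibble(
    item1 = do$item[a], option1 = do$option[a],
    item2 = do$item[b], option2 = do$option[b],
    lor_obs = lor_o[cbind(b, a)], lor_pred = lor_p[cbind(b, a)],
    se = se[cbind(b, a)]
  ) %>%
    mutate(l = abs(.data$lor_obs - .data$lor_pred), z = .data$l / .data$se)
  if (!include_within_item) out <- filter(out, .data$item1 != .data$item2)
  select(out, "item1", "option1", "item2", "option2",
         "lor_obs", "lor_pred", "l", "se", "z")
}

#' Absolute fit assessment by simulated-predicted LOR residuals
#'
#' Simulates predicted responses from the fitted model, computes the
#' z-scores of all pairwise log-odds-ratio residuals, and aggregates them
#' into root-mean-square statistics: per option
#' `sl_jc = sqrt(sum z^2 / (T - J - 1))`, per item
#' `sl_j = sum_c sl_jc / (C_j - 1)`, and the test level
#' `sl = sqrt(2 sum z^2 / ((T - J)(T - J - 1)))`.  The maximum z-score is
#' tested against the Bonferroni-corrected two-sided normal critical value
#' at level `alpha / n_pairs`.
#'
#' @param fit A `gndm_fit`.
#' @param observed Observed responses; defaults to the data the model was
#'   fitted to.
#' @param alpha Significance level for the max-z test (default 0.05).
#' @param multiplier Predicted-sample multiplier (default 10).
#' @param include_within_item Include within-item option pairs (default
#'   TRUE).
#' @param seed Optional seed for the predicted draw.
#' @param predicted Optionally a precomputed predicted response matrix
#'   (e.g. for a predicted-equals-observed self-test).
#' @return An object of class `gndm_assessment`: list with `pairs`
#'   (residual tibble), `option_stats`, `item_stats`, `sl`, `max_z`,
#'   `n_pairs`, `critical`, `reject`, `alpha`.
#' @export
assess_fit <- function(fit, observed = NULL, alpha = 0.05, multiplier = 10,
                       include_within_item = TRUE, seed = NULL,
                       predicted = NULL) {
  stopifnot(inherits(fit, "gndm_fit"))
  qmatrix <- fit$qmatrix
  X <- if (is.null(observed)) fit$data else response_matrix(observed, qmatrix)
  if (is.null(predicted)) {
    predicted <- simulate_predicted(fit, multiplier, seed)
  }
  pairs <- lor_residuals(X, predicted, qmatrix, include_within_item)
  stats <- fit_statistics(pairs, qmatrix, alpha)
  structure(
    c(list(pairs = pairs), stats,
      list(alpha = alpha, multiplier = multiplier,
           include_within_item = include_within_item,
           N = nrow(X), N_pred = nrow(predicted))),
    class = "gndm_assessment"
  )
}

#' Aggregate LOR residual z-scores into misfit statistics
#'
#' Computes the per-option root-mean-square statistic
#' `sl_jc = sqrt(sum z^2 / (T - J - 1))` over the pairs containing the
#' option, the per-item average `sl_j = sum_c sl_jc / (C_j - 1)`, the
#' test-level `sl = sqrt(2 sum z^2 / ((T - J)(T - J - 1)))`, and the
#' Bonferroni max-z decision: reject when the largest z-score exceeds the
#' two-sided normal critical value at `alpha / n_pairs`.
#'
#' @param pairs Residual tibble from [lor_residuals()].
#' @param qmatrix The `gndm_qmatrix` (supplies `T`, `J`, `C_j`).
#' @param alpha Significance level (default 0.05).
#' @return A list: `option_stats`, `item_stats`, `sl`, `max_z`, `n_pairs`,
#'   `critical`, `reject`.
#' @export
fit_statistics <- function(pairs, qmatrix, alpha = 0.05) {
  TmJ <- qmatrix$T_total - qmatrix$J
  z2 <- pairs$z^2
  opts <- purrr::map(seq_len(qmatrix$J), function(jj) {
    tibble(item = jj, option = 2:qmatrix$items[[jj]]$C)
  }) %>% bind_rows()
  option_stats <- opts %>%
    mutate(sl_jc = purrr::map2_dbl(.data$item, .data$option, function(j, c) {
      sel <- (pairs$item1 == j & pairs$option1 == c) |
             (pairs$item2 == j & pairs$option2 == c)
      sqrt(sum(z2[sel]) / (TmJ - 1))
    }))
  item_stats <- option_stats %>%
    group_by(item = .data$item) %>%
    summarise(sl_j = sum(.data$sl_jc) /
                (qmatrix$items[[.data$item[1]]]$C - 1), .groups = "drop")
  sl <- sqrt(2 * sum(z2) / (TmJ * (TmJ - 1)))
  n_pairs <- nrow(pairs)
  max_z <- if (n_pairs) max(pairs$z) else 0
  critical <- if (n_pairs) qnorm(1 - alpha / (2 * n_pairs)) else Inf
  list(option_stats = option_stats, item_stats = item_stats, sl = sl,
       max_z = max_z, n_pairs = n_pairs, critical = critical,
       reject = max_z > critical)
}

#' @export
print.gndm_assessment <- function(x, ...) {
  cat(sprintf("<gndm_assessment> %d LOR residual pairs (N = %d, N~ = %d)\n",
              x$n_pairs, x$N, x$N_pred))
  cat(sprintf("  sl = %.4f, max z = %.3f vs Bonferroni critical %.3f: %s\n",
              x$sl, x$max_z, x$critical,
              if (x$reject) "misfit flagged" else "no misfit flagged"))
  invisible(x)
}

#' @rdname tidy
#' @export
tidy.gndm_assessment <- function(x, ...) {
  x$pairs
}

#' @rdname glance
#' @export
glance.gndm_assessment <- function(x, ...) {
  tibble(sl = x$sl, max_z = x$max_z, n_pairs = x$n_pairs,
         critical = x$critical, reject = x$reject, alpha = x$alpha)
}

#' Rank items and options by misfit
#'
#' Orders options by `sl_jc` and items by `sl_j`, descending, ties broken
#' by index; the top-ranked entries are the most likely misspecified.
#'
#' @param report A `gndm_assessment`.
#' @return A list with tibbles `options` and `items`, ranked.
#' @export
flag_misfit <- function(report) {
  stopifnot(inherits(report, "gndm_assessment"))
  list(
    options = arrange(report$option_stats, dplyr::desc(.data$sl_jc),
                      .data$item, .data$option),
    items = arrange(report$item_stats, dplyr::desc(.data$sl_j), .data$item)
  )
}
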