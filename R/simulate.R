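#' Simulate correlated dichotomous attributes
#'
#' Multivariate-normal threshold method: a latent vector
#' `z ~ MVN(0, Sigma)` with unit variances and exchangeable correlation
#' `R` is drawn for each respondent, and attribute `k` is possessed when
#' `z_k` exceeds the `(1 - p_k)` normal quantile, so the marginal
#' prevalence of attribute `k` is `p_k`.
#'
#' @param n Number of respondents.
#' @param prevalence Vector of attribute prevalences in (0, 1); its length
#'   sets K.
#' @param R Exchangeable latent correlation in `[0, 1)`, or a full K x K
#'   correlation matrix.
#' @param seed Optional seed (caller's RNG state restored).
#' @return A tibble with columns `resp` and `A1..AK` (0/1).
#' @examples
#' a <- simulate_attributes(5, c(0.7, 0.3), R = 0.5, seed = 1)
#' @export
simulate_attributes <- function(n, prevalence, R = 0, seed = NULL) {
  K <- length(prevalence)
  stopifnot(all(prevalence > 0 & prevalence < 1))
  with_seed(seed, {
    if (is.matrix(R)) {
      ch <- tryCatch(chol(R), error = function(e) {
        abort("latent correlation matrix is not positive definite")
      })
      z <- matrix(rnorm(n * K), n, K) %*% ch
    } else {
      if (R < 0 || R >= 1) {
        abort("exchangeable latent correlation must be in [0, 1)")
      }
      g <- rnorm(n)
      z <- sqrt(R) * g + sqrt(1 - R) * matrix(rnorm(n * K), n, K)
    }
    thr <- qnorm(1 - prevalence)
    a <- sweep(z, 2, thr, ">") + 0L
    colnames(a) <- paste0("A", seq_len(K))
    bind_cols(tibble(resp = as.character(seq_len(n))), as_tibble(a))
  })
}

# coerce attribute input (tibble with resp/A* columns, or matrix) to N x K
attribute_matrix <- function(attributes, K = NULL) {
  if (is.data.frame(attributes)) {
    a <- as.matrix(attributes[setdiff(names(attributes), "resp")])
  } else {
    a <- attributes
  }
  storage.mode(a) <- "integer"
  if (!is.null(K)) stopifnot(ncol(a) == K)
  a
}

# generating blocks: covered reduced patterns follow the expanded
# pattern-expected rows (expected option e, others u), uncovered reduced
# patterns (no expected option) are answered uniformly at random
generating_blocks <- function(qmatrix, e, u, map = NULL) {
  if (is.null(map)) map <- expected_map(qmatrix)
  J <- qmatrix$J
  e <- rep_len(e, J)
  u <- rep_len(u, J)
  lapply(seq_len(J), function(jj) {
    it <- qmatrix$items[[jj]]
    mj <- map[map$item == it$item, , drop = FALSE]
    P <- matrix(0, it$H, it$C)
    for (h in seq_len(it$H)) {
      O <- mj$option[mj$h == h]
      if (length(O) == 0) {
        P[h, ] <- 1 / it$C
      } else if (length(O) == 1) {
        P[h, ] <- u[jj]
        P[h, O] <- e[jj]
      } else {
        abort(sprintf(
          "item %s pattern %d has %d expected options; supply full blocks",
          it$item, h, length(O)))
      }
    }
    bad <- abs(rowSums(P) - 1) > 1e-8
    if (any(bad)) {
      abort(sprintf(
        "item %s: generating row does not sum to 1 (e = %.4f, u = %.4f, C = %d)",
        it$item, e[jj], u[jj], it$C))
    }
    P
  })
}

#' Simulate nominal responses
#'
#' Generates option choices from pattern-expected (PEDM) generating
#' parameters or explicit item blocks.  Each respondent's attribute vector
#' is reduced per item; a covered reduced pattern selects its expected
#' option with probability `e` and each other option with probability `u`,
#' while an uncovered pattern (uncontrolled items without a NOA option)
#' selects uniformly among the options.
#'
#' @param attributes Attribute tibble from [simulate_attributes()] (or an
#'   N x K 0/1 matrix).
#' @param qmatrix A `gndm_qmatrix`.
#' @param e,u Expected / unexpected selection probabilities, scalar or
#'   per-item vectors; for covered items `e + (C_j - 1) u` must be 1.
#'   Ignored when `blocks` is supplied.
#' @param blocks Optional list of explicit `H_j x C_j` generating blocks.
#' @param seed Optional seed (caller's RNG state restored).
#' @return A tibble with columns `resp` and `I1..IJ` (option codes).
#' @export
simulate_responses <- function(attributes, qmatrix, e = NULL, u = NULL,
                               blocks = NULL, seed = NULL) {
  a <- attribute_matrix(attributes, qmatrix$K)
  if (is.null(blocks)) {
    stopifnot(!is.null(e), !is.null(u))
    blocks <- generating_blocks(qmatrix, e, u)
  }
  patterns <- pattern_matrix(qmatrix$K)
  hmaps <- lapply(qmatrix$items, function(it) {
    reduced_pattern_index(patterns, it$support)
  })
  l <- reduced_pattern_index(a, seq_len(qmatrix$K))
  X <- with_seed(seed, draw_responses(l, blocks, qmatrix, hmaps))
  bind_cols(
    tibble(resp = if (is.data.frame(attributes) &&
                      "resp" %in% names(attributes)) {
      as.character(attributes$resp)
    } else {
      as.character(seq_len(nrow(a)))
    }),
    as_tibble(X)
  )
}

#' Classification accuracy
#'
#' Compares estimated to true attributes: `ca_pattern` is the proportion
#' of respondents whose whole attribute vector is recovered exactly;
#' `ca_A<k>` the per-attribute agreement; `ca_attr_mean` their average.
#'
#' @param truth,estimate Attribute tibbles (columns `A1..AK`, optional
#'   `resp`) or 0/1 matrices of equal shape.
#' @return A one-row tibble.
#' @export
classification_accuracy <- function(truth, estimate) {
  a <- attribute_matrix(truth)
  b <- attribute_matrix(estimate, ncol(a))
  stopifnot(nrow(a) == nrow(b))
  agree <- a == b
  per_attr <- colMeans(agree)
  out <- tibble(ca_pattern = mean(rowSums(agree) == ncol(a)),
                ca_attr_mean = mean(per_attr))
  bind_cols(out, as_tibble(as.list(setNames(per_attr,
                                            paste0("ca_A", seq_along(per_attr))))))
}

#' Parameter-recovery statistics across replications
#'
#' For each parameter: `bias` = mean estimate minus truth, `rmse` =
#' root-mean-square deviation from truth, and `mean_se` = root mean
#' squared reported SE, across replications.
#'
#' @param estimates Long tibble with columns `rep`, grouping keys, and
#'   `estimate` (optionally `se`).
#' @param truth Tibble with the same grouping keys and a `truth` column.
#' @param keys Character vector of grouping key columns (default
#'   `c("item", "option", "parameter")` intersected with what is present).
#' @return A tibble with one row per parameter: keys, `truth`, `bias`,
#'   `rmse`, `mean_se`, `n_reps`.
#' @export
recovery_stats <- function(estimates, truth,
                           keys = intersect(c("item", "option", "parameter"),
                                            names(estimates))) {
  stopifnot(length(keys) > 0)
  est <- left_join(estimates, truth, by = keys)
  if (!"se" %in% names(est)) est$se <- NA_real_
  est %>%
    group_by(dplyr::across(dplyr::all_of(keys))) %>%
    summarise(
      truth = .data$truth[1],
      bias = mean(.data$estimate) - .data$truth[1],
      rmse = sqrt(mean((.data$estimate - .data$truth[1])^2)),
      mean_se = sqrt(mean(.data$se^2)),
      n_reps = dplyr::n(),
      .groups = "drop"
    )
}
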