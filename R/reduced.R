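#' Collapse a saturated fit to pattern-expected (PEDM) parameters
#'
#' For each option `c` of each item, the PEDM keeps two numbers: `e_jc`,
#' the (weighted) average of `P_c(eta_jh)` over the option's expected
#' reduced patterns, and `u_jc`, the weighted average over all remaining
#' (unexpected) patterns.  Averages are weighted by the estimated sample
#' size of each pattern, `w_jh = sum_i p(eta_jh | X_i)`.
#'
#' @param fit A `gndm_fit`.
#' @param map Optional [expected_map()]; defaults to the one implied by the
#'   fit's Q-matrix.
#' @return An object of class `pedm_par`: a tibble with columns `item`,
#'   `option`, `e`, `u`; options with an empty expected set get `e = NA`.
#' @export
collapse_pedm <- function(fit, map = NULL) {
  stopifnot(inherits(fit, "gndm_fit"))
  if (is.null(map)) map <- expected_map(fit$qmatrix)
  rows <- purrr::map(seq_len(fit$qmatrix$J), function(jj) {
    it <- fit$qmatrix$items[[jj]]
    w <- colSums(posterior_eta(fit, jj))
    mj <- map[map$item == it$item, , drop = FALSE]
    purrr::map(seq_len(it$C), function(c) {
      E <- mj$h[mj$option == c]
      U <- setdiff(seq_len(it$H), E)
      e <- if (length(E)) wmean(fit$P[[jj]][E, c], w[E]) else NA_real_
      u <- if (length(U)) wmean(fit$P[[jj]][U, c], w[U]) else NA_real_
      tibble(item = it$item, option = c, e = e, u = u)
    }) %>% bind_rows()
  })
  out <- bind_rows(rows)
  structure(out, class = c("pedm_par", class(out)), map = map)
}

wmean <- function(x, w) {
  if (sum(w) <= 0) return(mean(x))
  sum(x * w) / sum(w)
}

#' Collapse a saturated fit to option-expected (OEDM) parameters
#'
#' For each reduced pattern `h` of each item, `e*_jh` is the fitted
#' probability of selecting an expected option given `eta_jh`; with several
#' expected options it is by default the sum of their probabilities (the
#' probability of the event "selects an expected option", making
#' `u*_jh = 1 - e*_jh` a true probability), or their mean with
#' `aggregate = "mean"`.  Patterns with no expected option (uncontrolled
#' designs) are flagged and get `NA`.
#'
#' @param fit A `gndm_fit`.
#' @param map Optional [expected_map()].
#' @param aggregate `"sum"` (default) or `"mean"` over multiple expected
#'   options.
#' @return An object of class `oedm_par`: a tibble with columns `item`,
#'   `h`, `bits`, `e_star`, `u_star`, `uncovered`.
#' @export
collapse_oedm <- function(fit, map = NULL, aggregate = c("sum", "mean")) {
  stopifnot(inherits(fit, "gndm_fit"))
  aggregate <- match.arg(aggregate)
  if (is.null(map)) map <- expected_map(fit$qmatrix)
  rows <- purrr::map(seq_len(fit$qmatrix$J), function(jj) {
    it <- fit$qmatrix$items[[jj]]
    eta <- pattern_matrix(it$G)
    mj <- map[map$item == it$item, , drop = FALSE]
    purrr::map(seq_len(it$H), function(h) {
      O <- mj$option[mj$h == h]
      e <- if (length(O) == 0) NA_real_
      else if (aggregate == "sum") sum(fit$P[[jj]][h, O])
      else mean(fit$P[[jj]][h, O])
      tibble(item = it$item, h = h,
             bits = paste(eta[h, ], collapse = ""),
             e_star = e, u_star = 1 - e, uncovered = length(O) == 0)
    }) %>% bind_rows()
  })
  out <- bind_rows(rows)
  structure(out, class = c("oedm_par", class(out)), map = map)
}

#' Expand PEDM parameters to full item blocks
#'
#' Rebuilds generative `H_j x C_j` blocks from `(e_jc, u_jc)`: in the row
#' of reduced pattern `h`, the (single) expected option gets its `e` and
#' every other option gets its own `u`.  Requires every reduced pattern to
#' have exactly one expected option; rows are renormalized (with a
#' warning) only when they miss 1 by more than `1e-8`.
#'
#' @param params A `pedm_par` (or data frame with `item`, `option`, `e`,
#'   `u`).
#' @param qmatrix A `gndm_qmatrix`.
#' @param map Optional [expected_map()].
#' @return A list of `H_j x C_j` matrices.
#' @export
expand_pedm <- function(params, qmatrix, map = NULL) {
  if (is.null(map)) {
    map <- attr(params, "map")
    if (is.null(map)) map <- expected_map(qmatrix)
  }
  lapply(seq_len(qmatrix$J), function(jj) {
    it <- qmatrix$items[[jj]]
    pj <- params[params$item == it$item, , drop = FALSE]
    pj <- pj[order(pj$option), , drop = FALSE]
    mj <- map[map$item == it$item, , drop = FALSE]
    P <- matrix(rep(pj$u, each = it$H), it$H, it$C)
    for (h in seq_len(it$H)) {
      O <- mj$option[mj$h == h]
      if (length(O) != 1) {
        abort(sprintf(
          "not PEDM-expandable: item %s pattern %d has %d expected options",
          it$item, h, length(O)))
      }
      P[h, O] <- pj$e[O]
    }
    bad <- abs(rowSums(P) - 1) > 1e-8
    if (any(bad)) {
      warn(sprintf("item %s: %d expanded PEDM rows renormalized",
                   it$item, sum(bad)))
      P[bad, ] <- P[bad, , drop = FALSE] / rowSums(P[bad, , drop = FALSE])
    }
    P
  })
}

# expand OEDM parameters to generative blocks by uniform split:
# expected options share e*_jh equally, unexpected options share 1 - e*_jh
expand_oedm <- function(params, qmatrix, map = NULL) {
  if (is.null(map)) {
    map <- attr(params, "map")
    if (is.null(map)) map <- expected_map(qmatrix)
  }
  lapply(seq_len(qmatrix$J), function(jj) {
    it <- qmatrix$items[[jj]]
    pj <- params[params$item == it$item, , drop = FALSE]
    mj <- map[map$item == it$item, , drop = FALSE]
    P <- matrix(0, it$H, it$C)
    for (h in seq_len(it$H)) {
      O <- mj$option[mj$h == h]
      e <- pj$e_star[pj$h == h]
      if (length(O) == 0 || is.na(e)) {
        abort(sprintf("item %s pattern %d has no expected option",
                      it$item, h))
      }
      P[h, O] <- e / length(O)
      U <- setdiff(seq_len(it$C), O)
      if (length(U)) P[h, U] <- (1 - e) / length(U)
    }
    P
  })
}

#' Two-step reduced-model fit (PEDM or OEDM)
#'
#' Step 1 fits the saturated model (or reuses a supplied fit); step 2
#' collapses it to the reduced parameters, expands them back to full
#' blocks, re-estimates the structural distribution under the fixed
#' blocks, and re-evaluates the marginal log-likelihood.  This is the
#' two-step procedure used for likelihood-ratio comparison against the
#' saturated form.
#'
#' @param data Responses (as in [gndm()]); ignored when `fit` is given.
#' @param qmatrix A `gndm_qmatrix`; ignored when `fit` is given.
#' @param model `"PEDM"` or `"OEDM"`.
#' @param fit Optionally an existing saturated `gndm_fit` on the same data.
#' @param ... Passed to [gndm()] when the saturated model must be fitted.
#' @return An object of class `gndm_reduced` with the collapsed parameter
#'   tibble (`params`), implied full blocks (`P`), re-estimated
#'   `structural`, `posterior`, `logLik`, `npar`, and the underlying
#'   saturated fit (`saturated`).
#' @export
fit_reduced <- function(data, qmatrix, model = c("PEDM", "OEDM"),
                        fit = NULL, ...) {
  model <- match.arg(model)
  if (is.null(fit)) fit <- gndm(data, qmatrix, ...)
  stopifnot(inherits(fit, "gndm_fit"))
  qmatrix <- fit$qmatrix
  map <- expected_map(qmatrix)
  params <- if (model == "PEDM") collapse_pedm(fit, map)
            else collapse_oedm(fit, map)
  # collapsed estimates rarely satisfy the row-sum identity exactly, so the
  # expansion's renormalization is part of the procedure here, not a surprise
  P <- if (model == "PEDM") suppressWarnings(expand_pedm(params, qmatrix, map))
       else expand_oedm(params, qmatrix, map)
  refit <- refit_structural(fit$data, P, qmatrix, fit$structural)
  npar <- attr(count_parameters(qmatrix, model), "total") + 2L^qmatrix$K - 1L
  structure(
    list(
      model = model, params = params, P = P,
      structural = refit$structural, posterior = refit$posterior,
      logLik = refit$logLik, npar = npar, N = fit$N,
      qmatrix = qmatrix, map = map, saturated = fit,
      data = fit$data, resp = fit$resp
    ),
    class = c("gndm_reduced", "gndm_fit")
  )
}

# EM over the structural distribution only, item blocks held fixed
refit_structural <- function(X, P, qmatrix, start = NULL,
                             tol = 1e-10, max_iter = 1000) {
  B <- cond_loglik_matrix(X, P, qmatrix)
  L <- ncol(B)
  prior <- if (is.null(start)) rep(1 / L, L) else start
  ll_prev <- -Inf
  for (it in seq_len(max_iter)) {
    W <- sweep(B, 2, log(pmax(prior, 1e-300)), "+")
    m <- apply(W, 1, max)
    E <- exp(W - m)
    rs <- rowSums(E)
    ll <- sum(m + log(rs))
    post <- E / rs
    prior <- colMeans(post)
    if (abs(ll - ll_prev) < tol * (abs(ll_prev) + 1)) break
    ll_prev <- ll
  }
  list(structural = prior, posterior = post, logLik = ll)
}

#' @export
print.gndm_reduced <- function(x, ...) {
  cat(sprintf("<gndm_reduced> %s (two-step): N = %d, J = %d, %d free parameters\n",
              x$model, x$N, x$qmatrix$J, x$npar))
  cat(sprintf("  logLik %.3f (saturated %.3f)\n", x$logLik,
              x$saturated$logLik))
  invisible(x)
}

#' @rdname tidy
#' @export
tidy.gndm_reduced <- function(x, ...) {
  as_tibble(x$params)
}

#' @rdname glance
#' @export
glance.gndm_reduced <- function(x, ...) {
  tibble(
    model = x$model, N = x$N, J = x$qmatrix$J, npar = x$npar,
    logLik = x$logLik, AIC = -2 * x$logLik + 2 * x$npar,
    BIC = -2 * x$logLik + log(x$N) * x$npar
  )
}
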