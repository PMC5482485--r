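#' Item information matrix
#'
#' Observed (outer-product) Fisher information for the free conditional
#' probabilities of one item, with option 1 as the reference category.
#' The score of respondent `i` for free parameter `P_c(eta_jh)`
#' (`c = 2..C_j`) is
#' `p(eta_jh|X_i) X_ijc / P_c(eta_jh) - p(eta_jh|X_i) X_ij1 / P_1(eta_jh)`,
#' and the information entry for a pair of free parameters is the sum over
#' respondents of the product of their scores, evaluated at the estimates
#' with the observed data.  Free parameters are indexed `(c - 2) H_j + h`
#' for `c = 2..C_j`, `h = 1..H_j` (option blocks stacked, pattern index
#' fastest).
#'
#' @param fit A `gndm_fit`.
#' @param item Item position (1..J).
#' @return A symmetric positive semidefinite matrix of size
#'   `(C_j - 1) H_j`, with attributes `index` (tibble mapping rows to
#'   `(option, h)`) and `boundary` (TRUE when some estimate sits at the
#'   clipping boundary).
#' @export
item_information <- function(fit, item) {
  stopifnot(inherits(fit, "gndm_fit"))
  jj <- item
  it <- fit$qmatrix$items[[jj]]
  g <- item_groups(fit, jj)
  nG <- max(g)
  Pg <- fit$P[[jj]][match(seq_len(nG), g), , drop = FALSE]
  postG <- posterior_eta_groups(fit, jj, g)       # N x nG
  X_j <- fit$data[, jj]
  S <- matrix(0, fit$N, (it$C - 1L) * nG)
  ind1 <- as.numeric(X_j == 1L)
  for (c in 2:it$C) {
    indc <- as.numeric(X_j == c)
    for (gg in seq_len(nG)) {
      S[, (c - 2L) * nG + gg] <-
        postG[, gg] * (indc / Pg[gg, c] - ind1 / Pg[gg, 1])
    }
  }
  info <- crossprod(S)
  idx <- tidyr::expand_grid(option = 2:it$C, group = seq_len(nG))
  attr(info, "index") <- mutate(idx, row = (option - 2L) * nG + .data$group)
  attr(info, "groups") <- g
  attr(info, "boundary") <- any(Pg <= 1e-9 | Pg >= 1 - 1e-9)
  info
}

# h -> estimation-group map of a fitted item (identity when the fit did
# not pool NOA patterns, e.g. models reloaded from JSON)
item_groups <- function(fit, jj) {
  if (!is.null(fit$groups)) fit$groups[[jj]]
  else seq_len(fit$qmatrix$items[[jj]]$H)
}

# N x nG matrix of estimation-group posteriors
posterior_eta_groups <- function(fit, jj, g = item_groups(fit, jj)) {
  postH <- posterior_eta(fit, jj)
  sapply(seq_len(max(g)), function(gg) {
    rowSums(postH[, g == gg, drop = FALSE])
  })
}

# Moore-Penrose pseudo-inverse with condition-number warning
pinv <- function(m, cond_warn = 1e10, tol = NULL) {
  s <- svd(m)
  d <- s$d
  if (length(d) && d[1] > 0 && d[length(d)] > 0 &&
      d[1] / d[length(d)] > cond_warn) {
    warn(sprintf("information matrix ill-conditioned (condition number %.2e)",
                 d[1] / d[length(d)]))
  }
  if (is.null(tol)) tol <- max(dim(m)) * max(d) * .Machine$double.eps
  pos <- d > tol
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / d[pos])
}

#' Standard errors of the saturated item parameters
#'
#' Square roots of the diagonal of the inverse item information matrix,
#' one per free parameter `P_c(eta_jh)` with `c >= 2`; the reference
#' option (c = 1) has no free parameter and gets `NA`.  Items whose
#' information matrix is numerically singular get `NA` SEs.
#'
#' @param fit A `gndm_fit`.
#' @param items Item positions (default all).
#' @return A tibble with columns `item`, `option`, `h`, `bits`,
#'   `estimate`, `se`.
#' @export
item_se <- function(fit, items = seq_len(fit$qmatrix$J)) {
  rows <- purrr::map(items, function(jj) {
    it <- fit$qmatrix$items[[jj]]
    eta <- pattern_matrix(it$G)
    bits <- apply(eta, 1, paste, collapse = "")
    info <- item_information(fit, jj)
    g <- attr(info, "groups")
    nG <- max(g)
    d <- tryCatch(diag(pinv(info)), error = function(e) NULL)
    se_free <- if (is.null(d) || any(d < -1e-8)) {
      rep(NA_real_, nrow(info))
    } else {
      sqrt(pmax(d, 0))
    }
    tidyr::expand_grid(option = seq_len(it$C), h = seq_len(it$H)) %>%
      mutate(
        item = it$item,
        bits = bits[.data$h],
        estimate = fit$P[[jj]][cbind(.data$h, .data$option)],
        se = ifelse(.data$option == 1, NA_real_,
                    se_free[pmax((.data$option - 2L) * nG + g[.data$h], 1L)])
      ) %>%
      select("item", "option", "h", "bits", "estimate", "se")
  })
  bind_rows(rows)
}

# gradient of a collapse average w.r.t. the free parameters of one item:
# target = sum_{h in set} w_h P_c(eta_h) / sum w_h; P_1 = 1 - sum_{c>=2} P_c
collapse_gradient <- function(c, set, w, H, C) {
  g <- numeric((C - 1L) * H)
  if (length(set) == 0) return(g)
  ww <- w[set] / sum(w[set])
  if (sum(w[set]) <= 0) ww <- rep(1 / length(set), length(set))
  for (k in seq_along(set)) {
    h <- set[k]
    if (c >= 2) {
      g[(c - 2L) * H + h] <- g[(c - 2L) * H + h] + ww[k]
    } else {
      for (cc in 2:C) g[(cc - 2L) * H + h] <- g[(cc - 2L) * H + h] - ww[k]
    }
  }
  g
}

#' Delta-method standard errors for collapsed parameters
#'
#' Standard errors for the PEDM parameters `(e_jc, u_jc)` or the OEDM
#' parameters `e*_jh`, treating the collapse weights (estimated pattern
#' sample sizes) as constants: each collapsed parameter is a linear map
#' `g` of the item's free parameters, so `SE^2 = g' I^{-1} g` with `I`
#' the item information matrix.
#'
#' @param fit A `gndm_fit`.
#' @param params A `pedm_par` or `oedm_par` from the same fit.
#' @return The `params` tibble with added SE columns (`se_e`, `se_u` for
#'   PEDM; `se_e_star` for OEDM).
#' @export
collapsed_se <- function(fit, params) {
  map <- attr(params, "map")
  if (is.null(map)) map <- expected_map(fit$qmatrix)
  is_pedm <- inherits(params, "pedm_par")
  rows <- purrr::map(seq_len(fit$qmatrix$J), function(jj) {
    it <- fit$qmatrix$items[[jj]]
    info <- item_information(fit, jj)
    grp <- attr(info, "groups")
    nG <- max(grp)
    Vi <- tryCatch(pinv(info), error = function(e) NULL)
    w <- colSums(posterior_eta(fit, jj))
    # pattern weights aggregated to estimation groups
    wg <- as.numeric(rowsum(w, grp))
    set_groups <- function(set) sort(unique(grp[set]))
    wg_set <- function(set) {
      out <- numeric(nG)
      s <- rowsum(w[set], grp[set])
      out[as.integer(rownames(s))] <- s
      out
    }
    mj <- map[map$item == it$item, , drop = FALSE]
    if (is_pedm) {
      purrr::map(seq_len(it$C), function(c) {
        E <- mj$h[mj$option == c]
        U <- setdiff(seq_len(it$H), E)
        se2 <- function(set) {
          if (is.null(Vi) || length(set) == 0) return(NA_real_)
          g <- collapse_gradient(c, set_groups(set), wg_set(set), nG, it$C)
          max(drop(t(g) %*% Vi %*% g), 0)
        }
        tibble(item = it$item, option = c,
               se_e = sqrt(se2(E)), se_u = sqrt(se2(U)))
      }) %>% bind_rows()
    } else {
      purrr::map(seq_len(it$H), function(h) {
        O <- mj$option[mj$h == h]
        if (is.null(Vi) || length(O) == 0) {
          return(tibble(item = it$item, h = h, se_e_star = NA_real_))
        }
        # e*_jh = sum over expected options of P_c(eta_jh)
        g <- numeric((it$C - 1L) * nG)
        for (c in O) {
          g <- g + collapse_gradient(c, grp[h], wg, nG, it$C)
        }
        tibble(item = it$item, h = h,
               se_e_star = sqrt(max(drop(t(g) %*% Vi %*% g), 0)))
      }) %>% bind_rows()
    }
  })
  ses <- bind_rows(rows)
  key <- if (is_pedm) c("item", "option") else c("item", "h")
  out <- left_join(as_tibble(params), ses, by = key)
  structure(out, class = class(params), map = map)
}

#' Likelihood-ratio comparison of saturated and reduced models
#'
#' Deviance `2 (l_sat - l_red)` against the chi-squared reference with
#' degrees of freedom equal to the difference in free-parameter counts
#' (the shared structural parameters cancel).
#'
#' @param sat A saturated `gndm_fit`.
#' @param red A `gndm_reduced` from [fit_reduced()] on the same data.
#' @return A one-row tibble of class `gndm_lrt`: `deviance`, `df`,
#'   `p_value`, plus the two log-likelihoods.
#' @export
lrt_compare <- function(sat, red) {
  stopifnot(inherits(sat, "gndm_fit"), inherits(red, "gndm_reduced"))
  dev <- 2 * (sat$logLik - red$logLik)
  if (dev < -1e-6) {
    abort(sprintf(
      "reduced fit exceeded saturated (deviance %.3g): estimation failure",
      dev))
  }
  dev <- max(dev, 0)
  # structural parameters are shared and cancel; npar stores item + structural
  df <- sat$npar - red$npar
  out <- tibble(
    deviance = dev, df = df,
    p_value = pchisq(dev, df, lower.tail = FALSE),
    logLik_sat = sat$logLik, logLik_red = red$logLik,
    model = red$model
  )
  structure(out, class = c("gndm_lrt", class(out)))
}
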