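#' Fit the saturated general nominal diagnosis model
#'
#' Estimates, by marginal maximum likelihood EM, the conditional
#' selection probabilities `P_c(eta_jh)` of every response option `c` given
#' every reduced attribute pattern `eta_jh` of every item, together with the
#' saturated joint attribute distribution `p(alpha_l)` over the `L = 2^K`
#' attribute patterns.  Each EM cycle computes respondent posteriors over
#' attribute patterns (E-step), re-estimates every block row from the
#' expected option counts `R_jhc`, and updates the structural distribution
#' as the mean posterior.
#'
#' The default `variant = "standard"` is the classical EM for the marginal
#' likelihood and carries a single shared prior.  `variant = "individual"`
#' instead carries each respondent's previous posterior as their own prior
#' at the next cycle (an empirical-Bayes style update), which progressively
#' sharpens individual posteriors; it is provided for comparison and is not
#' the default because the standard EM maximizes the marginal likelihood.
#'
#' A NOA option carries no substantive content that could distinguish the
#' missing patterns it collectively covers, so by default
#' (`noa_collapse = TRUE`) those reduced patterns share a single block row
#' per item, which stabilizes their estimation considerably at realistic
#' sample sizes.  `noa_collapse = FALSE` fits the fully saturated block
#' with all `H_j` rows free.
#'
#' @param data Responses: a data frame with one row per respondent and one
#'   integer column per item (option codes starting at 1), optionally with
#'   a `resp` id column; or an N x J integer matrix.
#' @param qmatrix A [extended_qmatrix()] object.
#' @param variant `"standard"` or `"individual"` (see Details).
#' @param noa_collapse Pool the reduced patterns expected by a NOA option
#'   into one shared block row per item (default TRUE; see Details).
#' @param tol Convergence tolerance on the maximum absolute change of any
#'   conditional probability (default `1e-5`); convergence additionally
#'   requires a relative log-likelihood change below `ll_tol`.
#' @param ll_tol Relative log-likelihood change tolerance (default `1e-9`).
#' @param max_iter Maximum EM cycles (default 2000).
#' @param init `"anchored"` (default), `"uniform"`, or a list of initial
#'   item blocks (one `H_j x C_j` matrix per item).  The anchored start
#'   centres each covered block row on a mild advantage for the row's
#'   expected option before a seeded Dirichlet perturbation; because
#'   jointly complementing an attribute is a likelihood-preserving
#'   relabeling of the saturated model, this anchors the attribute
#'   orientation the Q-matrix intends.  `"uniform"` centres every row on
#'   `1/C_j` and leaves the orientation to chance.
#' @param seed Optional integer seed for the initialization draw; the
#'   caller's RNG state is restored afterwards.
#' @return An object of class `gndm_fit` with elements `P` (list of item
#'   blocks), `structural`, `posterior`, `logLik`, `trace`, `iterations`,
#'   `converged`, `npar`, and the inputs needed by downstream methods.
#' @examples
#' q <- sim_qmatrix(1)
#' att <- simulate_attributes(300, c(0.7, 0.6, 0.5, 0.4, 0.3), R = 0.5,
#'                            seed = 1)
#' resp <- simulate_responses(att, q, e = 0.6, u = 0.1, seed = 2)
#' fit <- gndm(resp, q, seed = 3)
#' glance(fit)
#' @export
gndm <- function(data, qmatrix, variant = c("standard", "individual"),
                 noa_collapse = TRUE, tol = 1e-5, ll_tol = 1e-9,
                 max_iter = 2000, init = NULL, seed = NULL) {
  variant <- match.arg(variant)
  stopifnot(inherits(qmatrix, "gndm_qmatrix"))
  X <- response_matrix(data, qmatrix)
  N <- nrow(X)
  if (N < 1) abort("no respondents")
  L <- 2L^qmatrix$K
  patterns <- pattern_matrix(qmatrix$K)
  hmaps <- lapply(qmatrix$items, function(it) {
    reduced_pattern_index(patterns, it$support)
  })
  map <- expected_map(qmatrix)
  groups <- noa_groups(qmatrix, map, noa_collapse)
  if (is.character(init) || is.null(init)) {
    kind <- if (is.null(init)) "anchored" else match.arg(init,
                                                        c("anchored", "uniform"))
    init <- with_seed(seed, init_blocks(qmatrix, kind, map))
  } else {
    stopifnot(length(init) == qmatrix$J)
    for (jj in seq_len(qmatrix$J)) {
      it <- qmatrix$items[[jj]]
      stopifnot(nrow(init[[jj]]) == it$H, ncol(init[[jj]]) == it$C)
    }
  }
  # estimation runs on the pooled (group-level) parameterization
  est_hmaps <- lapply(seq_len(qmatrix$J), function(jj) {
    groups[[jj]][hmaps[[jj]]]
  })
  est_init <- lapply(seq_len(qmatrix$J), function(jj) {
    g <- groups[[jj]]
    m <- rowsum(init[[jj]], g) / as.vector(table(g))
    m / rowSums(m)
  })
  res <- em_gndm_cpp(X, est_hmaps, est_init, rep(1 / L, L), tol, ll_tol,
                     max_iter, match(variant, c("standard", "individual")) - 1L,
                     1e-10, 1e-8)
  if (!res$converged) {
    warn(sprintf("EM did not converge in %d iterations", res$iterations))
  }
  # expand group-level blocks back to one row per reduced pattern
  P <- lapply(seq_len(qmatrix$J), function(jj) {
    m <- res$P[[jj]][groups[[jj]], , drop = FALSE]
    dimnames(m) <- NULL
    m
  })
  starved <- lapply(seq_len(qmatrix$J), function(jj) {
    as.logical(res$starved[[jj]][groups[[jj]]])
  })
  trace <- res$trace
  posterior <- res$posterior
  loglik <- trace[length(trace)]
  if (variant == "standard") {
    # refresh the posterior and likelihood at the final parameter values
    posterior <- e_step(X, P, res$structural, qmatrix)
    loglik <- marginal_loglik(X, P, res$structural, qmatrix)
    trace <- c(trace, loglik)
  }
  counts <- m_step(posterior, X, qmatrix, P)$counts
  structure(
    list(
      qmatrix = qmatrix, P = P, structural = as.numeric(res$structural),
      posterior = posterior, counts = counts, starved = starved,
      logLik = loglik, trace = trace, iterations = res$iterations,
      converged = res$converged, variant = variant,
      noa_collapse = noa_collapse, groups = groups, map = map,
      N = N, data = X, resp = rownames(X), hmaps = hmaps,
      npar = sum(vapply(seq_len(qmatrix$J), function(jj) {
        (qmatrix$items[[jj]]$C - 1) * max(groups[[jj]])
      }, 0)) + L - 1,
      seed = seed
    ),
    class = "gndm_fit"
  )
}

# h -> estimation-group map per item: identity, or with the reduced
# patterns expected by a NOA option pooled into one final group
noa_groups <- function(qmatrix, map, noa_collapse) {
  lapply(seq_len(qmatrix$J), function(jj) {
    it <- qmatrix$items[[jj]]
    g <- seq_len(it$H)
    if (!noa_collapse || is.na(it$noa)) return(g)
    mj <- map[map$item == it$item, , drop = FALSE]
    noa_h <- mj$h[mj$option == it$noa]
    if (length(noa_h) < 2) return(g)
    keep <- sort(setdiff(seq_len(it$H), noa_h))
    g[keep] <- seq_along(keep)
    g[noa_h] <- length(keep) + 1L
    g
  })
}

# Starting blocks.  The saturated model is invariant under complementing
# any attribute jointly across items and the structural distribution, so
# the attribute orientation is a label symmetry the data cannot resolve;
# the "anchored" start selects the orientation intended by the Q-matrix by
# centring each covered row on a mild expected-option advantage (weight 3
# vs 1) taken from the expected map.  "uniform" centres every row on 1/C.
# Rows are Dirichlet draws with concentration 50 * C around the centre.
init_blocks <- function(qmatrix, kind = c("anchored", "uniform"),
                        map = NULL) {
  kind <- match.arg(kind)
  if (kind == "anchored" && is.null(map)) map <- expected_map(qmatrix)
  lapply(seq_len(qmatrix$J), function(jj) {
    it <- qmatrix$items[[jj]]
    b <- matrix(1 / it$C, it$H, it$C)
    if (kind == "anchored") {
      mj <- map[map$item == it$item, , drop = FALSE]
      for (h in seq_len(it$H)) {
        O <- mj$option[mj$h == h]
        if (length(O)) {
          r <- rep(1, it$C)
          r[O] <- 3
          b[h, ] <- r / sum(r)
        }
      }
    }
    m <- matrix(rgamma(it$H * it$C, shape = 50 * it$C * as.numeric(b)),
                it$H, it$C)
    m / rowSums(m)
  })
}

# coerce responses to an N x J integer matrix and validate option ranges
response_matrix <- function(data, qmatrix) {
  ids <- NULL
  if (is.data.frame(data)) {
    if ("resp" %in% names(data)) {
      ids <- as.character(data$resp)
      data <- data[setdiff(names(data), "resp")]
    }
    X <- as.matrix(data)
  } else {
    X <- data
  }
  storage.mode(X) <- "integer"
  if (ncol(X) != qmatrix$J) {
    abort(sprintf("responses have %d item columns, Q-matrix has %d items",
                  ncol(X), qmatrix$J))
  }
  if (anyNA(X)) {
    bad <- which(is.na(X), arr.ind = TRUE)[1, ]
    abort(sprintf("missing response at respondent %d item %d (not supported)",
                  bad[1], bad[2]))
  }
  for (jj in seq_len(qmatrix$J)) {
    C_j <- qmatrix$items[[jj]]$C
    bad <- which(X[, jj] < 1L | X[, jj] > C_j)
    if (length(bad)) {
      abort(sprintf(
        "response out of range at respondent %d item %s: %d not in 1..%d",
        bad[1], qmatrix$items[[jj]]$item, X[bad[1], jj], C_j))
    }
  }
  if (!is.null(ids)) rownames(X) <- ids
  X
}

# run code with a temporary seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Conditional likelihood of a response vector given an attribute pattern
#'
#' The product over items of the probability of the observed option given
#' the reduced form of `alpha` for that item.
#'
#' @param responses_i Length-J integer option vector.
#' @param P List of item blocks (`H_j x C_j`).
#' @param alpha Binary attribute vector of length K.
#' @param qmatrix A `gndm_qmatrix`.
#' @return A single probability.
#' @export
conditional_likelihood <- function(responses_i, P, alpha, qmatrix) {
  out <- 1
  for (jj in seq_len(qmatrix$J)) {
    it <- qmatrix$items[[jj]]
    h <- reduced_pattern_index(matrix(alpha, 1), it$support)
    out <- out * P[[jj]][h, responses_i[jj]]
  }
  out
}

# N x L matrix of log conditional likelihoods
cond_loglik_matrix <- function(X, P, qmatrix, hmaps = NULL) {
  L <- 2L^qmatrix$K
  patterns <- pattern_matrix(qmatrix$K)
  if (is.null(hmaps)) {
    hmaps <- lapply(qmatrix$items, function(it) {
      reduced_pattern_index(patterns, it$support)
    })
  }
  B <- matrix(0, nrow(X), L)
  for (jj in seq_len(qmatrix$J)) {
    lp <- log(pmax(P[[jj]], 1e-10))    # H x C
    A <- t(lp[hmaps[[jj]], , drop = FALSE])  # C x L
    B <- B + A[X[, jj], , drop = FALSE]
  }
  B
}

#' Marginal log-likelihood of a response matrix
#'
#' `sum_i log sum_l L(X_i | alpha_l) p(alpha_l)`.
#'
#' @param X N x J integer response matrix (or data frame).
#' @param P List of item blocks.
#' @param structural Length-`2^K` probability vector over attribute
#'   patterns.
#' @param qmatrix A `gndm_qmatrix`.
#' @return A single number.
#' @export
marginal_loglik <- function(X, P, structural, qmatrix) {
  X <- response_matrix(X, qmatrix)
  B <- cond_loglik_matrix(X, P, qmatrix)
  W <- sweep(B, 2, log(pmax(structural, 1e-300)), "+")
  m <- apply(W, 1, max)
  sum(m + log(rowSums(exp(W - m))))
}

#' Posterior attribute-pattern probabilities (E-step)
#'
#' Row-normalized products of conditional likelihood and prior:
#' `p(alpha_l | X_i)` proportional to `L(X_i | alpha_l) p(alpha_l)`.
#'
#' @inheritParams marginal_loglik
#' @return An N x `2^K` matrix with rows summing to 1.
#' @export
e_step <- function(X, P, structural, qmatrix) {
  X <- response_matrix(X, qmatrix)
  B <- cond_loglik_matrix(X, P, qmatrix)
  W <- sweep(B, 2, log(pmax(structural, 1e-300)), "+")
  m <- apply(W, 1, max)
  E <- exp(W - m)
  E / rowSums(E)
}

#' Expected counts and block update (M-step)
#'
#' Computes the expected number of respondents `R_jhc` with reduced pattern
#' `h` selecting option `c` of item `j`, and the updated blocks
#' `P_c(eta_jh) = R_jhc / sum_c R_jhc`.  Rows whose total expected count
#' falls below `1e-8` are starved: they keep the previous values and are
#' flagged.
#'
#' @param posterior N x `2^K` posterior matrix from [e_step()].
#' @param X N x J integer response matrix (or data frame).
#' @param qmatrix A `gndm_qmatrix`.
#' @param P_prev Optional previous blocks used for starved rows.
#' @return A list with `counts`, `P`, and `starved` (per item).
#' @export
m_step <- function(posterior, X, qmatrix, P_prev = NULL) {
  X <- response_matrix(X, qmatrix)
  patterns <- pattern_matrix(qmatrix$K)
  counts <- P <- starved <- vector("list", qmatrix$J)
  for (jj in seq_len(qmatrix$J)) {
    it <- qmatrix$items[[jj]]
    hmap <- reduced_pattern_index(patterns, it$support)
    postH <- sapply(seq_len(it$H), function(h) {
      rowSums(posterior[, hmap == h, drop = FALSE])
    })  # N x H
    Xind <- matrix(0, nrow(X), it$C)
    Xind[cbind(seq_len(nrow(X)), X[, jj])] <- 1
    R <- crossprod(postH, Xind)        # H x C expected counts
    tot <- rowSums(R)
    newP <- R / tot
    st <- tot < 1e-8
    if (any(st)) {
      prev <- if (is.null(P_prev)) matrix(1 / it$C, it$H, it$C)
              else P_prev[[jj]]
      newP[st, ] <- prev[st, , drop = FALSE]
    }
    counts[[jj]] <- R
    P[[jj]] <- newP
    starved[[jj]] <- st
  }
  list(counts = counts, P = P, starved = starved)
}

#' Structural distribution update
#'
#' The saturated attribute-pattern distribution is re-estimated as the mean
#' posterior across respondents.
#'
#' @param posterior N x L posterior matrix.
#' @return A length-L probability vector.
#' @export
update_structural <- function(posterior) {
  colMeans(posterior)
}

# N x H matrix of reduced-pattern posteriors for one item
posterior_eta <- function(fit, jj) {
  it <- fit$qmatrix$items[[jj]]
  hmap <- fit$hmaps[[jj]]
  sapply(seq_len(it$H), function(h) {
    rowSums(fit$posterior[, hmap == h, drop = FALSE])
  })
}

#' Classify respondents from a fitted model
#'
#' The attribute-vector estimate is the posterior mode (MAP) over the
#' `2^K` patterns, ties broken toward the lowest canonical pattern index;
#' individual attribute estimates are 1 when the marginal posterior
#' probability of possession is at least 0.5.
#'
#' @param fit A `gndm_fit` (or reduced-model fit with a posterior).
#' @return A tibble with columns `resp`, `pattern` (MAP index), `bits`,
#'   marginal possession probabilities `p_A1..p_AK`, and attribute
#'   estimates `A1..AK`.
#' @export
classify <- function(fit) {
  post <- fit$posterior
  K <- fit$qmatrix$K
  patterns <- pattern_matrix(K)
  map_idx <- max.col(post, ties.method = "first")
  marg <- post %*% patterns          # N x K marginal possession probabilities
  est <- (marg >= 0.5) + 0L
  bits <- apply(patterns, 1, paste, collapse = "")
  out <- tibble(
    resp = if (!is.null(fit$resp)) fit$resp else as.character(seq_len(nrow(post))),
    pattern = map_idx,
    bits = bits[map_idx]
  )
  colnames(marg) <- paste0("p_A", seq_len(K))
  colnames(est) <- paste0("A", seq_len(K))
  bind_cols(out, as_tibble(marg), as_tibble(est))
}

#' @export
print.gndm_fit <- function(x, ...) {
  cat(sprintf(
    "<gndm_fit> saturated GNDM: N = %d, J = %d, K = %d, %d free parameters\n",
    x$N, x$qmatrix$J, x$qmatrix$K, x$npar))
  cat(sprintf("  logLik %.3f after %d EM iterations (%sconverged, %s)\n",
              x$logLik, x$iterations, if (x$converged) "" else "NOT ",
              x$variant))
  invisible(x)
}

#' @export
logLik.gndm_fit <- function(object, ...) {
  structure(object$logLik, df = object$npar, nobs = object$N,
            class = "logLik")
}

#' @rdname tidy
#' @param x A fitted object.
#' @param se Attach standard errors (via [item_se()]) when `TRUE`.
#' @param ... Unused.
#' @export
tidy.gndm_fit <- function(x, se = FALSE, ...) {
  rows <- purrr::map(seq_len(x$qmatrix$J), function(jj) {
    it <- x$qmatrix$items[[jj]]
    eta <- pattern_matrix(it$G)
    bits <- apply(eta, 1, paste, collapse = "")
    tidyr::expand_grid(option = seq_len(it$C), h = seq_len(it$H)) %>%
      mutate(
        item = it$item,
        bits = bits[.data$h],
        estimate = x$P[[jj]][cbind(.data$h, .data$option)]
      ) %>%
      select("item", "option", "h", "bits", "estimate")
  })
  out <- bind_rows(rows)
  if (se) {
    out <- left_join(out, select(item_se(x), "item", "option", "h", "se"),
                     by = c("item", "option", "h"))
  }
  out
}

#' @rdname glance
#' @param x A fitted object.
#' @param ... Unused.
#' @export
glance.gndm_fit <- function(x, ...) {
  tibble(
    N = x$N, J = x$qmatrix$J, K = x$qmatrix$K, npar = x$npar,
    logLik = x$logLik, AIC = -2 * x$logLik + 2 * x$npar,
    BIC = -2 * x$logLik + log(x$N) * x$npar,
    iterations = x$iterations, converged = x$converged,
    variant = x$variant
  )
}
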