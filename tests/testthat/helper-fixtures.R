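# Small Q-matrices built in code, plus independent oracles used across
# the test files.

# two OCOP items over K = 2 attributes (four options, bijection)
ocop_qmatrix <- function(J = 2) {
  rows <- purrr::map(seq_len(J), function(j) {
    tibble::tibble(item = j, option = 1:4,
                   A1 = c(1L, 0L, 1L, 0L), A2 = c(0L, 1L, 1L, 0L))
  })
  extended_qmatrix(dplyr::bind_rows(rows))
}

# one three-attribute item with four substantive options and a NOA row
# (same shape as the packaged study items)
noa_item_qmatrix <- function() {
  extended_qmatrix(tibble::tibble(
    item = 1, option = 1:5,
    A1 = c(1L, 1L, 0L, 0L, -1L),
    A2 = c(1L, 1L, 1L, 0L, -1L),
    A3 = c(1L, 0L, 1L, 1L, -1L)
  ))
}

# J items with a single required attribute each, two options
# (option 1 expected for possession, option 2 for non-possession)
onek_qmatrix <- function(J = 2, K = 1) {
  rows <- purrr::map(seq_len(J), function(j) {
    k <- (j - 1) %% K + 1
    a <- matrix(0L, 2, K)
    a[1, k] <- 1L
    out <- tibble::tibble(item = j, option = 1:2)
    for (kk in seq_len(K)) out[[paste0("A", kk)]] <- a[, kk]
    out
  })
  extended_qmatrix(dplyr::bind_rows(rows))
}

# small fitted models reused across test files
fit_for_se <- function(N = 400, seed = 15, J = 2, e = 0.7) {
  q <- ocop_qmatrix(J)
  att <- simulate_attributes(N, c(0.6, 0.4), R = 0.3, seed = seed)
  resp <- simulate_responses(att, q, e = e, u = (1 - e) / 3, seed = seed + 1)
  gndm(resp, q, seed = 3)
}

small_fit <- function(N = 300, seed = 61, J = 3, e = 0.7) {
  q <- ocop_qmatrix(J)
  att <- simulate_attributes(N, c(0.6, 0.4), R = 0.3, seed = seed)
  resp <- simulate_responses(att, q, e = e, u = (1 - e) / 3, seed = seed + 1)
  list(q = q, fit = gndm(resp, q, seed = 2),
       X = gndm:::response_matrix(resp, q))
}

# Independent brute-force maximizer of the marginal log-likelihood over
# all free parameters (softmax-parameterized), for tiny instances only.
brute_force_loglik <- function(X, qmatrix, n_starts = 3, seed = 1) {
  J <- qmatrix$J
  L <- 2L^qmatrix$K
  dims <- lapply(qmatrix$items, function(it) c(H = it$H, C = it$C))
  n_item <- sum(vapply(dims, function(d) d["H"] * (d["C"] - 1), 0))
  n_par <- n_item + (L - 1)
  unpack <- function(theta) {
    P <- vector("list", J)
    pos <- 0
    for (j in seq_len(J)) {
      H <- dims[[j]]["H"]; C <- dims[[j]]["C"]
      m <- matrix(0, H, C)
      m[, -1] <- matrix(theta[pos + seq_len(H * (C - 1))], H, C - 1)
      pos <- pos + H * (C - 1)
      em <- exp(m - apply(m, 1, max))
      P[[j]] <- em / rowSums(em)
    }
    s <- c(0, theta[pos + seq_len(L - 1)])
    prior <- exp(s - max(s)); prior <- prior / sum(prior)
    list(P = P, prior = prior)
  }
  nll <- function(theta) {
    par <- unpack(theta)
    -marginal_loglik(X, par$P, par$prior, qmatrix)
  }
  set.seed(seed)
  best <- Inf
  for (s in seq_len(n_starts)) {
    o <- optim(rnorm(n_par, sd = 0.5), nll, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-12))
    if (o$value < best) best <- o$value
  }
  -best
}

# central-difference numerical Hessian of the marginal log-likelihood with
# respect to the free parameters of one item (option 1 absorbs each step
# so rows stay on the simplex), returned as observed information (-H)
numerical_item_information <- function(fit, jj, d = 1e-4) {
  q <- fit$qmatrix
  it <- q$items[[jj]]
  X <- fit$data
  P0 <- fit$P
  npar <- (it$C - 1) * it$H
  perturb <- function(steps) {
    P <- P0
    m <- P[[jj]]
    for (s in steps) {
      m[s$h, s$c] <- m[s$h, s$c] + s$d
      m[s$h, 1] <- m[s$h, 1] - s$d
    }
    P[[jj]] <- m
    marginal_loglik(X, P, fit$structural, q)
  }
  idx <- expand.grid(h = seq_len(it$H), c = 2:it$C)
  idx <- idx[order(idx$c, idx$h), ]
  H <- matrix(0, npar, npar)
  for (a in seq_len(npar)) {
    for (b in a:npar) {
      sa <- list(h = idx$h[a], c = idx$c[a])
      sb <- list(h = idx$h[b], c = idx$c[b])
      f <- function(da, db) {
        perturb(list(modifyList(sa, list(d = da)),
                     modifyList(sb, list(d = db))))
      }
      H[a, b] <- H[b, a] <-
        (f(d, d) - f(d, -d) - f(-d, d) + f(-d, -d)) / (4 * d * d)
    }
  }
  -H
}

# exact-match classification from a posterior matrix (independent of
# classify(), used as its oracle)
map_patterns <- function(posterior, K) {
  pm <- as.matrix(attribute_patterns(K)[paste0("A", seq_len(K))])
  pm[max.col(posterior, ties.method = "first"), , drop = FALSE]
}
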