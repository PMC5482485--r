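# reusable tiny dataset: two OCOP items over K = 2, N = 60
make_toy <- function(N = 60, e = 0.7, seed = 42) {
  q <- ocop_qmatrix(2)
  att <- simulate_attributes(N, c(0.6, 0.4), R = 0.3, seed = seed)
  resp <- simulate_responses(att, q, e = e, u = (1 - e) / 3,
                             seed = seed + 1)
  list(q = q, att = att, resp = resp,
       X = gndm:::response_matrix(resp, q))
}

test_that("conditional likelihood is the product over items", {
  q <- ocop_qmatrix(2)
  P <- list(matrix(1 / 4, 4, 4), matrix(1 / 4, 4, 4))
  P[[1]][1, 2] <- 0.5; P[[1]][1, -2] <- (1 - 0.5) / 3
  P[[2]][1, 3] <- 0.4; P[[2]][1, -3] <- (1 - 0.4) / 3
  # alpha = (0, 0) reduces to pattern 00 = index 1 for both items
  expect_equal(conditional_likelihood(c(2, 3), P, c(0, 0), q), 0.2)
  Pdet <- list(matrix(rep(c(1, 0, 0, 0), each = 4), 4, 4),
               matrix(rep(c(1, 0, 0, 0), each = 4), 4, 4))
  expect_equal(conditional_likelihood(c(1, 1), Pdet, c(0, 0), q), 1)
  # three-item fixture checked against an explicit hand product
  q3 <- ocop_qmatrix(3)
  set.seed(9)
  P3 <- replicate(3, {
    m <- matrix(rgamma(16, 2), 4, 4); m / rowSums(m)
  }, simplify = FALSE)
  alpha <- c(1, 0)
  x <- c(3, 1, 4)
  h <- gndm:::reduced_pattern_index(matrix(alpha, 1), 1:2)
  byhand <- P3[[1]][h, 3] * P3[[2]][h, 1] * P3[[3]][h, 4]
  expect_equal(conditional_likelihood(x, P3, alpha, q3), byhand)
})

test_that("marginal log-likelihood matches a brute-force pattern sum", {
  toy <- make_toy(N = 5)
  set.seed(3)
  P <- replicate(2, {
    m <- matrix(rgamma(16, 2), 4, 4); m / rowSums(m)
  }, simplify = FALSE)
  prior <- c(0.4, 0.3, 0.2, 0.1)
  pm <- as.matrix(attribute_patterns(2)[paste0("A", 1:2)])
  byhand <- sum(log(vapply(seq_len(5), function(i) {
    sum(vapply(1:4, function(l) {
      conditional_likelihood(toy$X[i, ], P, pm[l, ], toy$q) * prior[l]
    }, 0))
  }, 0)))
  expect_equal(marginal_loglik(toy$X, P, prior, toy$q), byhand)
  # degenerate point-mass prior
  point <- c(0, 0, 1, 0)
  byhand2 <- sum(log(vapply(seq_len(5), function(i) {
    conditional_likelihood(toy$X[i, ], P, pm[3, ], toy$q)
  }, 0)))
  expect_equal(marginal_loglik(toy$X, P, point, toy$q), byhand2)
})

test_that("E-step posteriors are normalized elementwise products", {
  q <- onek_qmatrix(1, 1)
  # item block: P(option 1 | alpha = 0) = 0.1, P(option 1 | alpha = 1) = 0.4
  P <- list(matrix(c(0.1, 0.4, 0.9, 0.6), 2, 2))
  X <- matrix(1L, 1, 1)
  post <- e_step(X, P, c(0.8, 0.2), q)
  expect_equal(as.numeric(post), c(0.5, 0.5))  # 0.08 vs 0.08
  # flat prior and constant likelihood -> uniform posterior
  Pflat <- list(matrix(0.5, 2, 2))
  expect_equal(as.numeric(e_step(X, Pflat, c(0.5, 0.5), q)), c(0.5, 0.5))
  # toy fixture matches an independent normalized product
  toy <- make_toy(N = 7)
  set.seed(5)
  P2 <- replicate(2, {
    m <- matrix(rgamma(16, 2), 4, 4); m / rowSums(m)
  }, simplify = FALSE)
  prior <- c(0.1, 0.2, 0.3, 0.4)
  pm <- as.matrix(attribute_patterns(2)[paste0("A", 1:2)])
  W <- t(vapply(seq_len(7), function(i) {
    w <- vapply(1:4, function(l) {
      conditional_likelihood(toy$X[i, ], P2, pm[l, ], toy$q) * prior[l]
    }, 0)
    w / sum(w)
  }, numeric(4)))
  expect_equal(e_step(toy$X, P2, prior, toy$q), W, ignore_attr = TRUE)
  expect_equal(rowSums(e_step(toy$X, P2, prior, toy$q)), rep(1, 7))
})

test_that("M-step normalizes expected counts and flags starved rows", {
  toy <- make_toy(N = 40)
  post <- e_step(toy$X, gndm:::generating_blocks(toy$q, 0.7, 0.1),
                 rep(1 / 4, 4), toy$q)
  ms <- m_step(post, toy$X, toy$q)
  for (jj in 1:2) {
    R <- ms$counts[[jj]]
    expect_equal(sum(R), 40, tolerance = 1e-6)
    # hand-computed counts: R_hc = sum_i p(eta_h | X_i) [X_ij = c]
    hm <- gndm:::reduced_pattern_index(
      as.matrix(attribute_patterns(2)[paste0("A", 1:2)]),
      toy$q$items[[jj]]$support)
    byhand <- matrix(0, 4, 4)
    for (i in 1:40) {
      for (l in 1:4) {
        byhand[hm[l], toy$X[i, jj]] <- byhand[hm[l], toy$X[i, jj]] +
          post[i, l]
      }
    }
    expect_equal(R, byhand, ignore_attr = TRUE)
    expect_equal(ms$P[[jj]], byhand / rowSums(byhand), ignore_attr = TRUE)
  }
  # degenerate posterior: all mass on one pattern starves the others
  post1 <- matrix(0, 40, 4); post1[, 2] <- 1
  ms1 <- m_step(post1, toy$X, toy$q)
  expect_true(all(ms1$starved[[1]][-2]))
  h2 <- gndm:::reduced_pattern_index(
    as.matrix(attribute_patterns(2)[paste0("A", 1:2)]), 1:2)[2]
  freq <- tabulate(toy$X[, 1], 4) / 40
  expect_equal(ms1$P[[1]][h2, ], freq, ignore_attr = TRUE)
})

test_that("structural update is the mean posterior", {
  expect_equal(update_structural(rbind(c(1, 0), c(0, 1))), c(0.5, 0.5))
  expect_equal(update_structural(rbind(c(0.3, 0.7), c(0.3, 0.7))),
               c(0.3, 0.7))
})

test_that("EM log-likelihood trace is monotone and blocks row-stochastic", {
  for (s in 1:3) {
    toy <- make_toy(N = 150, seed = 100 + s)
    fit <- gndm(toy$resp, toy$q, seed = s)
    expect_true(all(diff(fit$trace) > -1e-8))
    for (P in fit$P) expect_equal(rowSums(P), rep(1, nrow(P)))
    expect_equal(sum(fit$structural), 1, tolerance = 1e-10)
    expect_true(all(fit$structural >= 0))
    expect_equal(rowSums(fit$posterior), rep(1, fit$N), tolerance = 1e-8)
  }
})

test_that("EM fixed point matches a brute-force likelihood maximization", {
  toy <- make_toy(N = 50, e = 0.75, seed = 7)
  fit <- gndm(toy$resp, toy$q, seed = 2)
  oracle <- brute_force_loglik(toy$X, toy$q, n_starts = 3, seed = 11)
  expect_gte(fit$logLik, oracle - 1e-4)
})

test_that("refitting data simulated from a fit recovers its parameters", {
  q <- ocop_qmatrix(3)
  truth <- gndm:::generating_blocks(q, 0.7, 0.1)
  prev <- c(0.6, 0.45)
  rmse_at <- function(N) {
    att <- simulate_attributes(N, prev, R = 0.3, seed = N)
    resp <- simulate_responses(att, q, blocks = truth, seed = N + 1)
    fit <- gndm(resp, q, seed = 3)
    sqrt(mean(unlist(purrr::map2(fit$P, truth, function(a, b) (a - b)^2))))
  }
  r1 <- rmse_at(1000)
  r2 <- rmse_at(20000)
  expect_lt(r2, r1)
  expect_lt(r2, 0.02)
})

test_that("degenerate constant responses converge to a point mass", {
  q <- ocop_qmatrix(2)
  X <- matrix(1L, 50, 2)
  fit <- suppressWarnings(gndm(X, q, seed = 1))
  for (P in fit$P) expect_true(all(P[, 1] > 0.999))
})

test_that("permuting option labels permutes the fitted parameters", {
  toy <- make_toy(N = 200, seed = 31)
  init <- gndm:::init_blocks(toy$q, "anchored")
  fit <- gndm(toy$resp, toy$q, init = init)
  # swap options 2 and 3 of item 1 (Q rows, data, init alike)
  perm <- c(1L, 3L, 2L, 4L)
  tbl <- toy$q$tbl
  i1 <- tbl$item == 1
  tbl[i1, ] <- tbl[i1, ][perm, ]
  tbl$option[i1] <- 1:4
  qp <- extended_qmatrix(tbl)
  Xp <- toy$X
  Xp[, 1] <- perm[Xp[, 1]]  # relabel responses (perm is an involution)
  initp <- init
  initp[[1]] <- init[[1]][, perm]
  fitp <- gndm(Xp, qp, init = initp)
  expect_equal(fitp$P[[1]], fit$P[[1]][, perm], tolerance = 1e-6)
  expect_equal(fitp$P[[2]], fit$P[[2]], tolerance = 1e-6)
  expect_equal(fitp$logLik, fit$logLik, tolerance = 1e-6)
})

test_that("the carried-posterior variant sharpens posteriors", {
  toy <- make_toy(N = 150, seed = 77)
  fit_s <- gndm(toy$resp, toy$q, seed = 1)
  fit_i <- suppressWarnings(gndm(toy$resp, toy$q, variant = "individual",
                                 seed = 1))
  expect_equal(fit_i$variant, "individual")
  expect_gt(mean(apply(fit_i$posterior, 1, max)),
            mean(apply(fit_s$posterior, 1, max)))
})

test_that("classification uses MAP patterns and marginal thresholds", {
  q <- ocop_qmatrix(1)
  stub <- structure(list(qmatrix = q, resp = NULL), class = "gndm_fit")
  stub$posterior <- matrix(c(0, 0, 1, 0), 1)  # point mass on pattern 10
  cls <- classify(stub)
  expect_equal(cls$bits, "10")
  expect_equal(c(cls$A1, cls$A2), c(1L, 0L))
  # 0.4 on 11, 0.3 on 10, 0.3 on 01 -> MAP 11, marginals (0.7, 0.7)
  stub$posterior <- matrix(c(0, 0.3, 0.3, 0.4), 1)
  cls <- classify(stub)
  expect_equal(cls$bits, "11")
  expect_equal(c(cls$p_A1, cls$p_A2), c(0.7, 0.7))
  # uniform posterior at K = 1: tie breaks to the all-zero pattern,
  # marginal exactly 0.5 classifies as possession
  q1 <- onek_qmatrix(1, 1)
  stub1 <- structure(list(qmatrix = q1, resp = NULL,
                          posterior = matrix(c(0.5, 0.5), 1)),
                     class = "gndm_fit")
  cls1 <- classify(stub1)
  expect_equal(cls1$bits, "0")
  expect_equal(cls1$A1, 1L)
})

test_that("response validation reports coordinates", {
  q <- ocop_qmatrix(2)
  X <- matrix(1L, 4, 2)
  X[3, 2] <- 9L
  expect_error(gndm(X, q), "respondent 3 item 2")
  Xna <- matrix(1L, 4, 2)
  Xna[2, 1] <- NA_integer_
  expect_error(gndm(Xna, q), "missing response")
  expect_error(gndm(matrix(1L, 4, 3), q), "3 item columns")
})

test_that("tidy and glance summarize a fit", {
  toy <- make_toy(N = 80)
  fit <- gndm(toy$resp, toy$q, seed = 1)
  td <- tidy(fit)
  expect_equal(nrow(td), 2 * 4 * 4)
  expect_true(all(td$estimate >= 0 & td$estimate <= 1))
  gl <- glance(fit)
  expect_equal(gl$npar, 2 * 12 + 3)
  expect_equal(gl$logLik, fit$logLik)
  expect_s3_class(autoplot(fit), "ggplot")
})
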