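test_that("predicted samples have the requested size and valid codes", {
  s <- small_fit()
  pred <- simulate_predicted(s$fit, multiplier = 10, seed = 5)
  expect_equal(nrow(pred), 10 * 300)
  expect_true(all(pred >= 1 & pred <= 4))
  # deterministic blocks: the response is a function of the drawn pattern
  fitd <- s$fit
  fitd$P <- gndm:::generating_blocks(s$q, 1, 0)
  fitd$structural <- c(0, 1, 0, 0)  # point mass on pattern 01
  p1 <- simulate_predicted(fitd, multiplier = 1, seed = 9)
  expect_equal(unname(unique(as.vector(p1))),
               expected_map(s$q)$option[expected_map(s$q)$bits == "01"][1])
})

test_that("predicted option marginals match the model-implied marginals", {
  s <- small_fit(N = 200, seed = 71)
  pred <- simulate_predicted(s$fit, multiplier = 500, seed = 6)  # 1e5 draws
  hm <- s$fit$hmaps[[1]]
  implied <- colSums(s$fit$structural * s$fit$P[[1]][hm, ])
  emp <- tabulate(pred[, 1], 4) / nrow(pred)
  mc_se <- sqrt(implied * (1 - implied) / nrow(pred))
  expect_true(all(abs(emp - implied) < 3 * mc_se + 1e-12))
})

test_that("a predicted-equals-observed assessment is exactly null", {
  s <- small_fit(N = 150)
  rep0 <- assess_fit(s$fit, predicted = s$X)
  expect_equal(rep0$pairs$l, rep(0, rep0$n_pairs))
  expect_equal(rep0$pairs$z, rep(0, rep0$n_pairs))
  expect_equal(rep0$sl, 0)
  expect_equal(rep0$max_z, 0)
  expect_false(rep0$reject)
  expect_equal(glance(rep0)$sl, 0)
})

test_that("pair counts follow (T-J)(T-J-1)/2 with within-item pairs", {
  q10 <- sim_qmatrix(1)
  att <- simulate_attributes(80, c(0.7, 0.6, 0.5, 0.4, 0.3), R = 0.5,
                             seed = 1)
  resp <- simulate_responses(att, q10, e = 0.6, u = 0.1, seed = 2)
  fit <- suppressWarnings(gndm(resp, q10, seed = 3, max_iter = 100))
  a <- assess_fit(fit, multiplier = 1, seed = 4)
  expect_equal(a$n_pairs, 40 * 39 / 2)  # T - J = 40 dichotomized options
  # two 2-option items give a single pair
  q2 <- onek_qmatrix(2, 1)
  X2 <- cbind(rep(1:2, 10), rep(1:2, each = 10))
  fit2 <- suppressWarnings(gndm(X2, q2, seed = 1, max_iter = 100))
  expect_equal(assess_fit(fit2, multiplier = 2, seed = 5)$n_pairs, 1L)
  # excluding within-item pairs on a single item leaves none
  q1 <- ocop_qmatrix(1)
  X1 <- matrix(sample(1:4, 60, TRUE), 60, 1)
  fit1 <- suppressWarnings(gndm(X1, q1, seed = 1, max_iter = 100))
  a1 <- assess_fit(fit1, multiplier = 2, include_within_item = FALSE,
                   seed = 6)
  expect_equal(a1$n_pairs, 0L)
  a1w <- assess_fit(fit1, multiplier = 2, seed = 6)
  expect_equal(a1w$n_pairs, 3L)
})

test_that("LOR residuals and SEs follow the continuity-corrected formulas", {
  # two 2-option items; joint counts of (option-2, option-2) indicators:
  # n11 = 40, n10 = 10, n01 = 10, n00 = 40
  q <- onek_qmatrix(2, 1)
  block <- rbind(c(2, 2), c(2, 1), c(1, 2), c(1, 1))
  X <- block[rep(1:4, c(40, 10, 10, 40)), ]
  pred <- block[rep(1:4, c(30, 20, 20, 30)), ]
  pr <- lor_residuals(X, pred, q)
  lor_obs <- log((40.5 * 40.5) / (10.5 * 10.5))
  lor_pred <- log((30.5 * 30.5) / (20.5 * 20.5))
  expect_equal(pr$lor_obs, lor_obs)
  expect_equal(pr$lor_pred, lor_pred)
  expect_equal(pr$l, abs(lor_obs - lor_pred))
  expect_equal(pr$se,
               sqrt(100 * (1 / 30.5 + 1 / 30.5 + 1 / 20.5 + 1 / 20.5) / 100))
  expect_equal(pr$z, pr$l / pr$se)
  # a 16-fold odds ratio against an even predicted table
  X16 <- block[rep(1:4, c(40, 10, 10, 40)), ]
  p16 <- block[rep(1:4, c(25, 25, 25, 25)), ]
  pr16 <- lor_residuals(X16, p16, q)
  expect_equal(pr16$l, log((40.5 * 40.5) / (10.5 * 10.5)), tolerance = 1e-12)
})

test_that("misfit statistics aggregate z-scores as root mean squares", {
  # hand-built residual set on a 2-item test with T - J = 4
  q <- ocop_qmatrix(2)
  pairs <- tibble::tibble(
    item1 = c(1, 1, 1), option1 = c(2, 2, 3),
    item2 = c(2, 2, 2), option2 = c(2, 3, 2),
    lor_obs = 0, lor_pred = 0, se = 1,
    l = c(1, 2, 2), z = c(1, 2, 2))
  # T = 8, J = 2 for this geometry
  qT <- q
  st <- fit_statistics(pairs, qT, alpha = 0.05)
  TmJ <- 6
  expect_equal(st$option_stats$sl_jc[st$option_stats$item == 1 &
                                       st$option_stats$option == 2],
               sqrt((1^2 + 2^2) / (TmJ - 1)))
  expect_equal(st$sl, sqrt(2 * (1 + 4 + 4) / (TmJ * (TmJ - 1))))
  expect_equal(st$item_stats$sl_j[1],
               sum(st$option_stats$sl_jc[st$option_stats$item == 1]) / 3)
  # single large z-score is rejected at the plain normal critical value
  one <- pairs[1, ]
  one$z <- 4
  st1 <- fit_statistics(one, q, alpha = 0.05)
  expect_equal(st1$critical, qnorm(0.975))
  expect_true(st1$reject)
  # all-zero z-scores: nothing flagged
  zero <- pairs
  zero$z <- 0
  st0 <- fit_statistics(zero, q)
  expect_equal(st0$sl, 0)
  expect_false(st0$reject)
})

test_that("misfit ranking is descending with ties broken by index", {
  pairs <- tibble::tibble(item1 = 1, option1 = 2, item2 = 2, option2 = 2,
                          lor_obs = 0, lor_pred = 0, se = 1, l = 1, z = 1)
  st <- fit_statistics(pairs, ocop_qmatrix(2))
  rep_stub <- structure(c(list(pairs = pairs), st,
                          list(alpha = 0.05, N = 1, N_pred = 1)),
                        class = "gndm_assessment")
  fm <- flag_misfit(rep_stub)
  expect_equal(fm$items$sl_j, sort(fm$items$sl_j, decreasing = TRUE))
  # equal sl_j: lower item index first
  expect_equal(fm$items$item[fm$items$sl_j == max(fm$items$sl_j)][1],
               min(fm$items$item[fm$items$sl_j == max(fm$items$sl_j)]))
})

test_that("an item with a misspecified q-vector is flagged as worst", {
  # six OCOP items over K = 3, two per attribute pair so the latent space
  # is anchored; data for item 2 actually depend on attributes (1, 2)
  # while its coded q-vector says (2, 3)
  pair_item <- function(j, a, b, K = 3) {
    m <- matrix(0L, 4, K)
    m[, a] <- c(1L, 0L, 1L, 0L)
    m[, b] <- c(0L, 1L, 1L, 0L)
    out <- tibble::tibble(item = j, option = 1:4)
    for (k in seq_len(K)) out[[paste0("A", k)]] <- m[, k]
    out
  }
  mk <- function(specs) {
    extended_qmatrix(dplyr::bind_rows(purrr::imap(specs, function(s, j) {
      pair_item(j, s[1], s[2])
    })))
  }
  q_fit <- mk(list(c(1, 2), c(2, 3), c(1, 3), c(1, 2), c(2, 3), c(1, 3)))
  q_gen <- mk(list(c(1, 2), c(1, 2), c(1, 3), c(1, 2), c(2, 3), c(1, 3)))
  hits <- 0L
  reps <- 10L
  for (r in seq_len(reps)) {
    att <- simulate_attributes(600, c(0.6, 0.5, 0.4), R = 0.3,
                               seed = 800 + r)
    resp <- simulate_responses(att, q_gen, e = 0.85, u = 0.05,
                               seed = 900 + r)
    fit <- suppressWarnings(gndm(resp, q_fit, seed = 1, max_iter = 300))
    a <- assess_fit(fit, multiplier = 5, seed = 950 + r)
    worst <- flag_misfit(a)$items$item[1]
    hits <- hits + (worst == 2L)
  }
  expect_gte(hits, 8L)
})

test_that("the Bonferroni max-z test is conservative under the truth", {
  rejections <- vapply(1:15, function(r) {
    s <- small_fit(N = 250, seed = 1000 + r)
    assess_fit(s$fit, multiplier = 5, seed = 2000 + r)$reject
  }, TRUE)
  expect_lte(mean(rejections), 0.1 + 1e-9)
})

test_that("sl shrinks with the predicted-sample multiplier", {
  sls <- vapply(1:5, function(r) {
    s <- small_fit(N = 250, seed = 3000 + r)
    c(assess_fit(s$fit, multiplier = 1, seed = 100 + r)$sl,
      assess_fit(s$fit, multiplier = 20, seed = 100 + r)$sl)
  }, numeric(2))
  expect_lt(mean(sls[2, ]), mean(sls[1, ]))
})
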