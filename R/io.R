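#' Read and write response files
#'
#' Responses travel as CSV with header `resp,I1..IJ` and 1-based option
#' codes.
#'
#' @param path CSV path.
#' @param qmatrix Optional `gndm_qmatrix` used to validate option ranges.
#' @return `read_responses()`: a tibble with `resp` and item columns.
#' @export
read_responses <- function(path, qmatrix = NULL) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  if (!"resp" %in% names(x)) {
    abort("responses CSV needs a `resp` column")
  }
  x$resp <- as.character(x$resp)
  if (!is.null(qmatrix)) response_matrix(x, qmatrix)
  x
}

#' @rdname read_responses
#' @param data Response tibble (columns `resp`, `I1..IJ`).
#' @export
write_responses <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}

#' Write a fitted model to JSON
#'
#' Stores the item blocks, structural distribution, log-likelihood,
#' iteration count, estimation variant, seed, and a hash of the extended
#' Q-matrix used, so a reloaded fit can be checked against its inputs.
#'
#' @param fit A `gndm_fit`.
#' @param path Output path.
#' @export
write_gndm_fit <- function(fit, path) {
  stopifnot(inherits(fit, "gndm_fit"))
  obj <- list(
    extq_hash = rlang::hash(fit$qmatrix$tbl),
    items = purrr::map(seq_len(fit$qmatrix$J), function(jj) {
      it <- fit$qmatrix$items[[jj]]
      list(item = it$item, H = it$H, C = it$C, P = fit$P[[jj]])
    }),
    structural = fit$structural,
    loglik = fit$logLik,
    iterations = fit$iterations,
    converged = fit$converged,
    variant = fit$variant,
    seed = if (is.null(fit$seed)) NULL else fit$seed
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a fitted model from JSON
#'
#' Restores the parameter part of a fit written by [write_gndm_fit()].
#' The posterior is recomputed when responses are supplied.
#'
#' @param path JSON path.
#' @param qmatrix The `gndm_qmatrix` the fit was estimated with; its hash
#'   is checked.
#' @param data Optional responses to recompute the posterior on.
#' @return A `gndm_fit` (without per-respondent fields unless `data` is
#'   given).
#' @export
read_gndm_fit <- function(path, qmatrix, data = NULL) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$extq_hash, rlang::hash(qmatrix$tbl))) {
    abort("fitted-model JSON was written with a different extended Q-matrix")
  }
  P <- purrr::map(seq_len(qmatrix$J), function(jj) {
    m <- obj$items$P[[jj]]
    matrix(as.numeric(m), nrow = obj$items$H[jj], ncol = obj$items$C[jj])
  })
  patterns <- pattern_matrix(qmatrix$K)
  hmaps <- lapply(qmatrix$items, function(it) {
    reduced_pattern_index(patterns, it$support)
  })
  fit <- list(
    qmatrix = qmatrix, P = P, structural = as.numeric(obj$structural),
    posterior = NULL, logLik = obj$loglik, trace = obj$loglik,
    iterations = obj$iterations, converged = obj$converged,
    variant = obj$variant, hmaps = hmaps,
    npar = sum(vapply(qmatrix$items, function(it) (it$C - 1) * it$H, 0)) +
      2L^qmatrix$K - 1L,
    seed = obj$seed, N = NA_integer_, data = NULL, resp = NULL
  )
  class(fit) <- "gndm_fit"
  if (!is.null(data)) {
    X <- response_matrix(data, qmatrix)
    fit$data <- X
    fit$N <- nrow(X)
    fit$resp <- rownames(X)
    fit$posterior <- e_step(X, P, fit$structural, qmatrix)
    fit$logLik <- marginal_loglik(X, P, fit$structural, qmatrix)
  }
  fit
}
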