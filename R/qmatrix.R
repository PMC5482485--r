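#' Attribute pattern space
#'
#' Enumerates all `2^K` binary attribute patterns in canonical order:
#' binary counting with attribute 1 as the most significant bit, so for
#' `K = 2` the order is 00, 01, 10, 11.  Pattern indices are 1-based.
#'
#' @param K Number of dichotomous attributes (1--20).
#' @return A tibble with columns `pattern` (index), `bits` (string such as
#'   `"101"`), and one 0/1 column `A1..AK` per attribute.
#' @examples
#' attribute_patterns(3)
#' @export
attribute_patterns <- function(K) {
  stopifnot(is.numeric(K), length(K) == 1, K == round(K))
  if (K < 1 || K > 20) {
    abort("pattern space too large: K must be between 1 and 20")
  }
  m <- pattern_matrix(K)
  out <- as_tibble(as.data.frame(m))
  names(out) <- paste0("A", seq_len(K))
  out <- mutate(out,
    pattern = row_number(),
    bits = apply(m, 1, paste, collapse = "")
  )
  select(out, "pattern", "bits", dplyr::everything())
}

# L x K 0/1 matrix, attribute 1 as most significant bit
pattern_matrix <- function(K) {
  L <- 2L^K
  m <- matrix(0L, L, K)
  for (k in seq_len(K)) {
    m[, k] <- as.integer(bitwAnd(seq_len(L) - 1L, bitwShiftL(1L, K - k)) > 0L)
  }
  m
}

#' Reduce an attribute pattern by an item q-vector
#'
#' Restricts a full attribute pattern to the attributes an item requires,
#' keeping attribute order: the reduced pattern of `alpha` under `q` is the
#' subvector of `alpha` at the positions where `q` is 1.
#'
#' @param alpha Binary vector of length `K` (a full attribute pattern).
#' @param q Binary vector of length `K` (the item's q-vector).
#' @return Integer vector of length `sum(q)`.
#' @examples
#' reduce_pattern(c(1, 0, 1, 1, 0), c(0, 0, 1, 1, 0))
#' @export
reduce_pattern <- function(alpha, q) {
  stopifnot(length(alpha) == length(q))
  as.integer(alpha[q == 1])
}

# 1-based reduced-pattern indices for every row of an L x K pattern matrix,
# restricted to attribute positions `support` (most significant first)
reduced_pattern_index <- function(patterns, support) {
  G <- length(support)
  w <- 2L^((G - 1L):0L)
  as.integer(patterns[, support, drop = FALSE] %*% w) + 1L
}

#' Build an extended Q-matrix object
#'
#' The extended Q-matrix codes the attribute requirements of every response
#' option of every item: one row per item-option, entries 1 (attribute
#' required by the option), 0 (not required), or -1 (marking a
#' none-of-the-above, NOA, option).  A NOA row carries -1 at exactly the
#' attributes the item involves and collectively represents all reduced
#' patterns not covered by any substantive option.
#'
#' Validation enforces: entries in \{-1, 0, 1\}; contiguous 1-based option
#' ids within item; at most one NOA row per item, with no mixed -1/1
#' entries; every substantive option's support inside the item support; at
#' least one required attribute per item; at least two options per item.
#'
#' @param x A data frame with columns `item`, `option`, and one column per
#'   attribute (any names; order gives attribute order).
#' @return An object of class `gndm_qmatrix`.
#' @examples
#' q <- sim_qmatrix(1)
#' q
#' @export
extended_qmatrix <- function(x) {
  x <- as.data.frame(x)
  if (!all(c("item", "option") %in% names(x))) {
    abort("extended Q-matrix needs `item` and `option` columns")
  }
  attr_cols <- setdiff(names(x), c("item", "option"))
  K <- length(attr_cols)
  if (K < 1) abort("extended Q-matrix has no attribute columns")
  qm <- as.matrix(x[attr_cols])
  storage.mode(qm) <- "integer"
  bad <- which(!(qm %in% c(-1L, 0L, 1L)))
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(qm))
    abort(sprintf("entry not in {-1,0,1} at item %s option %s attribute %d",
                  x$item[rc[1]], x$option[rc[1]], rc[2]))
  }
  item_ids <- unique(x$item)
  items <- vector("list", length(item_ids))
  for (jj in seq_along(item_ids)) {
    id <- item_ids[jj]
    rows <- which(x$item == id)
    opts <- x$option[rows]
    if (!identical(as.integer(opts), seq_along(rows))) {
      abort(sprintf("item %s: option ids must be contiguous from 1", id))
    }
    Q <- qm[rows, , drop = FALSE]
    C_j <- nrow(Q)
    if (C_j < 2) abort(sprintf("item %s: needs at least 2 options", id))
    is_noa <- apply(Q, 1, function(r) any(r == -1L))
    for (c in which(is_noa)) {
      if (any(Q[c, ] == 1L)) {
        abort(sprintf("malformed NOA row: item %s option %d mixes -1 and 1",
                      id, c))
      }
    }
    if (sum(is_noa) > 1) {
      abort(sprintf("duplicate NOA: item %s has %d NOA rows", id, sum(is_noa)))
    }
    noa <- if (any(is_noa)) which(is_noa) else NA_integer_
    support <- which(colSums(abs(Q)) > 0L)
    if (length(support) == 0) {
      abort(sprintf("item %s: no required attributes", id))
    }
    if (!is.na(noa)) {
      noa_pos <- which(Q[noa, ] == -1L)
      for (c in seq_len(C_j)[-noa]) {
        extra <- setdiff(which(Q[c, ] == 1L), noa_pos)
        if (length(extra)) {
          abort(sprintf(
            "option exceeds item q-vector: item %s option %d requires attribute %d outside the NOA support",
            id, c, extra[1]))
        }
      }
      support <- noa_pos
    }
    G <- length(support)
    items[[jj]] <- list(
      item = id, C = C_j, Q = Q, noa = noa,
      support = support, G = G, H = as.integer(2^G)
    )
  }
  structure(
    list(
      tbl = as_tibble(x), K = K, J = length(items),
      attr_names = attr_cols, items = items,
      T_total = sum(vapply(items, `[[`, 1L, "C"))
    ),
    class = "gndm_qmatrix"
  )
}

#' @export
print.gndm_qmatrix <- function(x, ...) {
  cat(sprintf("<gndm_qmatrix> %d items, %d attributes, %d option rows\n",
              x$J, x$K, x$T_total))
  d <- classify_design(x)
  tab <- table(d$design)
  cat("designs:", paste(sprintf("%s x%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' Read an extended Q-matrix from CSV
#'
#' Expects a header `item,option,A1..AK` with entries -1/0/1.
#'
#' @param path Path to a CSV file.
#' @return A `gndm_qmatrix` object.
#' @export
read_extended_qmatrix <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  extended_qmatrix(x)
}

#' Recover the item-level Q-matrix
#'
#' An attribute is required by an item when at least one of its option rows
#' has a nonzero entry (1 or -1) for it.
#'
#' @param extq A `gndm_qmatrix`.
#' @return A tibble with one row per item: `item`, `G` (number of required
#'   attributes) and 0/1 columns `A1..AK`.
#' @export
item_qmatrix <- function(extq) {
  stopifnot(inherits(extq, "gndm_qmatrix"))
  rows <- purrr::map(extq$items, function(it) {
    q <- integer(extq$K)
    q[it$support] <- 1L
    tibble(item = it$item, G = it$G, !!!setNames(as.list(q),
                                                 paste0("A", seq_len(extq$K))))
  })
  bind_rows(rows)
}

#' Option-to-expected-pattern map
#'
#' A substantive option's expected reduced pattern is its 0/1 row restricted
#' to the item support (a 0 means non-possession is expected).  A NOA
#' option's expected set is the complement: every reduced pattern not
#' expected by any substantive option.  An optional override can assign a
#' substantive option several expected patterns explicitly.
#'
#' @param extq A `gndm_qmatrix`.
#' @param override Optional data frame with columns `item`, `option`,
#'   `bits` (reduced-pattern bitstrings) replacing the coded expectation of
#'   those options.
#' @return An object of class `gndm_expected_map`: a tibble with columns
#'   `item`, `option`, `h` (expected reduced-pattern index), `bits`, plus a
#'   `designs` attribute (see [classify_design()]).
#' @export
expected_map <- function(extq, override = NULL) {
  stopifnot(inherits(extq, "gndm_qmatrix"))
  out <- vector("list", extq$J)
  for (jj in seq_len(extq$J)) {
    it <- extq$items[[jj]]
    eta <- pattern_matrix(it$G)
    expected <- vector("list", it$C)
    for (c in seq_len(it$C)) {
      if (!is.na(it$noa) && c == it$noa) next
      row <- it$Q[c, it$support]
      expected[[c]] <- reduced_pattern_index(matrix(row, 1), seq_len(it$G))
    }
    if (!is.null(override)) {
      ov <- override[override$item == it$item, , drop = FALSE]
      for (r in seq_len(nrow(ov))) {
        c <- ov$option[r]
        if (!is.na(it$noa) && c == it$noa) {
          abort(sprintf("item %s: cannot override the NOA option", it$item))
        }
        bits <- strsplit(unlist(ov$bits[r]), NULL)
        expected[[c]] <- vapply(bits, function(b) {
          reduced_pattern_index(matrix(as.integer(b), 1), seq_len(it$G))
        }, integer(1))
      }
    }
    if (!is.na(it$noa)) {
      covered <- sort(unique(unlist(expected)))
      comp <- setdiff(seq_len(it$H), covered)
      if (length(comp) == 0) {
        warn(sprintf("NOA covers no pattern in item %s", it$item))
      }
      expected[[it$noa]] <- comp
    }
    out[[jj]] <- tibble(
      item = it$item,
      option = rep(seq_len(it$C), lengths(expected)),
      h = unlist(expected)
    ) %>%
      mutate(bits = vapply(.data$h, function(h) {
        paste(eta[h, ], collapse = "")
      }, character(1)))
  }
  map <- bind_rows(out)
  structure(map, class = c("gndm_expected_map", class(map)),
            designs = design_labels(extq, map))
}

design_labels <- function(extq, map) {
  lab <- character(extq$J)
  for (jj in seq_len(extq$J)) {
    it <- extq$items[[jj]]
    mj <- map[map$item == it$item, , drop = FALSE]
    per_option <- table(factor(mj$option, levels = seq_len(it$C)))
    per_pattern <- table(factor(mj$h, levels = seq_len(it$H)))
    multi_pat <- any(per_option > 1)
    multi_opt <- any(per_pattern > 1)
    uncovered <- any(per_pattern == 0)
    lab[jj] <-
      if (multi_pat && multi_opt) "MCMP"
      else if (multi_opt) "MCOP"
      else if (!multi_pat && !uncovered && it$C == it$H) "OCOP"
      else if (uncovered) "OCMP-uncontrolled"
      else "OCMP-controlled"
  }
  tibble(item = vapply(extq$items, `[[`, extq$items[[1]]$item, "item"),
         design = lab)
}

#' Classify item designs
#'
#' Labels each item by the multiplicity of its option-to-pattern map:
#' `OCOP` (one choice one pattern: a bijection between options and reduced
#' patterns), `OCMP-controlled` (some option expects several patterns and
#' every pattern is covered, e.g. via a NOA option), `OCMP-uncontrolled`
#' (some reduced pattern has no expected option), `MCOP` (several options
#' expect the same pattern, each option expects at most one), and `MCMP`
#' (both multiplicities).
#'
#' @param extq A `gndm_qmatrix` (or an existing `gndm_expected_map`).
#' @param map Optionally a precomputed expected map.
#' @return A tibble with columns `item` and `design`.
#' @export
classify_design <- function(extq, map = NULL) {
  if (inherits(extq, "gndm_expected_map")) {
    return(attr(extq, "designs"))
  }
  if (is.null(map)) map <- expected_map(extq)
  attr(map, "designs")
}

#' Free-parameter counts
#'
#' Per-item and total numbers of independent conditional-probability
#' parameters: `(C_j - 1) H_j` for the saturated GNDM, `2 (C_j - 1)` for
#' the PEDM, and `H_j` for the OEDM, where `C_j` is the option count and
#' `H_j = 2^{G_j}` the number of reduced patterns.  The saturated joint
#' attribute distribution adds `2^K - 1` structural parameters, reported
#' separately.
#'
#' @param extq A `gndm_qmatrix`.
#' @param model One of `"GNDM"`, `"PEDM"`, `"OEDM"`.
#' @return A tibble with one row per item (`item`, `C`, `H`, `n_par`) and
#'   attributes `total` (sum of item counts) and `structural` (`2^K - 1`).
#' @examples
#' count_parameters(sim_qmatrix(1), "GNDM")
#' @export
count_parameters <- function(extq, model = c("GNDM", "PEDM", "OEDM")) {
  stopifnot(inherits(extq, "gndm_qmatrix"))
  model <- match.arg(model)
  out <- purrr::map(extq$items, function(it) {
    n <- switch(model,
      GNDM = (it$C - 1L) * it$H,
      PEDM = 2L * (it$C - 1L),
      OEDM = it$H
    )
    tibble(item = it$item, C = it$C, H = as.integer(it$H),
           n_par = as.integer(n))
  }) %>% bind_rows()
  attr(out, "total") <- sum(out$n_par)
  attr(out, "structural") <- 2L^extq$K - 1L
  out
}
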