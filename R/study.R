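#' Build a simulation-study configuration
#'
#' Bundles everything one replication needs: the extended Q-matrix, sample
#' size, attribute prevalences and latent correlation, generating item
#' quality, which models to fit, and the replication count and base seed.
#' Replication `r` uses seed `seed + r`, so studies are bit-reproducible.
#'
#' @param qmatrix A `gndm_qmatrix`.
#' @param N Respondents per replication.
#' @param prevalence Attribute prevalences (length K).
#' @param R Exchangeable latent correlation (or full matrix).
#' @param e,u Generating PEDM parameters, scalar or per-item.
#' @param reps Number of replications.
#' @param seed Base seed.
#' @param models Character subset of `c("gndm", "pedm")`: fit the saturated
#'   model and optionally collapse it to PEDM estimates per replication.
#' @param se Compute delta-method SEs for the PEDM estimates (used for the
#'   mean-SE recovery column).
#' @param label Optional named list describing the condition (carried into
#'   reports).
#' @param ... Extra arguments passed to [gndm()] (e.g. `variant`).
#' @return A list of class `gndm_study_config`.
#' @export
study_config <- function(qmatrix, N = 1000,
                         prevalence = c(0.7, 0.6, 0.5, 0.4, 0.3), R = 0.5,
                         e = 0.6, u = 0.1, reps = 200, seed = 1,
                         models = "gndm", se = FALSE, label = list(), ...) {
  stopifnot(inherits(qmatrix, "gndm_qmatrix"))
  stopifnot(all(models %in% c("gndm", "pedm")))
  if (is.matrix(R)) {
    tryCatch(chol(R), error = function(e) {
      abort("latent correlation matrix is not positive definite")
    })
  } else if (R < 0 || R >= 1) {
    abort("exchangeable latent correlation must be in [0, 1)")
  }
  structure(
    list(qmatrix = qmatrix, N = N, prevalence = prevalence, R = R,
         e = e, u = u, reps = reps, seed = seed, models = models,
         se = se, label = label, fit_args = list(...)),
    class = "gndm_study_config"
  )
}

#' Packaged study presets
#'
#' Conditions of the two packaged simulation studies: N = 1000, K = 5
#' attributes with prevalences 0.7, 0.6, 0.5, 0.4, 0.3, exchangeable
#' latent correlation 0.5, 200 replications.  Study 1 crosses design
#' (controlled / uncontrolled OCMP) with item quality (low / high) and
#' test length (J = 10 / 20), fitting the saturated model.  Study 2 uses
#' the mixed OCOP + controlled-OCMP form and additionally collapses each
#' saturated fit to PEDM estimates with delta-method SEs for
#' parameter-recovery statistics.
#'
#' @param study 1 or 2.
#' @param quality `"low"` or `"high"`.
#' @param design For study 1: `"controlled"` or `"uncontrolled"`.
#' @param J Test length, 10 or 20.
#' @param reps Replications (default 200).
#' @param seed Base seed.
#' @param N Respondents per replication (default 1000).
#' @return A `gndm_study_config`.
#' @export
study_preset <- function(study = 1, quality = c("low", "high"),
                         design = c("controlled", "uncontrolled"),
                         J = 10, reps = 200, seed = 1, N = 1000) {
  quality <- match.arg(quality)
  design <- match.arg(design)
  stopifnot(study %in% c(1, 2))
  if (study == 1) {
    controlled <- design == "controlled"
    q <- sim_qmatrix(1, J = J, controlled = controlled)
    pars <- sim_quality(1, quality, controlled)
    study_config(q, N = N, e = pars$e, u = pars$u, reps = reps, seed = seed,
                 max_iter = 6000,
                 label = list(study = 1, design = design, quality = quality,
                              J = J))
  } else {
    q <- sim_qmatrix(2, J = J)
    G <- vapply(q$items, `[[`, 1L, "G")
    e <- rep(c(low = 0.600, high = 0.760)[[quality]], q$J)
    u <- ifelse(G == 2, (1 - e) / 3, (1 - e) / 4)
    study_config(q, N = N, e = e, u = u, reps = reps, seed = seed,
                 models = c("gndm", "pedm"), se = TRUE, max_iter = 6000,
                 label = list(study = 2, design = "mixed", quality = quality,
                              J = J))
  }
}

#' Run a replication study
#'
#' For each replication: simulate attributes and responses, fit the
#' saturated model, classify respondents (posterior-mode attribute vector,
#' marginal-posterior attribute estimates), and accumulate classification
#' accuracy; when PEDM collapse is requested, also record the collapsed
#' parameter estimates (and SEs) for recovery statistics.  Replications
#' whose EM fails to converge are excluded and counted; a warning is
#' raised when they exceed 5%.
#'
#' @param config A `gndm_study_config`.
#' @param progress Print a dot per replication.
#' @return An object of class `gndm_study`: list with `ca` (per-rep
#'   accuracy tibble), `ca_summary` (mean and SD), `recovery` (per-group
#'   summary, if PEDM was requested), `recovery_params` (per-parameter
#'   stats), `n_failed`, `config`.
#' @export
run_study <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "gndm_study_config"))
  q <- config$qmatrix
  K <- q$K
  acc <- vector("list", config$reps)
  est <- vector("list", config$reps)
  failed <- logical(config$reps)
  want_pedm <- "pedm" %in% config$models
  with_seed(config$seed, {
    for (r in seq_len(config$reps)) {
      set.seed(config$seed + r)
      att <- simulate_attributes(config$N, config$prevalence, config$R)
      resp <- simulate_responses(att, q, e = config$e, u = config$u)
      fit <- suppressWarnings(do.call(gndm, c(
        list(data = resp, qmatrix = q), config$fit_args)))
      if (!fit$converged) {
        failed[r] <- TRUE
        next
      }
      cls <- classify(fit)
      acc[[r]] <- mutate(
        classification_accuracy(att, cls[paste0("A", seq_len(K))]),
        rep = r, .before = 1)
      if (want_pedm) {
        pp <- collapse_pedm(fit)
        if (config$se) pp <- suppressWarnings(collapsed_se(fit, pp))
        base <- as_tibble(pp)
        if (!config$se) base$se_e <- base$se_u <- NA_real_
        est[[r]] <- bind_rows(
          tibble(item = base$item, option = base$option, parameter = "e",
                 estimate = base$e, se = base$se_e),
          tibble(item = base$item, option = base$option, parameter = "u",
                 estimate = base$u, se = base$se_u)
        ) %>% mutate(rep = r)
      }
      if (progress) cat(".")
    }
  })
  if (progress) cat("\n")
  n_failed <- sum(failed)
  if (n_failed >= 0.05 * config$reps) {
    warn(sprintf("%d of %d replications failed to converge (excluded)",
                 n_failed, config$reps))
  }
  ca <- bind_rows(acc)
  ca_summary <- ca %>%
    select(-"rep") %>%
    tidyr::pivot_longer(dplyr::everything(), names_to = "statistic") %>%
    group_by(.data$statistic) %>%
    summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
              .groups = "drop")
  out <- list(ca = ca, ca_summary = ca_summary, n_failed = n_failed,
              config = config, recovery = NULL, recovery_params = NULL)
  if (want_pedm && length(bind_rows(est))) {
    truth <- pedm_truth(config)
    longest <- bind_rows(est)
    per_par <- recovery_stats(longest, truth,
                              keys = c("item", "option", "parameter"))
    G <- tibble(item = vapply(q$items, `[[`, q$items[[1]]$item, "item"),
                G = vapply(q$items, `[[`, 1L, "G"))
    out$recovery_params <- left_join(per_par, G, by = "item")
    out$recovery <- out$recovery_params %>%
      mutate(item_group = ifelse(.data$G == 2, "two-attribute",
                                 "three-attribute")) %>%
      group_by(.data$item_group, .data$parameter) %>%
      summarise(mean_bias = mean(.data$bias), rmse = mean(.data$rmse),
                mean_se = mean(.data$mean_se), .groups = "drop")
  }
  structure(out, class = "gndm_study")
}

# generating-value tibble in the shape recovery_stats() expects
pedm_truth <- function(config) {
  q <- config$qmatrix
  e <- rep_len(config$e, q$J)
  u <- rep_len(config$u, q$J)
  purrr::map(seq_len(q$J), function(jj) {
    it <- q$items[[jj]]
    tidyr::expand_grid(option = seq_len(it$C),
                       parameter = c("e", "u")) %>%
      mutate(item = it$item,
             truth = ifelse(.data$parameter == "e", e[jj], u[jj]))
  }) %>% bind_rows()
}

#' @export
print.gndm_study <- function(x, ...) {
  lab <- x$config$label
  cat(sprintf("<gndm_study> %d replications (%d excluded)%s\n",
              x$config$reps, x$n_failed,
              if (length(lab)) paste0(": ",
                paste(names(lab), unlist(lab), sep = "=", collapse = ", "))
              else ""))
  print(x$ca_summary)
  if (!is.null(x$recovery)) {
    cat("PEDM recovery:\n")
    print(x$recovery)
  }
  invisible(x)
}

#' @rdname tidy
#' @export
tidy.gndm_study <- function(x, ...) {
  x$ca_summary
}

#' @rdname glance
#' @export
glance.gndm_study <- function(x, ...) {
  s <- x$ca_summary
  tibble(
    reps = x$config$reps, n_failed = x$n_failed,
    ca_pattern = s$mean[s$statistic == "ca_pattern"],
    ca_pattern_sd = s$sd[s$statistic == "ca_pattern"],
    ca_attr_mean = s$mean[s$statistic == "ca_attr_mean"],
    ca_attr_mean_sd = s$sd[s$statistic == "ca_attr_mean"]
  )
}
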