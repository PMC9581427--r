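#' Cohort information-criterion summaries
#'
#' Arithmetic means of AIC and BIC across subjects per variant, from a
#' grid of per-subject fits. Errors if any subject is missing a variant.
#'
#' @param fit_tbl Tibble with one row per subject x variant and columns
#'   `subject_id`, `variant`, `AIC`, `BIC` (e.g. bound [glance.ddm_fit()]
#'   rows).
#' @return Tibble: `variant`, `n_params` (if present), `mean_aic`,
#'   `mean_bic`.
#' @export
information_criteria <- function(fit_tbl) {
  grid <- table(fit_tbl$subject_id, fit_tbl$variant)
  if (any(grid != 1)) {
    bad <- rownames(grid)[rowSums(grid != 1) > 0]
    stop("incomplete fit grid for subjects: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out <- fit_tbl |>
    dplyr::group_by(.data$variant) |>
    dplyr::summarise(
      dplyr::across(dplyr::any_of("n_params"), dplyr::first),
      mean_aic = mean(.data$AIC),
      mean_bic = mean(.data$BIC),
      .groups = "drop"
    )
  out[order(match(out$variant, unique(fit_tbl$variant))), ]
}

#' Pairwise mean AIC difference
#'
#' Mean over subjects of `AIC_a - AIC_b`.
#'
#' @param fit_tbl As in [information_criteria()].
#' @param a,b Variant names.
#' @return Scalar mean difference.
#' @export
delta_aic <- function(fit_tbl, a, b) {
  wide <- tidyr::pivot_wider(fit_tbl[c("subject_id", "variant", "AIC")],
                             names_from = "variant", values_from = "AIC")
  if (!all(c(a, b) %in% names(wide))) stop("unknown variant", call. = FALSE)
  mean(wide[[a]] - wide[[b]])
}

#' Random-effects Bayesian model selection
#'
#' Variational estimation of the population distribution over models from
#' per-subject log evidences (Dirichlet prior `alpha0 = 1` on model
#' frequencies, categorical model assignments), following the standard
#' random-effects scheme. Exceedance probabilities are computed by
#' Monte-Carlo sampling of the Dirichlet posterior; the protected
#' exceedance probability shrinks them toward chance by the Bayes omnibus
#' risk (BOR), the posterior probability that model frequencies are
#' indistinguishable: `pep = ep * (1 - bor) + bor / K`.
#'
#' @param log_evidence Numeric matrix, subjects x variants (column names
#'   kept), of model log evidences (e.g. `-AIC / 2`).
#' @param alpha0 Dirichlet prior concentration (default 1).
#' @param n_draws Dirichlet Monte-Carlo draws for exceedance (default
#'   1e5).
#' @param max_iter,tol Variational convergence controls.
#' @param seed Seed for the exceedance draws.
#' @return Object of class `bms`: `alpha`, `expected_freq`, `exceedance`,
#'   `bor`, `pep`, `free_energy`.
#' @export
#' @examples
#' le <- cbind(m1 = c(-10, -12, -9), m2 = c(-14, -13, -15))
#' rfx_bms(le)$pep
rfx_bms <- function(log_evidence, alpha0 = 1, n_draws = 1e5,
                    max_iter = 500, tol = 1e-6, seed = 1) {
  le <- as.matrix(log_evidence)
  if (!all(is.finite(le))) stop("log evidences must be finite", call. = FALSE)
  n <- nrow(le)
  K <- ncol(le)
  if (n < 2 || K < 2) stop("need >= 2 subjects and >= 2 variants",
                           call. = FALSE)
  if (is.null(colnames(le))) colnames(le) <- paste0("m", seq_len(K))

  alpha <- rep(alpha0, K)
  u <- matrix(1 / K, n, K)
  for (it in seq_len(max_iter)) {
    lu <- sweep(le, 2, digamma(alpha) - digamma(sum(alpha)), `+`)
    lu <- lu - apply(lu, 1, max)
    u_new <- exp(lu) / rowSums(exp(lu))
    alpha_new <- alpha0 + colSums(u_new)
    delta <- max(abs(alpha_new - alpha))
    alpha <- alpha_new
    u <- u_new
    if (delta < tol) break
  }

  # free energy of H1 (frequencies free) and H0 (frequencies fixed at 1/K)
  psi <- digamma(alpha) - digamma(sum(alpha))
  lnB <- function(a) sum(lgamma(a)) - lgamma(sum(a))
  ulogu <- sum(u[u > 0] * log(u[u > 0]))
  F1 <- sum(u * le) + sum(u %*% psi) - lnB(rep(alpha0, K)) +
    sum((alpha0 - 1) * psi) + lnB(alpha) - sum((alpha - 1) * psi) - ulogu
  F0 <- sum(apply(le, 1, function(r) {
    m <- max(r); m + log(mean(exp(r - m)))
  }))
  bor <- 1 / (1 + exp(F1 - F0))

  ep <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    g <- matrix(stats::rgamma(n_draws * K, shape = rep(alpha, each = n_draws)),
                nrow = n_draws)
    tabulate(max.col(g, ties.method = "random"), K) / n_draws
  })

  pep <- ep * (1 - bor) + bor / K
  structure(list(
    variants = colnames(le),
    alpha = stats::setNames(alpha, colnames(le)),
    expected_freq = stats::setNames(alpha / sum(alpha), colnames(le)),
    exceedance = stats::setNames(ep, colnames(le)),
    bor = bor,
    pep = stats::setNames(pep, colnames(le)),
    free_energy = c(F1 = F1, F0 = F0)
  ), class = "bms")
}

#' @export
print.bms <- function(x, ...) {
  cat("<bms>", length(x$variants), "variants, BOR =", signif(x$bor, 4), "\n")
  print(round(rbind(expected_freq = x$expected_freq, pep = x$pep), 4))
  invisible(x)
}

#' @rdname rfx_bms
#' @param x A `bms` object.
#' @param ... Unused.
#' @export
tidy.bms <- function(x, ...) {
  tibble::tibble(variant = x$variants,
                 expected_freq = unname(x$expected_freq),
                 exceedance = unname(x$exceedance),
                 pep = unname(x$pep))
}

#' Full model-comparison table
#'
#' Combines mean information criteria with random-effects model selection
#' on `-AIC / 2` evidences, in the standard layout (model, parameters,
#' mean AIC, PEP, mean BIC).
#'
#' @param fit_tbl Tibble of per-subject, per-variant fits with columns
#'   `subject_id`, `variant`, `AIC`, `BIC` and optionally `n_params`.
#' @param seed Seed for the exceedance draws.
#' @param n_draws Dirichlet Monte-Carlo draws.
#' @return Tibble: `variant`, `n_params`, `mean_aic`, `pep`, `mean_bic`.
#' @export
comparison_table <- function(fit_tbl, seed = 1, n_draws = 1e5) {
  ic <- information_criteria(fit_tbl)
  wide <- tidyr::pivot_wider(fit_tbl[c("subject_id", "variant", "AIC")],
                             names_from = "variant", values_from = "AIC")
  le <- -as.matrix(wide[-1]) / 2
  bms <- rfx_bms(le, seed = seed, n_draws = n_draws)
  ic$pep <- unname(bms$pep[ic$variant])
  cols <- intersect(c("variant", "n_params", "mean_aic", "pep", "mean_bic"),
                    names(ic))
  ic[cols]
}
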