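#' Lapse-limited logistic choice models
#'
#' Maximum-likelihood fits of `P(H) = lambda + (1 - 2 lambda) /
#' (1 + exp(-f))`, where `f` is a linear predictor of the trial. Models:
#' `base` (`f = b0 + b_SNR SNR`; 3 parameters), `bias` (cue-specific
#' intercepts `b0c`; 5), `bias_sensitivity` (cue-specific intercepts and
#' slopes; 7), `stim_bias` (`b0 + b_SNR SNR + sum_i b_pt,i pt_i` over the
#' last `n_back` pre-test tones, contrast-coded +0.5/-0.5; 5 at
#' `n_back = 2`) and `stim_bias_adapt` (adds the SNR-dependent
#' interactions `b_pta,i pt_i |SNR|`; 7 at `n_back = 2`). Pre-test
#' positions are indexed from 1 for the tone immediately before the test
#' tone. One lapse rate is shared across cues within a fit.
#'
#' @param trials Trial tibble with choices.
#' @param model Model name (see above).
#' @param n_back Number of trailing pre-test tone positions (<= 6).
#' @param n_starts Multi-start count for the optimizer (default 10).
#' @param seed Seed for the starts.
#' @return Object of class `psych_fit` with coefficients, `lapse`,
#'   `loglik`, `aic`, `bic`; separation is flagged via `clamped`.
#' @export
fit_logistic <- function(trials, model = c("base", "bias", "bias_sensitivity",
                                           "stim_bias", "stim_bias_adapt"),
                         n_back = 2, n_starts = 10, seed = 1) {
  model <- match.arg(model)
  stopifnot(n_back >= 1, n_back <= 6)
  trials <- filter_analyzable(trials)
  trials <- trials[!is.na(trials$choice) & trials$choice %in% c("L", "H"), ]
  if (nrow(trials) < 50) stop("need at least 50 trials with choices",
                              call. = FALSE)
  X <- logistic_design(trials, model, n_back)
  y <- as.integer(trials$choice == "H")
  k <- ncol(X) + 1L

  beta_cap <- 30
  nll <- function(par) {
    lambda <- par[1]
    f <- drop(X %*% par[-1])
    p <- lambda + (1 - 2 * lambda) * stats::plogis(f)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(y * log(p) + (1 - y) * log(1 - p))
  }

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  best <- NULL
  for (s in seq_len(n_starts)) {
    init <- c(stats::runif(1, 0.001, 0.1),
              stats::rnorm(ncol(X), 0, if (s == 1) 0 else 2))
    fit <- try(stats::optim(init, nll, method = "L-BFGS-B",
                            lower = c(0, rep(-beta_cap, ncol(X))),
                            upper = c(0.2, rep(beta_cap, ncol(X)))),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("logistic optimization failed", call. = FALSE)
  coefs <- stats::setNames(best$par[-1], colnames(X))
  structure(list(
    model = model, n_back = n_back,
    lapse = best$par[1], coef = coefs,
    loglik = -best$value, n_params = k, n_trials = nrow(trials),
    aic = 2 * k + 2 * best$value,
    bic = k * log(nrow(trials)) + 2 * best$value,
    clamped = any(abs(coefs) >= beta_cap - 1e-6)
  ), class = "psych_fit")
}

logistic_design <- function(trials, model, n_back) {
  snr <- trials$snr_unit
  if (model %in% c("bias", "bias_sensitivity")) {
    if (any(is.na(trials$cue))) stop("cue required for rule models",
                                     call. = FALSE)
    cue <- factor(trials$cue, levels = c("low", "neutral", "high"))
    B0 <- stats::model.matrix(~ cue - 1)
    colnames(B0) <- paste0("b0_", levels(cue))
    if (model == "bias") {
      X <- cbind(B0, b_snr = snr)
    } else {
      S <- B0 * snr
      colnames(S) <- paste0("b_snr_", levels(cue))
      X <- cbind(B0, S)
    }
  } else if (model == "base") {
    X <- cbind(b0 = 1, b_snr = snr)
  } else {
    pt <- pretest_contrasts(trials$pretest, n_back)
    if (model == "stim_bias") {
      X <- cbind(b0 = 1, b_snr = snr, pt)
    } else {
      pta <- pt * abs(snr)
      colnames(pta) <- sub("^b_pt", "b_pta", colnames(pt))
      X <- cbind(b0 = 1, b_snr = snr, pt, pta)
    }
  }
  X
}

# contrast codes (+0.5 H / -0.5 L / 0 absent) for the last n_back pre-test
# tones; position 1 = tone immediately before the test tone
pretest_contrasts <- function(pretest, n_back) {
  pretest[is.na(pretest)] <- ""
  out <- matrix(0, length(pretest), n_back,
                dimnames = list(NULL, paste0("b_pt", seq_len(n_back))))
  for (i in seq_along(pretest)) {
    tones <- rev(strsplit(pretest[i], "")[[1]])
    m <- min(length(tones), n_back)
    if (m > 0) out[i, seq_len(m)] <- ifelse(tones[seq_len(m)] == "H", 0.5, -0.5)
  }
  out
}

#' Predicted probability of a high-frequency choice
#'
#' @param fit A `psych_fit`.
#' @param trials Trial tibble matching the fit's condition.
#' @return Numeric vector of P(H).
#' @export
predict_choice_prob <- function(fit, trials) {
  stopifnot(inherits(fit, "psych_fit"))
  if (startsWith(fit$model, "stim") &&
      all(is.na(trials$pretest) | trials$pretest == "")) {
    stop("pre-test sequences required for stimulus-based fits",
         call. = FALSE)
  }
  X <- logistic_design(trials, fit$model, fit$n_back)
  f <- drop(X %*% fit$coef[colnames(X)])
  fit$lapse + (1 - 2 * fit$lapse) * stats::plogis(f)
}

#' @export
print.psych_fit <- function(x, ...) {
  cat("<psych_fit>", x$model, "| k =", x$n_params, " logL =",
      signif(x$loglik, 6), " AIC =", signif(x$aic, 6), "\n")
  invisible(x)
}

#' @rdname fit_logistic
#' @param x A `psych_fit`.
#' @param ... Unused.
#' @export
tidy.psych_fit <- function(x, ...) {
  tibble::tibble(term = c("lapse", names(x$coef)),
                 estimate = c(x$lapse, unname(x$coef)))
}

#' @rdname fit_logistic
#' @export
glance.psych_fit <- function(x, ...) {
  tibble::tibble(model = x$model, logLik = x$loglik, AIC = x$aic,
                 BIC = x$bic, n_params = x$n_params, n_trials = x$n_trials,
                 clamped = x$clamped)
}

#' Congruence of choice with the expectation cue
#'
#' Rule role: a low/high cue is congruent with the matching choice;
#' neutral-cue trials are labelled `"neutral"`. Stim role: trials whose
#' last two pre-test tones repeat (HH/LL) are congruent when the choice
#' matches that repeated frequency; other trials are `NA`.
#'
#' @param trials Trial tibble with choices.
#' @return Character vector: `"congruent"`, `"incongruent"`, `"neutral"`
#'   or `NA`.
#' @export
choice_congruence <- function(trials) {
  n <- nrow(trials)
  out <- rep(NA_character_, n)
  rule <- !is.na(trials$cue)
  out[rule & trials$cue == "neutral"] <- "neutral"
  cued <- rule & trials$cue %in% c("low", "high")
  match_cue <- (trials$cue == "high" & trials$choice == "H") |
    (trials$cue == "low" & trials$choice == "L")
  out[cued] <- ifelse(match_cue[cued], "congruent", "incongruent")
  if (any(!rule)) {
    last2 <- substr(trials$pretest, pmax(nchar(trials$pretest) - 1, 1),
                    nchar(trials$pretest))
    rep2 <- !rule & last2 %in% c("HH", "LL")
    match_pt <- substr(last2, 1, 1) == trials$choice
    out[rep2] <- ifelse(match_pt[rep2], "congruent", "incongruent")
  }
  out
}

#' Chronometric cell summary
#'
#' Median correct-trial RT per congruence x |SNR| cell: per-subject
#' medians first, then means across subjects. Empty cells are kept with
#' `NA` and flagged.
#'
#' @param trials Trial tibble with responses.
#' @return Tibble: `congruence`, `abs_snr`, `n_subjects`, `n_trials`,
#'   `median_rt_s` (across-subject mean of per-subject medians),
#'   `missing`.
#' @export
chronometric_summary <- function(trials) {
  trials <- filter_analyzable(trials)
  trials$congruence <- choice_congruence(trials)
  keep <- !is.na(trials$correct) & trials$correct & !is.na(trials$congruence)
  trials <- trials[keep, ]
  per_subj <- trials |>
    dplyr::mutate(abs_snr = abs(.data$snr_unit)) |>
    dplyr::group_by(.data$subject_id, .data$congruence, .data$abs_snr) |>
    dplyr::summarise(med = stats::median(.data$rt_s), n = dplyr::n(),
                     .groups = "drop")
  per_subj |>
    dplyr::group_by(.data$congruence, .data$abs_snr) |>
    dplyr::summarise(n_subjects = dplyr::n(), n_trials = sum(.data$n),
                     median_rt_s = mean(.data$med), .groups = "drop") |>
    tidyr::complete(.data$congruence,
                    abs_snr = abs(map_snr(snr_db_levels(), "H"))) |>
    dplyr::mutate(missing = is.na(.data$median_rt_s))
}

#' Coupling between starting-point and evidence-accumulation biases
#'
#' Spearman correlation between per-subject starting-point (`z`) and
#' evidence-accumulation (`v`) biases, per context, plus least-squares
#' slopes between the z-scored variables in both orientations.
#'
#' @param bias_tbl Tibble with columns `subject_id`, `z`, `v` and
#'   optionally `context`.
#' @return Tibble per context: `n`, `rho`, `p`, `slope_v_on_z`,
#'   `slope_z_on_v`, `degenerate` (constant input flagged).
#' @export
bias_coupling <- function(bias_tbl) {
  if (!"context" %in% names(bias_tbl)) bias_tbl$context <- "all"
  if (min(table(bias_tbl$context)) < 10) {
    stop("need at least 10 subjects per context", call. = FALSE)
  }
  bias_tbl |>
    dplyr::group_by(.data$context) |>
    dplyr::summarise(couple_one(.data$z, .data$v), .groups = "drop")
}

couple_one <- function(z, v) {
  degenerate <- stats::sd(z) == 0 || stats::sd(v) == 0
  if (degenerate) {
    return(tibble::tibble(n = length(z), rho = NA_real_, p = NA_real_,
                          slope_v_on_z = NA_real_, slope_z_on_v = NA_real_,
                          degenerate = TRUE))
  }
  ct <- suppressWarnings(stats::cor.test(z, v, method = "spearman"))
  zs <- as.numeric(scale(z))
  vs <- as.numeric(scale(v))
  tibble::tibble(
    n = length(z),
    rho = unname(ct$estimate),
    p = ct$p.value,
    slope_v_on_z = unname(stats::coef(stats::lm(vs ~ zs))[2]),
    slope_z_on_v = unname(stats::coef(stats::lm(zs ~ vs))[2]),
    degenerate = FALSE
  )
}

#' Rule-cue choice bias from a logistic fit
#'
#' The bias magnitude `b0_high - b0_low` used for brain-behavior
#' correlations.
#'
#' @param fit A `psych_fit` of the `bias` (or `bias_sensitivity`) model.
#' @return Scalar bias.
#' @export
choice_bias <- function(fit) {
  stopifnot(inherits(fit, "psych_fit"),
            all(c("b0_high", "b0_low") %in% names(fit$coef)))
  unname(fit$coef["b0_high"] - fit$coef["b0_low"])
}
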