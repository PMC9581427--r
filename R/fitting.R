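#' Model-variant lattice
#'
#' Free-parameter sets of the nested DDM variants fit per condition.
#' Rule-based variants: `base` (6 parameters), `collapsing` (7),
#' `starting_point_only` / `evidence_only` (9), `full_fixed_bound` (10),
#' `full` (11) and `drift_variability` (11, fixed bound with uniform
#' across-trial drift-gain variability). Stimulus-based variants: `base`
#' (6), `collapsing` (7), `bias_only` (11), `starting_point_only` /
#' `evidence_only` (13) and `full` (14). Mixed conditions use
#' `mixed_full` (both bias sets; 16 parameters for mixed-1, which has no
#' neutral cue, 18 for mixed-2).
#'
#' @param condition `"rule"`, `"stim"`, `"mixed1"` or `"mixed2"`.
#' @return Tibble with columns `variant`, `free_params` (list-column) and
#'   `n_params`.
#' @export
#' @examples
#' ddm_variants("stim")
ddm_variants <- function(condition = c("rule", "stim", "mixed1", "mixed2")) {
  condition <- match.arg(condition)
  base <- c("v_SNR", "B", "v_0", "z_0", "ndt_0", "lapse")
  sets <- switch(condition,
    rule = list(
      base = base,
      collapsing = c(base, "t_B"),
      starting_point_only = c(base, "t_B", "z_Low", "z_High"),
      evidence_only = c(base, "t_B", "v_Low", "v_High"),
      full_fixed_bound = c(base, "v_Low", "v_High", "z_Low", "z_High"),
      full = c(base, "t_B", "v_Low", "v_High", "z_Low", "z_High"),
      drift_variability = c(base, "v_Low", "v_High", "z_Low", "z_High",
                            "v_width")
    ),
    stim = {
      bias <- c(base, "t_B", "v_Bias", "z_Bias", "tau_Bias", "ndt_Bias")
      adapt <- c("va_Low", "va_High", "tau_va")
      list(
        base = base,
        collapsing = c(base, "t_B"),
        bias_only = bias,
        starting_point_only = c(setdiff(bias, "v_Bias"), adapt),
        evidence_only = c(setdiff(bias, "z_Bias"), adapt),
        full = c(bias, adapt)
      )
    },
    mixed1 = list(
      mixed_full = c("v_SNR", "B", "t_B", "ndt_0", "ndt_Bias", "lapse",
                     "v_Low", "v_High", "v_Bias", "tau_Bias",
                     "va_Low", "va_High", "tau_va",
                     "z_Low", "z_High", "z_Bias")
    ),
    mixed2 = list(
      mixed_full = c("v_SNR", "B", "t_B", "ndt_0", "ndt_Bias", "lapse",
                     "v_Low", "v_0", "v_High", "v_Bias", "tau_Bias",
                     "va_Low", "va_High", "tau_va",
                     "z_Low", "z_0", "z_High", "z_Bias")
    )
  )
  tibble::tibble(
    variant = names(sets),
    free_params = unname(sets),
    n_params = unname(vapply(sets, length, integer(1)))
  )
}

#' Parameter search boxes
#'
#' Lower/upper bounds used by the optimizer, generously covering the
#' plausible population range of each parameter.
#'
#' @return Named list of `c(lower, upper)` pairs.
#' @export
param_boxes <- function() {
  list(
    v_SNR = c(0, 20), B = c(0.3, 3), t_B = c(0, 3), ndt_0 = c(0, 1),
    ndt_Bias = c(-1, 1), lapse = c(0, 0.2),
    v_Low = c(-5, 5), v_0 = c(-5, 5), v_High = c(-5, 5), v_Bias = c(-5, 5),
    tau_Bias = c(0.2, 20), va_Low = c(-8, 8), va_High = c(-8, 8),
    tau_va = c(0.2, 20), z_Low = c(-5, 5), z_0 = c(-5, 5), z_High = c(-5, 5),
    z_Bias = c(-5, 5), v_width = c(0, 10)
  )
}

variant_free_params <- function(variant, condition) {
  v <- ddm_variants(condition)
  i <- match(variant, v$variant)
  if (is.na(i)) {
    stop("unknown variant '", variant, "' for condition ", condition,
         call. = FALSE)
  }
  v$free_params[[i]]
}

#' Build a full parameter set from a variant's free values
#'
#' @param theta Named numeric vector over the variant's free parameters.
#' @param variant,condition Variant name and condition.
#' @return A [ddm_params()] with non-free parameters absent.
#' @export
variant_params <- function(theta, variant, condition) {
  free <- variant_free_params(variant, condition)
  stopifnot(setequal(names(theta), free))
  do.call(ddm_params, as.list(theta[free]))
}

#' Differential-evolution global optimizer
#'
#' Minimal seedable rand/1/bin differential evolution over a box, with an
#' optional Nelder-Mead polish of the best member. Deterministic given
#' `seed`.
#'
#' @param fn Objective to minimize (takes a numeric vector).
#' @param lower,upper Box bounds.
#' @param control List: `np` (population; default `15 * d`), `F` (0.7),
#'   `CR` (0.9), `maxiter` (300), `tol` (1e-6, stop when the population
#'   cost spread falls below it), `polish` (TRUE), `polish_maxit` (100),
#'   `init` (optional matrix/vector of warm-start members placed into the
#'   initial population), `trace` (FALSE).
#' @param seed Integer seed.
#' @return List: `par`, `value`, `iterations`, `converged`.
#' @export
de_optim <- function(fn, lower, upper, control = list(), seed = 1) {
  d <- length(lower)
  ctl <- utils::modifyList(
    list(np = 15 * d, F = 0.7, CR = 0.9, maxiter = 300, tol = 1e-6,
         polish = TRUE, polish_maxit = 100, trace = FALSE),
    control
  )
  np <- max(ctl$np, 5)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)

  pop <- matrix(stats::runif(np * d, lower, upper), nrow = np, byrow = TRUE)
  if (!is.null(ctl$init)) {
    ini <- matrix(ctl$init, ncol = d, byrow = is.null(dim(ctl$init)))
    for (r in seq_len(min(nrow(ini), np))) {
      pop[r, ] <- pmin(pmax(ini[r, ], lower), upper)
    }
  }
  cost <- apply(pop, 1, fn)
  iter <- 0
  converged <- FALSE
  while (iter < ctl$maxiter) {
    iter <- iter + 1
    for (i in seq_len(np)) {
      r <- sample(setdiff(seq_len(np), i), 3)
      mutant <- pop[r[1], ] + ctl$F * (pop[r[2], ] - pop[r[3], ])
      cross <- stats::runif(d) < ctl$CR
      cross[sample.int(d, 1)] <- TRUE
      trial <- ifelse(cross, mutant, pop[i, ])
      trial <- pmin(pmax(trial, lower), upper)
      tc <- fn(trial)
      if (tc <= cost[i]) {
        pop[i, ] <- trial
        cost[i] <- tc
      }
    }
    if (max(cost) - min(cost) < ctl$tol) {
      converged <- TRUE
      break
    }
    if (ctl$trace) message("gen ", iter, " best ", signif(min(cost), 6))
  }
  best <- which.min(cost)
  par <- pop[best, ]
  value <- cost[best]
  if (isTRUE(ctl$polish)) {
    pol <- try(stats::optim(par, fn, method = "L-BFGS-B",
                            lower = lower, upper = upper,
                            control = list(maxit = ctl$polish_maxit)),
               silent = TRUE)
    if (!inherits(pol, "try-error") && pol$value < value) {
      par <- pmin(pmax(pol$par, lower), upper)
      value <- pol$value
    }
  }
  list(par = par, value = value, iterations = iter, converged = converged)
}

#' Fit one subject's data with a DDM variant
#'
#' Maximum-likelihood estimation on the full (choice, RT) distribution by
#' differential evolution within the [param_boxes()] search box, followed
#' by a local polish. Deterministic given `seed`.
#'
#' @param trials One subject's trial table (responses present).
#' @param variant Variant name (see [ddm_variants()]).
#' @param condition `"rule"`, `"stim"`, `"mixed1"` or `"mixed2"`.
#' @param optimizer_config Control list passed to [de_optim()], plus
#'   optional `solver_dt` / `solver_dx` (likelihood solver resolution,
#'   default 0.005) and `min_trials` (default 100).
#' @param seed Integer seed for the optimizer.
#' @return Object of class `ddm_fit`: estimates, log-likelihood, AIC/BIC
#'   (`aic = 2k - 2 logL`, `bic = k log n - 2 logL`) and optimizer
#'   metadata. Non-convergence is flagged, not an error.
#' @export
fit_subject <- function(trials, variant, condition,
                        optimizer_config = list(), seed = 1) {
  trials <- filter_analyzable(trials)
  min_trials <- optimizer_config$min_trials %||% 100
  if (nrow(trials) == 0) stop("no analyzable trials", call. = FALSE)
  if (nrow(trials) < min_trials) {
    stop("need at least ", min_trials, " analyzable trials", call. = FALSE)
  }
  sdt <- optimizer_config$solver_dt %||% 0.005
  sdx <- optimizer_config$solver_dx %||% 0.005
  role <- if (condition %in% c("mixed1", "mixed2")) "mixed" else condition
  free <- variant_free_params(variant, condition)
  box <- param_boxes()[free]
  lower <- vapply(box, `[`, numeric(1), 1)
  upper <- vapply(box, `[`, numeric(1), 2)

  pt_cache <- pretest_matrices(trials$pretest)
  nll <- function(theta) {
    names(theta) <- free
    p <- variant_params(theta, variant, condition)
    -ddm_loglik(p, trials, role, dt = sdt, dx = sdx, pt_cache = pt_cache)
  }
  ctl <- optimizer_config[!names(optimizer_config) %in%
                            c("solver_dt", "solver_dx", "min_trials")]
  res <- de_optim(nll, lower, upper, control = ctl, seed = seed)
  theta <- stats::setNames(res$par, free)
  k <- length(free)
  n <- nrow(trials)
  ll <- -res$value
  structure(list(
    subject_id = trials$subject_id[1],
    variant = variant,
    condition = condition,
    estimates = variant_params(theta, variant, condition),
    free = theta,
    loglik = ll,
    n_params = k,
    n_trials = n,
    aic = 2 * k - 2 * ll,
    bic = k * log(n) - 2 * ll,
    optimizer_meta = list(seed = seed, iterations = res$iterations,
                          converged = res$converged)
  ), class = "ddm_fit")
}

#' @export
print.ddm_fit <- function(x, ...) {
  cat("<ddm_fit> subject", x$subject_id, "| variant", x$variant,
      paste0("(", x$condition, ")"), "\n")
  cat("  logL =", signif(x$loglik, 6), " AIC =", signif(x$aic, 6),
      " BIC =", signif(x$bic, 6), " k =", x$n_params,
      " n =", x$n_trials, "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a DDM fit
#'
#' @param x A `ddm_fit`.
#' @param ... Unused.
#' @return One row per free parameter: `term`, `estimate`.
#' @export
tidy.ddm_fit <- function(x, ...) {
  tibble::tibble(term = names(x$free), estimate = unname(x$free))
}

#' @rdname tidy.ddm_fit
#' @export
glance.ddm_fit <- function(x, ...) {
  tibble::tibble(
    subject_id = x$subject_id, variant = x$variant, condition = x$condition,
    logLik = x$loglik, AIC = x$aic, BIC = x$bic,
    n_params = x$n_params, n_trials = x$n_trials,
    converged = x$optimizer_meta$converged
  )
}

#' Serialize a fit to JSON
#'
#' @param fit A `ddm_fit`.
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_ddm_fit <- function(fit, path) {
  jsonlite::write_json(unclass(fit)[c("subject_id", "variant", "condition",
                                      "free", "loglik", "n_params",
                                      "n_trials", "aic", "bic",
                                      "optimizer_meta")],
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Likelihood-ratio test between nested fits
#'
#' `chi2 = 2 (logL_full - logL_reduced)`, clipped at zero (small negative
#' log-likelihood ratios can arise from optimizer imprecision near the
#' global solution); degrees of freedom are the parameter-count
#' difference.
#'
#' @param full,reduced `ddm_fit` objects for the same subject and data,
#'   with `reduced`'s free parameters a strict subset of `full`'s.
#' @return Tibble: `chi2`, `df`, `p`.
#' @export
likelihood_ratio_test <- function(full, reduced) {
  f_free <- variant_free_params(full$variant, full$condition)
  r_free <- variant_free_params(reduced$variant, reduced$condition)
  if (!all(r_free %in% f_free) || length(r_free) >= length(f_free)) {
    stop("models are not strictly nested", call. = FALSE)
  }
  if (!identical(full$subject_id, reduced$subject_id)) {
    stop("fits are for different subjects", call. = FALSE)
  }
  chi2 <- max(0, 2 * (full$loglik - reduced$loglik))
  df <- full$n_params - reduced$n_params
  tibble::tibble(chi2 = chi2, df = df,
                 p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Classify a subject by which bias mechanisms the data require
#'
#' Runs likelihood-ratio tests of the full model against the
#' evidence-only model (tests the starting-point bias) and the
#' starting-point-only model (tests the evidence-accumulation bias).
#'
#' @param full,evidence_only,start_only `ddm_fit`s for one subject.
#' @param alpha Test level (default 0.05).
#' @return One of `"both_needed"`, `"evidence_needed"`, `"start_needed"`,
#'   `"neither"`.
#' @export
classify_subject <- function(full, evidence_only, start_only, alpha = 0.05) {
  start_needed <- likelihood_ratio_test(full, evidence_only)$p < alpha
  evid_needed <- likelihood_ratio_test(full, start_only)$p < alpha
  if (start_needed && evid_needed) "both_needed"
  else if (evid_needed) "evidence_needed"
  else if (start_needed) "start_needed"
  else "neither"
}

#' Fit a ladder of nested variants with warm starts
#'
#' Fits the given variants in order, warm-starting each richer variant's
#' population with the embeddings of every previously fitted nested
#' variant ([embed_in_variant()]). This keeps the high-dimensional fits
#' inside the basin found by the cheap low-dimensional ones and makes
#' every nesting inequality hold by construction.
#'
#' @param trials One subject's trial table.
#' @param condition Task condition.
#' @param variants Character vector of variant names, ordered so that
#'   each entry is preceded by the variants it should be seeded from
#'   (non-nested earlier entries are skipped as seeds).
#' @param optimizer_config As in [fit_subject()], applied to every rung.
#' @param seed Base seed; rung `i` uses `seed + i - 1`.
#' @return Named list of `ddm_fit` objects.
#' @export
fit_variant_ladder <- function(trials, condition,
                               variants = c("base", "collapsing", "full"),
                               optimizer_config = list(), seed = 1) {
  fits <- list()
  for (i in seq_along(variants)) {
    v <- variants[i]
    inits <- list()
    for (f in fits) {
      th <- try(embed_in_variant(f, v), silent = TRUE)
      if (!inherits(th, "try-error")) inits[[length(inits) + 1]] <- th
    }
    cfg <- optimizer_config
    if (length(inits) > 0) cfg$init <- do.call(rbind, inits)
    fits[[v]] <- fit_subject(trials, v, condition, cfg, seed = seed + i - 1)
  }
  fits
}

#' Embed a reduced fit into a richer variant's parameter space
#'
#' Returns a warm-start vector for the richer variant that reproduces the
#' reduced model exactly: shared parameters are copied; absent
#' cue-specific biases inherit the idiosyncratic `v_0` / `z_0`; all other
#' absent parameters take their neutral value (0; time constants take 1).
#' Passing the result as `optimizer_config$init` when fitting the richer
#' variant makes the nesting inequality hold by construction.
#'
#' @param fit A `ddm_fit` of the reduced variant.
#' @param variant Name of the richer variant.
#' @return Named numeric vector over the richer variant's free parameters.
#' @export
embed_in_variant <- function(fit, variant) {
  free <- variant_free_params(variant, fit$condition)
  if (!all(names(fit$free) %in% free)) {
    stop("fit's variant is not nested in '", variant, "'", call. = FALSE)
  }
  v0 <- fit$free["v_0"]
  z0 <- fit$free["z_0"]
  theta <- vapply(free, function(nm) {
    if (nm %in% names(fit$free)) return(unname(fit$free[nm]))
    if (nm %in% c("v_Low", "v_High") && !is.na(v0)) return(unname(v0))
    if (nm %in% c("z_Low", "z_High") && !is.na(z0)) return(unname(z0))
    if (nm %in% c("tau_Bias", "tau_va")) return(1)
    0
  }, numeric(1))
  stats::setNames(theta, free)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
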