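#' Construct a DDM parameter set
#'
#' Parameters of the generalized drift-diffusion model. The decision
#' variable evolves as `dx = v(t) dt + dW` (unit noise) between absorbing
#' bounds at `+/-(B - t_B t)`; the drift is
#' `v = v_SNR * SNR + bias_evidence + adapt * |SNR|`, the starting point is
#' `x0 = bias_start * 2B` with `bias_start` a logistic transform of the
#' starting-point bias, total non-decision time is
#' `ndt_0 + ndt_Bias * |pt_Bias|`, and a lapse mixture of weight `lapse`
#' adds a uniform (choice, RT) component. Parameters not supplied are
#' absent (`NA`) and act as their neutral value (0) when trials are
#' evaluated; cue-specific biases fall back to the idiosyncratic `v_0`,
#' `z_0` when absent.
#'
#' @param v_SNR Drift gain per unit signed SNR.
#' @param B Half the total bound separation (> 0).
#' @param t_B Linear bound collapse rate (per second, >= 0).
#' @param ndt_0 Baseline non-decision time (s).
#' @param ndt_Bias Non-decision time change per unit `|pt_Bias|` (s).
#' @param lapse Uniform lapse mixture weight in \[0, 0.5\].
#' @param v_Low,v_0,v_High Evidence-accumulation biases for low/neutral/high
#'   rule cues (`v_0` doubles as the idiosyncratic bias elsewhere).
#' @param v_Bias Gain of the recency-weighted tone sum on the drift
#'   (stimulus-based conditions).
#' @param tau_Bias Decay time constant of the tone-history bias, in tone
#'   positions (> 0).
#' @param va_Low,va_High Adaptation weights for low-/high-frequency
#'   pre-test tones (negative = repulsive).
#' @param tau_va Decay time constant of adaptation, in tone positions.
#' @param z_Low,z_0,z_High Starting-point biases (logit scale) for the
#'   rule cues.
#' @param z_Bias Gain of the tone-history sum on the starting point
#'   (logit scale).
#' @param v_width Width of the uniform across-trial drift-gain
#'   distribution (drift-variability variant only).
#' @param sigma Diffusion noise, fixed at 1.
#' @return An object of class `ddm_params` (named list).
#' @export
#' @examples
#' ddm_params(v_SNR = 6.51, B = 0.92, t_B = 0.92, ndt_0 = 0.27, lapse = 0.02)
ddm_params <- function(v_SNR = NA, B = NA, t_B = NA, ndt_0 = NA,
                       ndt_Bias = NA, lapse = NA, v_Low = NA, v_0 = NA,
                       v_High = NA, v_Bias = NA, tau_Bias = NA,
                       va_Low = NA, va_High = NA, tau_va = NA,
                       z_Low = NA, z_0 = NA, z_High = NA, z_Bias = NA,
                       v_width = NA, sigma = 1) {
  p <- list(v_SNR = v_SNR, B = B, t_B = t_B, ndt_0 = ndt_0,
            ndt_Bias = ndt_Bias, lapse = lapse, v_Low = v_Low, v_0 = v_0,
            v_High = v_High, v_Bias = v_Bias, tau_Bias = tau_Bias,
            va_Low = va_Low, va_High = va_High, tau_va = tau_va,
            z_Low = z_Low, z_0 = z_0, z_High = z_High, z_Bias = z_Bias,
            v_width = v_width, sigma = sigma)
  p <- lapply(p, as.numeric)
  if (!is.na(p$B) && p$B <= 0) stop("B must be > 0", call. = FALSE)
  if (!is.na(p$t_B) && p$t_B < 0) stop("t_B must be >= 0", call. = FALSE)
  if (!is.na(p$ndt_0) && p$ndt_0 < 0) stop("ndt_0 must be >= 0", call. = FALSE)
  if (!is.na(p$lapse) && (p$lapse < 0 || p$lapse > 0.5)) {
    stop("lapse must lie in [0, 0.5]", call. = FALSE)
  }
  for (tau in c("tau_Bias", "tau_va")) {
    if (!is.na(p[[tau]]) && p[[tau]] <= 0) {
      stop(tau, " must be > 0", call. = FALSE)
    }
  }
  if (p$sigma != 1) stop("sigma is fixed at 1", call. = FALSE)
  structure(p, class = "ddm_params")
}

ddm_param_names <- function() {
  c("v_SNR", "B", "t_B", "ndt_0", "ndt_Bias", "lapse", "v_Low", "v_0",
    "v_High", "v_Bias", "tau_Bias", "va_Low", "va_High", "tau_va",
    "z_Low", "z_0", "z_High", "z_Bias", "v_width")
}

#' Read / write DDM parameters as JSON
#'
#' JSON objects map parameter symbol names to reals; absent keys are
#' absent parameters.
#'
#' @param path File path.
#' @param params A [ddm_params()] object.
#' @return `read_ddm_params()` returns a `ddm_params`; `write_ddm_params()`
#'   returns `path` invisibly.
#' @export
read_ddm_params <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(ddm_params, vals[names(vals) %in% c(ddm_param_names(), "sigma")])
}

#' @rdname read_ddm_params
#' @export
write_ddm_params <- function(params, path) {
  keep <- params[!vapply(params, is.na, logical(1))]
  jsonlite::write_json(keep, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# value with NA treated as `default`
`%or%` <- function(x, default) {
  if (is.null(x) || length(x) == 0 || is.na(x)) default else x
}

#' Recency-weighted pre-test tone bias
#'
#' Exponentially weighted sum of the pre-test tones: each high-frequency
#' tone contributes `+exp(-p / tau_bias)` and each low-frequency tone
#' `-exp(-p / tau_bias)`, where `p` is the tone position in reverse
#' chronological order (`p = 0` for the tone immediately before the test
#' tone).
#'
#' @param pretest Character vector of tone sequences over `{L, H}`
#'   (chronological order; `""` allowed).
#' @param tau_bias Decay time constant in tone positions (> 0).
#' @return Numeric vector of biases.
#' @export
#' @examples
#' compute_pt_bias("LH", 1) # 1 - exp(-1)
compute_pt_bias <- function(pretest, tau_bias) {
  stopifnot(tau_bias > 0)
  pretest_weighted_sum(pretest, tau_bias, w_high = 1, w_low = 1)
}

#' SNR-dependent adaptation term
#'
#' Like [compute_pt_bias()] but with separate multiplicative weights for
#' high- and low-frequency tones:
#' `va_high * sum_high exp(-p/tau_va) - va_low * sum_low exp(-p/tau_va)`.
#' Multiplied by `|SNR|` in the drift, negative weights push choices away
#' from repeated tone frequencies.
#'
#' @param pretest Character vector of tone sequences (chronological).
#' @param va_high,va_low Adaptation weights.
#' @param tau_va Decay time constant in tone positions (> 0).
#' @return Numeric vector.
#' @export
compute_adapt <- function(pretest, va_high, va_low, tau_va) {
  stopifnot(tau_va > 0)
  pretest_weighted_sum(pretest, tau_va, w_high = va_high, w_low = va_low)
}

pretest_weighted_sum <- function(pretest, tau, w_high, w_low,
                                 cache = NULL) {
  if (is.null(cache)) cache <- pretest_matrices(pretest)
  wt <- exp(-(seq_len(ncol(cache$MH)) - 1) / tau)
  drop(w_high * (cache$MH %*% wt) - w_low * (cache$ML %*% wt))
}

# indicator matrices of tone identity by reverse-chronological position
# (column p+1 = position p, p = 0 for the tone just before the test tone)
pretest_matrices <- function(pretest) {
  pretest[is.na(pretest)] <- ""
  maxlen <- max(nchar(pretest), 1)
  MH <- ML <- matrix(0, length(pretest), maxlen)
  for (i in seq_along(pretest)) {
    n <- nchar(pretest[i])
    if (n == 0) next
    tones <- rev(strsplit(pretest[i], "")[[1]])
    MH[i, seq_len(n)] <- tones == "H"
    ML[i, seq_len(n)] <- tones == "L"
  }
  list(MH = MH, ML = ML)
}

#' Per-trial DDM drivers
#'
#' Maps a parameter set and a trial table onto the quantities that drive
#' each trial's diffusion: drift, starting fraction, bound geometry and
#' non-decision time. In the rule role the cue selects the
#' evidence-accumulation and starting-point biases; in the stim role the
#' tone-history sums act through `v_Bias`, `z_Bias` and the adaptation
#' weights; the mixed role applies both. Starting fractions are the
#' logistic transform of the (logit-scale) starting-point bias, clamped
#' to \[0.01, 0.99\].
#'
#' @param params A [ddm_params()].
#' @param trials Trial tibble (see [generate_session()]).
#' @param condition_role `"rule"`, `"stim"` or `"mixed"`; defaults from
#'   the table's `session_type`.
#' @return Tibble with one row per trial: `pt_bias`, `adapt`, `drift`,
#'   `start_frac`, `x0`, `bound_half`, `collapse`, `ndt`, `window`.
#' @export
trial_drivers <- function(params, trials, condition_role = NULL,
                          pt_cache = NULL) {
  if (is.null(condition_role)) {
    st <- unique(trials$session_type)
    condition_role <- switch(st[1], rule = "rule", stim = "stim", "mixed")
  }
  condition_role <- match.arg(condition_role, c("rule", "stim", "mixed"))
  n <- nrow(trials)

  uses_cue <- condition_role %in% c("rule", "mixed")
  uses_pt <- condition_role %in% c("stim", "mixed")
  if (uses_cue && any(is.na(trials$cue))) {
    stop("cue is required for the ", condition_role, " role", call. = FALSE)
  }
  if (condition_role == "stim" &&
      all(is.na(trials$pretest) | trials$pretest == "")) {
    stop("pre-test sequences are required for the stim role", call. = FALSE)
  }

  pt_bias <- adapt <- rep(0, n)
  if (uses_pt) {
    if (is.null(pt_cache)) pt_cache <- pretest_matrices(trials$pretest)
    tb <- params$tau_Bias %or% 1
    tv <- params$tau_va %or% 1
    pt_bias <- pretest_weighted_sum(trials$pretest, tb, 1, 1, pt_cache)
    adapt <- pretest_weighted_sum(trials$pretest, tv,
                                  params$va_High %or% 0,
                                  params$va_Low %or% 0, pt_cache)
  }

  v0 <- params$v_0 %or% 0
  z0 <- params$z_0 %or% 0
  if (uses_cue) {
    v_cue <- unname(c(low = params$v_Low %or% v0, neutral = v0,
                      high = params$v_High %or% v0)[trials$cue])
    z_cue <- unname(c(low = params$z_Low %or% z0, neutral = z0,
                      high = params$z_High %or% z0)[trials$cue])
  } else {
    v_cue <- rep(v0, n)
    z_cue <- rep(z0, n)
  }

  bias_evidence <- v_cue + if (uses_pt) (params$v_Bias %or% 0) * pt_bias else 0
  logit_start <- z_cue + if (uses_pt) (params$z_Bias %or% 0) * pt_bias else 0
  start_frac <- pmin(pmax(stats::plogis(logit_start), 0.01), 0.99)

  drift <- (params$v_SNR %or% 0) * trials$snr_unit + bias_evidence +
    adapt * abs(trials$snr_unit)
  ndt <- pmax((params$ndt_0 %or% 0) +
                (params$ndt_Bias %or% 0) * abs(pt_bias), 0)

  tibble::tibble(
    pt_bias = pt_bias, adapt = adapt, drift = drift,
    start_frac = start_frac, x0 = start_frac * 2 * (params$B %or% 1),
    bound_half = params$B %or% 1, collapse = params$t_B %or% 0,
    ndt = ndt, window = trials$response_window_s
  )
}

#' Solve the first-passage-time problem for one driver set
#'
#' Crank-Nicolson finite-difference solution of the forward equation for
#' a constant-drift diffusion (unit noise) between absorbing bounds that
#' collapse linearly at rate `collapse`, starting at fraction
#' `start_frac` of the total bound separation. Returns choice-conditional
#' decision-time defect densities on a uniform grid; if the bound reaches
#' zero before the window ends, all remaining mass is absorbed there and
#' the densities are truncated.
#'
#' @param drift Constant drift rate.
#' @param bound_half Half bound separation `B` (> 0).
#' @param collapse Linear collapse rate `t_B` (>= 0).
#' @param start_frac Starting point as a fraction of `2B`, in (0, 1).
#' @param window Time horizon (s).
#' @param dt,dx Solver steps (defaults 0.005 s / 0.005 evidence units).
#' @return Object of class `fpt_solution`: `time`, `dens_upper`,
#'   `dens_lower` (densities over decision time), `p_upper`, `p_lower`,
#'   `undecided`, `dt`.
#' @export
#' @examples
#' sol <- solve_fpt(drift = 1, bound_half = 0.5, collapse = 0,
#'                  start_frac = 0.5, window = 4)
#' sol$p_upper # ~ 1 / (1 + exp(-2 * 1 * 0.5))
solve_fpt <- function(drift, bound_half, collapse = 0, start_frac = 0.5,
                      window = 2, dt = 0.005, dx = 0.005) {
  stopifnot(dt > 0, dx > 0, bound_half > 0, collapse >= 0,
            start_frac > 0, start_frac < 1, window > 0)
  x0c <- (start_frac - 0.5) * 2 * bound_half
  sol <- fpt_solve_cpp(drift, bound_half, collapse, x0c, window, dt, dx)
  structure(sol, class = "fpt_solution")
}

solve_fpt_drivers <- function(d, dt = 0.005, dx = 0.005) {
  solve_fpt(d$drift, d$bound_half, d$collapse, d$start_frac, d$window,
            dt = dt, dx = dx)
}

# density of the decision-time distribution at times td (0 outside support)
fpt_density_at <- function(sol, td, side = c("upper", "lower")) {
  side <- match.arg(side)
  dens <- if (side == "upper") sol$dens_upper else sol$dens_lower
  mid <- sol$time - sol$dt / 2
  out <- stats::approx(mid, dens, xout = td, rule = 2)$y
  out[td <= 0 | td > max(sol$time)] <- 0
  out
}

#' Likelihood of observed (choice, RT) pairs
#'
#' Evaluates the generalized-DDM density of each trial's choice and RT:
#' the first-passage density at decision time `rt - ndt` (zero below the
#' non-decision floor), mixed with a uniform lapse component of weight
#' `lapse` over both choices and `(0, window]`. When `v_width` is present
#' the DDM component is averaged over a uniform distribution of drift
#' gains of that width (15-point Gauss-Legendre quadrature).
#'
#' @param params A [ddm_params()].
#' @param trials Trial tibble with `choice` in `{"L","H"}` and `rt_s` in
#'   `(0, response_window_s]`.
#' @param condition_role As in [trial_drivers()].
#' @param dt,dx Solver resolution.
#' @return Numeric vector of densities, one per trial.
#' @export
rt_likelihood <- function(params, trials, condition_role = NULL,
                          dt = 0.005, dx = 0.005, pt_cache = NULL) {
  if (any(is.na(trials$choice)) || any(!trials$choice %in% c("L", "H"))) {
    stop("choice must be 'L' or 'H' for likelihood evaluation", call. = FALSE)
  }
  if (any(is.na(trials$rt_s)) || any(trials$rt_s <= 0) ||
      any(trials$rt_s > trials$response_window_s)) {
    stop("rt must lie in (0, response_window]", call. = FALSE)
  }
  lambda <- params$lapse %or% 0
  win <- trials$response_window_s
  f_lapse <- 1 / (2 * win)
  if (lambda >= 1) return(rep(f_lapse, nrow(trials)))

  vw <- params$v_width %or% 0
  if (vw > 0) {
    gl <- gauss_legendre_15()
    offs <- gl$nodes * vw / 2        # deviations of v_SNR, uniform width vw
    f_ddm <- rep(0, nrow(trials))
    for (i in seq_along(offs)) {
      pi2 <- params
      pi2$v_SNR <- (params$v_SNR %or% 0) + offs[i]
      pi2$v_width <- NA
      f_ddm <- f_ddm + gl$weights[i] / 2 *
        ddm_component_density(pi2, trials, condition_role, dt, dx, pt_cache)
    }
  } else {
    f_ddm <- ddm_component_density(params, trials, condition_role, dt, dx,
                                   pt_cache)
  }
  (1 - lambda) * f_ddm + lambda * f_lapse
}

ddm_component_density <- function(params, trials, condition_role, dt, dx,
                                  pt_cache = NULL) {
  d <- trial_drivers(params, trials, condition_role, pt_cache)
  ord <- order(d$drift, d$start_frac, d$window)
  changed <- c(TRUE, diff(d$drift[ord]) != 0 | diff(d$start_frac[ord]) != 0 |
                 diff(d$window[ord]) != 0)
  grp <- cumsum(changed)
  x0c <- (d$start_frac - 0.5) * 2 * d$bound_half
  dens <- fpt_group_density_cpp(
    grp[ord], d$drift[ord], x0c[ord], d$bound_half[ord], d$collapse[ord],
    d$window[ord], (trials$rt_s - d$ndt)[ord],
    as.integer(trials$choice == "H")[ord], dt, dx
  )
  out <- numeric(nrow(trials))
  out[ord] <- dens
  out
}

# 15-point Gauss-Legendre nodes/weights on [-1, 1]
gauss_legendre_15 <- function() {
  j <- seq_len(14)
  b <- j / sqrt(4 * j^2 - 1)
  J <- diag(0, 15)
  J[cbind(j, j + 1)] <- b
  J[cbind(j + 1, j)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = 2 * e$vectors[1, ]^2)
}

#' Log-likelihood of a trial table under a parameter set
#'
#' Sum of per-trial log densities from [rt_likelihood()], with a floor of
#' `1e-10` per trial. Non-response trials are excluded via
#' [filter_analyzable()].
#'
#' @inheritParams rt_likelihood
#' @return Scalar log-likelihood.
#' @export
ddm_loglik <- function(params, trials, condition_role = NULL,
                       dt = 0.005, dx = 0.005, pt_cache = NULL) {
  trials <- filter_analyzable(trials)
  dens <- rt_likelihood(params, trials, condition_role, dt = dt, dx = dx,
                        pt_cache = pt_cache)
  sum(log(pmax(dens, 1e-10)))
}

#' Simulate trials from the generalized DDM
#'
#' Euler-Maruyama simulation of the decision variable until bound
#' crossing or window expiry; the reported RT is decision time plus
#' non-decision time. With probability `lapse` a trial's outcome is
#' replaced by a uniform lapse draw (either choice, RT uniform on the
#' window). Trials that neither cross nor lapse get `choice = "none"`.
#' Reproducible under `set.seed()`.
#'
#' @param params A [ddm_params()].
#' @param trials Trial table (stimuli; responses are overwritten).
#' @param condition_role As in [trial_drivers()].
#' @param dt_sim Euler step (default 1e-3 s).
#' @return The trial table with `choice`, `rt_s`, `correct` filled in.
#' @export
simulate_trials <- function(params, trials, condition_role = NULL,
                            dt_sim = 1e-3) {
  d <- trial_drivers(params, trials, condition_role)
  x0c <- (d$start_frac - 0.5) * 2 * d$bound_half
  sim <- ddm_sim_cpp(d$drift, x0c, d$bound_half, d$collapse, d$window, dt_sim)
  choice <- c("L", "none", "H")[sim$choice + 2]
  rt <- sim$t_s + d$ndt
  over <- !is.na(rt) & rt > d$window    # ndt pushed the RT past the deadline
  choice[over] <- "none"
  rt[choice == "none"] <- NA_real_

  lambda <- params$lapse %or% 0
  if (lambda > 0) {
    lapse <- stats::runif(nrow(trials)) < lambda
    choice[lapse] <- sample(c("L", "H"), sum(lapse), replace = TRUE)
    rt[lapse] <- stats::runif(sum(lapse), 0, d$window[lapse])
  }
  trials$choice <- choice
  trials$rt_s <- rt
  trials$correct <- ifelse(choice == "none", NA, choice == trials$tone)
  trials
}
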