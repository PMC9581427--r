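#' Population parameter anchors per condition
#'
#' Across-subject means and standard deviations of the generalized-DDM
#' parameters used as generative anchors by the cohort generator, one
#' column pair per task condition. Time constants are in tone positions;
#' times in seconds.
#'
#' @param condition `"rule"`, `"stim"`, `"mixed1"` or `"mixed2"`.
#' @return Tibble: `param`, `mean`, `sd`.
#' @export
population_param_table <- function(condition = c("rule", "stim",
                                                 "mixed1", "mixed2")) {
  condition <- match.arg(condition)
  tab <- switch(condition,
    rule = c(v_SNR = 6.51, 3.36, B = 0.92, 0.26, t_B = 0.92, 0.48,
             ndt_0 = 0.27, 0.08, lapse = 0.02, 0.01,
             v_Low = -0.83, 0.79, v_0 = 0.07, 0.41, v_High = 0.67, 0.71,
             z_Low = -0.20, 0.31, z_0 = 0.06, 0.22, z_High = 0.39, 0.31),
    stim = c(v_SNR = 4.97, 2.55, B = 1.02, 0.27, t_B = 0.80, 0.33,
             ndt_0 = 0.46, 0.07, ndt_Bias = -0.12, 0.29, lapse = 0.02, 0.02,
             v_0 = -0.20, 0.62, v_Bias = 0.84, 0.73, tau_Bias = 4.99, 4.89,
             va_Low = -2.31, 1.81, va_High = -1.40, 1.75, tau_va = 7.04, 6.25,
             z_0 = -0.03, 0.19, z_Bias = -0.09, 0.16),
    mixed1 = c(v_SNR = 4.40, 2.34, B = 1.06, 0.21, t_B = 1.01, 0.38,
               ndt_0 = 0.38, 0.05, ndt_Bias = -0.12, 0.32, lapse = 0.02, 0.01,
               v_Low = -1.60, 0.85, v_High = 1.59, 0.93, v_Bias = 0.83, 0.60,
               tau_Bias = 6.82, 5.24, va_Low = -2.05, 1.83,
               va_High = -1.53, 1.67, tau_va = 9.84, 5.45,
               z_Low = -0.12, 0.36, z_High = 0.13, 0.33, z_Bias = -0.11, 0.10),
    mixed2 = c(v_SNR = 5.46, 3.21, B = 0.93, 0.17, t_B = 0.87, 0.45,
               ndt_0 = 0.07, 0.07, ndt_Bias = -0.17, 0.29, lapse = 0.02, 0.01,
               v_Low = -1.36, 0.91, v_0 = -0.19, 0.61, v_High = 1.19, 1.04,
               v_Bias = 0.80, 0.49, tau_Bias = 7.80, 5.11,
               va_Low = -1.97, 1.37, va_High = -1.68, 1.22,
               tau_va = 8.74, 5.97, z_Low = 0.00, 0.30, z_0 = 0.02, 0.24,
               z_High = 0.03, 0.35, z_Bias = -0.03, 0.17)
  )
  m <- matrix(tab, ncol = 2, byrow = TRUE)
  tibble::tibble(param = names(tab)[seq(1, length(tab), 2)],
                 mean = m[, 1], sd = m[, 2])
}

#' Specify a synthetic cohort
#'
#' Bundles everything the generators need: the condition and its session
#' design, per-parameter population means/SDs, the target correlation
#' between the rule-based starting-point and evidence-accumulation bias
#' pairs, and the pupil-effect structure.
#'
#' @param condition Task condition.
#' @param n_subjects Cohort size.
#' @param param_table Tibble (`param`, `mean`, `sd`); defaults to
#'   [population_param_table()] for the condition.
#' @param coupling Target correlation between each rule cue's (z, v)
#'   bias pair (default -0.6; ignored when the condition has no rule
#'   biases).
#' @param n_trials Session-length override (default: the canonical
#'   design).
#' @param response_window_s Response window (s).
#' @param pupil_effect Extra choice-locked transient amplitude (z-units)
#'   on incongruent trials (rule condition).
#' @param pupil_latency_ms Window of the injected congruence effect,
#'   relative to choice.
#' @param blink_rate Blinks per second of recording.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(condition = "rule", n_subjects = 10,
                        param_table = NULL, coupling = -0.6,
                        n_trials = NULL, response_window_s = 2,
                        pupil_effect = 0.3,
                        pupil_latency_ms = c(200, 800),
                        blink_rate = 0.2) {
  if (is.null(param_table)) param_table <- population_param_table(condition)
  stopifnot(all(param_table$sd >= 0), coupling >= -1, coupling <= 1)
  structure(list(
    condition = condition, n_subjects = n_subjects,
    param_table = param_table, coupling = coupling,
    n_trials = n_trials, response_window_s = response_window_s,
    pupil_effect = pupil_effect, pupil_latency_ms = pupil_latency_ms,
    blink_rate = blink_rate
  ), class = "cohort_spec")
}

#' Draw one subject's generating parameters
#'
#' Independent Gaussian draws at the population (mean, SD), truncated to
#' the fitting search boxes by resampling (up to 1000 tries), except the
#' rule-based (z, v) bias pairs, which are drawn per cue from a bivariate
#' Gaussian with the spec's target correlation.
#'
#' @param spec A [cohort_spec()].
#' @return A [ddm_params()].
#' @export
sample_subject_params <- function(spec) {
  pt <- spec$param_table
  boxes <- param_boxes()
  draw1 <- function(m, s, box) {
    if (s == 0) return(min(max(m, box[1]), box[2]))
    for (i in seq_len(1000)) {
      x <- stats::rnorm(1, m, s)
      if (x >= box[1] && x <= box[2]) return(x)
    }
    min(max(m, box[1]), box[2])
  }
  vals <- stats::setNames(numeric(nrow(pt)), pt$param)
  coupled_pairs <- list(c("z_Low", "v_Low"), c("z_0", "v_0"),
                        c("z_High", "v_High"))
  coupled <- unlist(coupled_pairs[vapply(coupled_pairs, function(p) {
    all(p %in% pt$param)
  }, logical(1))])
  if (spec$condition %in% c("stim")) coupled <- character()

  for (i in seq_len(nrow(pt))) {
    if (pt$param[i] %in% coupled) next
    vals[pt$param[i]] <- draw1(pt$mean[i], pt$sd[i], boxes[[pt$param[i]]])
  }
  rho <- spec$coupling
  for (pair in coupled_pairs) {
    if (!all(pair %in% pt$param)) next
    mz <- pt$mean[pt$param == pair[1]]; sz <- pt$sd[pt$param == pair[1]]
    mv <- pt$mean[pt$param == pair[2]]; sv <- pt$sd[pt$param == pair[2]]
    for (i in seq_len(1000)) {
      e1 <- stats::rnorm(1); e2 <- stats::rnorm(1)
      z <- mz + sz * e1
      v <- mv + sv * (rho * e1 + sqrt(1 - rho^2) * e2)
      okz <- z >= boxes[[pair[1]]][1] && z <= boxes[[pair[1]]][2]
      okv <- v >= boxes[[pair[2]]][1] && v <= boxes[[pair[2]]][2]
      if ((okz && okv) || (sz == 0 && sv == 0)) break
    }
    vals[pair[1]] <- if (sz == 0) mz else z
    vals[pair[2]] <- if (sv == 0) mv else v
  }
  do.call(ddm_params, as.list(vals))
}

#' Generate a full synthetic behavioral cohort
#'
#' Samples each subject's generating parameters, builds that subject's
#' session stimuli, and simulates choices and RTs from the generalized
#' DDM. Window-expiry trials are re-simulated up to 5 times before being
#' recorded as `choice = "none"`. Reproducible under `set.seed()`.
#'
#' @param spec A [cohort_spec()].
#' @param dt_sim Euler step for the simulator (s).
#' @return Object of class `cohort`: `trials` (all subjects bound),
#'   `params` (named list of `ddm_params`), `truth` (tidy tibble of
#'   generating values), `spec`.
#' @export
generate_behavior <- function(spec, dt_sim = 1e-3) {
  role <- switch(spec$condition, rule = "rule", stim = "stim", "mixed")
  all_trials <- vector("list", spec$n_subjects)
  params <- vector("list", spec$n_subjects)
  ids <- sprintf("s%02d", seq_len(spec$n_subjects))
  for (s in seq_len(spec$n_subjects)) {
    p <- sample_subject_params(spec)
    design <- session_design(spec$condition,
                             response_window_s = spec$response_window_s,
                             n_trials = spec$n_trials)
    tr <- generate_session(design, subject_id = ids[s])
    tr <- simulate_trials(p, tr, role, dt_sim = dt_sim)
    for (try in seq_len(5)) {
      none <- which(tr$choice == "none")
      if (length(none) == 0) break
      tr[none, ] <- simulate_trials(p, tr[none, ], role, dt_sim = dt_sim)
    }
    params[[s]] <- p
    all_trials[[s]] <- tr
  }
  names(params) <- ids
  truth <- purrr::map_dfr(ids, function(id) {
    v <- unlist(params[[id]][ddm_param_names()])
    tibble::tibble(subject_id = id, param = names(v), value = unname(v))
  }) |> dplyr::filter(!is.na(.data$value))
  structure(list(trials = dplyr::bind_rows(all_trials), params = params,
                 truth = truth, spec = spec), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort>", x$spec$condition, "condition,", x$spec$n_subjects,
      "subjects,", nrow(x$trials), "trials\n")
  invisible(x)
}

#' Generate synthetic pupil recordings for a cohort
#'
#' Emulates the effect structure the pupil pipeline is designed to
#' detect: a slow baseline drift, Gaussian sensor noise, Poisson blinks
#' (missing spans), gaze jitter, and a choice-locked gamma-shaped
#' transient (shape 2, scale 300 ms) whose amplitude is increased by
#' `pupil_effect` (z-units) on choice-incongruent trials of rule-type
#' conditions. Traces are laid out at 1 kHz, one trial after another.
#'
#' @param cohort A [generate_behavior()] cohort (or its `trials` tibble).
#' @param spec The [cohort_spec()]; defaults to the cohort's.
#' @param pre_ms,post_ms Recording time allotted before tone onset and
#'   after the response window per trial.
#' @return Named list (one element per subject): `rec` (recording tibble
#'   for [clean_trace()]), `events`, `labels` (per-trial congruence and
#'   covariate columns).
#' @export
generate_pupil <- function(cohort, spec = NULL, pre_ms = 500,
                           post_ms = 1700) {
  trials <- if (inherits(cohort, "cohort")) cohort$trials else cohort
  if (is.null(spec)) spec <- cohort$spec
  out <- list()
  for (id in unique(trials$subject_id)) {
    tr <- trials[trials$subject_id == id, ]
    tr$congruence <- choice_congruence(tr)
    trial_len <- pre_ms + round(max(tr$response_window_s) * 1000) + post_ms
    n_ms <- nrow(tr) * trial_len
    t_ms <- seq_len(n_ms) - 1

    # slow arousal drift (AR(1) with ~10 s correlation time) plus a small
    # fast sensor-noise component; both stay below the cleaning pipeline's
    # velocity threshold so only injected blinks trigger interpolation
    drift <- as.numeric(stats::filter(stats::rnorm(n_ms, 0, 0.006), 0.9999,
                                      method = "recursive"))
    pupil <- drift + stats::rnorm(n_ms, 0, 0.004)

    onset_ms <- (seq_len(nrow(tr)) - 1) * trial_len + pre_ms
    rt_ms <- ifelse(is.na(tr$rt_s), NA, round(tr$rt_s * 1000))
    choice_ms <- onset_ms + rt_ms

    kern_t <- 0:3999
    kern <- (kern_t / 300) * exp(1 - kern_t / 300)  # gamma shape 2, peak 1
    incong <- !is.na(tr$congruence) & tr$congruence == "incongruent" &
      spec$condition %in% c("rule", "mixed1", "mixed2")
    for (i in seq_len(nrow(tr))) {
      if (is.na(choice_ms[i])) next
      amp <- 0.8 + spec$pupil_effect * incong[i]
      j0 <- choice_ms[i] + 1
      j1 <- min(j0 + length(kern) - 1, n_ms)
      pupil[j0:j1] <- pupil[j0:j1] + amp * kern[seq_len(j1 - j0 + 1)]
    }

    missing <- rep(FALSE, n_ms)
    n_blinks <- stats::rpois(1, spec$blink_rate * n_ms / 1000)
    if (n_blinks > 0) {
      starts <- sample.int(n_ms - 300, n_blinks)
      for (b in starts) {
        len <- sample(80:200, 1)
        missing[b:(b + len)] <- TRUE
      }
    }
    diam <- 3000 + 400 * pupil
    diam[missing] <- 0

    gx <- as.numeric(stats::filter(stats::rnorm(n_ms, 0, 0.01), 0.995,
                                   method = "recursive"))
    gy <- as.numeric(stats::filter(stats::rnorm(n_ms, 0, 0.01), 0.995,
                                   method = "recursive"))

    out[[id]] <- list(
      rec = tibble::tibble(t_ms = t_ms, diameter = diam, gaze_x = gx,
                           gaze_y = gy, missing = missing,
                           block_id = tr$block[ceiling((t_ms + 1) / trial_len)]),
      events = tibble::tibble(trial_index = tr$trial_index,
                              tone_onset_ms = onset_ms,
                              choice_ms = choice_ms),
      labels = tibble::tibble(
        trial_index = tr$trial_index,
        congruence = tr$congruence,
        congruent_code = dplyr::case_when(
          tr$congruence == "incongruent" ~ 0.5,
          tr$congruence == "congruent" ~ -0.5,
          TRUE ~ NA_real_
        ),
        tone_high = ifelse(tr$tone == "H", 0.5, -0.5),
        abs_snr = abs(tr$snr_unit),
        correct = tr$correct
      )
    )
  }
  out
}

#' Assemble the long epoch table for contrast regression
#'
#' Joins one subject's 50 Hz epochs with per-trial labels/covariates and
#' the trial baseline, ready for [timecourse_contrasts()].
#'
#' @param epoched An [epoch_and_exclude()] result.
#' @param labels Per-trial tibble keyed by `trial_index`.
#' @param subject_id Subject identifier column value.
#' @return Long tibble.
#' @export
epoch_table <- function(epoched, labels, subject_id) {
  epoched$epochs |>
    dplyr::inner_join(labels, by = "trial_index") |>
    dplyr::inner_join(epoched$baseline, by = "trial_index") |>
    dplyr::mutate(subject_id = subject_id)
}
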