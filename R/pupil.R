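#' Clean a continuous pupil recording
#'
#' Blink/missing spans are expanded by 100 ms on each side; additional
#' artifacts are found as samples whose sample-to-sample velocity exceeds
#' `velocity_threshold` (a.u./ms), with runs longer than
#' `long_artifact_ms` also expanded by 100 ms. All flagged spans are
#' linearly interpolated (pupil and gaze alike), and the pupil trace is
#' then low-pass filtered (3rd-order Butterworth, zero phase) at
#' `lp_cutoff_hz`. Gaps touching a recording edge are extended with the
#' nearest value and flagged.
#'
#' @param rec Tibble sampled at 1 kHz with columns `t_ms`, `diameter`,
#'   `gaze_x`, `gaze_y`, `missing` (logical) and optionally `block_id`.
#' @param velocity_threshold a.u. per ms (default 24).
#' @param expand_ms Expansion around blinks/long artifacts (default 100).
#' @param long_artifact_ms Velocity-run duration above which the run is
#'   expanded (default 16).
#' @param lp_cutoff_hz Low-pass cutoff (default 8).
#' @param fs Sampling rate in Hz (default 1000).
#' @return The recording tibble with `diameter` (filtered),
#'   `diameter_prefilter` (interpolated, unfiltered), gaze columns
#'   interpolated, and a logical `interpolated` column; attribute
#'   `edge_flag` marks gaps at the recording edges.
#' @export
clean_trace <- function(rec, velocity_threshold = 24, expand_ms = 100,
                        long_artifact_ms = 16, lp_cutoff_hz = 8, fs = 1000) {
  stopifnot(all(c("t_ms", "diameter", "gaze_x", "gaze_y", "missing") %in%
                  names(rec)))
  n <- nrow(rec)
  mask <- rec$missing | is.na(rec$diameter)
  mask <- expand_runs(mask, expand_ms)

  vel <- c(0, diff(rec$diameter))
  vel[is.na(vel)] <- 0
  fast <- abs(vel) > velocity_threshold
  runs <- run_spans(fast)
  for (k in seq_len(nrow(runs))) {
    lo <- runs$start[k]
    hi <- runs$end[k]
    if (hi - lo + 1 > long_artifact_ms) {
      lo <- max(1, lo - expand_ms)
      hi <- min(n, hi + expand_ms)
    }
    mask[lo:hi] <- TRUE
  }

  edge_flag <- (length(mask) > 0) && (mask[1] || mask[n])
  interp <- function(x) {
    if (!any(mask)) return(x)
    if (all(mask)) return(rep(mean(x, na.rm = TRUE), n))
    stats::approx(rec$t_ms[!mask], x[!mask], xout = rec$t_ms, rule = 2)$y
  }
  d_int <- interp(rec$diameter)
  out <- rec
  out$gaze_x <- interp(rec$gaze_x)
  out$gaze_y <- interp(rec$gaze_y)
  out$diameter_prefilter <- d_int

  bf <- signal::butter(3, lp_cutoff_hz / (fs / 2), type = "low")
  out$diameter <- filtfilt_padded(bf, d_int)
  out$interpolated <- mask
  attr(out, "edge_flag") <- edge_flag
  out
}

# zero-phase filtering with odd-reflection padding and demeaning, so the
# filter's zero initial conditions do not leak transients into the trace
filtfilt_padded <- function(bf, x) {
  n <- length(x)
  p <- min(n - 1, 1000)
  mu <- mean(x)
  xc <- x - mu
  xp <- c(2 * xc[1] - rev(xc[2:(p + 1)]), xc,
          2 * xc[n] - rev(xc[(n - p):(n - 1)]))
  y <- as.numeric(signal::filtfilt(bf, xp))
  y[(p + 1):(p + n)] + mu
}

expand_runs <- function(mask, by) {
  runs <- run_spans(mask)
  n <- length(mask)
  for (k in seq_len(nrow(runs))) {
    mask[max(1, runs$start[k] - by):min(n, runs$end[k] + by)] <- TRUE
  }
  mask
}

run_spans <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Epoch a cleaned recording and apply exclusion rules
#'
#' Z-scores the filtered pupil trace within block, extracts choice-locked
#' epochs, subtracts each trial's baseline (mean over 0-40 ms after
#' test-tone onset), and applies the exclusion rules: a trial is dropped
#' if more than half of its samples were interpolated (`missing_data`),
#' the whole session if more than 60% of all samples were interpolated
#' (`session`), and a trial whose baseline-centered gaze leaves the
#' session's 95% fixation circle for more than 15 consecutive ms
#' (`gaze`). Each excluded trial carries one primary reason (session >
#' missing_data > gaze). A 50 Hz downsampled copy (20-ms bin means) is
#' produced. A subject with fewer than `min_trials` surviving trials is
#' flagged excluded.
#'
#' @param cleaned Output of [clean_trace()].
#' @param events Tibble: `trial_index`, `tone_onset_ms`, `choice_ms`
#'   (NA choice = no epoch).
#' @param window_ms Epoch window relative to choice (default -500..1500).
#' @param fixation_quantile Quantile of baseline-centered gaze radii that
#'   defines the fixation circle (default 0.95).
#' @param max_gaze_out_ms Longest tolerated continuous gaze excursion
#'   (default 15 ms; longer excludes the trial).
#' @param min_trials Minimum surviving trials per subject (default 75).
#' @return Object of class `epoched_pupil`: `epochs` (long tibble
#'   `trial_index`, `bin_ms`, `pupil` at 50 Hz), `epochs_1k` (1 kHz),
#'   `excluded` (tibble `trial_index`, `reason`), `baseline` per trial,
#'   `subject_excluded`, `fixation_radius`.
#' @export
epoch_and_exclude <- function(cleaned, events, window_ms = c(-500, 1500),
                              fixation_quantile = 0.95,
                              max_gaze_out_ms = 15, min_trials = 75) {
  miss_ev <- is.na(events$tone_onset_ms)
  if (any(miss_ev)) {
    stop("missing tone onsets for trials: ",
         paste(events$trial_index[miss_ev], collapse = ", "), call. = FALSE)
  }
  block <- if ("block_id" %in% names(cleaned)) cleaned$block_id else 1L
  z <- stats::ave(cleaned$diameter, block, FUN = function(x) {
    s <- stats::sd(x)
    # constant blocks (up to filter round-off) are zeroed, not divided
    if (s <= 1e-8 * max(1, abs(mean(x)))) rep(0, length(x)) else
      (x - mean(x)) / s
  })
  t0 <- cleaned$t_ms[1]
  idx_of <- function(tm) round(tm - t0) + 1L

  session_bad <- mean(cleaned$interpolated) > 0.60
  n_samp <- nrow(cleaned)

  # baseline-centered gaze radii pooled over trials -> fixation circle
  centered <- list()
  for (i in seq_len(nrow(events))) {
    b0 <- idx_of(events$tone_onset_ms[i])
    bidx <- b0:min(b0 + 39, n_samp)
    span <- trial_span(events[i, ], window_ms, idx_of, n_samp)
    if (is.null(span)) next
    cx <- mean(cleaned$gaze_x[bidx])
    cy <- mean(cleaned$gaze_y[bidx])
    centered[[length(centered) + 1]] <-
      sqrt((cleaned$gaze_x[span] - cx)^2 + (cleaned$gaze_y[span] - cy)^2)
  }
  fix_r <- if (length(centered)) {
    stats::quantile(unlist(centered), fixation_quantile, names = FALSE)
  } else NA_real_

  epochs <- list()
  excl <- list()
  baselines <- list()
  times <- seq(window_ms[1], window_ms[2] - 1)
  for (i in seq_len(nrow(events))) {
    tr <- events$trial_index[i]
    span <- trial_span(events[i, ], window_ms, idx_of, n_samp)
    if (is.null(span)) {
      excl[[length(excl) + 1]] <- c(tr, "no_response")
      next
    }
    if (session_bad) {
      excl[[length(excl) + 1]] <- c(tr, "session")
      next
    }
    b0 <- idx_of(events$tone_onset_ms[i])
    bidx <- b0:min(b0 + 39, n_samp)
    full <- min(b0, span[1]):max(span)
    if (mean(cleaned$interpolated[full]) > 0.50) {
      excl[[length(excl) + 1]] <- c(tr, "missing_data")
      next
    }
    cx <- mean(cleaned$gaze_x[bidx])
    cy <- mean(cleaned$gaze_y[bidx])
    r <- sqrt((cleaned$gaze_x[span] - cx)^2 + (cleaned$gaze_y[span] - cy)^2)
    out_runs <- run_spans(r > fix_r)
    if (nrow(out_runs) > 0 &&
        max(out_runs$end - out_runs$start + 1) > max_gaze_out_ms) {
      excl[[length(excl) + 1]] <- c(tr, "gaze")
      next
    }
    base <- mean(z[bidx])
    trace <- z[span] - base
    baselines[[length(baselines) + 1]] <- c(tr, base)
    epochs[[length(epochs) + 1]] <- tibble::tibble(
      trial_index = tr, t_ms = times[seq_along(trace)], pupil = trace,
      gaze_x = cleaned$gaze_x[span] - cx, gaze_y = cleaned$gaze_y[span] - cy
    )
  }

  ep1k <- if (length(epochs)) dplyr::bind_rows(epochs) else
    tibble::tibble(trial_index = integer(), t_ms = numeric(),
                   pupil = numeric(), gaze_x = numeric(), gaze_y = numeric())
  ep50 <- ep1k |>
    dplyr::mutate(bin_ms = floor(.data$t_ms / 20) * 20) |>
    dplyr::group_by(.data$trial_index, .data$bin_ms) |>
    dplyr::summarise(pupil = mean(.data$pupil),
                     gaze_x = mean(.data$gaze_x),
                     gaze_y = mean(.data$gaze_y), .groups = "drop")
  excl_tbl <- if (length(excl)) {
    m <- do.call(rbind, excl)
    tibble::tibble(trial_index = as.integer(m[, 1]), reason = m[, 2])
  } else tibble::tibble(trial_index = integer(), reason = character())
  base_tbl <- if (length(baselines)) {
    m <- do.call(rbind, baselines)
    tibble::tibble(trial_index = as.integer(m[, 1]), baseline = m[, 2])
  } else tibble::tibble(trial_index = integer(), baseline = numeric())

  n_keep <- length(unique(ep1k$trial_index))
  structure(list(
    epochs = ep50, epochs_1k = ep1k, excluded = excl_tbl,
    baseline = base_tbl, subject_excluded = n_keep < min_trials,
    n_trials = n_keep, fixation_radius = fix_r
  ), class = "epoched_pupil")
}

trial_span <- function(ev, window_ms, idx_of, n_samp) {
  if (is.na(ev$choice_ms)) return(NULL)
  c0 <- idx_of(ev$choice_ms + window_ms[1])
  c1 <- idx_of(ev$choice_ms + window_ms[2]) - 1L
  if (c0 < 1 || c1 > n_samp) return(NULL)
  c0:c1
}

#' @export
print.epoched_pupil <- function(x, ...) {
  cat("<epoched_pupil>", x$n_trials, "trials kept,",
      nrow(x$excluded), "excluded",
      if (x$subject_excluded) "(subject excluded)" else "", "\n")
  invisible(x)
}

#' Per-bin two-stage contrast regression of pupil time courses
#'
#' Stage 1 fits, per subject and 20-ms bin, an ordinary least-squares
#' model of the pupil value on the contrast codes plus nuisance
#' covariates; stage 2 runs a one-sample t-test on the per-subject
#' contrast coefficients at each bin. P-values are Benjamini-Hochberg
#' adjusted jointly across bins and contrasts. Collinear covariates are
#' dropped (flagged in the `dropped` attribute).
#'
#' @param epoch_tbl Long tibble: `subject_id`, `trial_index`, `bin_ms`,
#'   `pupil`, plus the contrast and covariate columns (numeric,
#'   trial-level).
#' @param contrasts Character vector of contrast column names.
#' @param covariates Character vector of covariate column names.
#' @return Tibble: `bin_ms`, `contrast`, `beta` (across-subject mean),
#'   `se`, `t`, `p`, `p_fdr`, `n_subjects`.
#' @export
timecourse_contrasts <- function(epoch_tbl, contrasts,
                                 covariates = character()) {
  stopifnot(length(contrasts) >= 1)
  subj_betas <- subject_bin_betas(epoch_tbl, contrasts, covariates)
  res <- subj_betas |>
    dplyr::group_by(.data$bin_ms, .data$contrast) |>
    dplyr::summarise(
      n_subjects = sum(!is.na(.data$beta)),
      se = stats::sd(.data$beta, na.rm = TRUE) / sqrt(.data$n_subjects),
      t = mean(.data$beta, na.rm = TRUE) / .data$se,
      p = 2 * stats::pt(-abs(.data$t), .data$n_subjects - 1),
      beta = mean(.data$beta, na.rm = TRUE),
      .groups = "drop"
    )
  res$p_fdr <- stats::p.adjust(res$p, method = "BH")
  res[c("bin_ms", "contrast", "beta", "se", "t", "p", "p_fdr", "n_subjects")]
}

#' Per-subject, per-bin contrast coefficients
#'
#' The stage-1 estimates of [timecourse_contrasts()], exposed for
#' brain-behavior correlation.
#'
#' @inheritParams timecourse_contrasts
#' @return Tibble: `subject_id`, `bin_ms`, `contrast`, `beta`.
#' @export
subject_bin_betas <- function(epoch_tbl, contrasts,
                              covariates = character()) {
  vars <- c(contrasts, covariates)
  stopifnot(all(c("subject_id", "bin_ms", "pupil", vars) %in%
                  names(epoch_tbl)))
  X_all <- as.matrix(epoch_tbl[vars])
  y_all <- epoch_tbl$pupil
  keys <- paste(epoch_tbl$subject_id, epoch_tbl$bin_ms, sep = "\r")
  idx <- split(seq_along(keys), keys)
  rows <- lapply(idx, function(ii) {
    X <- X_all[ii, , drop = FALSE]
    keep <- vars[apply(X, 2, stats::sd) > 0]
    beta <- rep(NA_real_, length(contrasts))
    if (length(keep) > 0) {
      fit <- stats::lm.fit(cbind(1, X[, keep, drop = FALSE]), y_all[ii])
      cf <- stats::setNames(fit$coefficients, c("(Intercept)", keep))
      beta <- unname(cf[contrasts])
    }
    beta
  })
  first <- vapply(idx, `[`, integer(1), 1)
  tibble::tibble(
    subject_id = rep(epoch_tbl$subject_id[first], each = length(contrasts)),
    bin_ms = rep(epoch_tbl$bin_ms[first], each = length(contrasts)),
    contrast = rep(contrasts, times = length(idx)),
    beta = unlist(rows, use.names = FALSE)
  ) |>
    dplyr::arrange(.data$subject_id, .data$bin_ms)
}

#' Correlate behavioral bias with pupil contrasts across subjects
#'
#' Spearman correlation, per 20-ms bin (and contrast), between a
#' per-subject behavioral bias and the per-subject pupil contrast
#' coefficient, with Benjamini-Hochberg adjustment across bins and
#' contrasts.
#'
#' @param bias_tbl Tibble: `subject_id`, `bias`.
#' @param beta_tbl Output of [subject_bin_betas()].
#' @return Tibble: `bin_ms`, `contrast`, `rho`, `p`, `p_fdr`, `n`.
#' @export
bias_pupil_correlation <- function(bias_tbl, beta_tbl) {
  joined <- dplyr::inner_join(beta_tbl, bias_tbl, by = "subject_id")
  if (length(unique(joined$subject_id)) < 10) {
    stop("need at least 10 matched subjects", call. = FALSE)
  }
  res <- joined |>
    dplyr::filter(!is.na(.data$beta)) |>
    dplyr::group_by(.data$bin_ms, .data$contrast) |>
    dplyr::summarise(
      n = dplyr::n(),
      rho = suppressWarnings(stats::cor(.data$bias, .data$beta,
                                        method = "spearman")),
      p = suppressWarnings(stats::cor.test(.data$bias, .data$beta,
                                           method = "spearman")$p.value),
      .groups = "drop"
    )
  res$p_fdr <- stats::p.adjust(res$p, method = "BH")
  res
}
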