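#' DDM-predicted accuracy over bias combinations
#'
#' For each grid combination of a starting-point bias `z` and an
#' evidence-accumulation bias `v`, substitutes the pair into the
#' context's bias slots, computes the predicted proportion of correct
#' choices for every tone x |SNR| trial type via [solve_fpt()], and
#' averages with the trial-type proportions expected in that context
#' (rule contexts weight tone identity by the cue's `p_high`; stim
#' contexts are non-predictive, `p_high = 1/2`, with the pre-test pattern
#' fixed at the context). Lapse trials count as 50% correct; undecided
#' mass counts as incorrect. Accuracy is then normalized to proportion of
#' the grid maximum.
#'
#' Grid scales: `z_grid` values are realized starting fractions for rule
#' contexts (injected as `qlogis(z)` on the logit scale the model is fit
#' on); for stim contexts `z_grid` values set `z_Bias` directly (default
#' symmetric around 0). `v_grid` values set `v_Low`/`v_High` (rule) or
#' `v_Bias` (stim) directly.
#'
#' @param params A [ddm_params()] holding the subject's non-bias
#'   parameters (and, for stim contexts, the fitted adaptation weights,
#'   which are held fixed).
#' @param context `"low"` or `"high"` prior cue, or `"LL"` / `"HH"`
#'   pre-test pattern.
#' @param z_grid,v_grid Strictly increasing grid values (defaults: 17
#'   points over (0.1, 0.9) / (-0.9, 0.9) / \[-4, 4\]).
#' @param window Response window used in prediction (s).
#' @param dt,dx Solver resolution.
#' @return Object of class `performance_grid`: `z_grid`, `v_grid`,
#'   `accuracy` and `norm_accuracy` matrices (z by v), `context`,
#'   `subject_params`.
#' @export
performance_grid <- function(params, context = c("low", "high", "LL", "HH"),
                             z_grid = NULL, v_grid = NULL, window = 2,
                             dt = 0.005, dx = 0.005) {
  context <- match.arg(context)
  rule_ctx <- context %in% c("low", "high")
  if (is.null(z_grid)) {
    z_grid <- if (rule_ctx) seq(0.1, 0.9, length.out = 17) else
      seq(-0.9, 0.9, length.out = 17)
  }
  if (is.null(v_grid)) v_grid <- seq(-4, 4, length.out = 17)
  stopifnot(all(diff(z_grid) > 0), all(diff(v_grid) > 0))
  if (rule_ctx && (min(z_grid) < 0.1 - 1e-9 || max(z_grid) > 0.9 + 1e-9)) {
    warning("z_grid extends beyond the (0.1, 0.9) starting-fraction range")
  }
  if (min(v_grid) < -4 - 1e-9 || max(v_grid) > 4 + 1e-9) {
    warning("v_grid extends beyond [-4, 4]")
  }

  types <- tidyr::expand_grid(tone = c("L", "H"), snr_db = snr_db_levels())
  types$snr_unit <- map_snr(types$snr_db, types$tone)
  if (rule_ctx) {
    p_high <- cue_conditions()$p_high[match(context, cue_conditions()$cue)]
    types$pretest <- ""
  } else {
    p_high <- 0.5
    types$pretest <- context
  }
  types$weight <- ifelse(types$tone == "H", p_high, 1 - p_high) /
    length(snr_db_levels())
  trials <- tibble::tibble(
    subject_id = "grid", session_type = if (rule_ctx) "rule" else "stim",
    block = 1L, trial_index = seq_len(nrow(types)),
    cue = if (rule_ctx) context else NA_character_,
    pretest = types$pretest, tone = types$tone, snr_db = types$snr_db,
    snr_unit = types$snr_unit, choice = NA_character_, rt_s = NA_real_,
    correct = NA, response_window_s = window
  )
  lambda <- params$lapse %or% 0

  acc <- matrix(NA_real_, length(z_grid), length(v_grid))
  for (iz in seq_along(z_grid)) {
    for (iv in seq_along(v_grid)) {
      p <- inject_biases(params, context, z_grid[iz], v_grid[iv])
      d <- trial_drivers(p, trials, if (rule_ctx) "rule" else "stim")
      pc <- vapply(seq_len(nrow(d)), function(i) {
        sol <- solve_fpt_drivers(d[i, ], dt = dt, dx = dx)
        if (trials$tone[i] == "H") sol$p_upper else sol$p_lower
      }, numeric(1))
      acc[iz, iv] <- sum(types$weight * ((1 - lambda) * pc + lambda / 2))
    }
  }
  structure(list(
    z_grid = z_grid, v_grid = v_grid, accuracy = acc,
    norm_accuracy = acc / max(acc), context = context,
    subject_params = params
  ), class = "performance_grid")
}

inject_biases <- function(params, context, z, v) {
  p <- params
  switch(context,
    low = { p$z_Low <- stats::qlogis(z); p$v_Low <- v },
    high = { p$z_High <- stats::qlogis(z); p$v_High <- v },
    { p$z_Bias <- z; p$v_Bias <- v }
  )
  p
}

#' @export
print.performance_grid <- function(x, ...) {
  cat("<performance_grid>", x$context, "context,",
      length(x$z_grid), "x", length(x$v_grid), "grid; max accuracy",
      signif(max(x$accuracy), 4), "\n")
  invisible(x)
}

#' @rdname performance_grid
#' @param x A `performance_grid`.
#' @param ... Unused.
#' @export
tidy.performance_grid <- function(x, ...) {
  tidyr::expand_grid(z = x$z_grid, v = x$v_grid) |>
    dplyr::mutate(accuracy = as.vector(t(x$accuracy)),
                  norm_accuracy = as.vector(t(x$norm_accuracy)))
}

#' Iso-performance contour of a landscape
#'
#' Level set of the normalized accuracy surface (default at 0.97 of the
#' maximum), via bilinear-interpolating contour tracing. If the whole
#' grid sits at or above the level, the grid boundary is returned with a
#' flag.
#'
#' @param grid A [performance_grid()].
#' @param level Contour level on the proportion-of-maximum scale.
#' @return List of class `performance_contour`: `paths` (list of tibbles
#'   with `z`, `v`), `level`, `degenerate`.
#' @export
contour_97 <- function(grid, level = 0.97) {
  na <- grid$norm_accuracy
  if (all(na >= level)) {
    zr <- range(grid$z_grid)
    vr <- range(grid$v_grid)
    path <- tibble::tibble(z = c(zr[1], zr[2], zr[2], zr[1], zr[1]),
                           v = c(vr[1], vr[1], vr[2], vr[2], vr[1]))
    return(structure(list(paths = list(path), level = level,
                          degenerate = TRUE),
                     class = "performance_contour"))
  }
  cl <- grDevices::contourLines(grid$z_grid, grid$v_grid, na, levels = level)
  paths <- lapply(cl, function(p) tibble::tibble(z = p$x, v = p$y))
  structure(list(paths = paths, level = level, degenerate = FALSE),
            class = "performance_contour")
}

#' Proportion of maximum performance at fitted biases
#'
#' Bilinear interpolation of the normalized accuracy surface at a
#' subject's fitted (z, v) bias pair; points outside the grid hull are
#' evaluated at the nearest cell and flagged.
#'
#' @param grid A [performance_grid()].
#' @param z,v Fitted biases on the grid's scales (for rule contexts `z`
#'   is the realized starting fraction, i.e. `plogis(z_cue)`).
#' @return Tibble: `z`, `v`, `proportion_max`, `outside_grid`.
#' @export
proportion_max <- function(grid, z, v) {
  stopifnot(length(z) == length(v))
  outside <- z < min(grid$z_grid) | z > max(grid$z_grid) |
    v < min(grid$v_grid) | v > max(grid$v_grid)
  zc <- pmin(pmax(z, min(grid$z_grid)), max(grid$z_grid))
  vc <- pmin(pmax(v, min(grid$v_grid)), max(grid$v_grid))
  pm <- vapply(seq_along(zc), function(i) {
    bilinear_at(grid$z_grid, grid$v_grid, grid$norm_accuracy, zc[i], vc[i])
  }, numeric(1))
  tibble::tibble(z = z, v = v, proportion_max = pm, outside_grid = outside)
}

bilinear_at <- function(xg, yg, M, x, y) {
  i <- findInterval(x, xg, rightmost.closed = TRUE)
  j <- findInterval(y, yg, rightmost.closed = TRUE)
  i <- min(max(i, 1), length(xg) - 1)
  j <- min(max(j, 1), length(yg) - 1)
  tx <- (x - xg[i]) / (xg[i + 1] - xg[i])
  ty <- (y - yg[j]) / (yg[j + 1] - yg[j])
  (1 - tx) * (1 - ty) * M[i, j] + tx * (1 - ty) * M[i + 1, j] +
    (1 - tx) * ty * M[i, j + 1] + tx * ty * M[i + 1, j + 1]
}
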