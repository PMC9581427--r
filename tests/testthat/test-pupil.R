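# flat synthetic recording with optional injected artifacts
flat_rec <- function(n_ms = 8000, diameter = 3000) {
  tibble::tibble(t_ms = 0:(n_ms - 1), diameter = diameter,
                 gaze_x = 0, gaze_y = 0, missing = FALSE)
}

test_that("an artifact-free trace is unchanged before filtering", {
  rec <- flat_rec()
  rec$diameter <- 3000 + 10 * sin(2 * pi * 0.5 * rec$t_ms / 1000)
  out <- clean_trace(rec)
  expect_equal(out$diameter_prefilter, rec$diameter)
  expect_false(any(out$interpolated))
})

test_that("blinks are expanded by 100 ms and linearly interpolated", {
  rec <- flat_rec()
  rec$missing[1001:1051] <- TRUE          # samples at t = 1000..1050 ms
  rec$diameter[1001:1051] <- 0
  out <- clean_trace(rec)
  idx <- which(out$interpolated)
  expect_equal(range(rec$t_ms[idx]), c(900, 1150))
  expect_equal(out$diameter_prefilter[1001:1051], rep(3000, 51))
})

test_that("velocity artifacts expand only when longer than 16 ms", {
  rec <- flat_rec()
  rec$diameter[2001:2010] <- rec$diameter[2001:2010] + 300  # 10 ms step up
  short <- clean_trace(rec)
  idx_s <- which(short$interpolated)
  expect_true(length(idx_s) > 0)
  expect_lt(diff(range(idx_s)), 50)       # no +/-100 ms expansion

  rec2 <- flat_rec()
  jump <- seq(2001, 2030)                  # 30 ms of high-velocity samples
  rec2$diameter[jump] <- 3000 + cumsum(rep(100, length(jump)))
  long <- clean_trace(rec2)
  idx_l <- which(long$interpolated)
  expect_gt(diff(range(idx_l)), 200)      # expanded on both sides
})

test_that("the 8 Hz filter attenuates 20 Hz by 20 dB but passes 1 Hz", {
  t <- 0:19999
  amp <- function(hz) {
    rec <- flat_rec(20000)
    rec$diameter <- 3000 + 100 * sin(2 * pi * hz * t / 1000)
    out <- clean_trace(rec)
    mid <- 2000:18000
    sd(out$diameter[mid]) / sd(rec$diameter[mid])
  }
  expect_lt(20 * log10(amp(20)), -20)
  expect_gt(20 * log10(amp(1)), -1)
})

test_that("cleaning is idempotent within filter tolerance", {
  rec <- flat_rec(10000)
  rec$diameter <- 3000 + 50 * sin(2 * pi * 1.5 * rec$t_ms / 1000)
  rec$missing[4001:4080] <- TRUE
  once <- clean_trace(rec)
  again_in <- once
  again_in$diameter <- once$diameter
  again_in$missing <- rep(FALSE, nrow(once))
  twice <- clean_trace(again_in[names(rec)])
  mid <- 1000:9000
  expect_equal(twice$diameter[mid], once$diameter[mid], tolerance = 0.02)
})

# build a recording with evenly spaced trials; returns rec + events
toy_session <- function(n_trials = 8, trial_len = 3000, effect = 0,
                        seed = 1) {
  set.seed(seed)
  n_ms <- n_trials * trial_len
  rec <- flat_rec(n_ms)
  rec$diameter <- 3000 + cumsum(rnorm(n_ms, 0, 0.5))
  rec$gaze_x <- rnorm(n_ms, 0, 0.05)
  rec$gaze_y <- rnorm(n_ms, 0, 0.05)
  onset <- (seq_len(n_trials) - 1) * trial_len + 500
  choice <- onset + 600
  list(rec = rec,
       events = tibble::tibble(trial_index = seq_len(n_trials),
                               tone_onset_ms = onset, choice_ms = choice))
}

test_that("baseline windows average exactly to zero after correction", {
  s <- toy_session()
  cl <- clean_trace(s$rec)
  ep <- epoch_and_exclude(cl, s$events, window_ms = c(-700, 1200),
                          min_trials = 1)
  expect_equal(ep$n_trials, 8)
  # tone onset sits at -600 ms relative to choice; its 0-40 ms window
  # must average to zero in the corrected epoch
  for (tr in unique(ep$epochs_1k$trial_index)) {
    e <- ep$epochs_1k[ep$epochs_1k$trial_index == tr, ]
    win <- e$pupil[e$t_ms >= -600 & e$t_ms < -560]
    expect_equal(mean(win), 0, tolerance = 1e-12)
  }
})

test_that("heavily interpolated trials are excluded as missing_data", {
  s <- toy_session()
  s$rec$missing[9200:11000] <- TRUE   # most of trial 4's epoch
  cl <- clean_trace(s$rec)
  ep <- epoch_and_exclude(cl, s$events, window_ms = c(-700, 1200),
                          min_trials = 1)
  expect_true(any(ep$excluded$reason == "missing_data"))
  expect_false(4 %in% ep$epochs$trial_index)
})

test_that("a 16 ms gaze excursion outside the circle excludes the trial", {
  s <- toy_session()
  idx <- 6800:6820                     # 21 ms inside trial 3's epoch
  s$rec$gaze_x[idx] <- 5
  cl <- clean_trace(s$rec)
  ep <- epoch_and_exclude(cl, s$events, window_ms = c(-700, 1200),
                          min_trials = 1)
  expect_true(3 %in% ep$excluded$trial_index[ep$excluded$reason == "gaze"])
})

test_that("a constant block z-scores to zero rather than NaN", {
  s <- toy_session()
  s$rec$diameter <- 3000
  cl <- clean_trace(s$rec)
  ep <- epoch_and_exclude(cl, s$events, window_ms = c(-700, 1200),
                          min_trials = 1)
  expect_true(all(ep$epochs$pupil == 0))
})

test_that("missing events are reported by trial", {
  s <- toy_session()
  s$events$tone_onset_ms[2] <- NA
  cl <- clean_trace(s$rec)
  expect_error(epoch_and_exclude(cl, s$events), "trials: 2")
})

test_that("two-stage contrasts recover an injected congruence transient", {
  set.seed(60)
  bins <- seq(0, 980, by = 20)
  make_subject <- function(id, effect) {
    n_tr <- 40
    code <- sample(rep(c(-0.5, 0.5), n_tr / 2))
    cov1 <- rnorm(n_tr)
    purrr::map_dfr(seq_len(n_tr), function(i) {
      mu <- ifelse(bins >= 200 & bins <= 800, effect * code[i], 0)
      tibble::tibble(subject_id = id, trial_index = i, bin_ms = bins,
                     pupil = mu + 0.05 * cov1[i] + rnorm(length(bins), 0, 0.3),
                     congruent_code = code[i], baseline = cov1[i])
    })
  }
  cohort <- purrr::map_dfr(1:10, function(s) {
    make_subject(paste0("s", s), effect = 0.3)
  })
  res <- timecourse_contrasts(cohort, "congruent_code", "baseline")
  sig <- res$bin_ms[res$p_fdr < 0.05 & res$beta > 0]
  expect_gte(sum(sig >= 200 & sig <= 800), 5)
  expect_gte(mean(sig >= 200 & sig <= 800), 0.9)

  null <- purrr::map_dfr(1:10, function(s) {
    make_subject(paste0("s", s), effect = 0)
  })
  res0 <- timecourse_contrasts(null, "congruent_code", "baseline")
  expect_lte(sum(res0$p_fdr < 0.05), 3)
})

test_that("bias-beta correlations are exact for monotone relations", {
  beta_tbl <- tidyr::expand_grid(subject_id = paste0("s", 1:12),
                                 bin_ms = c(0, 20), contrast = "c")
  bias_tbl <- tibble::tibble(subject_id = paste0("s", 1:12), bias = 1:12)
  beta_tbl$beta <- rep(exp(1:12 / 3), each = 2)
  out <- bias_pupil_correlation(bias_tbl, beta_tbl)
  expect_true(all(out$rho == 1))
  expect_error(bias_pupil_correlation(bias_tbl[1:5, ], beta_tbl), "matched")
})
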