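make_psych_fit <- function(model, coef, lapse = 0, n_back = 2) {
  structure(list(model = model, n_back = n_back, lapse = lapse, coef = coef,
                 loglik = 0, n_params = length(coef) + 1, n_trials = 0,
                 aic = 0, bic = 0, clamped = FALSE), class = "psych_fit")
}

test_that("predicted choice probabilities follow the lapse-limited logistic", {
  f0 <- make_psych_fit("base", c(b0 = 0, b_snr = 0))
  expect_equal(predict_choice_prob(f0, trial_stub(snr_db = -13)), 0.5)
  fbig <- make_psych_fit("base", c(b0 = 50, b_snr = 0), lapse = 0.02)
  expect_equal(predict_choice_prob(fbig, trial_stub()), 0.98,
               tolerance = 1e-9)
  # a single pre-test tone at position 1 acts through its +0.5 contrast
  fpt <- make_psych_fit("stim_bias",
                        c(b0 = 0, b_snr = 0, b_pt1 = 0.8, b_pt2 = 0))
  expect_equal(unname(predict_choice_prob(fpt, trial_stub(pretest = "LH"))),
               plogis(0.4), tolerance = 1e-9)
  expect_equal(unname(predict_choice_prob(fpt, trial_stub(pretest = "H"))),
               plogis(0.4), tolerance = 1e-9)
  expect_error(predict_choice_prob(fpt, trial_stub(pretest = "")), "pre-test")
})

test_that("P(H) is strictly increasing in SNR for positive slope", {
  f <- make_psych_fit("base", c(b0 = 0.3, b_snr = 6), lapse = 0.05)
  db <- seq(-23, -6, length.out = 9)
  ph <- sapply(db, function(d) predict_choice_prob(f, trial_stub(snr_db = d)))
  pl <- sapply(rev(db), function(d) {
    predict_choice_prob(f, trial_stub(snr_db = d, tone = "L"))
  })
  expect_true(all(diff(c(pl, ph)) > 0))
})

test_that("sign equivariance holds for symmetric fits", {
  f <- make_psych_fit("stim_bias",
                      c(b0 = 0, b_snr = 4, b_pt1 = 0.6, b_pt2 = 0.2))
  tr <- trial_stub(tone = "H", snr_db = -10, pretest = "HLH")
  fl <- trial_stub(tone = "L", snr_db = -10, pretest = "LHL")
  expect_equal(predict_choice_prob(f, tr), 1 - predict_choice_prob(f, fl),
               tolerance = 1e-12)
})

test_that("model parameter counts match the fit table", {
  set.seed(30)
  rule_tr <- generate_session(session_design("rule", n_trials = 96))
  rule_tr$choice <- sample(c("L", "H"), 96, TRUE)
  rule_tr$rt_s <- runif(96, 0.3, 1.5)
  stim_tr <- generate_session(session_design("stim", n_trials = 96))
  stim_tr$choice <- sample(c("L", "H"), 96, TRUE)
  stim_tr$rt_s <- runif(96, 0.3, 1.5)
  counts <- c(
    fit_logistic(rule_tr, "base", n_starts = 2)$n_params,
    fit_logistic(rule_tr, "bias", n_starts = 2)$n_params,
    fit_logistic(rule_tr, "bias_sensitivity", n_starts = 2)$n_params,
    fit_logistic(stim_tr, "stim_bias", n_starts = 2)$n_params,
    fit_logistic(stim_tr, "stim_bias_adapt", n_starts = 2)$n_params
  )
  expect_equal(counts, c(3, 5, 7, 5, 7))
})

test_that("logistic recovery: known bias model is recovered within 15%", {
  set.seed(31)
  tr <- dplyr::bind_rows(lapply(1:9, function(i) {
    generate_session(session_design("rule"), "s")
  }))[1:5000, ]
  truth <- c(b0_low = -1, b0_neutral = 0, b0_high = 1, b_snr = 10)
  f <- truth["b0_low"] * (tr$cue == "low") +
    truth["b0_neutral"] * (tr$cue == "neutral") +
    truth["b0_high"] * (tr$cue == "high") + truth["b_snr"] * tr$snr_unit
  p <- 0.02 + (1 - 2 * 0.02) * plogis(f)
  tr$choice <- ifelse(runif(nrow(tr)) < p, "H", "L")
  tr$rt_s <- 0.5
  fit <- fit_logistic(tr, "bias", seed = 2)
  expect_equal(unname(fit$coef["b_snr"]), 10, tolerance = 0.15)
  expect_equal(unname(fit$coef["b0_high"]), 1, tolerance = 0.15 * 10)
  expect_equal(unname(fit$coef["b0_high"] - fit$coef["b0_low"]), 2,
               tolerance = 0.15)
  expect_equal(fit$lapse, 0.02, tolerance = 0.02)
  expect_equal(choice_bias(fit), unname(fit$coef["b0_high"] -
                                          fit$coef["b0_low"]))
})

test_that("nested logistic models respect the likelihood ordering", {
  set.seed(32)
  tr <- generate_session(session_design("stim"), "s")
  tr <- filter_analyzable(tr)
  pt1 <- ifelse(substr(tr$pretest, nchar(tr$pretest),
                       nchar(tr$pretest)) == "H", 0.5, -0.5)
  p <- plogis(8 * tr$snr_unit + 0.9 * pt1 - 1.5 * pt1 * abs(tr$snr_unit))
  tr$choice <- ifelse(runif(nrow(tr)) < p, "H", "L")
  tr$rt_s <- 0.5
  ll <- sapply(c("base", "stim_bias", "stim_bias_adapt"), function(m) {
    fit_logistic(tr, m, seed = 3)$loglik
  })
  expect_gte(ll["stim_bias_adapt"], ll["stim_bias"] - 1e-3)
  expect_gte(ll["stim_bias"], ll["base"] - 1e-3)
})

test_that("base model on symmetric data finds no spurious bias", {
  set.seed(33)
  tr <- generate_session(session_design("stim"), "s")
  tr <- filter_analyzable(tr)
  p <- plogis(8 * tr$snr_unit)
  tr$choice <- ifelse(runif(nrow(tr)) < p, "H", "L")
  tr$rt_s <- 0.5
  fit <- fit_logistic(tr, "base", seed = 4)
  # |b0| under 2 SE, with SE roughly 2/sqrt(n) on this design
  expect_lt(abs(fit$coef["b0"]), 2 * 4 / sqrt(nrow(tr)))
})

test_that("chronometric summaries take medians within subject first", {
  tr <- dplyr::bind_rows(
    trial_stub(cue = "high", session_type = "rule"),
    trial_stub(cue = "high", session_type = "rule"),
    trial_stub(cue = "high", session_type = "rule")
  )
  tr$subject_id <- "s1"
  tr$choice <- "H"
  tr$correct <- TRUE
  tr$rt_s <- c(0.3, 0.4, 1.0)
  out <- chronometric_summary(tr)
  got <- out$median_rt_s[out$congruence == "congruent" &
                           out$abs_snr == 0.5 & !is.na(out$median_rt_s)]
  expect_equal(got, 0.4)  # odd-count median, not mean
  expect_true(any(out$missing))  # unobserved cells flagged

  tr$rt_s <- 0.7
  out2 <- chronometric_summary(tr)
  expect_true(all(out2$median_rt_s[!out2$missing] == 0.7))
})

test_that("congruence labels cover rule and stim roles", {
  tr <- dplyr::bind_rows(
    trial_stub(cue = "low", session_type = "rule"),
    trial_stub(cue = "neutral", session_type = "rule"),
    trial_stub(pretest = "LHH"),
    trial_stub(pretest = "LHL")
  )
  tr$choice <- c("L", "H", "H", "H")
  expect_equal(choice_congruence(tr),
               c("congruent", "neutral", "congruent", NA))
})

test_that("bias coupling recovers monotone association and flags degeneracy", {
  perfect <- tibble::tibble(subject_id = paste0("s", 1:12),
                            z = 1:12, v = -(1:12)^2)
  out <- bias_coupling(perfect)
  expect_equal(out$rho, -1)
  expect_lt(out$slope_v_on_z, 0)
  flat <- tibble::tibble(subject_id = paste0("s", 1:12), z = rep(1, 12),
                         v = rnorm(12))
  expect_true(bias_coupling(flat)$degenerate)
  expect_error(bias_coupling(perfect[1:5, ]), "10 subjects")
})

test_that("independent biases rarely exceed the Spearman null band", {
  set.seed(34)
  rhos <- replicate(300, {
    suppressWarnings(cor(rnorm(45), rnorm(45), method = "spearman"))
  })
  expect_gte(mean(abs(rhos) < 0.29), 0.93)
})
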