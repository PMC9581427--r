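test_that("pt_bias is the reverse-chronological exponential sum", {
  expect_equal(compute_pt_bias("", 1), 0)
  expect_equal(compute_pt_bias("H", 1), 1)
  expect_equal(compute_pt_bias("LH", 1), 1 - exp(-1), tolerance = 1e-12)
  # antisymmetry under H<->L swap
  set.seed(1)
  for (i in 1:20) {
    s <- paste(sample(c("L", "H"), sample(2:14, 1), TRUE), collapse = "")
    flipped <- chartr("LH", "HL", s)
    tau <- runif(1, 0.3, 10)
    expect_equal(compute_pt_bias(s, tau), -compute_pt_bias(flipped, tau),
                 tolerance = 1e-12)
  }
})

test_that("adapt weights the two tone identities separately", {
  expect_equal(compute_adapt("", -1.4, -2.31, 7.04), 0)
  expect_equal(compute_adapt("H", -1.40, -2.31, 7.04), -1.40)
  expect_equal(compute_adapt("HH", -1, 0, 1), -(1 + exp(-1)),
               tolerance = 1e-12)
  # low tones enter with the opposite overall sign
  expect_equal(compute_adapt("L", 0, -2, 5), 2)
})

test_that("trial drivers compose cue biases, tone history, and ndt", {
  p <- rule_mean_params()
  tr <- trial_stub(tone = "H", snr_db = -6, cue = "high",
                   session_type = "rule")
  d <- trial_drivers(p, tr, "rule")
  expect_equal(d$drift, 6.51 * 0.5 + 0.67, tolerance = 1e-9) # 3.925
  expect_equal(d$start_frac, plogis(0.39), tolerance = 1e-12)
  expect_equal(d$ndt, 0.27)
  expect_equal(d$x0, plogis(0.39) * 2 * 0.92, tolerance = 1e-9)

  # empty-bias limit: drift = v_SNR * SNR, start = 1/2
  p0 <- ddm_params(v_SNR = 3, B = 1, ndt_0 = 0.2, lapse = 0,
                   v_0 = 0, z_0 = 0)
  d0 <- trial_drivers(p0, trial_stub(tone = "L", snr_db = -23,
                                     pretest = "HL"), "stim")
  expect_equal(d0$drift, 3 * -0.05, tolerance = 1e-12)
  expect_equal(d0$start_frac, 0.5)

  # full stim composition against an independent hand computation
  ps <- stim_mean_params()
  ds <- trial_drivers(ps, trial_stub(tone = "H", snr_db = -6,
                                     pretest = "HH"), "stim")
  ptb <- exp(0) + exp(-1 / 4.99)
  adp <- -1.40 * (exp(0) + exp(-1 / 7.04))
  expect_equal(ds$pt_bias, ptb, tolerance = 1e-12)
  expect_equal(ds$adapt, adp, tolerance = 1e-12)
  expect_equal(ds$drift, 4.97 * 0.5 + (-0.20) + 0.84 * ptb + adp * 0.5,
               tolerance = 1e-9)
  expect_equal(ds$start_frac, plogis(-0.03 - 0.09 * ptb), tolerance = 1e-9)
  expect_equal(ds$ndt, 0.46 - 0.12 * abs(ptb), tolerance = 1e-9)
})

test_that("driver validation catches role mismatches", {
  p <- rule_mean_params()
  expect_error(trial_drivers(p, trial_stub(cue = NA_character_,
                                           session_type = "rule"), "rule"),
               "cue")
  expect_error(trial_drivers(stim_mean_params(),
                             trial_stub(pretest = ""), "stim"),
               "pre-test")
})

test_that("fixed-bound absorption probabilities match the closed form", {
  # closed form for start midway between bounds, unit noise:
  # P(upper) = (1 - exp(-2 mu B)) / (1 - exp(-4 mu B))
  for (mu in c(0.5, 1.5, 2.5)) {
    for (B in c(0.3, 0.5, 0.7)) {
      s <- solve_fpt(mu, B, 0, 0.5, window = 8)
      expect_equal(s$p_upper / (s$p_upper + s$p_lower),
                   (1 - exp(-2 * mu * B)) / (1 - exp(-4 * mu * B)),
                   tolerance = 5e-4)
    }
  }
  s0 <- solve_fpt(0, 0.5, 0, 0.5, window = 8)
  expect_equal(s0$p_upper, 0.5, tolerance = 2e-3)
  s1 <- solve_fpt(1, 0.5, 0, 0.5, window = 8)
  expect_equal(s1$p_upper, 1 / (1 + exp(-2 * 1 * 0.5)), tolerance = 3e-3)
})

test_that("first-passage solutions conserve mass and respect symmetry", {
  set.seed(3)
  for (i in 1:8) {
    mu <- runif(1, -3, 3)
    B <- runif(1, 0.4, 1.5)
    tB <- sample(c(0, runif(1, 0, 0.6)), 1)
    z <- runif(1, 0.2, 0.8)
    s <- solve_fpt(mu, B, tB, z, window = 2)
    mass <- sum(s$dens_upper) * s$dt + sum(s$dens_lower) * s$dt + s$undecided
    expect_equal(mass, 1, tolerance = 1e-3)
    expect_true(all(s$dens_upper >= 0) && all(s$dens_lower >= 0))
    # mirror: negate drift, reflect start -> swap densities
    m <- solve_fpt(-mu, B, tB, 1 - z, window = 2)
    expect_equal(s$dens_upper, m$dens_lower, tolerance = 1e-6)
    expect_equal(s$dens_lower, m$dens_upper, tolerance = 1e-6)
  }
})

test_that("P(upper) increases strictly with drift", {
  p_up <- vapply(seq(-2, 2, by = 0.5), function(mu) {
    solve_fpt(mu, 0.8, 0.3, 0.4, window = 2)$p_upper
  }, numeric(1))
  expect_true(all(diff(p_up) > 0))
})

test_that("bound collapse to zero forces absorption and truncates densities", {
  s <- solve_fpt(0, 1, 1, 0.5, window = 2)  # bound hits 0 at t = 1
  expect_equal(s$undecided, 0, tolerance = 1e-9)
  late <- s$time > 1.01
  expect_true(all(s$dens_upper[late] == 0))
})

test_that("rt_likelihood mixes lapse, floors at ndt, and normalizes", {
  p <- ddm_params(v_SNR = 4, B = 1, t_B = 0.5, ndt_0 = 0.3, lapse = 0.5,
                  v_0 = 0, z_0 = 0)
  tr <- trial_stub(tone = "H", snr_db = -13, pretest = "LH")
  # below the non-decision floor only the lapse density remains
  t1 <- tr
  t1$choice <- "H"
  t1$rt_s <- 0.1
  expect_equal(rt_likelihood(p, t1, "stim"), 0.5 / (2 * 2), tolerance = 1e-12)
  p0 <- p
  p0$lapse <- 0
  expect_equal(rt_likelihood(p0, t1, "stim"), 0)

  # total probability: integral over both choices plus undecided mass
  rts <- seq(0.0025, 2, by = 0.005)
  dens <- sapply(c("L", "H"), function(ch) {
    tt <- tr[rep(1, length(rts)), ]
    tt$choice <- ch
    tt$rt_s <- rts
    rt_likelihood(p, tt, "stim")
  })
  d <- trial_drivers(p, tr, "stim")
  sol <- solve_fpt(d$drift, d$bound_half, d$collapse, d$start_frac, d$window)
  expect_equal(sum(dens) * 0.005 + (1 - 0.5) * sol$undecided, 1,
               tolerance = 2e-3)

  t_bad <- t1
  t_bad$rt_s <- 2.5
  expect_error(rt_likelihood(p, t_bad, "stim"), "rt")
})

test_that("drift variability averages densities over a uniform gain band", {
  pv <- ddm_params(v_SNR = 4, B = 0.8, ndt_0 = 0.2, lapse = 0, v_0 = 0,
                   z_0 = 0, v_width = 3)
  tr <- trial_stub(tone = "H", snr_db = -6, session_type = "rule",
                   cue = "neutral")
  tr$choice <- "H"
  tr$rt_s <- 0.6
  f_var <- rt_likelihood(pv, tr, "rule")
  # independent check: plain average over a fine uniform grid of gains
  gains <- seq(4 - 1.5, 4 + 1.5, length.out = 61)
  f_grid <- mean(vapply(gains, function(g) {
    pg <- pv
    pg$v_SNR <- g
    pg$v_width <- NA
    rt_likelihood(pg, tr, "rule")
  }, numeric(1)))
  expect_equal(f_var, f_grid, tolerance = 0.01 * f_grid + 1e-4)
})

test_that("simulated trials agree with solver probabilities and are seeded", {
  p <- ddm_params(v_SNR = 10, B = 0.5, ndt_0 = 0.1, lapse = 0, v_0 = 0,
                  z_0 = 0)
  tr <- trial_stub(tone = "H", snr_db = -6, session_type = "rule",
                   cue = "neutral")[rep(1, 1500), ]
  set.seed(10)
  sim <- simulate_trials(p, tr, "rule")
  expect_gt(mean(sim$choice == "H"), 0.95)  # strong-drift limit
  d <- trial_drivers(p, tr[1, ], "rule")
  sol <- solve_fpt(d$drift, d$bound_half, d$collapse, d$start_frac, d$window)
  expect_equal(mean(sim$choice == "H"), sol$p_upper, tolerance = 0.02)

  set.seed(11)
  a <- simulate_trials(p, tr[1:50, ], "rule")
  set.seed(11)
  b <- simulate_trials(p, tr[1:50, ], "rule")
  expect_identical(a, b)
})

test_that("parameter validation and JSON round-trip work", {
  expect_error(ddm_params(B = -1), "B")
  expect_error(ddm_params(lapse = 0.7), "lapse")
  expect_error(ddm_params(tau_Bias = 0), "tau_Bias")
  p <- stim_mean_params()
  path <- withr::local_tempfile(fileext = ".json")
  write_ddm_params(p, path)
  q <- read_ddm_params(path)
  expect_equal(q$v_Bias, 0.84)
  expect_equal(q$tau_va, 7.04)
  expect_true(is.na(q$v_Low))
})
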