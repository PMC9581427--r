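# shared fixtures: canonical parameter sets and small optimizer budgets

rule_mean_params <- function() {
  ddm_params(v_SNR = 6.51, B = 0.92, t_B = 0.92, ndt_0 = 0.27, lapse = 0.02,
             v_Low = -0.83, v_0 = 0.07, v_High = 0.67,
             z_Low = -0.20, z_0 = 0.06, z_High = 0.39)
}

stim_mean_params <- function() {
  ddm_params(v_SNR = 4.97, B = 1.02, t_B = 0.80, ndt_0 = 0.46,
             ndt_Bias = -0.12, lapse = 0.02, v_0 = -0.20, v_Bias = 0.84,
             tau_Bias = 4.99, va_Low = -2.31, va_High = -1.40,
             tau_va = 7.04, z_0 = -0.03, z_Bias = -0.09)
}

# a one-row trial stub with given stimulus fields
trial_stub <- function(tone = "H", snr_db = -6, cue = NA_character_,
                       pretest = "", session_type = "stim", window = 2) {
  tibble::tibble(
    subject_id = "t", session_type = session_type, block = 1L,
    trial_index = 1L, cue = cue, pretest = pretest, tone = tone,
    snr_db = snr_db, snr_unit = map_snr(snr_db, tone),
    choice = NA_character_, rt_s = NA_real_, correct = NA,
    response_window_s = window
  )
}

# optimizer budget for unit tests (keeps fits to a few seconds)
tiny_fit_config <- function(...) {
  utils::modifyList(
    list(np = 10, maxiter = 5, polish_maxit = 30,
         solver_dt = 0.02, solver_dx = 0.02, min_trials = 50),
    list(...)
  )
}
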