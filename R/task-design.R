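#' Cue conditions for the rule-based task
#'
#' The three visual prior cues and the probability that the upcoming test
#' tone is high frequency. Odds of high:low are 1:5 ("low"), 1:1
#' ("neutral") and 5:1 ("high"), i.e. `p_high` of 1/6, 1/2 and 5/6.
#'
#' @return A tibble with columns `cue`, `odds_high`, `odds_low`, `p_high`.
#' @export
#' @examples
#' cue_conditions()
cue_conditions <- function() {
  tibble::tibble(
    cue = c("low", "neutral", "high"),
    odds_high = c(1, 1, 5),
    odds_low = c(5, 1, 1),
    p_high = c(1 / 6, 1 / 2, 5 / 6)
  )
}

#' dB levels used for the test tone
#'
#' Test-tone sound levels relative to the background noise span -23 to
#' -6 dB; four levels are used per tone identity.
#'
#' @return Numeric vector of dB SNR levels (negative).
#' @export
snr_db_levels <- function() c(-23, -18, -13, -6)

#' Map dB SNR onto the signed unit scale
#'
#' Linearly rescales dB SNR from \[-23, -6\] onto the unsigned unit scale
#' \[0.05, 0.5\], then signs it by tone identity (high frequency positive,
#' low frequency negative).
#'
#' @param snr_db Numeric vector of dB SNR values in \[-23, -6\].
#' @param tone Character vector over `"L"`, `"H"` (recycled).
#' @return Signed unit SNR, same length as `snr_db`.
#' @export
#' @examples
#' map_snr(-23, "H") # 0.05
#' map_snr(-6, "L")  # -0.5
map_snr <- function(snr_db, tone) {
  if (any(snr_db < -23 - 1e-9 | snr_db > -6 + 1e-9)) {
    stop("snr_db must lie in [-23, -6]", call. = FALSE)
  }
  if (!all(tone %in% c("L", "H"))) stop("tone must be 'L' or 'H'", call. = FALSE)
  unsigned <- 0.05 + (snr_db + 23) / 17 * 0.45
  ifelse(tone == "H", unsigned, -unsigned)
}

#' Sample a pre-test tone sequence
#'
#' Lengths follow a geometric distribution truncated to
#' `[min_len, max_len]` (success probability `p_stop`, so short sequences
#' of 2-3 tones dominate); tone identities are fair coin flips. Session
#' level balance of H vs L is enforced in [generate_session()].
#'
#' @param n Number of sequences to draw.
#' @param min_len,max_len Length bounds (default 2 and 14).
#' @param p_stop Geometric success probability for the length (default 0.45).
#' @return Character vector of sequences over `{L, H}`, in chronological
#'   order (last character = tone immediately before the test tone).
#' @export
sample_pretest_sequence <- function(n = 1, min_len = 2, max_len = 14,
                                    p_stop = 0.45) {
  stopifnot(min_len >= 0, max_len >= min_len)
  lens <- sample_pretest_length(n, min_len, max_len, p_stop)
  vapply(lens, function(l) {
    paste(sample(c("L", "H"), l, replace = TRUE), collapse = "")
  }, character(1))
}

sample_pretest_length <- function(n, min_len, max_len, p_stop) {
  support <- seq.int(min_len, max_len)
  if (length(support) == 1L) return(rep.int(support, n))
  pr <- (1 - p_stop)^(support - min_len) * p_stop
  sample(support, n, replace = TRUE, prob = pr / sum(pr))
}

#' Session designs
#'
#' Canonical designs: rule-based sessions have 576 trials in 12
#' constant-cue mini-blocks of 48; stimulus-based sessions have 480 trials
#' of which 38 lack a pre-test sequence; mixed-condition 1 uses a fixed
#' prior cue for a 480-trial session with varying pre-test sequences;
#' mixed-condition 2 uses trial-wise cues with pre-test length fixed at 5.
#'
#' @param session_type One of `"rule"`, `"stim"`, `"mixed1"`, `"mixed2"`.
#' @param response_window_s Response window in seconds (default 2; 3 is
#'   used for a subset of rule-based subjects).
#' @param n_trials Override the canonical trial count (e.g. for small
#'   simulated sessions); must remain divisible by `miniblock_len` for
#'   cued designs.
#' @param mixed1_cue For `mixed1`, the session-constant cue
#'   (`"low"` or `"high"`).
#' @param p_stop Geometric stopping probability for pre-test lengths.
#' @return A list of class `session_design`.
#' @export
session_design <- function(session_type = c("rule", "stim", "mixed1", "mixed2"),
                           response_window_s = 2, n_trials = NULL,
                           mixed1_cue = "high", p_stop = 0.45) {
  session_type <- match.arg(session_type)
  d <- switch(session_type,
    rule = list(n_trials = 576, miniblock_len = 48, pretest_len = c(0, 0),
                n_no_pretest = 0),
    stim = list(n_trials = 480, miniblock_len = NA_integer_,
                pretest_len = c(2, 14), n_no_pretest = 38),
    mixed1 = list(n_trials = 480, miniblock_len = NA_integer_,
                  pretest_len = c(2, 14), n_no_pretest = 38),
    mixed2 = list(n_trials = 576, miniblock_len = 48,
                  pretest_len = c(5, 5), n_no_pretest = 0)
  )
  if (!is.null(n_trials)) d$n_trials <- as.integer(n_trials)
  d$session_type <- session_type
  d$response_window_s <- response_window_s
  d$mixed1_cue <- mixed1_cue
  d$p_stop <- p_stop
  if (!is.na(d$miniblock_len) && d$n_trials %% d$miniblock_len != 0) {
    stop("n_trials must be divisible by the mini-block length", call. = FALSE)
  }
  if (d$n_no_pretest >= d$n_trials) d$n_no_pretest <- 0L
  structure(d, class = "session_design")
}

#' Generate the stimuli of one session
#'
#' Builds the ordered trial table for a session (stimuli only; `choice`,
#' `rt_s` and `correct` are `NA`). Rule-based sessions interleave the
#' three cues in constant-cue mini-blocks with equal expected counts; the
#' test tone is drawn with the cue's `p_high` and a uniformly drawn |SNR|
#' level. Stimulus-based sessions draw non-predictive pre-test sequences
#' (p_high = 1/2) and place the no-pre-test trials uniformly at random;
#' session-level H/L tone balance in the pre-test sequences is enforced by
#' resampling tone identities (up to 100 rounds) until the H proportion is
#' within 2 percentage points of one half.
#'
#' @param design A [session_design()].
#' @param subject_id Subject identifier stored in the table.
#' @return Tibble with columns `subject_id`, `session_type`, `block`,
#'   `trial_index`, `cue`, `pretest`, `tone`, `snr_db`, `snr_unit`,
#'   `choice`, `rt_s`, `correct`, `response_window_s`.
#' @export
generate_session <- function(design, subject_id = "s01") {
  stopifnot(inherits(design, "session_design"))
  n <- design$n_trials
  type <- design$session_type
  cc <- cue_conditions()

  if (type %in% c("rule", "mixed2")) {
    nb <- n %/% design$miniblock_len
    block_cue <- sample(rep_len(cc$cue, nb))
    block <- rep(seq_len(nb), each = design$miniblock_len)
    cue <- if (type == "rule") block_cue[block] else sample(cc$cue, n, TRUE)
  } else if (type == "mixed1") {
    block <- rep(1L, n)
    cue <- rep(design$mixed1_cue, n)
  } else {
    block <- rep(1L, n)
    cue <- rep(NA_character_, n)
  }

  p_high <- if (type == "stim") rep(0.5, n) else cc$p_high[match(cue, cc$cue)]
  tone <- ifelse(stats::runif(n) < p_high, "H", "L")
  snr_db <- sample(snr_db_levels(), n, replace = TRUE)

  pretest <- rep("", n)
  if (design$pretest_len[2] > 0) {
    with_pt <- rep(TRUE, n)
    if (design$n_no_pretest > 0) {
      with_pt[sample.int(n, design$n_no_pretest)] <- FALSE
    }
    k <- sum(with_pt)
    lens <- sample_pretest_length(k, design$pretest_len[1],
                                  design$pretest_len[2], design$p_stop)
    seqs <- balanced_tone_fill(lens)
    pretest[with_pt] <- seqs
  }

  tibble::tibble(
    subject_id = subject_id,
    session_type = type,
    block = as.integer(block),
    trial_index = seq_len(n),
    cue = cue,
    pretest = pretest,
    tone = tone,
    snr_db = snr_db,
    snr_unit = map_snr(snr_db, tone),
    choice = NA_character_,
    rt_s = NA_real_,
    correct = NA,
    response_window_s = design$response_window_s
  )
}

# Fill tone identities for the given sequence lengths, resampling until the
# session-level proportion of H tones is within +/-2% of 0.5 (<= 100 rounds).
balanced_tone_fill <- function(lens) {
  total <- sum(lens)
  for (round in seq_len(100)) {
    tones <- sample(c("L", "H"), total, replace = TRUE)
    prop_h <- mean(tones == "H")
    if (abs(prop_h - 0.5) <= 0.02) break
  }
  ends <- cumsum(lens)
  starts <- ends - lens + 1
  vapply(seq_along(lens), function(i) {
    paste(tones[starts[i]:ends[i]], collapse = "")
  }, character(1))
}

#' Keep only analyzable trials
#'
#' Removes, for stimulus-based and mixed-1 sessions, the trials that have
#' no pre-test sequence, and (when responses are present) any
#' non-response trials (`choice == "none"`). Order is preserved.
#'
#' @param trials Trial tibble as produced by [generate_session()].
#' @return Filtered tibble.
#' @export
#' @examples
#' s <- generate_session(session_design("stim"))
#' nrow(filter_analyzable(s)) # 442
filter_analyzable <- function(trials) {
  if (nrow(trials) == 0) return(trials)
  keep_pt <- !(trials$session_type %in% c("stim", "mixed1") &
                 (is.na(trials$pretest) | trials$pretest == ""))
  keep_resp <- is.na(trials$choice) | trials$choice != "none"
  trials[keep_pt & keep_resp, , drop = FALSE]
}

#' Read / write trial tables
#'
#' Plain CSV round-trip of the shared trial schema.
#'
#' @param path File path.
#' @param trials Trial tibble.
#' @return `read_trials()` returns a tibble; `write_trials()` returns
#'   `path` invisibly.
#' @export
read_trials <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    subject_id = "c", session_type = "c", cue = "c",
                    pretest = "c", tone = "c", choice = "c",
                    .default = readr::col_guess()
                  )) |>
    dplyr::mutate(pretest = dplyr::coalesce(.data$pretest, ""))
}

#' @rdname read_trials
#' @export
write_trials <- function(trials, path) {
  readr::write_csv(trials, path)
  invisible(path)
}
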