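# Fixtures are built in code: tiny hand-constructed trials with known
# attention traces, and small synthetic profiles.

# A single-trial tibble with a prescribed attention trace. Band columns
# default to flat positive values unless overridden with a named list of
# per-band vectors.
make_trial <- function(attention, trial_type = "attention", valid = TRUE,
                       bands = NULL, n_bands = 8, subject_id = "T",
                       session_index = 1L, trial_index = 1L) {
  n <- length(attention)
  tr <- tibble::tibble(
    subject_id = subject_id,
    session_index = session_index,
    trial_index = trial_index,
    trial_type = trial_type,
    t_in_trial = seq_len(n) - 1L,
    poor_signal = 0L,
    attention = attention,
    meditation = rep(50, n)
  )
  defaults <- 1000 / seq_len(n_bands)
  for (b in seq_len(n_bands)) {
    col <- paste0("band_", b)
    tr[[col]] <- if (!is.null(bands) && col %in% names(bands)) {
      rep_len(bands[[col]], n)
    } else {
      rep(defaults[b], n)
    }
  }
  tr$valid <- rep_len(valid, n)
  tr
}

# Profile with perfect latency-free control and no contamination.
ideal_profile <- function(id = "ideal") {
  subject_profile(id, mu_att = 85, mu_non = 15, sigma_within = 4,
                  ar_coeff = 0.3, tau_on = 0, tau_off = 0,
                  artifact_rates = c(blink = 0, emg = 0, motion = 0),
                  poor_signal_rate = 0)
}

# Chance-level profile: no class separation, no band shifts.
null_profile <- function(id = "null") {
  subject_profile(id, mu_att = 50.001, mu_non = 49.999, sigma_within = 15,
                  ar_coeff = 0.6, tau_on = 0, tau_off = 0,
                  band_shift = rep(0, 8),
                  artifact_rates = c(blink = 0, emg = 0, motion = 0),
                  poor_signal_rate = 0)
}

# Sessions for one profile, bound into a single tibble.
make_subject_sessions <- function(profile, n_sessions = 5, seed = 1,
                                  config = sim_config()) {
  dplyr::bind_rows(lapply(seq_len(n_sessions), function(s) {
    generate_session(profile, config, s, seed = seed + s)
  }))
}

# Brute-force per-window least-squares quadratic smoother: the oracle for
# the Savitzky-Golay residual on interior samples.
ls_quadratic_residual <- function(x, half = 17L) {
  n <- length(x)
  res <- rep(NA_real_, n)
  for (t in (half + 1):(n - half)) {
    idx <- (t - half):(t + half)
    tt <- idx - t
    fit <- stats::lm.fit(cbind(1, tt, tt^2), x[idx])
    res[t] <- x[t] - fit$coefficients[1]
  }
  res
}

# O(n^2) pairwise AUC oracle: P(score_pos > score_neg) + 0.5 P(tie).
pairwise_auc <- function(scores, is_positive) {
  pos <- scores[is_positive]
  neg <- scores[!is_positive]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}
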