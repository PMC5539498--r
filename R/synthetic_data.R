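#' Subject profile for the synthetic attention-stream generator
#'
#' A subject profile collects the generative parameters that determine how
#' well a simulated participant separates the two attentional states: the
#' class means of the 1 Hz attention indicator, the within-trial noise and
#' its lag-1 autocorrelation, the mean switching latencies after a trial
#' starts, the per-band log-scale shifts between attention and
#' non-attention trials, and the contamination rates (artifact kinds per
#' raw epoch, probability of a poor-signal second).
#'
#' The default profile emulates a participant who controls the indicator
#' well: class means far from the 50% feedback threshold, a couple of
#' seconds of switching latency, and a band-shift pattern in which delta
#' and the theta/beta ratio decrease with attention while gamma increases.
#'
#' @param subject_id Subject label.
#' @param mu_att,mu_non Class means of the attention indicator (percent,
#'   `0 <= mu_non < mu_att <= 100`).
#' @param sigma_within Stationary per-second standard deviation of the
#'   attention indicator around its class mean.
#' @param ar_coeff Lag-1 autocorrelation of the per-second noise, in `[0, 1)`.
#' @param tau_on,tau_off Mean switching latency (seconds) after the onset of
#'   an attention / non-attention trial; latencies are drawn from an
#'   exponential distribution with these means.
#' @param band_shift Signed per-band shift of the log band power in
#'   attention trials relative to non-attention trials; length must match
#'   the configured number of bands.
#' @param artifact_rates Named per-epoch probabilities for `blink`, `emg`
#'   and `motion` contamination of the raw signal.
#' @param poor_signal_rate Probability that a second is flagged unusable by
#'   the sensor's contact-quality indicator.
#' @return An object of class `subject_profile`.
#' @export
#' @examples
#' subject_profile("A1", mu_att = 80, mu_non = 20)
subject_profile <- function(subject_id,
                            mu_att = 75,
                            mu_non = 30,
                            sigma_within = 12,
                            ar_coeff = 0.6,
                            tau_on = 2,
                            tau_off = 2,
                            band_shift = c(
                              delta = -0.35, theta = -0.15,
                              low_alpha = -0.1, high_alpha = -0.1,
                              low_beta = 0.15, high_beta = 0.15,
                              low_gamma = 0.3, mid_gamma = 0.3
                            ),
                            artifact_rates = c(blink = 0.04, emg = 0.02, motion = 0.01),
                            poor_signal_rate = 0.01) {
  stop_field(is.character(subject_id) && length(subject_id) == 1 && nzchar(subject_id),
             "subject_id", "must be a non-empty string")
  stop_field(is.numeric(mu_att) && is.numeric(mu_non) &&
               mu_non >= 0 && mu_non < mu_att && mu_att <= 100,
             "mu_att/mu_non", "need 0 <= mu_non < mu_att <= 100")
  stop_field(sigma_within >= 0, "sigma_within", "must be >= 0")
  stop_field(ar_coeff >= 0 && ar_coeff < 1, "ar_coeff", "must lie in [0, 1)")
  stop_field(tau_on >= 0 && tau_off >= 0, "tau_on/tau_off", "must be >= 0")
  stop_field(is.numeric(band_shift) && length(band_shift) >= 8,
             "band_shift", "must be numeric with one entry per band")
  stop_field(all(c("blink", "emg", "motion") %in% names(artifact_rates)) &&
               all(artifact_rates >= 0) && sum(artifact_rates) <= 1,
             "artifact_rates", "needs blink/emg/motion probabilities summing to <= 1")
  stop_field(poor_signal_rate >= 0 && poor_signal_rate <= 1,
             "poor_signal_rate", "must be a probability")
  structure(
    list(
      subject_id = subject_id, mu_att = mu_att, mu_non = mu_non,
      sigma_within = sigma_within, ar_coeff = ar_coeff,
      tau_on = tau_on, tau_off = tau_off,
      band_shift = band_shift,
      artifact_rates = artifact_rates[c("blink", "emg", "motion")],
      poor_signal_rate = poor_signal_rate
    ),
    class = "subject_profile"
  )
}

#' Simulation configuration for the recording protocol
#'
#' Describes the shape of one recording campaign: number of sessions per
#' subject, trials per session (alternating attention / non-attention,
#' starting with attention), the 30 s task half and 30 s rest half of each
#' one-minute trial, the raw sampling rate, and the number of power bands
#' the sensor reports.
#'
#' @param n_sessions Sessions per subject.
#' @param trials_per_session Trials per session; must be even so the two
#'   trial types stay balanced.
#' @param trial_task_seconds Length of the task half of a trial (1 Hz).
#' @param rest_seconds Length of the rest half of a trial (1 Hz).
#' @param sample_rate_raw Raw EEG sampling rate (Hz); one raw epoch spans
#'   one second.
#' @param n_bands Number of power bands in the stream (8 or 9).
#' @param seed Base integer seed for cohort generation.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_sessions = 5,
                       trials_per_session = 14,
                       trial_task_seconds = 30,
                       rest_seconds = 30,
                       sample_rate_raw = 512,
                       n_bands = 8,
                       seed = 1) {
  counts <- c(
    n_sessions = n_sessions, trials_per_session = trials_per_session,
    trial_task_seconds = trial_task_seconds, rest_seconds = rest_seconds,
    sample_rate_raw = sample_rate_raw
  )
  for (f in names(counts)) {
    stop_field(is.numeric(counts[[f]]) && counts[[f]] >= 1 && counts[[f]] == round(counts[[f]]),
               f, "must be a positive whole number")
  }
  stop_field(trials_per_session %% 2 == 0, "trials_per_session",
             "must be even (trial types alternate)")
  band_names(n_bands) # validates 8 or 9
  structure(
    list(
      n_sessions = as.integer(n_sessions),
      trials_per_session = as.integer(trials_per_session),
      trial_task_seconds = as.integer(trial_task_seconds),
      rest_seconds = as.integer(rest_seconds),
      sample_rate_raw = as.integer(sample_rate_raw),
      n_bands = as.integer(n_bands),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# Baseline log-scale band powers (sensor units); magnitudes fall off with
# frequency, as the device's unit-less FFT powers do.
band_baseline_meanlog <- function(n_bands) {
  log(c(1e5, 6e4, 3e4, 2e4, 1.5e4, 1e4, 6e3, 4e3, 3e3))[seq_len(n_bands)]
}

#' Generate one synthetic recording session
#'
#' Produces the 1 Hz processed stream of a single session: alternating
#' attention / non-attention task halves (odd trials are attention trials)
#' each followed by a rest half. The attention indicator is a clipped AR(1)
#' process whose target mean starts at the opposite class mean and switches
#' to the trial's class mean after an exponential latency (`tau_on` for
#' attention trials, `tau_off` for non-attention ones); the switch takes
#' effect at the sample whose one-second window centre the latency falls
#' before. Band powers are log-normal with the profile's class-dependent
#' log-scale shifts, meditation is class-independent noise, and seconds are
#' flagged unusable with probability `poor_signal_rate`.
#'
#' @param profile A [subject_profile()].
#' @param config A [sim_config()].
#' @param session_index Session number in `1:n_sessions`.
#' @param seed Integer seed; identical arguments give bit-identical output.
#' @return A tibble with one row per second: `subject_id`, `session_index`,
#'   `trial_index`, `trial_type` (`attention`, `non_attention` or `rest`),
#'   `t_in_trial` (0-based within the task or rest half), `poor_signal`,
#'   `attention`, `meditation`, `band_1` ... `band_N`, `valid`.
#' @export
#' @examples
#' p <- subject_profile("S1", mu_att = 80, mu_non = 20,
#'                      sigma_within = 0, tau_on = 0, tau_off = 0)
#' s <- generate_session(p, sim_config(), session_index = 1, seed = 42)
#' table(s$trial_type)
generate_session <- function(profile, config, session_index, seed) {
  stopifnot(inherits(profile, "subject_profile"), inherits(config, "sim_config"))
  stop_field(session_index >= 1 && session_index <= config$n_sessions,
             "session_index", "must lie in 1..n_sessions")
  stop_field(length(profile$band_shift) >= config$n_bands, "band_shift",
             "profile must provide a shift for every configured band")

  n_task <- config$trial_task_seconds
  n_rest <- config$rest_seconds
  n_trials <- config$trials_per_session
  nb <- config$n_bands
  mu_rest <- (profile$mu_att + profile$mu_non) / 2

  with_seed(seed, {
    types <- rep(c("attention", "non_attention"), length.out = n_trials)
    # Switching latency per trial, then the per-second target mean.
    latency <- vapply(types, function(ty) {
      tau <- if (ty == "attention") profile$tau_on else profile$tau_off
      if (tau > 0) stats::rexp(1, rate = 1 / tau) else 0
    }, numeric(1))
    mean_one_trial <- function(i) {
      ty <- types[i]
      mu_to <- if (ty == "attention") profile$mu_att else profile$mu_non
      mu_from <- if (ty == "attention") profile$mu_non else profile$mu_att
      k <- seq_len(n_task) - 1L
      task <- ifelse(k >= round(latency[i]), mu_to, mu_from)
      c(task, rep(mu_rest, n_rest))
    }
    mean_vec <- unlist(lapply(seq_len(n_trials), mean_one_trial))
    total <- length(mean_vec)

    # AR(1) deviation around the (possibly switching) target mean; the
    # deviation chain runs across trial boundaries within the session.
    innov_sd <- profile$sigma_within * sqrt(1 - profile$ar_coeff^2)
    dev0 <- stats::rnorm(1, 0, profile$sigma_within)
    innov <- stats::rnorm(total, 0, innov_sd)
    dev <- as.numeric(stats::filter(innov, profile$ar_coeff,
                                    method = "recursive", init = dev0))
    attention <- clamp(mean_vec + dev, 0, 100)

    meditation <- clamp(stats::rnorm(total, 50, 12), 0, 100)

    is_task <- rep(rep(c(TRUE, FALSE), times = c(n_task, n_rest)), n_trials)
    trial_type <- rep(types, each = n_task + n_rest)
    trial_type[!is_task] <- "rest"
    shift_on <- as.numeric(trial_type == "attention")
    baseline <- band_baseline_meanlog(nb)
    shifts <- profile$band_shift[seq_len(nb)]
    bands <- vapply(seq_len(nb), function(b) {
      exp(stats::rnorm(total, baseline[b] + shifts[b] * shift_on, 0.55))
    }, numeric(total))
    colnames(bands) <- band_cols(nb)

    poor_signal <- ifelse(stats::runif(total) < profile$poor_signal_rate, 200L, 0L)

    out <- tibble::tibble(
      subject_id = profile$subject_id,
      session_index = as.integer(session_index),
      trial_index = rep(seq_len(n_trials), each = n_task + n_rest),
      trial_type = trial_type,
      t_in_trial = unlist(lapply(seq_len(n_trials), function(i) {
        c(seq_len(n_task), seq_len(n_rest)) - 1L
      })),
      poor_signal = poor_signal,
      attention = attention,
      meditation = meditation
    )
    out <- dplyr::bind_cols(out, tibble::as_tibble(bands))
    out$valid <- out$poor_signal == 0L
    out
  })
}

#' Generate one raw 512-sample epoch
#'
#' Simulates one second of the raw 12-bit signal, either clean (band-limited
#' 1/f-like noise at EEG-scale amplitude) or contaminated: a `blink` adds a
#' single large biphasic deflection of roughly 400 ms (raising the
#' peak-to-peak MinMax feature while leaving the high-frequency residual
#' energy low), `emg` adds a broadband high-frequency burst (raising ESF),
#' and `motion` adds a large slow swing plus broadband noise (raising both).
#'
#' @param kind One of `"clean"`, `"blink"`, `"emg"`, `"motion"`.
#' @param config A [sim_config()]; `sample_rate_raw` sets the epoch length.
#' @param seed Integer seed. The clean background for a given seed is shared
#'   by all kinds, so artifact epochs are paired with their clean
#'   counterpart.
#' @param amplitude Scale of the clean background (ADC counts, roughly the
#'   standard deviation of the clean signal); 0 gives an all-zero epoch for
#'   `kind = "clean"`.
#' @return Integer vector of `sample_rate_raw` ADC samples in the signed
#'   12-bit range.
#' @export
generate_raw_epoch <- function(kind, config = sim_config(), seed = 1, amplitude = 50) {
  kind <- match.arg(kind, c("clean", "blink", "emg", "motion"))
  stopifnot(inherits(config, "sim_config"))
  n <- config$sample_rate_raw
  with_seed(seed, {
    scale <- amplitude / 50
    # AR(1)-filtered white noise: spectrum falls off with frequency like
    # resting EEG; stationary sd about `amplitude`.
    base <- as.numeric(stats::filter(stats::rnorm(n + 64), 0.95, method = "recursive"))
    x <- (amplitude * 0.31) * base[-seq_len(64)]
    if (kind == "blink") {
      width <- round(0.4 * n) # ~400 ms biphasic deflection
      at <- floor(stats::runif(1, n * 0.2, n * 0.6))
      idx <- at + seq_len(width)
      x[idx] <- x[idx] + (900 * scale) * sin(2 * pi * seq_len(width) / width)
    } else if (kind == "emg") {
      width <- round(0.3 * n)
      at <- floor(stats::runif(1, n * 0.15, n * 0.65))
      idx <- at + seq_len(width)
      env <- 0.5 * (1 - cos(2 * pi * seq_len(width) / width))
      x[idx] <- x[idx] + stats::rnorm(width, 0, 4 * amplitude) * env
    } else if (kind == "motion") {
      x <- x + (30 * amplitude) * sin(pi * seq_len(n) / n) +
        stats::rnorm(n, 0, 2 * amplitude)
    }
    as.integer(round(clamp(x, -2048, 2047)))
  })
}

#' Generate a full cohort of synthetic sessions
#'
#' Runs the complete protocol (all sessions) for each profile. Per-session
#' seeds are derived deterministically from `config$seed` and the subject
#' identifier, so the same configuration always regenerates the same
#' cohort.
#'
#' @param profiles List of [subject_profile()] objects with distinct ids.
#' @param config A [sim_config()].
#' @return A tibble stacking every subject's sessions (see
#'   [generate_session()] for columns).
#' @export
generate_cohort <- function(profiles, config = sim_config()) {
  stopifnot(length(profiles) >= 1)
  if (inherits(profiles, "subject_profile")) profiles <- list(profiles)
  ids <- vapply(profiles, function(p) p$subject_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate subject_id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  sessions <- purrr::map(profiles, function(p) {
    purrr::map(seq_len(config$n_sessions), function(s) {
      seed <- (config$seed + 7919 * hash_id(p$subject_id) + 104729 * s) %% 2147483647
      generate_session(p, config, s, seed = seed)
    })
  })
  dplyr::bind_rows(purrr::flatten(sessions))
}

#' Bundled demonstration profiles
#'
#' Three contrasting synthetic participants: an `ideal` subject with
#' perfect, latency-free control (class means at 85/15 with little noise),
#' a `typical` subject resembling a participant who controls the indicator
#' well but not perfectly, and a `null` subject with no class separation at
#' all (chance-level control).
#'
#' @return Named list of [subject_profile()] objects.
#' @export
demo_profiles <- function() {
  list(
    ideal = subject_profile(
      "ideal", mu_att = 85, mu_non = 15, sigma_within = 4,
      ar_coeff = 0.3, tau_on = 0, tau_off = 0,
      artifact_rates = c(blink = 0, emg = 0, motion = 0), poor_signal_rate = 0
    ),
    typical = subject_profile("typical"),
    null = subject_profile(
      "null", mu_att = 50.001, mu_non = 49.999, sigma_within = 15,
      ar_coeff = 0.6, tau_on = 0, tau_off = 0,
      band_shift = rep(0, 8)
    )
  )
}

#' Split a cohort tibble into per-subject session lists
#'
#' @param cohort Tibble from [generate_cohort()] or [read_session_csv()].
#' @return Named list (by subject) of lists of single-session tibbles.
#' @export
cohort_sessions <- function(cohort) {
  lapply(split(cohort, cohort$subject_id), function(subj) {
    unname(split(subj, subj$session_index))
  })
}
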