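# Trial- and subject-level attentional metrics.
#
# The goal of a trial is to hold the attention indicator strictly above
# (attention trials) or strictly below (non-attention trials) a threshold,
# 50% by default. Seconds flagged invalid by the artifact screen are
# excluded from every metric.

#' Extract the task-half trials of a session
#'
#' @param session Session tibble (one row per second).
#' @return List of single-trial tibbles (task halves only, rest rows
#'   dropped), ordered by trial index.
#' @export
session_trials <- function(session) {
  task <- session[session$trial_type != "rest", , drop = FALSE]
  unname(split(task, task$trial_index))
}

#' Interquartile-range outlier filter
#'
#' Keeps the values inside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`, with quartiles
#' computed by linear interpolation of the order statistics
#' ([stats::quantile()] type 7). Input order is preserved, and refiltering
#' the output returns it unchanged.
#'
#' @param values Numeric vector; `NA`s are dropped first.
#' @return The retained values, in their original order. Fewer than 4
#'   values are returned unfiltered with a warning.
#' @export
#' @examples
#' iqr_filter(c(1, 2, 3, 4, 100)) # drops 100
iqr_filter <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 4) {
    warning("fewer than 4 values: returned unfiltered", call. = FALSE)
    return(values)
  }
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  values[values >= q[1] - 1.5 * iqr & values <= q[2] + 1.5 * iqr]
}

trial_goal_mask <- function(attention, trial_type, threshold) {
  if (trial_type == "attention") attention > threshold else attention < threshold
}

trial_type_of <- function(trial) {
  ty <- unique(trial$trial_type)
  if (length(ty) != 1 || !ty %in% c("attention", "non_attention")) {
    stop("trial must hold exactly one task trial type, got: ",
         paste(ty, collapse = ", "), call. = FALSE)
  }
  ty
}

#' Successful score of a trial
#'
#' Percentage of the valid seconds on the goal side of the threshold
#' (strictly above for attention trials, strictly below for non-attention
#' ones; a second exactly at the threshold does not meet the goal).
#'
#' @param trial Single-trial tibble from [session_trials()].
#' @param threshold Attention threshold (percent), default 50.
#' @return Percentage in `[0, 100]`, or `NA` with a warning when the trial
#'   has no valid seconds.
#' @export
successful_score <- function(trial, threshold = 50) {
  v <- trial[trial$valid, , drop = FALSE]
  if (nrow(v) == 0) {
    warning("trial has no valid samples; successful score is NA", call. = FALSE)
    return(NA_real_)
  }
  goal <- trial_goal_mask(v$attention, trial_type_of(trial), threshold)
  100 * sum(goal) / nrow(v)
}

#' Initial time of a trial
#'
#' Seconds elapsed from trial onset until the attention level first reaches
#' the goal side of the threshold: the 0-based time of the first valid
#' goal-side sample plus one, so a trial that starts on the goal side has
#' an initial time of 1 s.
#'
#' @inheritParams successful_score
#' @return Seconds, or `NA` if the goal side is never reached.
#' @export
initial_time <- function(trial, threshold = 50) {
  v <- trial[trial$valid, , drop = FALSE]
  if (nrow(v) == 0) return(NA_real_)
  goal <- trial_goal_mask(v$attention, trial_type_of(trial), threshold)
  if (!any(goal)) return(NA_real_)
  v$t_in_trial[which(goal)[1]] + 1
}

#' Sustained time of a trial
#'
#' Mean length of the maximal runs of consecutive valid seconds on the
#' goal side of the threshold, i.e. how long on average the subject held
#' the required state without crossing back.
#'
#' @inheritParams successful_score
#' @return Seconds, or `NA` if the goal side is never reached.
#' @export
sustained_time <- function(trial, threshold = 50) {
  v <- trial[trial$valid, , drop = FALSE]
  if (nrow(v) == 0) return(NA_real_)
  goal <- trial_goal_mask(v$attention, trial_type_of(trial), threshold)
  if (!any(goal)) return(NA_real_)
  r <- rle(goal)
  mean(r$lengths[r$values])
}

#' Per-condition summary of a subject's sessions
#'
#' Pools the successful score over all valid seconds of each condition and
#' averages the initial and sustained times over trials; standard errors
#' are sample SD / sqrt(number of contributing trials). Trials where a
#' metric is absent (goal never reached, no valid seconds) are excluded
#' from that metric's average but still counted.
#'
#' @param sessions A session tibble, a list of session tibbles, or a
#'   cohort tibble restricted to one subject.
#' @param threshold Attention threshold (percent).
#' @return Tibble with one row per condition: `subject_id`, `condition`,
#'   `ss`, `t_i_mean`, `t_i_se`, `t_s_mean`, `t_s_se`, `n_trials`,
#'   `n_trials_t_i`, `n_trials_t_s`. A single contributing trial gives an
#'   `NA` standard error.
#' @export
subject_summary <- function(sessions, threshold = 50) {
  data <- if (is.data.frame(sessions)) sessions else dplyr::bind_rows(sessions)
  stopifnot(length(unique(data$subject_id)) == 1)
  trials <- unlist(
    lapply(unname(split(data, data$session_index)), session_trials),
    recursive = FALSE
  )
  se_of <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
  purrr::map_dfr(c("attention", "non_attention"), function(cond) {
    sel <- trials[vapply(trials, trial_type_of, character(1)) == cond]
    if (length(sel) == 0) {
      warning("no trials for condition ", cond, call. = FALSE)
      return(tibble::tibble(
        subject_id = data$subject_id[1], condition = cond,
        ss = NA_real_, t_i_mean = NA_real_, t_i_se = NA_real_,
        t_s_mean = NA_real_, t_s_se = NA_real_,
        n_trials = 0L, n_trials_t_i = 0L, n_trials_t_s = 0L
      ))
    }
    valid_rows <- dplyr::bind_rows(sel)
    valid_rows <- valid_rows[valid_rows$valid, , drop = FALSE]
    goal <- trial_goal_mask(valid_rows$attention, cond, threshold)
    t_i <- vapply(sel, initial_time, numeric(1), threshold = threshold)
    t_s <- vapply(sel, sustained_time, numeric(1), threshold = threshold)
    tibble::tibble(
      subject_id = data$subject_id[1], condition = cond,
      ss = 100 * sum(goal) / nrow(valid_rows),
      t_i_mean = mean(t_i, na.rm = TRUE), t_i_se = se_of(t_i[!is.na(t_i)]),
      t_s_mean = mean(t_s, na.rm = TRUE), t_s_se = se_of(t_s[!is.na(t_s)]),
      n_trials = length(sel),
      n_trials_t_i = sum(!is.na(t_i)),
      n_trials_t_s = sum(!is.na(t_s))
    )
  })
}

#' Averaged feature vector of a trial
#'
#' Reduces a trial (or a window of it) to the per-trial averages used by
#' the classifier. Each signal is outlier-filtered with [iqr_filter()]
#' over the selected valid seconds before averaging. The three feature
#' sets are: `set1` the averaged attention alone; `set2` attention plus
#' the theta/beta ratio (computed as mean(theta) / mean(beta) after
#' filtering each series); `set3` attention plus all raw band averages
#' (meditation is never included).
#'
#' @param trial Single-trial tibble.
#' @param feature_set `"set1"`, `"set2"` or `"set3"`.
#' @param window Optional `c(start_s, length_s)` window (0-based start
#'   within the task half); `NULL` uses the whole trial.
#' @return Named numeric feature vector, or `NULL` when no valid seconds
#'   remain in the window.
#' @export
trial_average_features <- function(trial, feature_set = c("set1", "set2", "set3"),
                                   window = NULL) {
  feature_set <- match.arg(feature_set)
  v <- trial[trial$valid, , drop = FALSE]
  if (!is.null(window)) {
    stopifnot(length(window) == 2, window[1] >= 0, window[2] >= 1)
    if (window[1] + window[2] > max(trial$t_in_trial) + 1) {
      window[2] <- max(trial$t_in_trial) + 1 - window[1]
    }
    if (window[2] < 1) stop("window lies outside the trial", call. = FALSE)
    v <- v[v$t_in_trial >= window[1] & v$t_in_trial < window[1] + window[2], ,
           drop = FALSE]
  }
  if (nrow(v) == 0) return(NULL)
  fmean <- function(x) mean(iqr_filter_quiet(x))
  out <- c(attention = fmean(v$attention))
  if (feature_set == "set2") {
    cb <- canonical_band_series(v)
    out <- c(out, theta_beta = fmean(cb$theta) / fmean(cb$beta))
  } else if (feature_set == "set3") {
    nb <- n_bands_of(v)
    bands <- vapply(band_cols(nb), function(col) fmean(v[[col]]), numeric(1))
    out <- c(out, bands)
  }
  out
}

# iqr_filter without the small-n warning, for inner loops where short
# windows are expected.
iqr_filter_quiet <- function(values) {
  suppressWarnings(iqr_filter(values))
}

#' Per-trial matrix of outlier-filtered means
#'
#' One row per task trial with the trial's filtered mean attention, the
#' canonical band means (delta, theta, alpha, beta, gamma; split sensor
#' bands are summed) and the theta/beta ratio. This is the 70-row (full
#' protocol) input to the per-subject rank-sum analysis.
#'
#' @inheritParams subject_summary
#' @return Tibble with columns `subject_id`, `session_index`,
#'   `trial_index`, `trial_type`, `mean_attention`, `delta`, `theta`,
#'   `alpha`, `beta`, `gamma`, `theta_beta`.
#' @export
trial_matrix <- function(sessions) {
  data <- if (is.data.frame(sessions)) sessions else dplyr::bind_rows(sessions)
  trials <- unlist(
    lapply(unname(split(data, data$session_index)), session_trials),
    recursive = FALSE
  )
  purrr::map_dfr(trials, function(tr) {
    v <- tr[tr$valid, , drop = FALSE]
    base <- tibble::tibble(
      subject_id = tr$subject_id[1],
      session_index = tr$session_index[1],
      trial_index = tr$trial_index[1],
      trial_type = trial_type_of(tr)
    )
    if (nrow(v) == 0) {
      return(dplyr::bind_cols(base, tibble::tibble(
        mean_attention = NA_real_, delta = NA_real_, theta = NA_real_,
        alpha = NA_real_, beta = NA_real_, gamma = NA_real_,
        theta_beta = NA_real_
      )))
    }
    cb <- canonical_band_series(v)
    fmean <- function(x) mean(iqr_filter_quiet(x))
    dplyr::bind_cols(base, tibble::tibble(
      mean_attention = fmean(v$attention),
      delta = fmean(cb$delta), theta = fmean(cb$theta),
      alpha = fmean(cb$alpha), beta = fmean(cb$beta), gamma = fmean(cb$gamma),
      theta_beta = fmean(cb$theta) / fmean(cb$beta)
    ))
  })
}
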