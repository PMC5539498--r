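# Scanning-access characterization: windowed classifier evaluation,
# classifier-threshold latencies, false-positive pulse counts, the
# dwell-time feasibility constraints, the optimal window search and the
# Wolpaw information transfer rate.
#
# Temporal model of one selection on a board of N icons scanned with
# period t_scan: the user raises attention (latency t_on), must hold it
# for the dwell window t_w, then releases it (latency t_off) before the
# next icon highlights. Feasibility requires
#   t_scan = (mean t_on + 1.64 sd t_on) + t_w        (95% of on-latencies),
#   t_w    > mean t_off + 1.64 sd t_off              (95% of off-latencies),
#   Np * (N_icons - 1) * t_scan < T_non_att          (false-pulse budget),
# where Np is the mean number of supra-threshold pulses of length >= t_w
# in a 30 s non-attention trial.

#' Evaluation protocol for the windowed analysis
#'
#' Each session's 14 trials are split, balanced between classes, into 6
#' training, 4 validation and 4 test trials; the split is redrawn
#' `repeats` times and results averaged. The dwell-window grid is scanned
#' ascending and capped at 15 s because the cohort's average sustained
#' time is around 14 s.
#'
#' @param n_train,n_validation,n_test Trials per split; must sum to the
#'   session's trial count and be even.
#' @param repeats Number of random splits per session (default 10).
#' @param t_w_grid Candidate dwell windows in seconds (default 2:15).
#' @param seed Integer seed for the split draws.
#' @return An object of class `eval_protocol`.
#' @export
eval_protocol <- function(n_train = 6, n_validation = 4, n_test = 4,
                          repeats = 10, t_w_grid = 2:15, seed = 1) {
  stopifnot(
    n_train %% 2 == 0, n_validation %% 2 == 0, n_test %% 2 == 0,
    n_train >= 2, n_validation >= 2, n_test >= 2,
    repeats >= 1, length(t_w_grid) >= 1, all(t_w_grid >= 1)
  )
  structure(
    list(
      n_train = as.integer(n_train), n_validation = as.integer(n_validation),
      n_test = as.integer(n_test), repeats = as.integer(repeats),
      t_w_grid = as.integer(sort(t_w_grid)), seed = as.integer(seed)
    ),
    class = "eval_protocol"
  )
}

#' Training features from the first seconds of a trial
#'
#' The windowed analysis trains the classifier on the first `t_w` seconds
#' of each trial instead of the whole 30 s.
#'
#' @param trial Single-trial tibble.
#' @param t_w Window length in seconds (must not exceed the trial).
#' @param feature_set `"set1"`, `"set2"` or `"set3"`.
#' @return Named feature vector (see [trial_average_features()]), or
#'   `NULL` when the window holds no valid seconds.
#' @export
train_window_features <- function(trial, t_w, feature_set = "set1") {
  stopifnot(t_w >= 1, t_w <= max(trial$t_in_trial) + 1)
  trial_average_features(trial, feature_set, window = c(0, t_w))
}

# Per-second feature matrix of a trial's valid seconds, for projecting the
# running stream through a fitted discriminant. No outlier filtering here:
# single-second vectors are projected as they arrive.
per_second_features <- function(trial, feature_set = c("set1", "set2", "set3")) {
  feature_set <- match.arg(feature_set)
  v <- trial[trial$valid, , drop = FALSE]
  if (nrow(v) == 0) {
    return(list(t = integer(0), x = matrix(numeric(0), 0, 0)))
  }
  x <- switch(feature_set,
    set1 = cbind(attention = v$attention),
    set2 = {
      cb <- canonical_band_series(v)
      cbind(attention = v$attention, theta_beta = cb$theta / cb$beta)
    },
    set3 = {
      nb <- n_bands_of(v)
      cbind(attention = v$attention, as.matrix(v[band_cols(nb)]))
    }
  )
  list(t = v$t_in_trial, x = x)
}

# Time (0-based second + 1) of the first valid second whose projection is
# strictly above (direction = "on") or below ("off") the model threshold;
# NA when the stream never crosses.
crossing_time <- function(trial, model, feature_set, direction = c("on", "off")) {
  direction <- match.arg(direction)
  ps <- per_second_features(trial, feature_set)
  if (length(ps$t) == 0) return(NA_real_)
  sc <- project_lda(model, ps$x)
  hit <- if (direction == "on") sc > model$threshold else sc < model$threshold
  if (!any(hit)) return(NA_real_)
  ps$t[which(hit)[1]] + 1
}

#' Threshold-triggered evaluation features of a trial
#'
#' Mirrors online use: per-second feature vectors are projected in trial
#' order and the first second whose projection exceeds the classifier
#' threshold starts a window of `t_w` seconds (truncated at trial end);
#' the trial's features are the averaged window. When no second crosses,
#' the features are absent and the trial is predicted non-attention.
#'
#' @param trial Single-trial tibble.
#' @param model Fitted `attn_lda` model.
#' @param t_w Window length (seconds).
#' @param feature_set Feature set name.
#' @return List with `features` (or `NULL`), `window_start` (0-based
#'   second, or `NA`) and `prediction`.
#' @export
eval_window_features <- function(trial, model, t_w, feature_set = "set1") {
  ps <- per_second_features(trial, feature_set)
  if (length(ps$t) == 0) {
    return(list(features = NULL, window_start = NA_real_,
                prediction = model$negative))
  }
  sc <- project_lda(model, ps$x)
  hit <- which(sc > model$threshold)
  if (length(hit) == 0) {
    return(list(features = NULL, window_start = NA_real_,
                prediction = model$negative))
  }
  t0 <- ps$t[hit[1]]
  feats <- trial_average_features(trial, feature_set, window = c(t0, t_w))
  pred <- if (is.null(feats)) {
    model$negative
  } else if (project_lda(model, feats) > model$threshold) {
    model$positive
  } else {
    model$negative
  }
  list(features = feats, window_start = t0, prediction = pred)
}

#' Classifier-threshold switching latencies
#'
#' Estimates the connection latency t_on (time from attention-trial onset
#' to the first second projecting above the classifier threshold) and the
#' disconnection latency t_off (time from non-attention-trial onset to the
#' first second projecting below it). Trials that never cross are excluded
#' from the statistics but counted.
#'
#' @param trials List of single-trial tibbles containing both trial types.
#' @param model Fitted `attn_lda` model.
#' @param feature_set Feature set name.
#' @return List with `t_on_mean`, `t_on_sd`, `t_off_mean`, `t_off_sd`
#'   (sample SD; 0 by convention for a single contributing trial),
#'   `n_on`, `n_off`, `n_on_excluded`, `n_off_excluded`.
#' @export
latency_stats <- function(trials, model, feature_set = "set1") {
  types <- vapply(trials, trial_type_of, character(1))
  if (!all(c("attention", "non_attention") %in% types)) {
    stop("both trial types are required to estimate latencies", call. = FALSE)
  }
  t_on <- vapply(trials[types == "attention"], crossing_time, numeric(1),
                 model = model, feature_set = feature_set, direction = "on")
  t_off <- vapply(trials[types == "non_attention"], crossing_time, numeric(1),
                  model = model, feature_set = feature_set, direction = "off")
  summarize_latencies(t_on, t_off)
}

sd0 <- function(x) if (length(x) > 1) stats::sd(x) else 0

summarize_latencies <- function(t_on, t_off) {
  on <- t_on[!is.na(t_on)]
  off <- t_off[!is.na(t_off)]
  if (length(on) == 0 && length(t_on) > 0) {
    stop("no attention trial ever crossed the classifier threshold", call. = FALSE)
  }
  if (length(off) == 0 && length(t_off) > 0) {
    stop("no non-attention trial ever crossed the classifier threshold",
         call. = FALSE)
  }
  list(
    t_on_mean = mean(on), t_on_sd = sd0(on),
    t_off_mean = mean(off), t_off_sd = sd0(off),
    n_on = length(on), n_off = length(off),
    n_on_excluded = sum(is.na(t_on)), n_off_excluded = sum(is.na(t_off))
  )
}

#' Count false-positive pulses in a non-attention trial
#'
#' A pulse is a maximal run of consecutive valid seconds whose projection
#' exceeds the classifier threshold; pulses of length at least `t_w` would
#' select an unwanted icon during scanning.
#'
#' @inheritParams eval_window_features
#' @return Number of pulses of length >= `t_w`.
#' @export
count_pulses <- function(trial, model, t_w, feature_set = "set1") {
  if (trial_type_of(trial) != "non_attention") {
    stop("pulse counting is defined on non-attention trials", call. = FALSE)
  }
  ps <- per_second_features(trial, feature_set)
  if (length(ps$t) == 0) return(0L)
  above <- project_lda(model, ps$x) > model$threshold
  r <- rle(above)
  sum(r$values & r$lengths >= t_w)
}

#' Minimal scanning period for a dwell window
#'
#' `t_scan = (mean t_on + 1.64 sd t_on) + t_w`: the period covering 95% of
#' the on-latencies plus the dwell window itself. Strictly increasing in
#' every argument.
#'
#' @param t_on_mean,t_on_sd Mean and SD of the on-latency (seconds).
#' @param t_w Dwell window (seconds).
#' @return Scanning period in seconds.
#' @export
#' @examples
#' tscan_min(3.3, 2, 4) # 10.58
tscan_min <- function(t_on_mean, t_on_sd, t_w) {
  t_on_mean + 1.64 * t_on_sd + t_w
}

#' Feasibility of a dwell window on a scanning board
#'
#' A dwell window is feasible iff it strictly exceeds the 95% off-latency
#' bound (`t_w > mean t_off + 1.64 sd t_off`) and the expected
#' false-pulse cost fits in the non-attention budget
#' (`np * (n_icons - 1) * t_scan < t_non_att`); both inequalities strict.
#'
#' @param t_w Dwell window (seconds).
#' @param t_off_mean,t_off_sd Off-latency statistics (seconds).
#' @param np Mean supra-threshold pulses (length >= `t_w`) per
#'   non-attention trial.
#' @param n_icons Number of icons on the board (>= 2).
#' @param t_scan Scanning period (seconds), e.g. from [tscan_min()].
#' @param t_non_att Non-attention trial length (seconds, default 30).
#' @return Logical.
#' @export
access_feasible <- function(t_w, t_off_mean, t_off_sd, np, n_icons, t_scan,
                            t_non_att = 30) {
  stopifnot(n_icons >= 2)
  (t_w > t_off_mean + 1.64 * t_off_sd) &
    (np * (n_icons - 1) * t_scan < t_non_att)
}

#' Wolpaw information transfer rate
#'
#' Bits per selection for an N-choice channel with accuracy P:
#' `B = log2(N) + P log2(P) + (1 - P) log2((1 - P) / (N - 1))`, defined by
#' continuity as `log2(N)` at P = 1; the rate is `B * 60 / t_select`
#' bits/min. Accuracies at or below chance are clamped to 0 bits with a
#' warning.
#'
#' @param accuracy Classification accuracy as a fraction in (0, 1].
#' @param t_select Time per selection (seconds).
#' @param n_choices Number of choices (default 2: attention high/low).
#' @return Information transfer rate in bits/min.
#' @export
#' @examples
#' itr(1, 2)    # 30 bits/min
#' itr(0.9, 2)  # ~15.92 bits/min
itr <- function(accuracy, t_select, n_choices = 2) {
  stopifnot(accuracy > 0, accuracy <= 1, t_select > 0, n_choices >= 2)
  if (accuracy <= 1 / n_choices) {
    warning("accuracy at or below chance: ITR clamped to 0", call. = FALSE)
    return(0)
  }
  p <- accuracy
  bits <- if (p == 1) {
    log2(n_choices)
  } else {
    log2(n_choices) + p * log2(p) + (1 - p) * log2((1 - p) / (n_choices - 1))
  }
  bits * 60 / t_select
}

balanced_split <- function(att_idx, non_idx, protocol) {
  a <- sample(att_idx)
  n <- sample(non_idx)
  h <- function(k) k / 2
  list(
    train = c(a[seq_len(h(protocol$n_train))],
              n[seq_len(h(protocol$n_train))]),
    validation = c(a[h(protocol$n_train) + seq_len(h(protocol$n_validation))],
                   n[h(protocol$n_train) + seq_len(h(protocol$n_validation))]),
    test = c(a[h(protocol$n_train) + h(protocol$n_validation) +
                 seq_len(h(protocol$n_test))],
             n[h(protocol$n_train) + h(protocol$n_validation) +
                 seq_len(h(protocol$n_test))])
  )
}

#' Windowed evaluation of one session at a fixed dwell window
#'
#' Repeats a balanced train/validation/test split of the session's trials
#' (`repeats` times), fits the discriminant on the first `t_w` seconds of
#' the training trials, measures validation and test accuracy with
#' threshold-triggered windows, estimates the classifier-threshold
#' latencies and the false-pulse count on the validation trials, and
#' averages over the repeats (latencies are pooled across repeats before
#' taking mean and SD).
#'
#' @param session Session tibble whose trial count matches the protocol.
#' @param t_w Dwell window (seconds).
#' @param feature_set Feature set name.
#' @param protocol An [eval_protocol()].
#' @return List with `t_w`, `feature_set`, `val_accuracy`, `test_accuracy`
#'   (percent), `latency` (pooled stats as in [latency_stats()]),
#'   `np_mean`, `t_on_values`, `t_off_values`, `n_repeats_used`.
#' @export
session_evaluation <- function(session, t_w, feature_set = "set1",
                               protocol = eval_protocol()) {
  trials <- session_trials(session)
  n_needed <- protocol$n_train + protocol$n_validation + protocol$n_test
  if (length(trials) != n_needed) {
    stop("session has ", length(trials), " trials but the protocol needs ",
         n_needed, call. = FALSE)
  }
  types <- vapply(trials, trial_type_of, character(1))
  att_idx <- which(types == "attention")
  non_idx <- which(types == "non_attention")
  if (length(att_idx) != length(non_idx)) {
    stop("session is unbalanced between trial types", call. = FALSE)
  }

  acc <- function(split_trials, model) {
    preds <- vapply(split_trials, function(tr) {
      eval_window_features(tr, model, t_w, feature_set)$prediction
    }, character(1))
    truth <- vapply(split_trials, trial_type_of, character(1))
    100 * mean(preds == truth)
  }

  val_acc <- test_acc <- np <- numeric(0)
  t_on_all <- t_off_all <- numeric(0)
  with_seed(protocol$seed, {
    for (r in seq_len(protocol$repeats)) {
      sp <- balanced_split(att_idx, non_idx, protocol)
      xs <- lapply(trials[sp$train], train_window_features,
                   t_w = t_w, feature_set = feature_set)
      keep <- !vapply(xs, is.null, logical(1))
      y <- types[sp$train][keep]
      if (length(unique(y)) < 2) next # split unusable after validity gating
      model <- fit_lda(do.call(rbind, xs[keep]), y)

      val_acc <- c(val_acc, acc(trials[sp$validation], model))
      test_acc <- c(test_acc, acc(trials[sp$test], model))

      vtypes <- types[sp$validation]
      t_on_all <- c(t_on_all, vapply(
        trials[sp$validation][vtypes == "attention"], crossing_time,
        numeric(1), model = model, feature_set = feature_set, direction = "on"
      ))
      t_off_all <- c(t_off_all, vapply(
        trials[sp$validation][vtypes == "non_attention"], crossing_time,
        numeric(1), model = model, feature_set = feature_set, direction = "off"
      ))
      np <- c(np, mean(vapply(
        trials[sp$validation][vtypes == "non_attention"], count_pulses,
        numeric(1), model = model, t_w = t_w, feature_set = feature_set
      )))
    }
  })
  if (length(val_acc) == 0) {
    stop("no usable split: training windows held no valid data", call. = FALSE)
  }
  list(
    t_w = t_w, feature_set = feature_set,
    val_accuracy = mean(val_acc), test_accuracy = mean(test_acc),
    latency = summarize_latencies(t_on_all, t_off_all),
    np_mean = mean(np),
    t_on_values = t_on_all, t_off_values = t_off_all,
    n_repeats_used = length(val_acc)
  )
}

#' First feasible dwell window in an evaluation table
#'
#' Scans the rows of a per-window evaluation table in ascending `t_w`
#' order and returns the first row satisfying both feasibility
#' constraints; used by [optimal_window()] and directly applicable to a
#' table of published or precomputed quantities.
#'
#' @param eval_tbl Tibble with columns `t_w`, `t_on_mean`, `t_on_sd`,
#'   `t_off_mean`, `t_off_sd`, `np`.
#' @param n_icons Number of icons on the board.
#' @param t_non_att Non-attention budget (seconds).
#' @return List with `index` (row of the first feasible window, or `NA`),
#'   `t_w_opt`, `t_scan`, `feasible`.
#' @export
select_optimal_tw <- function(eval_tbl, n_icons = 4, t_non_att = 30) {
  eval_tbl <- eval_tbl[order(eval_tbl$t_w), , drop = FALSE]
  for (i in seq_len(nrow(eval_tbl))) {
    row <- eval_tbl[i, ]
    t_scan <- tscan_min(row$t_on_mean, row$t_on_sd, row$t_w)
    if (access_feasible(row$t_w, row$t_off_mean, row$t_off_sd, row$np,
                        n_icons, t_scan, t_non_att)) {
      return(list(index = i, t_w_opt = row$t_w, t_scan = t_scan, feasible = TRUE))
    }
  }
  list(index = NA_integer_, t_w_opt = NA_real_, t_scan = NA_real_, feasible = FALSE)
}

#' Optimal dwell window and access parameters for a subject
#'
#' Scans the dwell-window grid ascending; at each candidate the subject's
#' sessions are evaluated (validation/test accuracy, pooled latencies,
#' false-pulse count averaged over sessions and repeats) and the first
#' window satisfying both feasibility constraints is optimal. The reported
#' accuracy comes from the test set at that window, and the information
#' transfer rate uses the test accuracy with the dwell window as
#' selection time. If no window in the grid is feasible, the largest one
#' is reported with `feasible = FALSE` (the infeasibility marker).
#'
#' @param sessions List of session tibbles (or a one-subject cohort
#'   tibble).
#' @param feature_set Feature set name.
#' @param n_icons Number of icons on the board (default 4).
#' @param protocol An [eval_protocol()].
#' @param t_non_att Non-attention budget per trial (seconds).
#' @return One-row tibble: `subject_id`, `feature_set`, `t_w_opt`,
#'   `feasible`, `accuracy`, `val_accuracy`, `t_scan`, `np`,
#'   `t_on_mean`, `t_on_sd`, `t_off_mean`, `t_off_sd`, `n_icons`, `itr`.
#' @export
optimal_window <- function(sessions, feature_set = "set1", n_icons = 4,
                           protocol = eval_protocol(), t_non_att = 30) {
  if (is.data.frame(sessions)) {
    sessions <- unname(split(sessions, sessions$session_index))
  }
  stopifnot(length(sessions) >= 1)
  subject <- sessions[[1]]$subject_id[1]

  eval_at <- function(t_w) {
    evals <- lapply(sessions, session_evaluation, t_w = t_w,
                    feature_set = feature_set, protocol = protocol)
    lat <- summarize_latencies(
      unlist(lapply(evals, `[[`, "t_on_values")),
      unlist(lapply(evals, `[[`, "t_off_values"))
    )
    list(
      t_w = t_w,
      val_accuracy = mean(vapply(evals, `[[`, numeric(1), "val_accuracy")),
      test_accuracy = mean(vapply(evals, `[[`, numeric(1), "test_accuracy")),
      np = mean(vapply(evals, `[[`, numeric(1), "np_mean")),
      latency = lat
    )
  }

  chosen <- NULL
  feasible <- FALSE
  for (t_w in protocol$t_w_grid) {
    ev <- eval_at(t_w)
    t_scan <- tscan_min(ev$latency$t_on_mean, ev$latency$t_on_sd, t_w)
    ok <- access_feasible(t_w, ev$latency$t_off_mean, ev$latency$t_off_sd,
                          ev$np, n_icons, t_scan, t_non_att)
    chosen <- c(ev, list(t_scan = t_scan))
    if (ok) {
      feasible <- TRUE
      break
    }
  }

  rate <- if (chosen$test_accuracy > 50) {
    itr(chosen$test_accuracy / 100, chosen$t_w)
  } else {
    0
  }
  tibble::tibble(
    subject_id = subject,
    feature_set = feature_set,
    t_w_opt = chosen$t_w,
    feasible = feasible,
    accuracy = chosen$test_accuracy,
    val_accuracy = chosen$val_accuracy,
    t_scan = chosen$t_scan,
    np = chosen$np,
    t_on_mean = chosen$latency$t_on_mean,
    t_on_sd = chosen$latency$t_on_sd,
    t_off_mean = chosen$latency$t_off_mean,
    t_off_sd = chosen$latency$t_off_sd,
    n_icons = as.integer(n_icons),
    itr = rate
  )
}

#' Group-level summary of an access-parameter table
#'
#' From a long table of per-subject, per-feature-set access parameters
#' (with the best set flagged per subject), recomputes each subject's
#' scanning period from its latency statistics and best-set dwell window
#' and reports per-group means of the best-set accuracy and of the
#' scanning period.
#'
#' @param access_tbl Tibble with columns `subject`, `group`, `set`,
#'   `accuracy`, `t_w_opt`, `best`, `t_on_mean`, `t_on_sd`, `t_off_mean`,
#'   `t_off_sd` (latencies repeated across a subject's rows).
#' @return Tibble with `group`, `n_subjects`, `mean_best_accuracy`,
#'   `mean_t_scan`.
#' @export
access_report_summary <- function(access_tbl) {
  best <- access_tbl[access_tbl$best, , drop = FALSE]
  stopifnot(!anyDuplicated(best$subject))
  best$t_scan <- tscan_min(best$t_on_mean, best$t_on_sd, best$t_w_opt)
  best |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n_subjects = dplyr::n(),
      mean_best_accuracy = mean(.data$accuracy),
      mean_t_scan = mean(.data$t_scan),
      .groups = "drop"
    )
}
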