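# A 1-D model with threshold 50 on the attention value, for constructed
# traces.
threshold_model <- function() {
  fit_lda(c(40, 45, 55, 60), rep(c("non_attention", "attention"), c(2, 2)))
}

test_that("training windows are prefixes of the trial", {
  ramp <- make_trial(seq(10, 97, 3))
  full <- train_window_features(ramp, 30, "set1")
  expect_equal(full, trial_average_features(ramp, "set1"))
  expect_lt(train_window_features(ramp, 2, "set1")["attention"],
            train_window_features(ramp, 15, "set1")["attention"])
  flat <- make_trial(rep(64, 30))
  expect_equal(train_window_features(flat, 2, "set1"),
               train_window_features(flat, 15, "set1"))
  expect_error(train_window_features(flat, 31, "set1"))
})

test_that("evaluation windows start at the first supra-threshold projection", {
  m <- threshold_model()
  tr <- make_trial(c(rep(40, 7), rep(c(80, 70), 6), rep(40, 11)), "attention")
  out <- eval_window_features(tr, m, 4, "set1")
  expect_equal(out$window_start, 7)
  expect_equal(unname(out$features["attention"]), mean(c(80, 70, 80, 70)))
  expect_identical(out$prediction, "attention")
  # never crossing: absent features, default prediction
  low <- eval_window_features(make_trial(rep(30, 30), "non_attention"), m, 4, "set1")
  expect_null(low$features)
  expect_true(is.na(low$window_start))
  expect_identical(low$prediction, "non_attention")
  # window truncated at trial end
  late <- make_trial(c(rep(40, 28), 80, 80), "attention")
  out2 <- eval_window_features(late, m, 10, "set1")
  expect_equal(out2$window_start, 28)
  expect_equal(unname(out2$features["attention"]), 80)
})

test_that("latencies are measured against the classifier threshold", {
  m <- threshold_model()
  trials <- list(
    make_trial(c(40, 40, 80, rep(80, 27)), "attention"),
    make_trial(c(80, rep(80, 29)), "attention"),
    make_trial(c(80, 80, 40, rep(40, 27)), "non_attention"),
    make_trial(c(40, rep(40, 29)), "non_attention")
  )
  st <- latency_stats(trials, m, "set1")
  expect_equal(st$t_on_mean, mean(c(3, 1)))
  expect_equal(st$t_off_mean, mean(c(3, 1)))
  expect_equal(st$n_on, 2)
  # a never-crossing trial is excluded but counted
  st2 <- latency_stats(c(trials, list(make_trial(rep(30, 30), "attention"))),
                       m, "set1")
  expect_equal(st2$t_on_mean, 2)
  expect_equal(st2$n_on_excluded, 1)
  # single contributing trial: SD 0 by convention
  st3 <- latency_stats(trials[c(2, 4)], m, "set1")
  expect_equal(st3$t_on_sd, 0)
  expect_error(latency_stats(trials[1:2], m, "set1"), "both trial types")
})

test_that("pulse counting obeys the run-length rule and is monotone in t_w", {
  m <- threshold_model()
  runs <- c(rep(80, 3), rep(30, 2), rep(80, 5), rep(30, 2), rep(80, 7),
            rep(30, 11))
  tr <- make_trial(runs, "non_attention")
  expect_equal(count_pulses(tr, m, 5, "set1"), 2) # runs {3, 5, 7}
  expect_equal(count_pulses(tr, m, 1, "set1"), 3)
  expect_equal(count_pulses(tr, m, 8, "set1"), 0)
  expect_equal(count_pulses(tr, m, 31, "set1"), 0)
  expect_equal(count_pulses(make_trial(rep(10, 30), "non_attention"), m, 2), 0)
  expect_error(count_pulses(make_trial(rep(80, 30), "attention"), m, 2),
               "non-attention")
  # exact monotonicity on arbitrary traces
  set.seed(15)
  for (i in 1:10) {
    tri <- make_trial(runif(30, 0, 100), "non_attention")
    np <- vapply(1:16, function(tw) count_pulses(tri, m, tw, "set1"), numeric(1))
    expect_true(all(diff(np) <= 0))
  }
})

test_that("the scanning-period formula and feasibility constraints are strict", {
  expect_equal(tscan_min(3.3, 2, 4), 10.58)
  expect_equal(round(tscan_min(3.3, 2, 4), 1), 10.6)
  expect_equal(tscan_min(2.43, 0.8, 8), 11.742)
  expect_equal(tscan_min(0, 0, 7), 7)
  # strictly increasing in each argument
  expect_gt(tscan_min(3.4, 2, 4), tscan_min(3.3, 2, 4))
  expect_gt(tscan_min(3.3, 2.1, 4), tscan_min(3.3, 2, 4))
  expect_gt(tscan_min(3.3, 2, 5), tscan_min(3.3, 2, 4))

  expect_true(access_feasible(5, 2, 1, np = 0, n_icons = 4, t_scan = 12))
  # boundary: t_w exactly at the off bound fails (strict)
  expect_false(access_feasible(3.64, 3.64, 0, np = 0, n_icons = 4, t_scan = 12))
  # pulse budget: 1 * (4 - 1) * 10 = 30 is not < 30
  expect_false(access_feasible(5, 1, 0.5, np = 1, n_icons = 4, t_scan = 10))
  expect_true(access_feasible(5, 1, 0.5, np = 1, n_icons = 4, t_scan = 9.9))
})

test_that("the information transfer rate matches the binary entropy form", {
  expect_equal(itr(1, 2), 30)
  expect_warning(zero <- itr(0.5, 2), "chance")
  expect_equal(zero, 0)
  h <- function(p) -p * log2(p) - (1 - p) * log2(1 - p)
  expect_equal(itr(0.9, 2), (1 - h(0.9)) * 60 / 2)
  expect_equal(itr(0.75, 5, n_choices = 4),
               (log2(4) + 0.75 * log2(0.75) + 0.25 * log2(0.25 / 3)) * 12)
})

test_that("the optimal window scan picks the first feasible grid point", {
  # constructed per-window profile: off-latency bound blocks t_w <= 4
  tbl <- tibble::tibble(
    t_w = 2:15,
    t_on_mean = 2, t_on_sd = 0.5,
    t_off_mean = 2.5, t_off_sd = 1.2, # bound = 4.468
    np = 0
  )
  sel <- select_optimal_tw(tbl, n_icons = 4)
  expect_equal(sel$t_w_opt, 5)
  expect_true(sel$feasible)
  expect_equal(sel$t_scan, 2 + 1.64 * 0.5 + 5)
  # infeasible everywhere: pulse cost always exceeds the budget
  # (np * 3 icons * t_scan >= 3 * 3 * (2.82 + 2) > 30 at every t_w)
  tbl2 <- tibble::tibble(
    t_w = 2:15, t_on_mean = 2, t_on_sd = 0.5,
    t_off_mean = 0.5, t_off_sd = 0.1, np = 3
  )
  sel2 <- select_optimal_tw(tbl2, n_icons = 4)
  expect_false(sel2$feasible)
  expect_true(is.na(sel2$t_w_opt))
  # an unconstrained subject takes the grid minimum
  tbl3 <- tibble::tibble(t_w = 2:15, t_on_mean = 0, t_on_sd = 0,
                         t_off_mean = 0, t_off_sd = 0, np = 0)
  expect_equal(select_optimal_tw(tbl3, n_icons = 4)$t_w_opt, 2)
})

test_that("session evaluation separates an ideal subject and is deterministic", {
  cfg <- sim_config(seed = 7)
  sess <- generate_session(ideal_profile(), cfg, 1, seed = 107)
  ev <- session_evaluation(sess, t_w = 2, protocol = eval_protocol(seed = 3))
  expect_equal(ev$val_accuracy, 100)
  expect_equal(ev$test_accuracy, 100)
  expect_equal(ev$latency$t_on_mean, 1)
  expect_equal(ev$np_mean, 0)
  ev2 <- session_evaluation(sess, t_w = 2, protocol = eval_protocol(seed = 3))
  expect_identical(ev, ev2)
  short <- generate_session(ideal_profile(), sim_config(trials_per_session = 4),
                            1, seed = 1)
  expect_error(session_evaluation(short, 2), "14")
})

test_that("the ideal subject's optimal window is the grid minimum with perfect accuracy", {
  sess <- lapply(1:3, function(s) {
    generate_session(ideal_profile(), sim_config(seed = 7), s, seed = 100 + s)
  })
  ow <- optimal_window(sess, "set1", protocol = eval_protocol(seed = 3))
  expect_true(ow$feasible)
  expect_equal(ow$t_w_opt, 2L)
  expect_equal(ow$accuracy, 100)
  expect_equal(ow$t_scan, 1 + 2) # zero-latency subject: t_on = 1 s, sd 0
  expect_equal(ow$itr, 30)
  expect_true(access_feasible(ow$t_w_opt, ow$t_off_mean, ow$t_off_sd, ow$np,
                              ow$n_icons, ow$t_scan))
})
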