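test_that("the IQR filter keeps ties, drops gross outliers, and is idempotent", {
  expect_warning(out <- iqr_filter(c(1, 2, 3)), "unfiltered")
  expect_equal(out, c(1, 2, 3))
  expect_equal(iqr_filter(c(5, 5, 5, 5)), c(5, 5, 5, 5))
  # brute-force bound check with type-7 quartiles
  v <- c(1, 2, 3, 4, 100)
  q <- stats::quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
  keep <- v >= q[1] - 1.5 * (q[2] - q[1]) & v <= q[2] + 1.5 * (q[2] - q[1])
  expect_equal(iqr_filter(v), v[keep])
  expect_equal(iqr_filter(v), c(1, 2, 3, 4))
  # the output is always an order-preserving subsequence of the input
  set.seed(2)
  for (i in 1:20) {
    x <- rnorm(30) + sample(c(0, 50), 30, replace = TRUE, prob = c(0.9, 0.1))
    f <- iqr_filter(x)
    expect_true(all(f %in% x))
    expect_identical(f, x[x %in% f])
  }
  # refiltering is a no-op once the far outlier is gone
  expect_identical(iqr_filter(iqr_filter(v)), iqr_filter(v))
})

test_that("successful score counts valid goal-side seconds, strictly", {
  expect_equal(successful_score(make_trial(rep(100, 30), "attention")), 100)
  expect_equal(successful_score(make_trial(rep(100, 30), "non_attention")), 0)
  # threshold equality does not meet the goal
  expect_equal(successful_score(make_trial(rep(50, 30), "attention")), 0)
  expect_equal(successful_score(make_trial(rep(50, 30), "non_attention")), 0)
  att <- c(rep(60, 18), rep(40, 12))
  expect_equal(successful_score(make_trial(att, "attention")), 60)
  # order-free: permuting samples leaves SS unchanged
  set.seed(7)
  for (i in 1:10) {
    x <- runif(30, 0, 100)
    tr <- make_trial(x, "attention")
    perm <- make_trial(sample(x), "attention")
    expect_equal(successful_score(perm), successful_score(tr))
  }
  expect_warning(ss <- successful_score(make_trial(rep(60, 5), valid = FALSE)),
                 "no valid")
  expect_true(is.na(ss))
})

test_that("initial time is the first valid goal-side second, 1-based", {
  expect_equal(initial_time(make_trial(c(60, rep(40, 29)), "attention")), 1)
  expect_equal(initial_time(make_trial(c(40, 45, 55, rep(60, 27)), "attention")), 3)
  expect_true(is.na(initial_time(make_trial(rep(10, 30), "attention"))))
  # an invalid leading second does not hide a later crossing
  tr <- make_trial(c(90, 40, 70, rep(40, 27)), "attention",
                   valid = c(FALSE, rep(TRUE, 29)))
  expect_equal(initial_time(tr), 3)
})

test_that("sustained time is the mean maximal goal-side run length", {
  expect_equal(sustained_time(make_trial(rep(80, 30), "attention")), 30)
  att <- c(rep(80, 10), rep(20, 5), rep(80, 5), rep(20, 10))
  expect_equal(sustained_time(make_trial(att, "attention")), 7.5)
  expect_equal(sustained_time(make_trial(rep(c(80, 20), 15), "attention")), 1)
  expect_true(is.na(sustained_time(make_trial(rep(20, 30), "attention"))))
  # unlike SS, the run structure is order-sensitive
  att2 <- c(rep(80, 15), rep(20, 15))
  expect_false(isTRUE(all.equal(
    sustained_time(make_trial(att2, "attention")),
    sustained_time(make_trial(rep(c(80, 20), 15), "attention"))
  )))
})

test_that("metrics never exceed the task duration", {
  set.seed(31)
  for (i in 1:20) {
    tr <- make_trial(runif(30, 0, 100), sample(c("attention", "non_attention"), 1))
    ts <- sustained_time(tr)
    ti <- initial_time(tr)
    if (!is.na(ts)) expect_lte(ts, 30)
    if (!is.na(ti)) expect_lte(ti, 30)
  }
})

test_that("the ideal subject's summary hits the theoretical values exactly", {
  p <- subject_profile("S", mu_att = 80, mu_non = 20, sigma_within = 0,
                       tau_on = 0, tau_off = 0, poor_signal_rate = 0)
  s <- make_subject_sessions(p, n_sessions = 5, seed = 10)
  sm <- subject_summary(s)
  expect_equal(sm$ss, c(100, 100))
  expect_equal(sm$t_i_mean, c(1, 1))
  expect_equal(sm$t_s_mean, c(30, 30))
  expect_equal(sm$n_trials, c(35L, 35L))
  expect_equal(sm$t_i_se, c(0, 0))
})

test_that("switching latencies injected by the generator are recovered", {
  p <- subject_profile("S", mu_att = 85, mu_non = 15, sigma_within = 8,
                       ar_coeff = 0.5, tau_on = 2, tau_off = 3,
                       poor_signal_rate = 0)
  s <- make_subject_sessions(p, n_sessions = 5, seed = 300)
  sm <- subject_summary(s)
  on <- sm[sm$condition == "attention", ]
  off <- sm[sm$condition == "non_attention", ]
  # discrete-time detection of an exponential latency adds one second
  expect_lt(abs(on$t_i_mean - (2 + 1)), 2 * on$t_i_se)
  expect_lt(abs(off$t_i_mean - (3 + 1)), 2 * off$t_i_se)
})

test_that("a single contributing trial yields an absent standard error", {
  s <- generate_session(ideal_profile(), sim_config(trials_per_session = 2),
                        1, seed = 1)
  sm <- subject_summary(s)
  expect_true(all(is.na(sm$t_i_se)))
  expect_equal(sm$n_trials, c(1L, 1L))
})

test_that("trial feature averaging follows the set definitions", {
  tr <- make_trial(rep(70, 30))
  expect_equal(trial_average_features(tr, "set1"), c(attention = 70))
  f3 <- trial_average_features(make_trial(rep(70, 30), n_bands = 9), "set3")
  expect_length(f3, 10)
  f38 <- trial_average_features(tr, "set3")
  expect_length(f38, 9)
  # theta/beta is the ratio of filtered means (theta = band 2, beta = 5 + 6)
  tr2 <- make_trial(rep(70, 30), bands = list(
    band_2 = rep(40, 30), band_5 = rep(5, 30), band_6 = rep(15, 30)
  ))
  f2 <- trial_average_features(tr2, "set2")
  expect_equal(unname(f2["theta_beta"]), 40 / 20)
  # windowed vs whole-trial means differ on a ramp, agree on a constant
  ramp <- make_trial(seq(10, 97, 3))
  expect_lt(trial_average_features(ramp, "set1", window = c(0, 5))["attention"],
            trial_average_features(ramp, "set1")["attention"])
  expect_equal(trial_average_features(tr, "set1", window = c(0, 5)),
               trial_average_features(tr, "set1"))
  # no valid seconds in the window -> absent
  tr3 <- make_trial(rep(70, 30), valid = c(rep(FALSE, 10), rep(TRUE, 20)))
  expect_null(trial_average_features(tr3, "set1", window = c(0, 5)))
})

test_that("the trial matrix has one filtered-mean row per task trial", {
  s <- make_subject_sessions(ideal_profile(), n_sessions = 2, seed = 77)
  m <- trial_matrix(s)
  expect_equal(nrow(m), 28)
  expect_equal(sum(m$trial_type == "attention"), 14)
  expect_true(all(c("mean_attention", "delta", "theta", "alpha", "beta",
                    "gamma", "theta_beta") %in% names(m)))
  expect_true(all(m$theta_beta > 0))
})
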