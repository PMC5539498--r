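# Per-subject two-sample rank tests between trial types, and the session
# survey aggregation.

#' Two-sided Mann-Whitney-Wilcoxon rank-sum test
#'
#' Ties are handled with mid-ranks. When both samples have at most 20
#' observations and there are no ties the p-value comes from the exact
#' null distribution of the rank-sum statistic; otherwise the normal
#' approximation with continuity and tie correction is used. No
#' multiple-testing correction is applied anywhere in this module: the
#' per-variable p-values are reported raw.
#'
#' @param x,y Non-empty numeric samples.
#' @return Two-sided p-value.
#' @export
#' @examples
#' rank_sum_test(1:10, 11:20)
rank_sum_test <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) == 0 || length(y) == 0) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  n1 <- length(x)
  n2 <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2 # Mann-Whitney U of x
  ties <- table(r)
  exact <- max(n1, n2) <= 20 && all(ties == 1)
  if (exact) {
    p <- if (u > n1 * n2 / 2) {
      2 * stats::pwilcox(u - 1, n1, n2, lower.tail = FALSE)
    } else {
      2 * stats::pwilcox(u, n1, n2)
    }
  } else {
    mu <- n1 * n2 / 2
    n <- n1 + n2
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * (n + 1 - tie_term)
    if (sigma2 == 0) return(1)
    z <- u - mu
    z <- z - sign(z) * 0.5 # continuity correction
    p <- 2 * stats::pnorm(-abs(z) / sqrt(sigma2))
  }
  min(1, p)
}

stat_variables <- c("mean_attention", "delta", "theta", "alpha", "beta",
                    "gamma", "theta_beta")

check_matrix_classes <- function(matrix) {
  matrix <- matrix[stats::complete.cases(matrix[stat_variables]), , drop = FALSE]
  n_att <- sum(matrix$trial_type == "attention")
  n_non <- sum(matrix$trial_type == "non_attention")
  if (n_att == 0 || n_non == 0) {
    stop("both trial types must be present in the trial matrix", call. = FALSE)
  }
  if (n_att != n_non) {
    stop("unbalanced trial matrix: ", n_att, " attention vs ", n_non,
         " non-attention trials", call. = FALSE)
  }
  matrix
}

#' Per-variable significance of the attention effect
#'
#' Compares attention and non-attention trial means (from
#' [trial_matrix()]) with the rank-sum test for each of attention, the
#' five canonical bands and the theta/beta ratio.
#'
#' @param matrix Trial matrix from [trial_matrix()], balanced between
#'   trial types.
#' @param alpha Significance level for the flags (default 0.05).
#' @return Tibble with `variable`, `p_value`, `significant`.
#' @export
significance_table <- function(matrix, alpha = 0.05) {
  matrix <- check_matrix_classes(matrix)
  att <- matrix[matrix$trial_type == "attention", , drop = FALSE]
  non <- matrix[matrix$trial_type == "non_attention", , drop = FALSE]
  purrr::map_dfr(stat_variables, function(var) {
    p <- rank_sum_test(att[[var]], non[[var]])
    tibble::tibble(
      variable = if (var == "mean_attention") "attention" else var,
      p_value = p,
      significant = p < alpha
    )
  })
}

#' Direction of significant attention effects
#'
#' For every variable flagged significant by [significance_table()],
#' reports whether its class mean is higher or lower in attention trials;
#' non-significant variables (and exact mean ties) get `"none"`.
#'
#' @inheritParams significance_table
#' @return Tibble with `variable`, `p_value`, `significant`, `direction`
#'   (`higher_in_attention`, `lower_in_attention` or `none`).
#' @export
effect_directions <- function(matrix, alpha = 0.05) {
  matrix <- check_matrix_classes(matrix)
  sig <- significance_table(matrix, alpha = alpha)
  att <- matrix[matrix$trial_type == "attention", , drop = FALSE]
  non <- matrix[matrix$trial_type == "non_attention", , drop = FALSE]
  sig$direction <- unname(vapply(stat_variables, function(var) {
    row <- sig[sig$variable == (if (var == "mean_attention") "attention" else var), ]
    if (!row$significant) return("none")
    d <- mean(att[[var]]) - mean(non[[var]])
    if (d > 0) "higher_in_attention" else if (d < 0) "lower_in_attention" else "none"
  }, character(1)))
  sig
}

#' Aggregate the end-of-session survey
#'
#' Each session ends with three questions (could you keep attention high;
#' could you keep it low; did you get tired) rated on a 3-point scale:
#' 1 (no, badly), 2 (neutral), 3 (yes, well). Ratings are averaged per
#' subject across sessions, then per group across subjects (so the group
#' mean is the mean of subject means, not of pooled sessions).
#'
#' @param responses Tibble with one row per subject and session and
#'   columns `subject_id`, `q_a`, `q_b`, `q_c` (ratings in 1..3).
#' @param grouping Named character vector mapping `subject_id` to group.
#' @return List with `subjects` (per-subject means) and `groups`
#'   (per-group means of the subject means).
#' @export
survey_aggregate <- function(responses, grouping) {
  ratings <- unlist(responses[c("q_a", "q_b", "q_c")])
  if (!all(ratings %in% 1:3)) {
    stop("ratings must lie in {1, 2, 3}", call. = FALSE)
  }
  subjects <- responses |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(dplyr::across(c("q_a", "q_b", "q_c"), mean), .groups = "drop")
  subjects$group <- unname(grouping[subjects$subject_id])
  list(subjects = subjects, groups = survey_group_means(subjects))
}

#' Group means of per-subject survey ratings
#'
#' @param subjects Tibble with `group` and per-subject mean ratings in
#'   columns `q_a`, `q_b`, `q_c`.
#' @return Tibble of per-group means (mean of subject means per question).
#' @export
survey_group_means <- function(subjects) {
  subjects |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(dplyr::across(c("q_a", "q_b", "q_c"), mean), .groups = "drop")
}
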