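# Published per-participant summary tables from the original
# single-channel EEG attention-access study, shipped as plain CSV so the
# report arithmetic (group means of best-set accuracy, scanning periods,
# sustained times, survey ratings) can be recomputed from the printed
# per-subject values. The underlying recordings were never deposited;
# these tables are the study's reported results, not outputs of this
# package.

study_csv <- function(name) {
  path <- system.file("extdata", name, package = "attenscan", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Published access parameters per participant and feature set
#'
#' Optimal dwell-window accuracy, the dwell window itself, a per-subject
#' best-set flag, the feasibility marker (one subject/feature-set pair
#' found no feasible window on a 4-icon board) and the classifier-threshold
#' latency statistics, as reported per participant in the original study.
#'
#' @return Tibble with columns `subject`, `group`, `set`, `accuracy`
#'   (percent), `t_w_opt` (s), `feasible`, `best`, `t_on_mean`, `t_on_sd`,
#'   `t_off_mean`, `t_off_sd` (s; repeated across a subject's rows).
#' @export
#' @examples
#' access_report_summary(study_access_table())
study_access_table <- function() study_csv("study_access_table.csv")

#' Published trial summary per participant and condition
#'
#' Successful score, initial time and sustained time (with standard
#' errors) per participant and condition, as reported in the original
#' study.
#'
#' @return Tibble with `subject`, `group`, `condition`, `ss` (percent),
#'   `t_i_mean`, `t_i_se`, `t_s_mean`, `t_s_se` (seconds).
#' @export
study_trial_summary <- function() study_csv("study_trial_summary.csv")

#' Published survey ratings per participant
#'
#' Mean per-subject ratings (across five sessions) of the three
#' end-of-session questions: (a) could you keep attention high, (b) could
#' you keep it low, (c) did you get tired; 3-point scale.
#'
#' @return Tibble with `subject`, `group`, `q_a`, `q_b`, `q_c`.
#' @export
study_survey <- function() study_csv("study_survey.csv")
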