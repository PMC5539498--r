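# Two-class linear discriminant on per-trial averaged features, with
# stratified k-fold cross-validation, ROC and AUC.

as_feature_matrix <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  as.matrix(x)
}

#' Fit a two-class linear discriminant
#'
#' Computes the pooled within-class covariance and the discriminant
#' direction `w = (S + lambda I)^-1 (mu_att - mu_non)` with equal class
#' priors, so the decision threshold sits at the midpoint of the projected
#' class means. When the pooled covariance is singular or has condition
#' number above 1e8 (routine in the small-sample regime where ten-plus
#' features are fit from six trials), a ridge term
#' `lambda = 1e-3 * trace(S) / d` keeps the solve well posed; otherwise
#' `lambda = 0`. The orientation is fixed so the attention class projects
#' higher.
#'
#' @param x Feature matrix (rows = trials) or vector for 1-D features.
#' @param labels Vector of trial labels; exactly two classes, containing
#'   `positive`.
#' @param positive Label of the attention class (default `"attention"`).
#' @return An object of class `attn_lda`: `weights`, `threshold`,
#'   `lambda`, `proj_means`, `positive`, `dim`.
#' @export
fit_lda <- function(x, labels, positive = "attention") {
  x <- as_feature_matrix(x)
  labels <- as.character(labels)
  stopifnot(nrow(x) == length(labels))
  classes <- unique(labels)
  if (length(classes) != 2 || !positive %in% classes) {
    stop("training data must contain exactly two classes including '",
         positive, "'", call. = FALSE)
  }
  negative <- setdiff(classes, positive)
  x1 <- x[labels == positive, , drop = FALSE]
  x0 <- x[labels == negative, , drop = FALSE]
  mu1 <- colMeans(x1)
  mu0 <- colMeans(x0)
  d <- ncol(x)

  pooled_ss <- function(m) {
    if (nrow(m) < 2) return(matrix(0, d, d))
    (nrow(m) - 1) * stats::cov(m)
  }
  # ML normalization (by n, not n - 2): the fit is then exactly invariant
  # to duplicating the training set, and the direction is unchanged.
  s <- (pooled_ss(x1) + pooled_ss(x0)) / nrow(x)

  tr <- sum(diag(s))
  if (tr == 0) {
    if (all(mu1 == mu0)) {
      stop("degenerate training data: zero variance and identical class means",
           call. = FALSE)
    }
    lambda <- 1
    s_reg <- diag(d)
  } else {
    ev <- eigen(s, symmetric = TRUE, only.values = TRUE)$values
    cond <- max(ev) / max(min(ev), 0)
    lambda <- if (!is.finite(cond) || cond > 1e8) 1e-3 * tr / d else 0
    s_reg <- s + diag(lambda, d)
  }
  w <- drop(solve(s_reg, mu1 - mu0))
  if (sum(w * (mu1 - mu0)) < 0) w <- -w
  proj <- c(sum(w * mu1), sum(w * mu0))
  structure(
    list(
      weights = w,
      threshold = mean(proj),
      lambda = lambda,
      proj_means = stats::setNames(proj, c(positive, negative)),
      positive = positive,
      negative = negative,
      dim = d
    ),
    class = "attn_lda"
  )
}

#' Project feature vectors onto the discriminant axis
#'
#' @param model An `attn_lda` model from [fit_lda()].
#' @param x Feature vector, or matrix with one row per observation.
#' @return Numeric score(s); scores above `model$threshold` are classified
#'   as the attention class.
#' @export
project_lda <- function(model, x) {
  stopifnot(inherits(model, "attn_lda"))
  x <- as_feature_matrix(if (is.null(dim(x)) && length(x) == model$dim) {
    matrix(x, nrow = 1)
  } else {
    x
  })
  if (ncol(x) != model$dim) {
    stop("feature dimension ", ncol(x), " does not match model dimension ",
         model$dim, call. = FALSE)
  }
  drop(x %*% model$weights)
}

#' @rdname project_lda
#' @param ... Unused.
#' @export
predict.attn_lda <- function(object, x, ...) {
  ifelse(project_lda(object, x) > object$threshold, object$positive, object$negative)
}

rank_auc <- function(scores, is_positive) {
  n1 <- sum(is_positive)
  n0 <- sum(!is_positive)
  r <- rank(scores) # mid-ranks on ties
  (sum(r[is_positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified k-fold cross-validation of the linear discriminant
#'
#' Trials of each class are shuffled with the given seed and dealt into k
#' folds; accuracy is pooled correct/total over the held-out folds and the
#' AUC is computed from the pooled held-out projection scores via the
#' rank (Mann-Whitney) statistic with mid-ranks on ties.
#'
#' @inheritParams fit_lda
#' @param k Number of folds (default 4); each class needs at least k trials.
#' @param seed Integer seed controlling the fold assignment.
#' @return List with `accuracy` (percent), `auc`, and the pooled held-out
#'   `scores` tibble.
#' @export
kfold_cv <- function(x, labels, k = 4, seed = 1, positive = "attention") {
  x <- as_feature_matrix(x)
  labels <- as.character(labels)
  stopifnot(nrow(x) == length(labels))
  classes <- unique(labels)
  if (length(classes) != 2) stop("need exactly two classes", call. = FALSE)
  if (min(table(labels)) < k) {
    stop("each class needs at least k = ", k, " trials", call. = FALSE)
  }
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in sort(classes)) {
      idx <- which(labels == cl)
      fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
    }
  })
  held <- purrr::map_dfr(seq_len(k), function(f) {
    test <- fold == f
    model <- fit_lda(x[!test, , drop = FALSE], labels[!test], positive = positive)
    sc <- project_lda(model, x[test, , drop = FALSE])
    tibble::tibble(
      score = as.numeric(sc),
      label = labels[test],
      predicted = ifelse(sc > model$threshold, positive,
                         setdiff(classes, positive)),
      fold = f
    )
  })
  list(
    accuracy = 100 * mean(held$predicted == held$label),
    auc = rank_auc(held$score, held$label == positive),
    scores = held
  )
}

#' ROC curve and AUC from projection scores
#'
#' Sweeps the decision threshold over the observed scores and returns the
#' (FPR, TPR) path from (0, 0) to (1, 1). The AUC is computed with the
#' rank statistic and therefore equals the probability that a random
#' attention-trial score exceeds a random non-attention one (ties counted
#' half).
#'
#' @param scores Numeric projection scores.
#' @param labels Labels aligned with `scores`; both classes must appear.
#' @param positive Label of the attention class.
#' @return List with `points` (tibble `threshold`, `fpr`, `tpr`) and `auc`.
#' @export
roc_curve <- function(scores, labels, positive = "attention") {
  labels <- as.character(labels)
  stopifnot(length(scores) == length(labels))
  pos <- labels == positive
  if (all(pos) || !any(pos)) {
    stop("both classes must be present to build a ROC curve", call. = FALSE)
  }
  thresholds <- c(Inf, sort(unique(scores), decreasing = TRUE))
  points <- purrr::map_dfr(thresholds, function(th) {
    tibble::tibble(
      threshold = th,
      fpr = sum(!pos & scores >= th) / sum(!pos),
      tpr = sum(pos & scores >= th) / sum(pos)
    )
  })
  list(points = points, auc = rank_auc(scores, pos))
}
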