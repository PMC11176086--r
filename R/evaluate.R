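#' Binary classification metrics for a score
#'
#' ROC AUC by the rank (Mann-Whitney) statistic with a bootstrap standard
#' error, precision-recall AUC by step interpolation, the odds ratio per
#' score standard deviation with 95% CI from a univariate logistic refit,
#' and Nagelkerke pseudo-R-squared of that refit against the null model.
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 labels (both classes required).
#' @param n_boot Bootstrap replicates for the AUC se (default 200; 0
#'   skips it).
#' @return Object of class \code{prediction_metrics}: auc, auc_se, pr_auc,
#'   or_per_sd, or_ci, log_or_se, nagelkerke, n, n_case.
#' @export
evaluate_classifier <- function(scores, labels, n_boot = 200) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("both classes must be present")
  auc <- .rank_auc(scores, labels)
  auc_se <- NA_real_
  if (n_boot > 0) {
    n <- length(labels)
    bs <- vapply(seq_len(n_boot), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      if (length(unique(labels[i])) < 2) return(NA_real_)
      .rank_auc(scores[i], labels[i])
    }, numeric(1))
    auc_se <- stats::sd(bs, na.rm = TRUE)
  }
  pr <- .pr_auc(scores, labels)
  z <- if (stats::sd(scores) > 0) (scores - mean(scores)) / stats::sd(scores)
       else scores
  f1 <- stats::glm(labels ~ z, family = stats::binomial())
  cf <- summary(f1)$coefficients
  log_or <- cf["z", 1]; log_or_se <- cf["z", 2]
  f0 <- stats::glm(labels ~ 1, family = stats::binomial())
  r2 <- nagelkerke_r2(as.numeric(stats::logLik(f0)),
                      as.numeric(stats::logLik(f1)), length(labels))
  structure(list(auc = auc, auc_se = auc_se, pr_auc = pr,
                 or_per_sd = exp(log_or),
                 or_ci = exp(log_or + c(-1.96, 1.96) * log_or_se),
                 log_or = log_or, log_or_se = log_or_se,
                 nagelkerke = r2,
                 n = length(labels), n_case = sum(labels)),
            class = "prediction_metrics")
}

.rank_auc <- function(scores, labels) {
  r <- rank(scores)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# step-interpolated area under the precision-recall curve
.pr_auc <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  tp <- cumsum(y)
  prec <- tp / seq_along(y)
  rec <- tp / sum(y)
  keep <- c(diff(rec) > 0, TRUE)      # right edge of tied-score runs
  sum(diff(c(0, rec[keep])) * prec[keep])
}

#' @export
print.prediction_metrics <- function(x, ...) {
  cat(sprintf(
    "AUC %.3f (se %s) | PR-AUC %.3f | OR/sd %.2f (%.2f-%.2f) | R2 %.3f | n=%d (%d cases)\n",
    x$auc, ifelse(is.na(x$auc_se), "NA", sprintf("%.3f", x$auc_se)),
    x$pr_auc, x$or_per_sd, x$or_ci[1], x$or_ci[2], x$nagelkerke,
    x$n, x$n_case))
  invisible(x)
}

#' Share of explained variance due to nonlinearities and interactions
#'
#' \eqn{(R^2_{full} - R^2_{linear}) / R^2_{full}}, floored at 0 with a
#' warning when the full model explains less than the linear one; both
#' values must come from the same folds of the same evaluation protocol.
#'
#' @param r2_linear,r2_full Nested pseudo-R-squared values.
#' @return Share in [0, 1].
#' @export
interaction_variance_share <- function(r2_linear, r2_full) {
  if (r2_full == 0) stop("r2_full is 0: share undefined")
  share <- (r2_full - r2_linear) / r2_full
  if (share < 0) {
    warning("full model explains less than the linear model; share floored at 0")
    share <- 0
  }
  share
}

#' Learner contract constructors
#'
#' Any model exposing \code{fit(features, labels)} and
#' \code{predict_scores(model, features)} plugs into [cv_evaluate()].
#' \code{glm_learner} is a plain main-effects logistic regression;
#' \code{glm_interaction_learner} adds all pairwise interactions;
#' \code{ranger_learner} is a random-forest adapter (requires the ranger
#' package, probability forests).
#'
#' @param num_trees Trees for the forest learner (default 200).
#' @return A list with elements \code{fit} and \code{predict_scores}.
#' @export
glm_learner <- function() {
  list(
    fit = function(X, y) stats::glm.fit(cbind(1, as.matrix(X)), y,
                                        family = stats::binomial()),
    predict_scores = function(model, X)
      stats::plogis(cbind(1, as.matrix(X)) %*% model$coefficients))
}

#' @rdname glm_learner
#' @export
glm_interaction_learner <- function() {
  expand <- function(X) {
    X <- as.matrix(X)
    cn <- colnames(X)
    extra <- list()
    for (i in seq_len(ncol(X) - 1)) for (j in (i + 1):ncol(X))
      extra[[paste0(cn[i], ":", cn[j])]] <- X[, i] * X[, j]
    cbind(X, do.call(cbind, extra))
  }
  list(
    fit = function(X, y) stats::glm.fit(cbind(1, expand(X)), y,
                                        family = stats::binomial()),
    predict_scores = function(model, X)
      stats::plogis(cbind(1, expand(X)) %*% model$coefficients))
}

#' @rdname glm_learner
#' @export
ranger_learner <- function(num_trees = 200) {
  if (!requireNamespace("ranger", quietly = TRUE))
    stop("the ranger package is required for the forest learner")
  list(
    fit = function(X, y) {
      d <- data.frame(y = factor(y), as.data.frame(X))
      ranger::ranger(y ~ ., data = d, num.trees = num_trees,
                     probability = TRUE, num.threads = 1,
                     seed = 1L)
    },
    predict_scores = function(model, X) {
      pr <- stats::predict(model, data = as.data.frame(X),
                           num.threads = 1)$predictions
      pr[, "1"]
    })
}

#' Cross-validated evaluation of a learner
#'
#' Stratified k-fold cross-validation: the learner is fitted on k-1 folds
#' and scored on the held-out fold; out-of-fold scores are pooled and
#' passed to [evaluate_classifier()]. Metrics are invariant to the row
#' order of the input.
#'
#' @param X Feature matrix/data.frame.
#' @param y 0/1 labels.
#' @param learner A learner contract (see [glm_learner()]).
#' @param folds Number of folds (default 10).
#' @param seed Seed controlling fold assignment.
#' @param n_boot Passed to [evaluate_classifier()].
#' @return \code{prediction_metrics} with attribute \code{scores}
#'   (out-of-fold scores in input order).
#' @export
cv_evaluate <- function(X, y, learner, folds = 10L, seed = 1L,
                        n_boot = 0) {
  X <- as.matrix(X)
  y <- as.integer(y)
  n <- length(y)
  set.seed(seed)
  # canonical row order makes fold membership invariant to input shuffles
  canon <- do.call(order, as.data.frame(cbind(y, X)))
  fold <- integer(n)
  for (cls in sort(unique(y))) {
    i <- canon[y[canon] == cls]
    fold[i] <- sample(rep_len(seq_len(folds), length(i)))
  }
  scores <- numeric(n)
  for (f in seq_len(folds)) {
    tr <- fold != f
    m <- learner$fit(X[tr, , drop = FALSE], y[tr])
    scores[!tr] <- learner$predict_scores(m, X[!tr, , drop = FALSE])
  }
  out <- evaluate_classifier(scores, y, n_boot = n_boot)
  attr(out, "scores") <- scores
  out
}
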