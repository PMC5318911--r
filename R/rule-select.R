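# Fit a linear soft-margin SVM (C = 1) on training rows and predict the
# test rows. x is a 1-column matrix (the rule's averaged representative).
# A single-class training fold cannot define a margin; predict its class.
.svm_fold <- function(x_train, y_train, x_test) {
  if (nlevels(droplevels(y_train)) < 2L)
    return(factor(rep(droplevels(y_train)[1L], nrow(x_test)),
                  levels = levels(y_train)))
  fit <- e1071::svm(x_train, y_train, kernel = "linear", cost = 1,
                    scale = FALSE, type = "C-classification")
  stats::predict(fit, x_test)
}

#' Leave-one-out cross-validated accuracy of a rule representative
#'
#' Each sample in turn is held out; a linear-kernel soft-margin classifier
#' (C = 1) is trained on the remaining samples' representative values and
#' predicts the held-out sample.
#'
#' @param representative Numeric vector, the rule's averaged expression per
#'   sample.
#' @param labels Class label per sample (2 classes, each with at least 2
#'   samples).
#' @return Accuracy as a percentage in \eqn{[0, 100]}.
#' @export
loocv_accuracy <- function(representative, labels) {
  y <- factor(labels)
  if (nlevels(y) < 2L) stop("need at least 2 classes")
  if (any(tabulate(y) < 2L)) stop("need >= 2 samples per class")
  x <- matrix(representative, ncol = 1L)
  correct <- vapply(seq_along(y), function(i) {
    pred <- .svm_fold(x[-i, , drop = FALSE], y[-i], x[i, , drop = FALSE])
    pred == y[i]
  }, logical(1))
  100 * mean(correct)
}

# Stratified fold assignment: within each class, shuffle and deal samples
# round-robin into k folds. Uses its own RNG stream; the caller's
# .Random.seed is untouched.
.stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  rng <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(rng)) assign(".Random.seed", rng, envir = globalenv()))
  set.seed(seed)
  for (lev in levels(y)) {
    idx <- sample(which(y == lev))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Stratified k-fold cross-validated accuracy
#'
#' Folds are stratified by class and generated deterministically from
#' \code{seed}. With \code{k = n} this reduces to leave-one-out.
#'
#' @inheritParams loocv_accuracy
#' @param k Number of folds (default 10).
#' @param seed Integer seed for the fold assignment (default 42).
#' @return Mean per-fold accuracy as a percentage.
#' @export
kfold_accuracy <- function(representative, labels, k = 10, seed = 42) {
  y <- factor(labels)
  n <- length(y)
  if (k > n) stop("k must not exceed the number of samples")
  if (nlevels(y) < 2L) stop("need at least 2 classes")
  x <- matrix(representative, ncol = 1L)
  fold <- .stratified_folds(y, k, seed)
  acc <- vapply(seq_len(k), function(f) {
    te <- which(fold == f)
    if (length(te) == 0L) return(NA_real_)
    pred <- .svm_fold(x[-te, , drop = FALSE], y[-te], x[te, , drop = FALSE])
    mean(pred == y[te])
  }, numeric(1))
  100 * mean(acc, na.rm = TRUE)
}

#' Evaluate every rule of a fitted clustering
#'
#' Scores each rule's averaged representative with the linear-kernel
#' classifier under LOOCV and/or stratified 10-fold CV and applies the
#' selection rule: a rule is selected when its LOOCV accuracy is exactly
#' 100\% and it contains more than one member feature.
#'
#' @param fit A fitted \code{\link{rhsac}} object.
#' @param cv \code{"loocv"}, \code{"10fold"}, or \code{"both"} (default).
#' @param k Folds for the k-fold scheme.
#' @param seed Fold-assignment seed.
#' @return data.frame with columns \code{rule_id}, \code{loocv_accuracy},
#'   \code{cv10_accuracy}, \code{n_members}, \code{selected}.
#' @export
evaluate_rules <- function(fit, cv = c("both", "loocv", "10fold"),
                           k = 10, seed = 42) {
  stopifnot(inherits(fit, "rhsac"))
  cv <- match.arg(cv)
  y <- fit$labels
  ev <- do.call(rbind, lapply(fit$rules, function(r) {
    loo <- if (cv != "10fold") loocv_accuracy(r$representative, y) else NA_real_
    c10 <- if (cv != "loocv")
      kfold_accuracy(r$representative, y, k = k, seed = seed) else NA_real_
    data.frame(rule_id = r$rule_id, loocv_accuracy = loo,
               cv10_accuracy = c10, n_members = length(r$members))
  }))
  crit <- if (cv == "10fold") ev$cv10_accuracy else ev$loocv_accuracy
  ev$selected <- crit == 100 & ev$n_members >= 2L
  if (!any(ev$selected))
    warning("no rule reached 100% CV accuracy with > 1 member")
  ev
}

#' Selected rule ids
#'
#' @param evaluations data.frame from \code{\link{evaluate_rules}}.
#' @return Integer vector of selected \code{rule_id}s.
#' @export
select_rules <- function(evaluations) {
  evaluations$rule_id[evaluations$selected]
}
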