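#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a randomly drawn positive
#' case outscores a randomly drawn negative case, ties counting one half.
#'
#' @param scores numeric scores (typically fitted probabilities).
#' @param labels binary 0/1 outcomes.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    rlang::abort("AUC is undefined with a single outcome class",
                 class = "streamhyb_degenerate_outcome")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

error_counts <- function(scores, labels, cutoff) {
  pred <- as.numeric(scores >= cutoff)
  c(fn = sum(pred == 0 & labels == 1), fp = sum(pred == 1 & labels == 0))
}

#' Classification cutoff balancing omission and commission errors
#'
#' Scans candidate cutoffs (the unique score values plus 0 and 1; cases
#' with score at or above the cutoff are predicted positive) and returns
#' the cutoff minimizing the absolute difference between false negatives
#' ("0 predicted but 1 observed") and false positives ("1 predicted but 0
#' observed"), ties broken toward the smallest such cutoff.
#'
#' @inheritParams auc
#' @return the selected probability cutoff.
#' @export
balanced_threshold <- function(scores, labels) {
  labels <- as.numeric(labels)
  cand <- sort(unique(c(0, 1, scores)))
  imbalance <- vapply(cand, function(ct) {
    e <- error_counts(scores, labels, ct)
    abs(e["fn"] - e["fp"])
  }, numeric(1))
  cand[which.min(imbalance)]
}

#' 2x2 classification table at a cutoff
#'
#' Counts with the at-or-above-cutoff-positive convention, plus percent
#' accuracy.
#'
#' @inheritParams auc
#' @param cutoff probability cutoff in `[0, 1]`.
#' @return one-row tibble: `tp`, `fp`, `fn`, `tn`, `accuracy_pct`.
#' @export
classification_table <- function(scores, labels, cutoff) {
  stopifnot(cutoff >= 0, cutoff <= 1)
  labels <- as.numeric(labels)
  pred <- as.numeric(scores >= cutoff)
  tibble::tibble(
    tp = sum(pred == 1 & labels == 1),
    fp = sum(pred == 1 & labels == 0),
    fn = sum(pred == 0 & labels == 1),
    tn = sum(pred == 0 & labels == 0),
    accuracy_pct = 100 * mean(pred == labels)
  )
}

#' k-fold cross-validated classification accuracy
#'
#' Seeded random partition into k near-equal folds (optionally stratified
#' by outcome class). For each fold the model is refitted on the remaining
#' folds, the error-balancing cutoff is computed on those training folds
#' only (no leakage), and the held-out fold is classified. Folds whose
#' training data contain a single outcome class are flagged and excluded
#' from the pooled accuracy.
#'
#' @param data data frame with response and covariates.
#' @param response binary outcome column.
#' @param covariates covariate subset to fit.
#' @param k number of folds.
#' @param seed integer seed for the fold assignment.
#' @param stratified sample fold labels within each outcome class.
#' @return a `cv_result`: `cv_accuracy_pct`, `k`, `seed`, `folds` tibble
#'   (per-fold size, accuracy, flag), `n_excluded_folds`.
#' @export
kfold_cv <- function(data, response, covariates, k = 10, seed = 1,
                     stratified = FALSE) {
  data <- tibble::as_tibble(data)
  n <- nrow(data)
  stopifnot(n >= k)
  y <- as.numeric(data[[response]])
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  # folds are assigned in a canonical row ordering so the partition (and the
  # pooled accuracy) is invariant to the order rows arrive in
  canon <- do.call(order, unname(as.list(data)))
  fold <- integer(n)
  if (stratified) {
    for (cls in sort(unique(y))) {
      i <- canon[y[canon] == cls]
      fold[i] <- sample(rep_len(seq_len(k), length(i)))
    }
  } else {
    fold[canon] <- sample(rep_len(seq_len(k), n))
  }
  res <- lapply(seq_len(k), function(f) {
    train <- data[fold != f, ]
    test <- data[fold == f, ]
    if (length(unique(train[[response]])) < 2) {
      return(tibble::tibble(fold = f, n = nrow(test),
                            accuracy_pct = NA_real_,
                            n_correct = NA_integer_, flagged = TRUE))
    }
    fit <- fit_logistic(train, response, covariates)
    cutoff <- balanced_threshold(fit$fitted, fit$y)
    p <- predict_probability(fit, test)
    correct <- sum((p >= cutoff) == (test[[response]] == 1))
    tibble::tibble(fold = f, n = nrow(test),
                   accuracy_pct = 100 * correct / nrow(test),
                   n_correct = as.integer(correct), flagged = FALSE)
  })
  folds <- dplyr::bind_rows(res)
  used <- dplyr::filter(folds, !.data$flagged)
  structure(list(
    cv_accuracy_pct = 100 * sum(used$n_correct) / sum(used$n),
    k = k, seed = seed, folds = folds,
    n_excluded_folds = sum(folds$flagged)
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold CV (seed %d): pooled held-out accuracy %.1f%%",
              x$k, x$seed, x$cv_accuracy_pct))
  if (x$n_excluded_folds > 0) {
    cat(sprintf(" [%d fold(s) excluded: single-class training data]",
                x$n_excluded_folds))
  }
  cat("\n")
  invisible(x)
}

#' Full evaluation report for a fitted exceedance model
#'
#' AUC, the error-balancing classification cutoff, the 2x2 table and
#' training accuracy at that cutoff, and k-fold cross-validated accuracy.
#'
#' @param fit an `exceedance_fit` from [fit_logistic()] (carries its model
#'   frame for the CV refits).
#' @param k CV folds.
#' @param seed fold-assignment seed.
#' @param stratified passed to [kfold_cv()].
#' @return an `evaluation_report` list; `as_tibble()` gives the one-row
#'   summary.
#' @export
evaluate_model <- function(fit, k = 10, seed = 1, stratified = FALSE) {
  stopifnot(inherits(fit, "exceedance_fit"))
  if (is.null(fit$model_frame)) {
    rlang::abort("fit carries no training data to evaluate",
                 class = "streamhyb_contract_error")
  }
  a <- auc(fit$fitted, fit$y)
  cutoff <- balanced_threshold(fit$fitted, fit$y)
  tab <- classification_table(fit$fitted, fit$y, cutoff)
  cv <- kfold_cv(fit$model_frame, fit$response, fit$covariates,
                 k = k, seed = seed, stratified = stratified)
  structure(list(auc = a, threshold = cutoff, table2x2 = tab,
                 training_accuracy_pct = tab$accuracy_pct,
                 cv_accuracy_pct = cv$cv_accuracy_pct,
                 cv = cv, k = k, seed = seed),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "AUC %.2f | cutoff %.3f | training accuracy %.1f%% | %d-fold CV %.1f%%\n",
    x$auc, x$threshold, x$training_accuracy_pct, x$k, x$cv_accuracy_pct))
  print(x$table2x2)
  invisible(x)
}

#' @method as_tibble evaluation_report
#' @export
as_tibble.evaluation_report <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(auc = x$auc, threshold = x$threshold),
    x$table2x2,
    tibble::tibble(cv_accuracy_pct = x$cv_accuracy_pct,
                   folds = x$k, seed = x$seed)
  )
}
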