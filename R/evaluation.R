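# Metrics, cross-validation, threshold calibration and site ranking.

#' Confusion-matrix metrics and AUC for a score vector
#'
#' Predicts positive when `score > threshold` (strictly greater) and reports
#' sensitivity Sn = TP/(TP+FN), specificity Sp = TN/(TN+FP), accuracy,
#' Matthews correlation coefficient, and the threshold-independent AUC
#' computed as the rank (Mann-Whitney) statistic with midrank tie handling.
#' MCC is reported as 0 with `mcc_defined = FALSE` when any factor of its
#' denominator is zero; AUC is `NA` with `auc_defined = FALSE` when a class
#' is absent.
#'
#' @param scores Numeric score vector.
#' @param truth Logical (or 0/1) ground-truth vector, `TRUE` = positive.
#' @param threshold Decision threshold (default 0, the SVM decision
#'   boundary).
#' @return A one-row `pup_metrics` tibble: `threshold`, `tp`, `tn`, `fp`,
#'   `fn`, `sn`, `sp`, `acc`, `mcc`, `auc`, `mcc_defined`, `auc_defined`.
#' @examples
#' compute_metrics(c(0.9, 0.8, 0.3, 0.1), c(TRUE, TRUE, FALSE, FALSE), 0.5)
#' @export
compute_metrics <- function(scores, truth, threshold = 0) {
  if (length(scores) != length(truth)) {
    abort("scores and truth must have the same length")
  }
  truth <- as.logical(truth)
  pred <- scores > threshold
  tp <- sum(pred & truth)
  tn <- sum(!pred & !truth)
  fp <- sum(pred & !truth)
  fn <- sum(!pred & truth)
  sn <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  sp <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  acc <- (tp + tn) / length(scores)
  den <- as.numeric(tp + fn) * (tn + fp) * (tp + fp) * (tn + fn)
  mcc_defined <- den > 0
  mcc <- if (mcc_defined) {
    (as.numeric(tp) * tn - as.numeric(fn) * fp) / sqrt(den)
  } else {
    0
  }
  auc <- rank_auc(scores, truth)
  out <- tibble(
    threshold = threshold, tp = tp, tn = tn, fp = fp, fn = fn,
    sn = sn, sp = sp, acc = acc, mcc = mcc, auc = auc,
    mcc_defined = mcc_defined, auc_defined = !is.na(auc)
  )
  class(out) <- c("pup_metrics", class(out))
  out
}

#' ROC curve points
#'
#' Sensitivity/1-specificity pairs swept over every distinct score cutoff
#' (prediction rule `score > cutoff`), suitable for plotting or TSV export.
#'
#' @inheritParams compute_metrics
#' @return Tibble with columns `cutoff`, `fpr`, `tpr`.
#' @export
roc_points <- function(scores, truth) {
  truth <- as.logical(truth)
  cuts <- c(Inf, sort(unique(scores), decreasing = TRUE))
  n1 <- sum(truth)
  n0 <- sum(!truth)
  tibble(
    cutoff = cuts,
    fpr = vapply(cuts, function(cc) sum(scores > cc & !truth), 0) / n0,
    tpr = vapply(cuts, function(cc) sum(scores > cc & truth), 0) / n1
  )
}

#' Stratified cross-validation of the final classifier
#'
#' K-fold stratified CV on the positive set against the reliable-negative
#' set, refitting the SVM with the frozen `(cost, gamma)` inside each
#' training fold and pooling the held-out decision values into one
#' (micro-averaged) metrics row; per-fold metrics are also returned. The
#' fold count is reduced with a warning when a class has fewer members than
#' requested folds.
#'
#' @param p_rows,rn_rows Feature matrices for the two classes.
#' @param cost,gamma Frozen SVM parameters.
#' @param folds Requested fold count (default 10).
#' @param threshold Decision threshold for the pooled confusion matrix
#'   (default 0).
#' @param seed Seed for the fold assignment.
#' @return A `pup_cv` object: `pooled` (one-row `pup_metrics`), `per_fold`
#'   (tibble), `scores`, `truth`, `fold`.
#' @export
cross_validate <- function(p_rows, rn_rows, cost, gamma, folds = 10,
                           threshold = 0, seed = 1) {
  n1 <- nrow(p_rows)
  n0 <- nrow(rn_rows)
  if (n1 == 0 || n0 == 0) abort("Both classes must be non-empty")
  k <- min(folds, n1, n0)
  if (k < folds) {
    warn(paste0("Reducing folds from ", folds, " to ", k,
                " (smallest class has ", min(n1, n0), " samples)"))
  }
  if (k < 2) abort("Need at least 2 samples per class for cross-validation")
  x <- rbind(p_rows, rn_rows)
  positive <- rep(c(TRUE, FALSE), c(n1, n0))
  fold <- withr::with_seed(seed, stratified_folds(positive, k))
  scores <- numeric(length(positive))
  for (f in seq_len(k)) {
    held <- fold == f
    fit <- fit_rbf_svm(x[!held, , drop = FALSE], positive[!held], cost, gamma)
    scores[held] <- svm_decision_values(fit, x[held, , drop = FALSE])
  }
  per_fold <- purrr::map_dfr(seq_len(k), function(f) {
    m <- compute_metrics(scores[fold == f], positive[fold == f], threshold)
    mutate(as_tibble(m), fold = f, .before = 1)
  })
  structure(
    list(
      pooled = compute_metrics(scores, positive, threshold),
      per_fold = per_fold,
      scores = scores,
      truth = positive,
      fold = fold,
      folds = k
    ),
    class = "pup_cv"
  )
}

#' @export
print.pup_cv <- function(x, ...) {
  cat(x$folds, "-fold stratified cross-validation (pooled)\n", sep = "")
  p <- x$pooled
  cat(sprintf("  Sn %.4f  Sp %.4f  ACC %.4f  MCC %.4f  AUC %.4f\n",
              p$sn, p$sp, p$acc, p$mcc, p$auc))
  invisible(x)
}

#' @export
tidy.pup_cv <- function(x, ...) {
  x$per_fold
}

#' @export
glance.pup_cv <- function(x, ...) {
  as_tibble(x$pooled)
}

#' Cross-validate a trained pipeline model
#'
#' Convenience wrapper running [cross_validate()] on the positive and
#' final reliable-negative rows stored on a [pup_train()] model, with its
#' frozen `(cost, gamma)`.
#'
#' @param model A `pup_model` from [pup_train()].
#' @param folds Fold count (default 10).
#' @param seed Seed for fold assignment (default: the model's seed).
#' @return A `pup_cv` object.
#' @export
pup_cross_validate <- function(model, folds = 10, seed = NULL) {
  if (is.null(model$p_rows) || is.null(model$rn_rows)) {
    abort("Model does not carry its training rows; use cross_validate()")
  }
  cross_validate(model$p_rows, model$rn_rows, model$cost, model$gamma,
                 folds = folds, seed = seed %||% model$config$seed)
}

#' Evaluate a model on labelled test windows
#'
#' Encodes the test windows in the model's feature space and scores them;
#' annotated sites (label `"positive"`) are ground-truth positives and all
#' other lysines ground-truth negatives — a convention that is necessarily
#' noisy because nonannotated lysines may hide unvalidated sites. One
#' metrics row is produced per named cutoff.
#'
#' @param model A `pup_model`.
#' @param test_windows Window tibble with labels ([extract_windows()]).
#' @param thresholds Named numeric cutoffs (e.g.
#'   `c(high = 0.9672, medium = 0.4032, low = 0.1088)`) or a
#'   `pup_thresholds` tibble from [calibrate_thresholds()].
#' @return A tibble of `pup_metrics` rows with a leading `threshold_name`
#'   column.
#' @export
evaluate_on_test <- function(model, test_windows,
                             thresholds = c(threshold = 0)) {
  if (is.null(test_windows) || nrow(test_windows) == 0) {
    abort("Test window set is empty")
  }
  if (inherits(thresholds, "pup_thresholds")) {
    thresholds <- setNames(thresholds$cutoff, thresholds$name)
  }
  feats <- build_feature_matrix(test_windows, k_set = model$config$k_set)
  scores <- predict_scores(model, feats)
  truth <- test_windows$label == "positive"
  purrr::map_dfr(seq_along(thresholds), function(i) {
    m <- compute_metrics(scores, truth, thresholds[[i]])
    mutate(as_tibble(m),
           threshold_name = names(thresholds)[i] %||% as.character(i),
           .before = 1)
  })
}

#' Calibrate named score thresholds from training scores
#'
#' For each requested specificity, finds the smallest cutoff whose
#' training-set specificity (under the strict `score > cutoff` rule) reaches
#' it. This offers a reproducible route to stringency tiers such as
#' high/medium/low confidence.
#'
#' @param scores Scores of the final model on labelled training rows.
#' @param truth Logical ground truth for those rows.
#' @param specificities Named numeric vector of target specificities in
#'   `[0, 1]`, e.g. `c(high = 0.99, medium = 0.95, low = 0.90)`.
#' @return A `pup_thresholds` tibble: `name`, `specificity`, `cutoff`,
#'   ordered by descending cutoff.
#' @export
calibrate_thresholds <- function(scores, truth,
                                 specificities = c(high = 0.99,
                                                   medium = 0.95,
                                                   low = 0.90)) {
  truth <- as.logical(truth)
  neg <- scores[!truth]
  if (length(neg) == 0) abort("No negative rows to calibrate against")
  cand <- sort(unique(c(min(scores) - 1, scores)))
  sp_at <- vapply(cand, function(cc) mean(neg <= cc), numeric(1))
  cutoffs <- vapply(specificities, function(target) {
    ok <- which(sp_at >= target)
    if (length(ok) == 0) {
      abort(paste0("Specificity ", target, " unattainable; attainable range [",
                   min(sp_at), ", ", max(sp_at), "]"))
    }
    cand[ok[1]]
  }, numeric(1))
  out <- tibble(
    name = names(specificities) %||% as.character(seq_along(specificities)),
    specificity = unname(specificities),
    cutoff = unname(cutoffs)
  )
  out <- arrange(out, desc(.data$cutoff))
  class(out) <- c("pup_thresholds", class(out))
  out
}

#' Rank nonannotated lysines by model score
#'
#' Scores unlabeled windows and returns the top candidates in descending
#' score order — the most likely unvalidated pupylation sites. Score ties
#' are broken lexicographically by `(protein_id, position)`.
#'
#' @param model A `pup_model`.
#' @param windows Window tibble; rows labelled `"positive"` are dropped
#'   before ranking (annotated sites are not candidates).
#' @param top_n Number of sites to report (default 20; the full pool when
#'   fewer are available).
#' @return Tibble `protein_id`, `position`, `score`, non-increasing in
#'   `score`.
#' @export
rank_unlabeled_sites <- function(model, windows, top_n = 20) {
  pool <- filter(windows, .data$label != "positive")
  if (nrow(pool) == 0) {
    return(tibble(protein_id = character(), position = integer(),
                  score = numeric()))
  }
  feats <- build_feature_matrix(pool, k_set = model$config$k_set)
  pool$score <- predict_scores(model, feats)
  out <- arrange(pool, desc(.data$score), .data$protein_id, .data$position)
  select(out, "protein_id", "position", "score")[
    seq_len(min(top_n, nrow(out))), ]
}

#' ROC plot for a score vector or cross-validation result
#'
#' @param object A `pup_cv` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pup_cv <- function(object, ...) {
  pts <- roc_points(object$scores, object$truth)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate (1 - Sp)",
      y = "True positive rate (Sn)",
      title = sprintf("Pooled cross-validation ROC (AUC = %.3f)",
                      object$pooled$auc)
    ) +
    ggplot2::theme_minimal()
}

#' Expansion-history plot
#'
#' Reliable-negative and unlabeled set sizes across expansion iterations.
#'
#' @param object A `pup_pu_state` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pup_pu_state <- function(object, ...) {
  h <- select(object$history, "iteration", "n_rn", "n_u")
  long <- tidyr::pivot_longer(h, c("n_rn", "n_u"), names_to = "set",
                              values_to = "size")
  long$set <- c(n_rn = "reliable negatives", n_u = "unlabeled pool")[long$set]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$iteration, y = .data$size,
                                     colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Iteration", y = "Set size", colour = NULL,
                  title = "Reliable-negative expansion") +
    ggplot2::theme_minimal()
}
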