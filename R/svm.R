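# Internal SVM helpers: fitting, sign-normalised decision values, folds, AUC.
# Features are CKSAAP compositions in [0,1] already, so scale = FALSE
# everywhere — rescaling would change the decision-value scale that the
# expansion threshold T is defined on.

fit_rbf_svm <- function(x, positive, cost, gamma) {
  y <- factor(ifelse(positive, "pos", "neg"), levels = c("pos", "neg"))
  if (length(unique(y[!is.na(y)])) < 2 || !any(positive) || all(positive)) {
    abort("SVM training needs both classes")
  }
  e1071::svm(x, y, type = "C-classification", kernel = "radial",
             cost = cost, gamma = gamma, scale = FALSE)
}

# libsvm orders classes by first appearance; the decision-value column name
# ("pos/neg" or "neg/pos") records which sign means which, so parse it.
svm_decision_values <- function(fit, x) {
  pred <- predict(fit, x, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  first <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
  if (identical(first, "pos")) as.numeric(dv[, 1]) else -as.numeric(dv[, 1])
}

# Stratified fold assignment; returns an integer vector of fold ids.
stratified_folds <- function(positive, k) {
  folds <- integer(length(positive))
  for (cls in c(TRUE, FALSE)) {
    idx <- which(positive == cls)
    folds[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

# Rank-based AUC (Mann-Whitney with midrank ties).
rank_auc <- function(scores, positive) {
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) {
    return(NA_real_)
  }
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
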