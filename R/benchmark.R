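# End-to-end synthetic benchmark: PU pipeline vs the balanced-negative
# baseline on a proteome with hidden (nonannotated) true sites.

#' Run the synthetic PU-recovery benchmark
#'
#' Simulates a proteome with partially annotated sites, splits it at the
#' protein level, trains the full PU pipeline and the balanced-negative SVM
#' baseline on the same training windows, and scores both against the
#' *ground truth* (annotated and hidden sites alike) on the held-out
#' proteins. Also reports the mean final-model score of hidden positives vs
#' true negatives in the training unlabeled pool — recovery of hidden sites
#' is the point of PU learning.
#'
#' @param seed Integer seed driving the simulation, split, and both models.
#' @param sim_config A [simulation_config()]; its seed is overridden by
#'   `seed`.
#' @param config A [pu_config()]; its seed is overridden by `seed`.
#' @param test_fraction Protein fraction held out (default 0.3).
#' @return One-row tibble: `seed`, `n_positive`, `n_unlabeled`,
#'   `auc_pu`, `auc_baseline`, `mean_score_hidden`, `mean_score_negative`.
#' @export
run_pu_benchmark <- function(seed,
                             sim_config = simulation_config(),
                             config = pu_config(),
                             test_fraction = 0.3) {
  sim_config$seed <- as.integer(seed)
  config$seed <- as.integer(seed)
  sim <- simulate_proteome(sim_config)
  split <- train_test_split_by_protein(sim$proteins, test_fraction, seed)
  truth_key <- paste(sim$truth$protein_id, sim$truth$position)

  tr_prot <- filter(sim$proteins, .data$id %in% split$train)
  te_prot <- filter(sim$proteins, .data$id %in% split$test)
  tr_ann <- filter(sim$annotations, .data$protein_id %in% split$train)
  w_tr <- extract_windows(tr_prot, tr_ann, config$window_size)

  model <- pup_train(w_tr, config)
  base <- baseline_svm_balance(model$p_rows, model$u_rows, config,
                               features = model$features)

  w_te <- extract_windows(te_prot, NULL, config$window_size)
  te_truth <- paste(w_te$protein_id, w_te$position) %in% truth_key
  fe_te <- build_feature_matrix(w_te, k_set = config$k_set)
  auc_pu <- rank_auc(predict_scores(model, fe_te), te_truth)
  auc_baseline <- rank_auc(predict_scores(base, fe_te), te_truth)

  hidden <- paste(model$unlabeled_keys$protein_id,
                  model$unlabeled_keys$position) %in% truth_key
  u_scores <- predict_scores(model, model$u_rows)

  tibble(
    seed = as.integer(seed),
    n_positive = model$n_positive,
    n_unlabeled = nrow(model$u_rows),
    auc_pu = auc_pu,
    auc_baseline = auc_baseline,
    mean_score_hidden = mean(u_scores[hidden]),
    mean_score_negative = mean(u_scores[!hidden])
  )
}
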