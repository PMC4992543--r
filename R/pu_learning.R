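# The three-stage positive-unlabeled learning algorithm.

#' Stage 1: select initial reliable negatives
#'
#' Scores every unlabeled row by its Euclidean distance to the nearest
#' positive and returns the `size` rows farthest from the positive set —
#' the unlabeled samples most dissimilar from every known positive, hence
#' the safest initial stand-ins for negatives. Ties are broken by ascending
#' row index.
#'
#' @param p_rows,u_rows Numeric feature matrices for the positive and
#'   unlabeled sets (same column space).
#' @param size Number of rows to select (default `nrow(p_rows)`).
#' @return Integer vector of row indices into `u_rows`, sorted ascending.
#' @export
select_initial_negatives <- function(p_rows, u_rows, size = nrow(p_rows)) {
  if (size < 1) abort("size must be >= 1")
  if (nrow(u_rows) < size) {
    abort(paste0("Unlabeled pool (", nrow(u_rows),
                 ") smaller than requested size (", size, ")"))
  }
  d <- min_dist_to_set(u_rows, p_rows)
  sort(order(-d, seq_along(d))[seq_len(size)])
}

# Per-row minimum Euclidean distance from rows of x to the row set ref.
min_dist_to_set <- function(x, ref) {
  cross <- tcrossprod(x, ref)                      # n x m
  d2 <- outer(rowSums(x^2), rowSums(ref^2), "+") - 2 * cross
  sqrt(pmax(apply(d2, 1, min), 0))
}

#' Tune SVM cost and kernel width by grid search
#'
#' Exhaustive search over `cost_grid` x `gamma_grid` with stratified
#' cross-validation, selecting the pair with the best mean held-out AUC.
#' AUC ties are frequent on separable data, and some tied pairs underfit so
#' heavily that every decision value sits near zero — under such a pair the
#' reliable-negative admission threshold `T` (defined on the canonical
#' libsvm decision-value scale, where margins sit at ±1) could never be
#' crossed and the expansion stage would be inert. Ties are therefore
#' resolved by preferring pairs whose held-out decision values attain the
#' canonical margin scale (reach -1), then pairs where `T` is at least
#' reachable, then the smallest cost, then the smallest gamma. The fold
#' count drops to the
#' smaller class size when needed, with a warning. The chosen pair is meant
#' to be frozen for the whole expansion and the final fit.
#'
#' @param p_rows,n_rows Feature matrices for the positive and (reliable)
#'   negative sets.
#' @param config A [pu_config()].
#' @return List with `cost`, `gamma`, `cv_auc`, and `grid` (a tibble of all
#'   evaluated pairs and their mean AUC).
#' @export
tune_svm_params <- function(p_rows, n_rows, config = pu_config()) {
  n1 <- nrow(p_rows)
  n0 <- nrow(n_rows)
  if (n1 == 0 || n0 == 0) abort("Both classes must be non-empty for tuning")
  k <- min(config$tuning_folds, n1, n0)
  if (k < config$tuning_folds) {
    warn(paste0("Reducing tuning folds from ", config$tuning_folds,
                " to ", k, " (smallest class has ", min(n1, n0), " samples)"))
  }
  x <- rbind(p_rows, n_rows)
  positive <- rep(c(TRUE, FALSE), c(n1, n0))
  folds <- withr::with_seed(config$seed, stratified_folds(positive, k))
  grid <- expand.grid(gamma = config$gamma_grid, cost = config$cost_grid,
                      KEEP.OUT.ATTRS = FALSE)
  aucs <- numeric(nrow(grid))
  min_dv <- numeric(nrow(grid))
  if (k >= 2) {
    held <- lapply(seq_len(k), function(f) which(folds == f))
    train <- lapply(seq_len(k), function(f) which(folds != f))
  }
  for (g in seq_len(nrow(grid))) {
    if (k < 2) {
      # degenerate: no held-out data possible, score on the training set
      fit <- fit_rbf_svm(x, positive, grid$cost[g], grid$gamma[g])
      dv <- svm_decision_values(fit, x)
      aucs[g] <- rank_auc(dv, positive)
      min_dv[g] <- min(dv)
    } else {
      fold_auc <- numeric(k)
      fold_min <- numeric(k)
      for (f in seq_len(k)) {
        fit <- fit_rbf_svm(x[train[[f]], , drop = FALSE], positive[train[[f]]],
                           grid$cost[g], grid$gamma[g])
        dv <- svm_decision_values(fit, x[held[[f]], , drop = FALSE])
        fold_auc[f] <- rank_auc(dv, positive[held[[f]]])
        fold_min[f] <- min(dv)
      }
      aucs[g] <- mean(fold_auc, na.rm = TRUE)
      min_dv[g] <- min(fold_min)
    }
  }
  # Among AUC ties prefer pairs whose held-out decision values attain the
  # canonical libsvm margin scale (<= -1, the scale T is defined on), then
  # pairs where T is at least reachable, then the smallest (cost, gamma).
  scale_level <- (min_dv < config$decision_threshold) + (min_dv <= -1)
  ord <- order(grid$cost, grid$gamma)
  best <- ord[1]
  for (g in ord[-1]) {
    if (aucs[g] > aucs[best] ||
        (aucs[g] == aucs[best] && scale_level[g] > scale_level[best])) {
      best <- g
    }
  }
  list(
    cost = grid$cost[best],
    gamma = grid$gamma[best],
    cv_auc = aucs[best],
    threshold_reachable = min_dv[best] < config$decision_threshold,
    grid = tibble(cost = grid$cost, gamma = grid$gamma, mean_auc = aucs,
                  min_decision_value = min_dv)
  )
}

#' Stage 2: iterative expansion of the reliable-negative set
#'
#' Repeats until the unlabeled pool shrinks to `stop_multiplier * |P|` (or no
#' candidate qualifies): train an RBF SVM on positives vs the current
#' reliable negatives with the frozen `(cost, gamma)`; score the unlabeled
#' pool; admit the rows with decision value below `decision_threshold` —
#' at most `pred_cap_multiplier * |P|` of them, keeping the most negative, to
#' control class imbalance; compress the previous negatives to the negative
#' support vectors plus (in the full method) one nearest non-SV neighbour
#' each; and remove the newly admitted rows from the pool.
#'
#' @param p_rows,u_rows Feature matrices for positives and the unlabeled pool.
#' @param rn0 Initial reliable-negative indices into `u_rows`
#'   ([select_initial_negatives()]).
#' @param cost,gamma Frozen SVM parameters from [tune_svm_params()].
#' @param config A [pu_config()].
#' @return A `pup_pu_state` object: `rn` (final indices into `u_rows`),
#'   `u_remaining`, `iterations`, `stopped` (`"pool_small"` or
#'   `"no_candidates"`), and `history` — a tibble with one row per
#'   iteration recording set sizes, admitted decision values and the
#'   compression bookkeeping.
#' @export
expand_reliable_negatives <- function(p_rows, u_rows, rn0, cost, gamma,
                                      config = pu_config()) {
  n_p <- nrow(p_rows)
  rn <- sort(rn0)
  u_remaining <- setdiff(seq_len(nrow(u_rows)), rn)
  cap <- floor(config$pred_cap_multiplier * n_p)
  history <- list()
  i <- 0L
  stopped <- "pool_small"
  while (length(u_remaining) > config$stop_multiplier * n_p) {
    if (i >= config$max_iterations) {
      abort(
        paste0("Reliable-negative expansion did not terminate within ",
               config$max_iterations, " iterations"),
        class = "pup_expansion_overrun",
        history = bind_rows(history)
      )
    }
    fit <- fit_rbf_svm(rbind(p_rows, u_rows[rn, , drop = FALSE]),
                       rep(c(TRUE, FALSE), c(n_p, length(rn))),
                       cost, gamma)
    dv <- svm_decision_values(fit, u_rows[u_remaining, , drop = FALSE])
    cand <- which(dv < config$decision_threshold)
    if (length(cand) == 0) {
      stopped <- "no_candidates"
      break
    }
    keep <- cand[order(dv[cand], cand)][seq_len(min(length(cand), cap))]
    n_pred <- u_remaining[keep]

    # negative support vectors (training rows beyond the |P| positives)
    sv_train <- fit$index[fit$index > n_p] - n_p
    n_sv <- rn[sort(sv_train)]
    n_sv_tilde <- integer(0)
    if (config$rn_representation == "sv_plus_neighbors") {
      n_sv_tilde <- nearest_non_sv_neighbors(u_rows, n_sv, setdiff(rn, n_sv))
    }
    rn <- sort(unique(c(n_pred, n_sv, n_sv_tilde)))
    u_remaining <- setdiff(u_remaining, n_pred)
    i <- i + 1L
    history[[i]] <- tibble(
      iteration = i,
      n_rn = length(rn),
      n_u = length(u_remaining),
      n_pred = length(n_pred),
      n_sv = length(n_sv),
      n_sv_neighbors = length(n_sv_tilde),
      pred_max_value = max(dv[keep]),
      pred_min_value = min(dv[keep]),
      pred_values = list(unname(dv[keep]))
    )
  }
  structure(
    list(
      rn = rn,
      u_remaining = u_remaining,
      iterations = i,
      stopped = stopped,
      n_positive = n_p,
      history = if (length(history)) bind_rows(history) else tibble(
        iteration = integer(), n_rn = integer(), n_u = integer(),
        n_pred = integer(), n_sv = integer(), n_sv_neighbors = integer(),
        pred_max_value = numeric(), pred_min_value = numeric(),
        pred_values = list()
      )
    ),
    class = "pup_pu_state"
  )
}

# For each negative support vector (ascending index), its nearest non-SV
# reliable negative by Euclidean distance, without replacement, ties by
# ascending index; truncated when the pool runs out.
nearest_non_sv_neighbors <- function(u_rows, sv_idx, pool_idx) {
  chosen <- integer(0)
  pool <- pool_idx
  for (s in sv_idx) {
    if (length(pool) == 0) break
    d2 <- colSums((t(u_rows[pool, , drop = FALSE]) - u_rows[s, ])^2)
    pick <- pool[order(d2, pool)[1]]
    chosen <- c(chosen, pick)
    pool <- setdiff(pool, pick)
  }
  chosen
}

#' @export
print.pup_pu_state <- function(x, ...) {
  cat("Reliable-negative expansion: ", x$iterations, " iteration(s)\n",
      sep = "")
  cat("  final |RN| = ", length(x$rn), ", remaining |U| = ",
      length(x$u_remaining), " (|P| = ", x$n_positive, ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.pup_pu_state <- function(x, ...) {
  select(x$history, -"pred_values")
}

#' Stage 3: train the final classifier
#'
#' Fits the RBF SVM on the positives against the final reliable-negative set
#' with the frozen `(cost, gamma)` and packages it with the selected feature
#' set and training provenance.
#'
#' @param p_rows,rn_rows Feature matrices for positives and final reliable
#'   negatives.
#' @param cost,gamma Frozen SVM parameters.
#' @param features Ranking tibble of the retained features
#'   ([select_top_features()]), or `NULL` when `p_rows` columns are already
#'   the model space.
#' @param config A [pu_config()].
#' @param provenance Optional list of extra provenance fields (iterations,
#'   tuning grid, ...) stored on the model.
#' @return A `pup_model` object.
#' @export
train_final_classifier <- function(p_rows, rn_rows, cost, gamma,
                                   features = NULL, config = pu_config(),
                                   provenance = list()) {
  if (nrow(rn_rows) == 0) abort("Reliable-negative set is empty")
  if (nrow(p_rows) == 0) abort("Positive set is empty")
  fit <- fit_rbf_svm(rbind(p_rows, rn_rows),
                     rep(c(TRUE, FALSE), c(nrow(p_rows), nrow(rn_rows))),
                     cost, gamma)
  feature_names <- if (!is.null(features)) {
    features$name
  } else {
    colnames(p_rows) %||% paste0("f", seq_len(ncol(p_rows)))
  }
  structure(
    c(list(
      svm = fit,
      cost = cost,
      gamma = gamma,
      features = features,
      feature_names = feature_names,
      n_positive = nrow(p_rows),
      n_reliable_negative = nrow(rn_rows),
      config = config,
      version = 1L,
      package_version = as.character(packageVersion("puplearn"))
    ), provenance),
    class = "pup_model"
  )
}

#' Score feature rows with a trained model
#'
#' Returns the signed SVM decision value for each row; larger means more
#' pupylation-like. Rows must live in the model's selected feature space —
#' either a bare matrix of matching width, or a full `pup_features` object
#' from which the model's columns are pulled by descriptor name.
#'
#' @param model A `pup_model`.
#' @param rows Numeric matrix (width = number of selected features) or a
#'   `pup_features` object.
#' @return Numeric vector of decision values, one per row.
#' @export
predict_scores <- function(model, rows) {
  x <- resolve_feature_rows(model, rows)
  svm_decision_values(model$svm, x)
}

resolve_feature_rows <- function(model, rows) {
  if (inherits(rows, "pup_features")) {
    missing <- setdiff(model$feature_names, colnames(rows$values))
    if (length(missing) > 0) {
      abort(paste0("Feature matrix lacks model features: ",
                   paste(head(missing, 5), collapse = ", ")))
    }
    return(rows$values[, model$feature_names, drop = FALSE])
  }
  if (ncol(rows) != length(model$feature_names)) {
    abort(paste0("Row width ", ncol(rows), " does not match the model's ",
                 length(model$feature_names), " selected features"))
  }
  if (!is.null(colnames(rows)) &&
      !identical(colnames(rows), model$feature_names)) {
    abort("Column names do not match the model's selected features")
  }
  rows
}

#' @export
predict.pup_model <- function(object, newdata, ...) {
  predict_scores(object, newdata)
}

#' @export
print.pup_model <- function(x, ...) {
  cat("PU-learned pupylation site model (RBF SVM)\n")
  cat("  cost = ", x$cost, ", gamma = ", x$gamma, "\n", sep = "")
  cat("  trained on ", x$n_positive, " positives vs ",
      x$n_reliable_negative, " reliable negatives; ",
      length(x$feature_names), " features\n", sep = "")
  if (!is.null(x$expansion)) {
    cat("  expansion iterations: ", x$expansion$iterations, "\n", sep = "")
  }
  invisible(x)
}

#' @export
glance.pup_model <- function(x, ...) {
  tibble(
    cost = x$cost,
    gamma = x$gamma,
    n_positive = x$n_positive,
    n_reliable_negative = x$n_reliable_negative,
    n_features = length(x$feature_names),
    n_support_vectors = nrow(x$svm$SV),
    iterations = if (!is.null(x$expansion)) x$expansion$iterations else NA_integer_
  )
}

#' @export
tidy.pup_model <- function(x, ...) {
  if (is.null(x$features)) {
    return(tibble(name = x$feature_names))
  }
  x$features
}

#' Train the full PU pipeline on a window table
#'
#' End-to-end convenience wrapper: encode windows (CKSAAP), rank features by
#' chi-square and keep the top `config$n_features`, select initial reliable
#' negatives by maximum distance, tune `(cost, gamma)` once on positives vs
#' that initial set, expand the reliable negatives iteratively, and train the
#' final classifier. The expansion history and unlabeled scores are carried
#' on the returned model.
#'
#' @param windows Window tibble from [extract_windows()] containing both
#'   positive and unlabeled rows.
#' @param config A [pu_config()].
#' @return A `pup_model` with `expansion` (a `pup_pu_state`) attached.
#' @export
pup_train <- function(windows, config = pu_config()) {
  feats <- build_feature_matrix(windows, k_set = config$k_set)
  ranked <- chi_square_rank(feats)
  sel <- select_top_features(ranked, min(config$n_features, nrow(ranked)))
  x <- feats$values[, sel$column, drop = FALSE]
  pos <- feats$windows$label == "positive"
  p_rows <- x[pos, , drop = FALSE]
  u_rows <- x[!pos, , drop = FALSE]
  if (nrow(u_rows) < nrow(p_rows)) {
    abort("Unlabeled pool is smaller than the positive set")
  }
  rn0 <- select_initial_negatives(p_rows, u_rows)
  tuned <- tune_svm_params(p_rows, u_rows[rn0, , drop = FALSE], config)
  state <- expand_reliable_negatives(p_rows, u_rows, rn0, tuned$cost,
                                     tuned$gamma, config)
  model <- train_final_classifier(
    p_rows, u_rows[state$rn, , drop = FALSE],
    tuned$cost, tuned$gamma,
    features = sel, config = config,
    provenance = list(
      expansion = state,
      tuning = tuned[c("cv_auc", "grid")],
      p_rows = p_rows,
      rn_rows = u_rows[state$rn, , drop = FALSE],
      unlabeled_keys = feats$windows[!pos, ],
      u_rows = u_rows
    )
  )
  model
}

#' Balanced-negative SVM baseline
#'
#' The naive alternative to reliable-negative mining: draw a uniform random
#' sample of unlabeled rows the same size as the positive set, treat it as
#' the negative class, tune `(cost, gamma)` by cross-validation and train.
#' Hidden positives in the unlabeled pool contaminate this negative sample,
#' which is exactly the weakness PU learning addresses.
#'
#' @param p_rows,u_rows Feature matrices for positives and the unlabeled
#'   pool (`nrow(u_rows) >= nrow(p_rows)`).
#' @param config A [pu_config()]; `config$seed` drives the sample.
#' @param features Optional ranking tibble stored on the model.
#' @return A `pup_model` with `negative_sample` (the sampled indices)
#'   attached.
#' @export
baseline_svm_balance <- function(p_rows, u_rows, config = pu_config(),
                                 features = NULL) {
  if (nrow(u_rows) < nrow(p_rows)) {
    abort("Unlabeled pool is smaller than the positive set")
  }
  idx <- withr::with_seed(config$seed,
                          sort(sample(nrow(u_rows), nrow(p_rows))))
  n_rows <- u_rows[idx, , drop = FALSE]
  tuned <- tune_svm_params(p_rows, n_rows, config)
  train_final_classifier(
    p_rows, n_rows, tuned$cost, tuned$gamma,
    features = features, config = config,
    provenance = list(negative_sample = idx,
                      tuning = tuned[c("cv_auc", "grid")])
  )
}

#' Save or load a trained model archive
#'
#' The archive is a versioned, self-contained RDS holding the SVM, the
#' selected feature names, the configuration and the seed. Loading fails
#' loudly when the archive is not a model or its version is unknown;
#' scoring fails on any feature-name mismatch.
#'
#' @param model A `pup_model`.
#' @param path Archive path.
#' @return `save_model()` returns `path` invisibly; `load_model()` the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "pup_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "pup_model")) {
    abort(paste0(path, " is not a saved pupylation model"))
  }
  if (is.null(model$version) || model$version != 1L) {
    abort(paste0("Unsupported model archive version: ",
                 model$version %||% "<missing>"))
  }
  model
}
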