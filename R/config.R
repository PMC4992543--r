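# Hyperparameter container for the PU pipeline.

#' PU learning configuration
#'
#' Collects every tunable of the three-stage pipeline. Defaults are the
#' method's published operating point: decision threshold T = -0.25 for
#' admitting new reliable negatives, predicted-negative cap 2|P| per
#' iteration, stop when the unlabeled pool falls to 4|P|, and 16 x 16
#' log-spaced grids for the RBF-SVM cost and kernel width.
#'
#' @param decision_threshold Decision-value cutoff T below which an unlabeled
#'   sample may be admitted as a reliable negative (must be negative).
#' @param pred_cap_multiplier Per-iteration cap on newly predicted negatives,
#'   as a multiple of |P|.
#' @param stop_multiplier Expansion stops once |U| <= `stop_multiplier` * |P|.
#' @param cost_grid,gamma_grid Grids searched for the SVM cost C and RBF
#'   gamma.
#' @param tuning_folds Stratified CV folds used during grid search (reduced
#'   automatically when a class is smaller).
#' @param rn_representation `"sv_plus_neighbors"` keeps negative support
#'   vectors plus one nearest non-SV neighbour each when compressing the
#'   reliable-negative set between iterations (the full method);
#'   `"sv_only"` keeps support vectors alone (the PSoL-style variant).
#' @param window_size Peptide window length (odd; default 21).
#' @param k_set CKSAAP gaps (default `0:4`).
#' @param n_features Retained top-ranked CKSAAP features (default 150).
#' @param max_iterations Hard safety cap on expansion iterations.
#' @param seed Integer seed driving every stochastic step.
#' @return A `pu_config` list.
#' @export
pu_config <- function(decision_threshold = -0.25,
                      pred_cap_multiplier = 2,
                      stop_multiplier = 4,
                      cost_grid = c(0.1, 0.2, 0.5, 1, 2, 5, 10, 20, 50, 100,
                                    200, 500, 1000, 2000, 5000, 10000),
                      gamma_grid = c(1e-5, 2e-5, 5e-5, 1e-4, 2e-4, 5e-4,
                                     1e-3, 2e-3, 5e-3, 0.01, 0.02, 0.05,
                                     0.1, 0.2, 0.5, 1),
                      tuning_folds = 10,
                      rn_representation = c("sv_plus_neighbors", "sv_only"),
                      window_size = 21,
                      k_set = 0:4,
                      n_features = 150,
                      max_iterations = 100,
                      seed = 1) {
  rn_representation <- match.arg(rn_representation)
  if (decision_threshold >= 0) abort("decision_threshold must be negative")
  if (pred_cap_multiplier <= 0) abort("pred_cap_multiplier must be positive")
  if (stop_multiplier < 1) abort("stop_multiplier must be >= 1")
  if (length(cost_grid) == 0 || any(cost_grid <= 0)) {
    abort("cost_grid must be non-empty and positive")
  }
  if (length(gamma_grid) == 0 || any(gamma_grid <= 0)) {
    abort("gamma_grid must be non-empty and positive")
  }
  if (window_size < 3 || window_size %% 2 == 0) {
    abort("window_size must be an odd integer >= 3")
  }
  structure(
    list(
      decision_threshold = decision_threshold,
      pred_cap_multiplier = pred_cap_multiplier,
      stop_multiplier = stop_multiplier,
      cost_grid = sort(cost_grid),
      gamma_grid = sort(gamma_grid),
      tuning_folds = as.integer(tuning_folds),
      rn_representation = rn_representation,
      window_size = as.integer(window_size),
      k_set = sort(unique(as.integer(k_set))),
      n_features = as.integer(n_features),
      max_iterations = as.integer(max_iterations),
      seed = as.integer(seed)
    ),
    class = "pu_config"
  )
}

#' Read a PU configuration from a YAML file
#'
#' Flat key-value YAML where every key matches a [pu_config()] argument;
#' unspecified fields keep their defaults, unknown keys are an error.
#' `overrides` (a named list, e.g. from CLI flags) wins over the file.
#'
#' @param path YAML file path.
#' @param overrides Named list of fields overriding the file.
#' @return A `pu_config`.
#' @export
pu_config_from_file <- function(path, overrides = list()) {
  if (!file.exists(path)) abort(paste0("Config file not found: ", path))
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(pu_config)))
  if (length(unknown) > 0) {
    abort(paste0("Unknown config field(s): ", paste(unknown, collapse = ", ")))
  }
  vals[names(overrides)] <- overrides
  do.call(pu_config, vals)
}

#' @export
print.pu_config <- function(x, ...) {
  cat("PU learning configuration\n")
  cat("  T = ", x$decision_threshold,
      ", pred cap = ", x$pred_cap_multiplier, "|P|",
      ", stop at |U| <= ", x$stop_multiplier, "|P|\n", sep = "")
  cat("  grid: ", length(x$cost_grid), " costs x ", length(x$gamma_grid),
      " gammas, ", x$tuning_folds, "-fold tuning\n", sep = "")
  cat("  RN representation: ", x$rn_representation, "\n", sep = "")
  cat("  window ", x$window_size, ", gaps ", paste(x$k_set, collapse = ","),
      ", top ", x$n_features, " features, seed ", x$seed, "\n", sep = "")
  invisible(x)
}
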