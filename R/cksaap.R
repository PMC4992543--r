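# CKSAAP encoding: composition of k-spaced amino-acid pairs.

#' The padded amino-acid alphabet
#'
#' The 20 standard residues in alphabetical order followed by the terminal
#' placeholder `X`, giving the 21-symbol alphabet over which ordered residue
#' pairs are counted (21^2 = 441 pairs per gap; 2205 features for gaps 0-4).
#'
#' @return Character vector of 21 one-letter symbols.
#' @export
cksaap_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
    "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")
}

#' Enumerate CKSAAP feature descriptors
#'
#' One descriptor per ordered residue pair and gap, in the canonical column
#' order: gap ascending, then first residue, then second residue in alphabet
#' order. Descriptor names follow the `"A.k.B"` convention (pair A,B with
#' gap k).
#'
#' @param k_set Integer gaps (default `0:4`).
#' @param alphabet Ordered symbol alphabet (default [cksaap_alphabet()]).
#' @return A tibble with columns `column`, `name`, `first`, `second`, `gap`.
#' @export
cksaap_descriptors <- function(k_set = 0:4, alphabet = cksaap_alphabet()) {
  k_set <- sort(unique(as.integer(k_set)))
  a <- length(alphabet)
  grid <- expand.grid(second = seq_len(a), first = seq_len(a), gap = k_set,
                      KEEP.OUT.ATTRS = FALSE)
  tibble(
    column = seq_len(nrow(grid)),
    name = paste(alphabet[grid$first], grid$gap, alphabet[grid$second], sep = "."),
    first = alphabet[grid$first],
    second = alphabet[grid$second],
    gap = as.integer(grid$gap)
  )
}

#' Encode peptides as k-spaced amino-acid pair compositions
#'
#' For each gap `k`, counts every ordered residue pair at positions
#' `(i, i + k + 1)` of the peptide and divides by the number of such slots,
#' `length - k - 1`, so each k-block is a composition summing to 1. Blocks
#' are concatenated gap-ascending with pairs in alphabet-major order. A
#' 21-residue window over the 21-symbol alphabet with gaps 0-4 yields
#' 5 x 441 = 2205 features.
#'
#' @param peptides Character vector of equal-length peptides over `alphabet`.
#' @param k_set Integer gaps (default `0:4`).
#' @param alphabet Ordered symbol alphabet (default [cksaap_alphabet()]).
#' @return Numeric matrix, one row per peptide, with descriptor-name columns.
#' @examples
#' encode_cksaap("XKA", k_set = 0)["X.0.K"]
#' @export
encode_cksaap <- function(peptides, k_set = 0:4, alphabet = cksaap_alphabet()) {
  if (length(peptides) == 0) {
    abort("No peptides to encode")
  }
  k_set <- sort(unique(as.integer(k_set)))
  len <- unique(nchar(peptides))
  if (length(len) != 1) {
    abort("Peptides must all have the same length")
  }
  if (len <= max(k_set) + 1) {
    abort(paste0("Peptide length ", len, " too short for gap ", max(k_set)))
  }
  chars <- matrix(match(unlist(strsplit(peptides, "", fixed = TRUE)), alphabet),
                  nrow = length(peptides), byrow = TRUE)
  if (anyNA(chars)) {
    bad <- which(is.na(chars), arr.ind = TRUE)[1, ]
    abort(paste0("Peptide ", bad[["row"]], " contains symbol '",
                 substr(peptides[bad[["row"]]], bad[["col"]], bad[["col"]]),
                 "' outside the alphabet"))
  }
  a <- length(alphabet)
  n <- length(peptides)
  desc <- cksaap_descriptors(k_set, alphabet)
  out <- matrix(0, n, nrow(desc), dimnames = list(NULL, desc$name))
  for (ki in seq_along(k_set)) {
    k <- k_set[ki]
    slots <- len - k - 1L
    codes <- (chars[, seq_len(slots), drop = FALSE] - 1L) * a +
      chars[, (k + 2L):len, drop = FALSE]
    # flat index (row-major over a 2205-wide block) so one tabulate() counts
    # all pairs of all peptides at this gap
    idx <- (rep(seq_len(n), times = slots) - 1L) * (a * a) + as.integer(codes)
    counts <- matrix(tabulate(idx, nbins = n * a * a), nrow = n, byrow = TRUE)
    out[, ((ki - 1L) * a * a + 1L):(ki * a * a)] <- counts / slots
  }
  out
}

#' Build a feature matrix from a window table
#'
#' Encodes every window with [encode_cksaap()] and bundles the value matrix
#' with its descriptor metadata, row keys and PU labels.
#'
#' @param windows Window tibble from [extract_windows()] (non-empty, uniform
#'   peptide length).
#' @param k_set,alphabet Passed to [encode_cksaap()].
#' @return A `pup_features` object: list with `values` (matrix),
#'   `descriptors` (tibble), `windows` (row-key tibble incl. labels),
#'   `k_set`, `alphabet`, `window_size`.
#' @export
build_feature_matrix <- function(windows, k_set = 0:4, alphabet = cksaap_alphabet()) {
  if (is.null(windows) || nrow(windows) == 0) {
    abort("No windows to encode")
  }
  values <- encode_cksaap(windows$peptide, k_set = k_set, alphabet = alphabet)
  structure(
    list(
      values = values,
      descriptors = cksaap_descriptors(k_set, alphabet),
      windows = as_tibble(windows[, c("protein_id", "position", "label")]),
      k_set = sort(unique(as.integer(k_set))),
      alphabet = alphabet,
      window_size = nchar(windows$peptide[1])
    ),
    class = "pup_features"
  )
}

#' @export
print.pup_features <- function(x, ...) {
  cat("CKSAAP feature matrix: ", nrow(x$values), " windows x ",
      ncol(x$values), " features (gaps ",
      paste(x$k_set, collapse = ","), ")\n", sep = "")
  cat("  labels: ", sum(x$windows$label == "positive"), " positive / ",
      sum(x$windows$label != "positive"), " unlabeled\n", sep = "")
  invisible(x)
}

#' Export or import a feature matrix as TSV
#'
#' Wide TSV with `protein_id`, `position`, `label` columns followed by one
#' column per descriptor (named `"A.k.B"`); `read_feature_matrix()`
#' round-trips it into a `pup_features` object.
#'
#' @param features A `pup_features` object.
#' @param path TSV path.
#' @return `write_feature_matrix()` returns `path` invisibly;
#'   `read_feature_matrix()` the `pup_features` object.
#' @export
write_feature_matrix <- function(features, path) {
  out <- dplyr::bind_cols(features$windows,
                          as_tibble(features$values, .name_repair = "minimal"))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  meta_cols <- c("protein_id", "position", "label")
  if (!all(meta_cols %in% names(tab))) {
    abort("Feature matrix file lacks protein_id/position/label columns")
  }
  values <- as.matrix(tab[, setdiff(names(tab), meta_cols)])
  desc <- parse_descriptor_names(colnames(values))
  structure(
    list(
      values = values,
      descriptors = desc,
      windows = as_tibble(tab[, meta_cols]),
      k_set = sort(unique(desc$gap)),
      alphabet = unique(c(desc$first, desc$second)),
      window_size = NA_integer_
    ),
    class = "pup_features"
  )
}

parse_descriptor_names <- function(names) {
  parts <- stringr::str_match(names, "^([A-Z])\\.(\\d+)\\.([A-Z])$")
  if (anyNA(parts[, 1])) {
    abort(paste0("Malformed descriptor name: ", names[which(is.na(parts[, 1]))[1]]))
  }
  tibble(column = seq_along(names), name = names,
         first = parts[, 2], second = parts[, 4],
         gap = as.integer(parts[, 3]))
}

#' Serialize a selected feature set as plain text
#'
#' One descriptor name per line, in rank order.
#'
#' @param selected Ranking tibble ([select_top_features()]).
#' @param path Text file path.
#' @return `write_feature_set()` returns `path` invisibly;
#'   `read_feature_set()` a character vector of descriptor names.
#' @export
write_feature_set <- function(selected, path) {
  writeLines(selected$name, path)
  invisible(path)
}

#' @rdname write_feature_set
#' @export
read_feature_set <- function(path) {
  readLines(path)
}

#' Rank features by the chi-square statistic
#'
#' Each feature is binarised to presence (value > 0) and the 2x2 contingency
#' of presence against class (positive vs unlabeled-as-negative) gives a
#' chi-square statistic without continuity correction. Features with any zero
#' margin score 0. Ranking is by descending statistic, ties broken by
#' ascending column index, so the order is deterministic.
#'
#' @param features A `pup_features` object with both labels present.
#' @return A tibble with columns `rank`, `column`, `name`, `statistic`,
#'   ordered by rank.
#' @export
chi_square_rank <- function(features) {
  pos <- features$windows$label == "positive"
  if (!any(pos) || all(pos)) {
    abort("Chi-square ranking needs both positive and unlabeled windows")
  }
  present <- features$values > 0
  n1 <- sum(pos)
  n0 <- sum(!pos)
  a <- colSums(present[pos, , drop = FALSE])   # present in positives
  c_ <- colSums(present[!pos, , drop = FALSE]) # present in unlabeled
  b <- n1 - a
  d <- n0 - c_
  nn <- n1 + n0
  den <- (a + b) * (c_ + d) * (a + c_) * (b + d)
  stat <- ifelse(den == 0, 0, nn * (a * d - b * c_)^2 / den)
  ord <- order(-stat, features$descriptors$column)
  tibble(
    rank = seq_along(ord),
    column = features$descriptors$column[ord],
    name = features$descriptors$name[ord],
    statistic = unname(stat[ord])
  )
}

#' Select the top-ranked features
#'
#' Fixed-size shortcut taking the `n` best-ranked features; the library
#' default for the retained set (n = 150 under the method's defaults).
#'
#' @param ranked Ranking tibble from [chi_square_rank()].
#' @param n Number of features to keep.
#' @return The first `n` rows of `ranked`.
#' @export
select_top_features <- function(ranked, n = 150) {
  if (n < 1 || n > nrow(ranked)) {
    abort(paste0("n must be between 1 and ", nrow(ranked)))
  }
  ranked[seq_len(n), ]
}

#' Backward feature elimination
#'
#' Starting from all features, repeatedly drops the `step` lowest-ranked
#' remaining features (clamping the last step to land exactly on `target`),
#' scores each working set with `evaluator`, and returns the set with the
#' best score.
#'
#' @param features A `pup_features` object.
#' @param ranked Ranking tibble from [chi_square_rank()].
#' @param step Features removed per iteration (default 50).
#' @param target Smallest set size to evaluate (default 150).
#' @param evaluator Function `(values_subset, labels) -> numeric score`
#'   (higher is better), e.g. a cross-validated AUC.
#' @return A list with `selected` (ranking rows of the best set) and
#'   `provenance` (tibble of iteration, n_features, score).
#' @export
backward_feature_elimination <- function(features, ranked, step = 50,
                                         target = 150, evaluator) {
  if (step < 1) abort("step must be >= 1")
  if (target >= nrow(ranked)) abort("target must be smaller than the feature count")
  labels <- features$windows$label
  sizes <- nrow(ranked)
  while (sizes[length(sizes)] > target) {
    sizes <- c(sizes, max(target, sizes[length(sizes)] - step))
  }
  scores <- purrr::map_dbl(seq_along(sizes), function(i) {
    keep <- ranked$column[seq_len(sizes[i])]
    tryCatch(
      evaluator(features$values[, keep, drop = FALSE], labels),
      error = function(e) {
        abort(paste0("Evaluator failed at iteration ", i, " (",
                     sizes[i], " features): ", conditionMessage(e)))
      }
    )
  })
  # among score ties prefer the smaller set
  best <- which(scores == max(scores))
  best <- best[length(best)]
  list(
    selected = ranked[seq_len(sizes[best]), ],
    provenance = tibble(iteration = seq_along(sizes), n_features = sizes,
                        score = scores)
  )
}
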