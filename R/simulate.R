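# Synthetic proteome generator: motif-bearing pupylation sites with partial
# annotation, so the PU pipeline can be exercised end to end without any
# external dataset.

#' Average SwissProt-like amino-acid background composition
#'
#' Residue frequencies typical of globular proteins, normalised to sum to 1;
#' lysine sits near 5.8% so a few hundred residues of sequence yield a
#' realistic density of candidate sites.
#'
#' @return Named numeric vector over the 20 standard residues.
#' @export
background_composition <- function() {
  comp <- c(
    A = 0.0826, R = 0.0553, N = 0.0406, D = 0.0546, C = 0.0137,
    Q = 0.0393, E = 0.0674, G = 0.0708, H = 0.0227, I = 0.0593,
    L = 0.0965, K = 0.0582, M = 0.0241, F = 0.0386, P = 0.0472,
    S = 0.0660, T = 0.0535, W = 0.0110, Y = 0.0292, V = 0.0686
  )
  comp / sum(comp)
}

#' Default planted pupylation motif
#'
#' A strong four-position preference around the modified lysine, expressed
#' as (offset, residue, weight) where `weight` is the probability that the
#' residue is imposed at that offset of a true site. Fixed-offset residue
#' preferences induce exactly the k-spaced pair enrichment the CKSAAP
#' encoding measures.
#'
#' @return Tibble with columns `offset`, `residue`, `weight`.
#' @export
default_motif <- function() {
  tibble(
    offset = c(-4L, -2L, 1L, 3L),
    residue = c("E", "W", "D", "R"),
    weight = c(0.90, 0.95, 0.95, 0.90)
  )
}

#' Simulation configuration
#'
#' Defines the synthetic study conditions: proteome size, background
#' composition, the density of true pupylation sites among lysines, the
#' planted motif, and the annotation rate — the fraction of true sites that
#' are experimentally "known"; the remainder stay hidden inside the
#' unlabeled pool, which is the positive-unlabeled contamination the method
#' is built for.
#'
#' @param n_proteins Number of proteins (default 72).
#' @param length_range Min/max protein length (default 60-160).
#' @param background Residue composition, 20 probabilities summing to 1.
#' @param site_rate Probability that a lysine is a true site (default 0.15).
#' @param motif Motif tibble as in [default_motif()].
#' @param annotation_rate Fraction of true sites that are annotated
#'   (default 0.5).
#' @param window_size Window length the motif must fit inside (default 21).
#' @param seed Integer seed.
#' @return A `pup_sim_config` list.
#' @export
simulation_config <- function(n_proteins = 72,
                              length_range = c(60, 160),
                              background = background_composition(),
                              site_rate = 0.15,
                              motif = default_motif(),
                              annotation_rate = 0.5,
                              window_size = 21,
                              seed = 1) {
  if (abs(sum(background) - 1) > 1e-9) {
    abort("background composition must sum to 1")
  }
  if (any(background < 0) || any(background > 1)) {
    abort("background composition entries must lie in [0, 1]")
  }
  if (site_rate < 0 || site_rate > 1 || annotation_rate < 0 ||
      annotation_rate > 1) {
    abort("site_rate and annotation_rate must lie in [0, 1]")
  }
  flank <- (window_size - 1) %/% 2
  if (any(motif$offset == 0) || any(abs(motif$offset) > flank)) {
    abort(paste0("Motif offsets must be nonzero and within ±", flank,
                 " of the central lysine"))
  }
  if (any(motif$residue == "K")) {
    abort("Motif residues may not be lysine (would create spurious sites)")
  }
  structure(
    list(
      n_proteins = as.integer(n_proteins),
      length_range = as.integer(length_range),
      background = background,
      site_rate = site_rate,
      motif = motif,
      annotation_rate = annotation_rate,
      window_size = as.integer(window_size),
      seed = as.integer(seed)
    ),
    class = "pup_sim_config"
  )
}

#' Simulate a proteome with planted, partially annotated pupylation sites
#'
#' Draws protein sequences i.i.d. from the background composition, marks
#' each lysine a true site with probability `site_rate`, imposes the motif
#' residues around every true site (never overwriting another true site's
#' central lysine), and annotates exactly
#' `round(annotation_rate * n_true)` of the true sites, chosen uniformly at
#' random. Hidden (nonannotated) true sites are indistinguishable from
#' negatives in the annotations — the truth table is a separate artifact
#' meant for evaluation only and must never feed training.
#'
#' @param config A [simulation_config()].
#' @return List with `proteins` (tibble `id`, `sequence`), `annotations`
#'   (tibble `protein_id`, `site`), and `truth` (tibble `protein_id`,
#'   `position`, `annotated` — one row per true site, hidden ones flagged
#'   `FALSE`).
#' @export
simulate_proteome <- function(config = simulation_config()) {
  withr::with_seed(config$seed, {
    aa <- names(config$background)
    truth <- list()
    proteins <- vector("list", config$n_proteins)
    for (pi in seq_len(config$n_proteins)) {
      len <- sample(config$length_range[1]:config$length_range[2], 1)
      s <- sample(aa, len, replace = TRUE, prob = config$background)
      k_pos <- which(s == "K")
      is_site <- k_pos[runif(length(k_pos)) < config$site_rate]
      for (center in is_site) {
        for (mi in seq_len(nrow(config$motif))) {
          pos <- center + config$motif$offset[mi]
          if (pos >= 1 && pos <= len && !(pos %in% is_site) &&
              runif(1) < config$motif$weight[mi]) {
            s[pos] <- config$motif$residue[mi]
          }
        }
      }
      id <- sprintf("syn%03d", pi)
      proteins[[pi]] <- tibble(id = id, sequence = paste(s, collapse = ""))
      if (length(is_site) > 0) {
        truth[[length(truth) + 1]] <- tibble(protein_id = id,
                                             position = as.integer(is_site))
      }
    }
    proteins <- bind_rows(proteins)
    truth <- if (length(truth)) bind_rows(truth) else
      tibble(protein_id = character(), position = integer())
    n_ann <- round(config$annotation_rate * nrow(truth))
    ann_rows <- sort(sample(nrow(truth), n_ann))
    truth$annotated <- seq_len(nrow(truth)) %in% ann_rows
    annotations <- tibble(
      protein_id = truth$protein_id[truth$annotated],
      site = truth$position[truth$annotated]
    )
    list(proteins = proteins, annotations = annotations, truth = truth)
  })
}

#' Protein-level train/test split
#'
#' Splits at protein granularity so no window from one protein can appear on
#' both sides, mirroring an independent test set of held-out proteins.
#'
#' @param proteins Tibble with column `id`.
#' @param fraction Fraction of proteins held out for testing (0 < f < 1).
#' @param seed Integer seed.
#' @return List with `train` and `test` protein-id character vectors.
#' @export
train_test_split_by_protein <- function(proteins, fraction = 0.3, seed = 1) {
  if (fraction <= 0 || fraction >= 1) {
    abort("fraction must lie strictly between 0 and 1")
  }
  n <- nrow(proteins)
  n_test <- max(1L, round(fraction * n))
  if (n_test >= n) {
    abort("Too few proteins to split at this fraction")
  }
  test_idx <- withr::with_seed(seed, sort(sample(n, n_test)))
  list(train = proteins$id[-test_idx], test = proteins$id[test_idx])
}

#' Write the simulation truth table
#'
#' TSV with columns `protein_id`, `position`, `annotated`; evaluation-only.
#'
#' @param truth Truth tibble from [simulate_proteome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  readr::write_tsv(truth, path, progress = FALSE)
  invisible(path)
}

#' Write an annotation table
#'
#' TSV with columns `protein_id`, `site`.
#'
#' @param annotations Annotation tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  readr::write_tsv(annotations, path, progress = FALSE)
  invisible(path)
}
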