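# Proteins, site annotations, and lysine-centered windows.

# Residues that occur in real FASTA but are outside the 20-letter code.
NONSTANDARD_RESIDUES <- c("B", "Z", "U", "O", "J")

#' Read protein sequences from a FASTA file
#'
#' Sequences are uppercased and the ambiguous one-letter codes B, Z, U, O and
#' J are mapped to the placeholder `X` (with a warning), so every sequence is
#' drawn from the 21-symbol alphabet used by the CKSAAP encoding. Any other
#' letter is an error.
#'
#' @param path Path to a FASTA file. The record id is the first
#'   whitespace-delimited token of the header line.
#' @return A tibble with columns `id` and `sequence`, one row per record, in
#'   file order.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 demo", "MKVAKL"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path))
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      abort(paste0("Malformed FASTA in ", path, ": ", conditionMessage(e)))
    }
  )
  if (length(set) == 0) {
    abort(paste0("FASTA file is empty: ", path))
  }
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1)
  seqs <- toupper(as.character(set))
  has_ns <- stringr::str_detect(seqs, paste0("[", paste(NONSTANDARD_RESIDUES, collapse = ""), "]"))
  if (any(has_ns)) {
    warn(paste0(
      "Mapping nonstandard residues (B/Z/U/O/J) to 'X' in: ",
      paste(ids[has_ns], collapse = ", ")
    ))
    seqs <- stringr::str_replace_all(seqs, "[BZUOJ]", "X")
  }
  bad <- stringr::str_detect(seqs, "[^ACDEFGHIKLMNPQRSTVWYX]")
  if (any(bad)) {
    abort(paste0(
      "Sequence for ", ids[which(bad)[1]],
      " contains letters outside the amino-acid alphabet"
    ))
  }
  tibble(id = unname(ids), sequence = unname(seqs))
}

#' Read a lysine site annotation table
#'
#' Reads a TSV or CSV file with header columns `protein_id` and `site`
#' (1-based position; `position` is accepted as a synonym), validates every
#' site against the protein sequences, and deduplicates.
#'
#' @param path Path to the annotation file. Comma- or tab-separated; the
#'   delimiter is sniffed from the header line.
#' @param proteins Tibble of proteins as returned by [read_fasta()].
#' @return A tibble with columns `protein_id` and `site`, one row per unique
#'   annotated lysine.
#' @export
read_annotations <- function(path, proteins) {
  if (!file.exists(path)) {
    abort(paste0("Annotation file not found: ", path))
  }
  header <- readLines(path, n = 1)
  delim <- if (stringr::str_detect(header, "\t")) "\t" else ","
  ann <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  names(ann) <- tolower(names(ann))
  if ("position" %in% names(ann) && !"site" %in% names(ann)) {
    ann$site <- ann$position
  }
  if (!all(c("protein_id", "site") %in% names(ann))) {
    abort("Annotation file must have columns 'protein_id' and 'site'")
  }
  ann <- distinct(tibble(protein_id = as.character(ann$protein_id),
                         site = as.integer(ann$site)))
  validate_annotations(ann, proteins)
  ann
}

validate_annotations <- function(annotations, proteins) {
  unknown <- setdiff(annotations$protein_id, proteins$id)
  if (length(unknown) > 0) {
    abort(paste0("Annotations refer to unknown protein(s): ",
                 paste(unknown, collapse = ", ")))
  }
  seq_of <- setNames(proteins$sequence, proteins$id)
  for (i in seq_len(nrow(annotations))) {
    pid <- annotations$protein_id[i]
    pos <- annotations$site[i]
    s <- seq_of[[pid]]
    if (is.na(pos) || pos < 1 || pos > nchar(s)) {
      abort(paste0("Annotated site out of range: ", pid, " position ", pos))
    }
    if (substr(s, pos, pos) != "K") {
      abort(paste0("Annotated site is not a lysine: ", pid, " position ", pos,
                   " (residue ", substr(s, pos, pos), ")"))
    }
  }
  invisible(annotations)
}

#' Extract lysine-centered peptide windows
#'
#' Emits one window per lysine in every protein. Windows truncated by a
#' sequence terminus are padded with `X` so all peptides have the same odd
#' length. A window is labelled `"positive"` when its position is annotated
#' and `"unlabeled"` otherwise — there are no confirmed negatives, which is
#' the premise of positive-unlabeled learning.
#'
#' @param proteins Tibble with columns `id`, `sequence` ([read_fasta()]).
#' @param annotations Optional tibble with columns `protein_id`, `site`
#'   ([read_annotations()]); `NULL` labels every window `"unlabeled"`.
#' @param window_size Odd window length (default 21, i.e. 10 residues either
#'   side of the central lysine).
#' @return A tibble with columns `protein_id`, `position` (1-based),
#'   `peptide`, `label`.
#' @examples
#' prot <- tibble::tibble(id = "p1", sequence = "MKVAKL")
#' ann <- tibble::tibble(protein_id = "p1", site = 2L)
#' extract_windows(prot, ann, window_size = 5)
#' @export
extract_windows <- function(proteins, annotations = NULL, window_size = 21) {
  if (window_size < 3 || window_size %% 2 == 0) {
    abort("window_size must be an odd integer >= 3")
  }
  if (!is.null(annotations)) {
    validate_annotations(annotations, proteins)
  }
  flank <- (window_size - 1) %/% 2
  pad <- strrep("X", flank)
  out <- purrr::map2(proteins$id, proteins$sequence, function(pid, s) {
    pos <- stringr::str_locate_all(s, "K")[[1]][, 1]
    if (length(pos) == 0) {
      return(NULL)
    }
    padded <- paste0(pad, s, pad)
    tibble(
      protein_id = pid,
      position = as.integer(pos),
      peptide = substr(rep(padded, length(pos)), pos, pos + 2L * flank)
    )
  })
  out <- bind_rows(out)
  if (nrow(out) == 0) {
    return(tibble(protein_id = character(), position = integer(),
                  peptide = character(), label = character()))
  }
  out$label <- "unlabeled"
  if (!is.null(annotations) && nrow(annotations) > 0) {
    key <- paste(out$protein_id, out$position)
    out$label[key %in% paste(annotations$protein_id, annotations$site)] <- "positive"
  }
  out
}

#' Write and read window tables
#'
#' Tab-separated dump of a window tibble (`protein_id`, `position`,
#' `peptide`, `label`); `read_windows()` round-trips it exactly.
#'
#' @param windows Window tibble from [extract_windows()].
#' @param path Output/input TSV path.
#' @return `write_windows()` returns `path` invisibly; `read_windows()`
#'   returns the window tibble.
#' @export
write_windows <- function(windows, path) {
  readr::write_tsv(windows, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_windows
#' @export
read_windows <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    protein_id = readr::col_character(),
                    position = readr::col_integer(),
                    peptide = readr::col_character(),
                    label = readr::col_character()
                  ))
}

#' Write proteins to FASTA
#'
#' @param proteins Tibble with columns `id`, `sequence`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  set <- Biostrings::BStringSet(setNames(proteins$sequence, proteins$id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
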