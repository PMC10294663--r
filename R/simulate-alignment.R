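# Synthetic pre-aligned response-regulator proteins: full-length sequences
# covering both the receiver and the DNA-binding effector domain, and
# truncated effector-only sequences that are all-gap across the receiver.

.aa_alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Simulate a grouped protein alignment with planted domain truncations
#'
#' Generates an aligned amino-acid fixture for the coverage/truncation stage:
#' `n_full_length` "bacteria"-labelled sequences with residues across both
#' domain spans, and `n_effector_only` "virome"-labelled sequences that are
#' entirely gapped across the receiver span but covered across the effector
#' span — the structure seen in phage-carried truncated \emph{spo0A}
#' homologs. Gap noise is applied per column per sequence at `indel_rate`,
#' never inside the receiver span of effector-only sequences (which stays
#' all-gap by construction).
#'
#' @param n_full_length,n_effector_only Group sizes (defaults mirror a
#'   57-bacteria / 29-virome design).
#' @param receiver_span,effector_span Disjoint 1-based inclusive column
#'   intervals, receiver strictly before effector.
#' @param aln_length Total alignment length (columns). Defaults to 10 columns
#'   past the effector span.
#' @param indel_rate Per-column probability of flipping a residue to a gap.
#' @param seed Integer seed.
#'
#' @return A tibble of class `grouped_alignment` with columns `sequence_id`,
#'   `group` (`"bacteria"`/`"virome"`), `sequence` (aligned string, gap
#'   `"-"`) and the ground-truth `truth` call
#'   (`"full_length"`/`"effector_only"`). The spans are kept in attributes
#'   `receiver_span` and `effector_span`.
#' @export
#' @examples
#' aln <- simulate_regulator_alignment(3, 2, indel_rate = 0, seed = 1)
#' nchar(aln$sequence)
simulate_regulator_alignment <- function(n_full_length = 57,
                                         n_effector_only = 29,
                                         receiver_span = c(8L, 130L),
                                         effector_span = c(140L, 230L),
                                         aln_length = NULL,
                                         indel_rate = 0.02,
                                         seed = 1L) {
  n_full_length <- check_count(n_full_length, "n_full_length")
  n_effector_only <- check_count(n_effector_only, "n_effector_only")
  indel_rate <- check_fraction(indel_rate, "indel_rate")
  receiver_span <- check_span(receiver_span, "receiver_span")
  if (is.null(aln_length)) aln_length <- effector_span[2] + 10L
  aln_length <- check_count(aln_length, "aln_length", min = 1L)
  effector_span <- check_span(effector_span, "effector_span", max_len = aln_length)
  if (receiver_span[2] > aln_length) {
    abort("`receiver_span` exceeds the alignment length.",
          class = "phagetrait_validation_error")
  }
  if (receiver_span[2] >= effector_span[1]) {
    abort("`receiver_span` and `effector_span` must be disjoint, receiver before effector.",
          class = "phagetrait_validation_error")
  }

  n <- n_full_length + n_effector_only
  withr::with_seed(as.integer(seed), {
    receiver_cols <- seq(receiver_span[1], receiver_span[2])
    mat <- matrix("-", nrow = n, ncol = aln_length)
    if (n_full_length > 0) {
      # full-length: residues from start of receiver through end of effector
      covered <- seq(receiver_span[1], effector_span[2])
      mat[seq_len(n_full_length), covered] <-
        sample(.aa_alphabet, n_full_length * length(covered), replace = TRUE)
    }
    if (n_effector_only > 0) {
      rows <- n_full_length + seq_len(n_effector_only)
      covered <- seq(effector_span[1], effector_span[2])
      mat[rows, covered] <-
        sample(.aa_alphabet, n_effector_only * length(covered), replace = TRUE)
    }
    if (indel_rate > 0 && n > 0) {
      flip <- matrix(runif(n * aln_length) < indel_rate, nrow = n)
      # never degrade the truncation ground truth inside the receiver span
      if (n_effector_only > 0) {
        flip[n_full_length + seq_len(n_effector_only), receiver_cols] <- FALSE
      }
      mat[flip] <- "-"
    }

    out <- tibble(
      sequence_id = c(sprintf("bact_%03d", seq_len(n_full_length)),
                      sprintf("virome_%03d", seq_len(n_effector_only))),
      group = c(rep("bacteria", n_full_length), rep("virome", n_effector_only)),
      sequence = apply(mat, 1, paste, collapse = ""),
      truth = c(rep("full_length", n_full_length),
                rep("effector_only", n_effector_only))
    )
    new_grouped_alignment(out, receiver_span, effector_span)
  })
}

new_grouped_alignment <- function(tbl, receiver_span = NULL, effector_span = NULL) {
  structure(
    tbl,
    receiver_span = receiver_span,
    effector_span = effector_span,
    class = c("grouped_alignment", class(tibble()))
  )
}

#' Write / read a grouped alignment as aligned FASTA plus a label table
#'
#' `write_alignment()` writes the aligned sequences as FASTA (`.afa`) through
#' Biostrings plus a two-column `labels.tsv` (`sequence_id`, `group`).
#' `read_alignment()` reads the pair back, normalising the gap characters
#' `-`, `.` and the typographic minus to `"-"` and upper-casing residues.
#'
#' @param aln A `grouped_alignment` tibble (columns `sequence_id`, `group`,
#'   `sequence`).
#' @param fasta_path,labels_path File paths.
#' @return `write_alignment()` returns the paths invisibly;
#'   `read_alignment()` returns a `grouped_alignment` tibble.
#' @export
write_alignment <- function(aln, fasta_path, labels_path) {
  check_columns(aln, c("sequence_id", "group", "sequence"), "alignment table")
  seqs <- Biostrings::AAStringSet(setNames(aln$sequence, aln$sequence_id))
  Biostrings::writeXStringSet(seqs, fasta_path)
  readr::write_tsv(aln[, c("sequence_id", "group")], labels_path)
  invisible(c(fasta = fasta_path, labels = labels_path))
}

#' @rdname write_alignment
#' @export
read_alignment <- function(fasta_path, labels_path) {
  seqs <- Biostrings::readAAStringSet(fasta_path)
  labels <- readr::read_tsv(labels_path, show_col_types = FALSE,
                            col_types = readr::cols(.default = "c"))
  check_columns(labels, c("sequence_id", "group"), "label table")
  seq_chr <- toupper(as.character(seqs))
  seq_chr <- gsub("\\.|−", "-", seq_chr)
  if (length(unique(nchar(seq_chr))) > 1) {
    abort("aligned FASTA sequences are not all the same length.",
          class = "phagetrait_validation_error")
  }
  tbl <- tibble(sequence_id = names(seqs), sequence = unname(seq_chr))
  missing <- setdiff(tbl$sequence_id, labels$sequence_id)
  if (length(missing) > 0) {
    abort(sprintf("sequence(s) without a group label: %s",
                  paste(missing, collapse = ", ")),
          class = "phagetrait_validation_error")
  }
  out <- dplyr::left_join(tbl, labels[, c("sequence_id", "group")],
                          by = "sequence_id")
  new_grouped_alignment(out[, c("sequence_id", "group", "sequence")])
}
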