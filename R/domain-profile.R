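# Alignment-coverage profiling by source group and per-sequence domain
# truncation calls. Works on a grouped alignment: equal-length aligned
# strings with a group label per sequence (e.g. "virome" vs "bacteria").

.gap_normalise <- function(sequence) {
  gsub("\\.|−", "-", toupper(sequence))
}

.aln_matrix <- function(aln) {
  check_columns(aln, c("sequence_id", "group", "sequence"), "grouped alignment")
  if (anyNA(aln$group)) {
    abort("every sequence must carry a group label.",
          class = "phagetrait_validation_error")
  }
  seqs <- .gap_normalise(aln$sequence)
  widths <- nchar(seqs)
  if (length(unique(widths)) > 1) {
    abort("aligned sequences must all have the same length.",
          class = "phagetrait_validation_error")
  }
  matrix(unlist(strsplit(seqs, "")), nrow = length(seqs), byrow = TRUE,
         dimnames = list(aln$sequence_id, NULL))
}

#' Per-group, per-column non-gap coverage of an alignment
#'
#' For every source group and alignment column, the percentage of sequences
#' in that group with a residue (non-gap character) at the column — the
#' quantity plotted when comparing alignment coverage of viral versus
#' bacterial homologs.
#'
#' @param aln A grouped alignment tibble (columns `sequence_id`, `group`,
#'   `sequence`), e.g. from [simulate_regulator_alignment()] or
#'   [read_alignment()].
#' @return A tibble of class `coverage_profile` with columns `group`,
#'   `column` (1-based) and `coverage_pct` in \[0, 100\].
#' @export
#' @examples
#' aln <- simulate_regulator_alignment(4, 2, indel_rate = 0, seed = 1)
#' column_coverage(aln)
column_coverage <- function(aln) {
  mat <- .aln_matrix(aln)
  if (nrow(mat) == 0) {
    abort("alignment is empty.", class = "phagetrait_validation_error")
  }
  groups <- split(seq_len(nrow(mat)), aln$group)
  out <- purrr::map_dfr(names(groups), function(g) {
    rows <- groups[[g]]
    tibble(
      group = g,
      column = seq_len(ncol(mat)),
      coverage_pct = 100 * colMeans(mat[rows, , drop = FALSE] != "-")
    )
  })
  class(out) <- c("coverage_profile", class(tibble()))
  out
}

#' Non-gap fraction of one sequence across a column span
#'
#' @param sequence A single aligned sequence string.
#' @param span 1-based inclusive column interval `c(start, end)`.
#' @return Fraction of non-gap characters within the span, in \[0, 1\].
#' @export
#' @examples
#' span_coverage("AC--EF", c(1, 4))
span_coverage <- function(sequence, span) {
  sequence <- .gap_normalise(sequence)
  if (length(sequence) != 1L) {
    abort("`sequence` must be a single string.", class = "phagetrait_domain_error")
  }
  span <- check_span(span, "span", max_len = nchar(sequence))
  chars <- substring(sequence, seq(span[1], span[2]), seq(span[1], span[2]))
  mean(chars != "-")
}

#' Call full-length versus effector-only domain architecture
#'
#' Classifies every sequence by its non-gap coverage of the receiver and
#' effector spans: `"full_length"` when both spans are covered at or above
#' `present_min`, `"effector_only"` when the effector span is covered but the
#' receiver span is at or below `absent_max` (the truncated architecture of
#' phage-carried \emph{spo0A} homologs), `"other"` otherwise.
#'
#' @inheritParams column_coverage
#' @param receiver_span,effector_span Disjoint 1-based column intervals. If
#'   missing, taken from the alignment's attributes (set by the simulator).
#' @param present_min Minimum span coverage counted as "domain present".
#' @param absent_max Maximum span coverage counted as "domain absent".
#' @return A tibble of class `truncation_calls` with `sequence_id`, `group`,
#'   `coverage_receiver`, `coverage_effector`, `call`.
#' @export
#' @examples
#' aln <- simulate_regulator_alignment(2, 2, indel_rate = 0, seed = 1)
#' call_truncation(aln)
call_truncation <- function(aln, receiver_span = NULL, effector_span = NULL,
                            present_min = 0.5, absent_max = 0.1) {
  if (is.null(receiver_span)) receiver_span <- attr(aln, "receiver_span")
  if (is.null(effector_span)) effector_span <- attr(aln, "effector_span")
  if (is.null(receiver_span) || is.null(effector_span)) {
    abort("`receiver_span` and `effector_span` must be supplied (or carried by the alignment).",
          class = "phagetrait_validation_error")
  }
  mat <- .aln_matrix(aln)
  width <- ncol(mat)
  receiver_span <- check_span(receiver_span, "receiver_span", max_len = width)
  effector_span <- check_span(effector_span, "effector_span", max_len = width)
  if (max(receiver_span[1], effector_span[1]) <= min(receiver_span[2], effector_span[2])) {
    abort("`receiver_span` and `effector_span` must be disjoint.",
          class = "phagetrait_validation_error")
  }
  present_min <- check_fraction(present_min, "present_min")
  absent_max <- check_fraction(absent_max, "absent_max")

  cov_span <- function(span) {
    rowMeans(mat[, seq(span[1], span[2]), drop = FALSE] != "-")
  }
  cov_r <- cov_span(receiver_span)
  cov_e <- cov_span(effector_span)
  call <- dplyr::case_when(
    cov_r >= present_min & cov_e >= present_min ~ "full_length",
    cov_e >= present_min & cov_r <= absent_max ~ "effector_only",
    .default = "other"
  )
  out <- tibble(
    sequence_id = aln$sequence_id,
    group = aln$group,
    coverage_receiver = unname(cov_r),
    coverage_effector = unname(cov_e),
    call = call
  )
  class(out) <- c("truncation_calls", class(tibble()))
  attr(out, "thresholds") <- c(present_min = present_min, absent_max = absent_max)
  out
}

#' Plot a per-group alignment coverage profile
#'
#' Line plot of per-column non-gap coverage, one panel-free line per source
#' group — the standard way to show that one group of homologs aligns only
#' to part of the protein.
#'
#' @param object A `coverage_profile` tibble from [column_coverage()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coverage_profile <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$column, y = .data$coverage_pct,
                               colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Alignment position", y = "Non-gap characters (%)",
                  colour = "Source") +
    ggplot2::theme_minimal()
}
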