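# Readers for the tab-separated annotation/metadata dialects. All
# coordinates are 1-based inclusive (GFF convention). Extra columns are
# ignored; missing required columns raise a schema error naming them.

.annotation_cols <- c("gene_id", "scaffold_id", "phage_id", "start", "end",
                      "strand", "ko_id", "description")

#' Read a per-gene annotation table
#'
#' Reads a DRAM-v-like tab-separated annotation table with (at least) the
#' columns `gene_id`, `scaffold_id`, `phage_id`, `start`, `end`, `strand`,
#' `ko_id`, `description`. Rows with an empty `ko_id` are retained with
#' `ko_id = NA`; coordinates are parsed as integers and validated
#' (`start <= end`, strand `+`/`-`).
#'
#' @param path Path to the TSV file.
#' @return A tibble with one row per annotation row.
#' @export
read_annotations <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  check_columns(raw, .annotation_cols, sprintf("annotation table '%s'", path))
  out <- tibble(
    gene_id = raw$gene_id,
    scaffold_id = raw$scaffold_id,
    phage_id = raw$phage_id,
    start = suppressWarnings(as.integer(raw$start)),
    end = suppressWarnings(as.integer(raw$end)),
    strand = gsub("−", "-", raw$strand),
    ko_id = dplyr::na_if(raw$ko_id, ""),
    description = dplyr::coalesce(raw$description, "")
  )
  bad_coord <- which(is.na(out$start) | is.na(out$end) | out$start > out$end)
  if (length(bad_coord) > 0) {
    abort(sprintf(
      "invalid coordinates (start > end or non-integer) at data line(s): %s",
      paste(head(bad_coord, 10), collapse = ", ")),
      class = "phagetrait_validation_error")
  }
  bad_strand <- which(!out$strand %in% c("+", "-"))
  if (length(bad_strand) > 0) {
    abort(sprintf("strand must be '+' or '-' at data line(s): %s",
                  paste(head(bad_strand, 10), collapse = ", ")),
          class = "phagetrait_validation_error")
  }
  dup <- duplicated(out[, c("scaffold_id", "gene_id")])
  if (any(dup)) {
    abort(sprintf("gene_id must be unique within a scaffold; duplicated: %s",
                  paste(head(unique(out$gene_id[dup]), 5), collapse = ", ")),
          class = "phagetrait_validation_error")
  }
  out
}

#' Read host and phage metadata tables
#'
#' `read_hosts()` expects columns `host_id`, `taxon`, `is_spore_former`;
#' `read_phages()` expects `phage_id`, `host_id` (one row per predicted
#' host, so a phage may span several rows) and optionally `source`.
#'
#' @param path Path to the TSV file.
#' @return A tibble.
#' @export
read_hosts <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  check_columns(raw, c("host_id", "taxon", "is_spore_former"),
                sprintf("host table '%s'", path))
  dplyr::mutate(raw, is_spore_former = as.logical(.data$is_spore_former))
}

#' @rdname read_hosts
#' @export
read_phages <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  check_columns(raw, c("phage_id", "host_id"), sprintf("phage table '%s'", path))
  dplyr::mutate(raw, host_id = dplyr::na_if(.data$host_id, ""))
}

#' Read (or load the packaged) sporulation gene catalog
#'
#' The catalog lists the KEGG orthologs screened by the pipeline together
#' with the associated locus/gene names, the regulatory type (`R`
#' regulatory, `NR` non-regulatory, `R+NR` both, `U` uncharacterized) and a
#' sporulation flag. Several loci (e.g. a \emph{B. subtilis} and a
#' \emph{C. difficile} gene) may map to one KO; the KO is the unit of
#' testing. With no `path`, the packaged catalog of sporulation genes
#' detected in viral genomes is returned.
#'
#' @param path Optional path to a catalog TSV (`ko_id`, `locus`, `gene_name`,
#'   `reg_type`, `function`, `is_sporulation`).
#' @return A tibble with one row per locus.
#' @export
#' @examples
#' catalog <- read_gene_catalog()
#' dplyr::n_distinct(catalog$ko_id)
read_gene_catalog <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "sporulation_gene_catalog.tsv",
                        package = "phagetrait", mustWork = TRUE)
  }
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  check_columns(raw, c("ko_id", "locus", "gene_name", "reg_type", "function",
                       "is_sporulation"),
                sprintf("gene catalog '%s'", path))
  bad <- setdiff(unique(raw$reg_type), c("R", "NR", "R+NR", "U"))
  if (length(bad) > 0) {
    abort(sprintf("reg_type must be one of R, NR, R+NR, U (got: %s).",
                  paste(bad, collapse = ", ")),
          class = "phagetrait_validation_error")
  }
  dplyr::mutate(raw, is_sporulation = as.logical(.data$is_sporulation))
}
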