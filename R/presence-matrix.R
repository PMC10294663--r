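# Gene x phage presence/absence with host-trait labels: the container that
# holds all four counts of the per-gene hypergeometric test (N phages
# surveyed, K phages of spore-forming hosts, per-gene n and k).

#' Assemble the gene-by-phage presence matrix with host-trait labels
#'
#' Joins annotations, phage-host predictions and host traits into a boolean
#' KO-by-phage detection matrix restricted to catalog KOs. A phage counts as
#' a spore-host phage if \emph{any} of its predicted hosts is a
#' spore-former. Duplicate detections of a KO in one phage collapse to a
#' single presence. All phages in the phage table count towards `N`
#' (including phages with zero catalog hits); phages whose host is unknown
#' (`NA`) are excluded from the universe and their count is retained on the
#' object.
#'
#' @param annotations Annotation tibble ([read_annotations()]).
#' @param phages Phage table (`phage_id`, `host_id`; one row per predicted
#'   host).
#' @param hosts Host table (`host_id`, `is_spore_former`).
#' @param catalog Gene catalog ([read_gene_catalog()]); tested genes are its
#'   distinct `ko_id`s.
#' @return An object of class `presence_matrix`: a list with the logical
#'   matrix `present` (genes x phages), `genes`, `phages`, logical
#'   `spore_host` per phage, totals `N` and `K`, the catalog, and
#'   `n_excluded_unknown_host`.
#' @export
#' @examples
#' pop <- simulate_population(30, 0.5, gene_spec_table(2, 2), seed = 1)
#' pm <- build_presence_matrix(pop$annotations, pop$phages, pop$hosts,
#'                             catalog = pop$truth)
#' pm
build_presence_matrix <- function(annotations, phages, hosts, catalog) {
  check_columns(phages, c("phage_id", "host_id"), "phage table")
  check_columns(hosts, c("host_id", "is_spore_former"), "host table")
  check_columns(catalog, "ko_id", "gene catalog")
  check_columns(annotations, c("phage_id", "ko_id"), "annotation table")

  known <- phages[!is.na(phages$host_id), , drop = FALSE]
  n_excluded <- dplyr::n_distinct(phages$phage_id) - dplyr::n_distinct(known$phage_id)
  if (n_excluded > 0) {
    message(sprintf("excluding %d phage(s) with no host prediction from the test universe.",
                    n_excluded))
  }

  bad_host <- setdiff(known$host_id, hosts$host_id)
  if (length(bad_host) > 0) {
    abort(sprintf("phage table references unknown host_id(s): %s",
                  paste(head(bad_host, 10), collapse = ", ")),
          class = "phagetrait_integrity_error")
  }
  bad_phage <- setdiff(annotations$phage_id, phages$phage_id)
  if (length(bad_phage) > 0) {
    abort(sprintf("annotations reference unknown phage_id(s): %s",
                  paste(head(bad_phage, 10), collapse = ", ")),
          class = "phagetrait_integrity_error")
  }

  phage_ids <- sort(unique(known$phage_id))
  # spore_host = OR over all predicted hosts of the phage
  trait_join <- dplyr::left_join(known, hosts[, c("host_id", "is_spore_former")],
                                 by = "host_id")
  trait <- dplyr::summarise(dplyr::group_by(trait_join, .data$phage_id),
                            spore_host = any(.data$is_spore_former),
                            .groups = "drop")
  spore_host <- setNames(trait$spore_host, trait$phage_id)[phage_ids]

  gene_ids <- sort(unique(catalog$ko_id))
  present <- matrix(FALSE, nrow = length(gene_ids), ncol = length(phage_ids),
                    dimnames = list(gene_ids, phage_ids))
  hits <- annotations[!is.na(annotations$ko_id) &
                        annotations$ko_id %in% gene_ids &
                        annotations$phage_id %in% phage_ids, , drop = FALSE]
  if (nrow(hits) > 0) {
    present[cbind(match(hits$ko_id, gene_ids), match(hits$phage_id, phage_ids))] <- TRUE
  }

  structure(
    list(present = present,
         genes = gene_ids,
         phages = phage_ids,
         spore_host = unname(spore_host),
         N = length(phage_ids),
         K = sum(spore_host),
         catalog = as_tibble(catalog),
         n_excluded_unknown_host = n_excluded),
    class = "presence_matrix"
  )
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat(sprintf("<presence_matrix> %d catalog genes x %d phages (N = %d, spore-host K = %d)\n",
              length(x$genes), length(x$phages), x$N, x$K))
  if (x$n_excluded_unknown_host > 0) {
    cat(sprintf("  %d phage(s) without host prediction excluded from N\n",
                x$n_excluded_unknown_host))
  }
  invisible(x)
}

#' Tidy and summarise a presence matrix
#'
#' `tidy()` returns the matrix in long form (`ko_id`, `phage_id`,
#' `present`, `spore_host`); `glance()` returns the one-row test-universe
#' summary (`n_genes`, `N`, `K`, `n_excluded_unknown_host`).
#'
#' @param x A `presence_matrix`.
#' @param ... Unused.
#' @export
tidy.presence_matrix <- function(x, ...) {
  tibble(
    ko_id = rep(x$genes, times = length(x$phages)),
    phage_id = rep(x$phages, each = length(x$genes)),
    present = as.vector(x$present),
    spore_host = rep(x$spore_host, each = length(x$genes))
  )
}

#' @rdname tidy.presence_matrix
#' @export
glance.presence_matrix <- function(x, ...) {
  tibble(n_genes = length(x$genes), N = x$N, K = x$K,
         n_excluded_unknown_host = x$n_excluded_unknown_host)
}
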