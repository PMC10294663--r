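# Synthetic phage/host universe with planted gene-carriage enrichment.

.spore_former_taxa <- c(
  "Bacillus subtilis", "Bacillus cereus", "Clostridioides difficile",
  "Clostridium botulinum", "Paenibacillus polymyxa", "Bacillus licheniformis",
  "Clostridium perfringens", "Sporosarcina pasteurii"
)
.non_spore_taxa <- c(
  "Escherichia coli", "Bacteroides fragilis", "Lactobacillus gasseri",
  "Akkermansia muciniphila", "Prevotella copri", "Faecalibacterium prausnitzii",
  "Klebsiella pneumoniae", "Bifidobacterium longum"
)

#' Build a gene-specification table for the population simulator
#'
#' Convenience constructor for the `genes` argument of
#' [simulate_population()]: `n_enriched` genes whose carriage probability is
#' higher in phages of spore-forming hosts, plus `n_null` genes carried at the
#' same rate regardless of host trait.
#'
#' @param n_enriched Number of planted enriched genes.
#' @param n_null Number of null (trait-independent) genes.
#' @param p_spore,p_other Carriage probabilities of enriched genes in phages
#'   of spore-forming vs other hosts.
#' @param p_null Carriage probability of null genes (both host groups).
#' @param enriched_sporulation Should the enriched genes be flagged as
#'   sporulation genes? (They model the planted trait genes.)
#'
#' @return A tibble with columns `ko_id`, `is_sporulation`,
#'   `p_carry_spore_host`, `p_carry_other` and the derived ground-truth
#'   `label` (`"enriched"` iff the spore-host probability is strictly larger).
#' @export
#' @examples
#' gene_spec_table(n_enriched = 2, n_null = 3)
gene_spec_table <- function(n_enriched = 20, n_null = 200,
                            p_spore = 0.2, p_other = 0.02, p_null = 0.05,
                            enriched_sporulation = TRUE) {
  n_enriched <- check_count(n_enriched, "n_enriched")
  n_null <- check_count(n_null, "n_null")
  tibble(
    ko_id = c(sprintf("K9%04d", seq_len(n_enriched)),
              sprintf("K8%04d", seq_len(n_null))),
    is_sporulation = c(rep(enriched_sporulation, n_enriched), rep(FALSE, n_null)),
    p_carry_spore_host = c(rep(p_spore, n_enriched), rep(p_null, n_null)),
    p_carry_other = c(rep(p_other, n_enriched), rep(p_null, n_null))
  )
}

#' Simulate a phage population with known host traits and gene carriage
#'
#' Generates the full input set of the enrichment stage: a host table, a
#' phage table (one predicted host per phage), a per-gene annotation table in
#' the tab-separated annotation dialect, and a ground-truth table recording
#' each gene's planted label. Exactly `round(n_phages * frac_spore_host)`
#' phages are assigned spore-forming hosts; each gene is then carried by each
#' phage independently with the carriage probability matching the phage's
#' host trait.
#'
#' @param n_phages Number of phages (>= 1).
#' @param frac_spore_host Fraction of phages whose host is a spore-former.
#' @param genes Gene specification tibble with columns `ko_id`,
#'   `is_sporulation`, `p_carry_spore_host`, `p_carry_other`
#'   (see [gene_spec_table()]).
#' @param seed Integer seed; identical seeds give identical output.
#'
#' @return A named list of tibbles: `hosts` (`host_id`, `taxon`,
#'   `is_spore_former`), `phages` (`phage_id`, `host_id`, `source`),
#'   `annotations` (the seven-column annotation dialect), and `truth`
#'   (`ko_id`, `is_sporulation`, carriage probabilities, `label`).
#' @export
#' @examples
#' pop <- simulate_population(20, 0.5, gene_spec_table(1, 2), seed = 1)
#' sum(pop$phages$host_id %in% pop$hosts$host_id[pop$hosts$is_spore_former])
simulate_population <- function(n_phages, frac_spore_host, genes, seed = 1L) {
  n_phages <- check_count(n_phages, "n_phages", min = 1L)
  frac_spore_host <- check_fraction(frac_spore_host, "frac_spore_host")
  check_columns(genes, c("ko_id", "is_sporulation",
                         "p_carry_spore_host", "p_carry_other"),
                "`genes` specification")
  check_probability_vec(genes$p_carry_spore_host, "p_carry_spore_host")
  check_probability_vec(genes$p_carry_other, "p_carry_other")
  if (anyDuplicated(genes$ko_id)) {
    abort("`ko_id` values in `genes` must be unique.",
          class = "phagetrait_validation_error")
  }

  withr::with_seed(as.integer(seed), {
    hosts <- tibble(
      host_id = sprintf("host_%02d", seq_along(c(.spore_former_taxa, .non_spore_taxa))),
      taxon = c(.spore_former_taxa, .non_spore_taxa),
      is_spore_former = c(rep(TRUE, length(.spore_former_taxa)),
                          rep(FALSE, length(.non_spore_taxa)))
    )

    n_spore <- as.integer(round(n_phages * frac_spore_host))
    trait <- c(rep(TRUE, n_spore), rep(FALSE, n_phages - n_spore))
    host_pool_spore <- hosts$host_id[hosts$is_spore_former]
    host_pool_other <- hosts$host_id[!hosts$is_spore_former]
    phages <- tibble(
      phage_id = sprintf("phage_%05d", seq_len(n_phages)),
      host_id = ifelse(trait,
                       sample(host_pool_spore, n_phages, replace = TRUE),
                       sample(host_pool_other, n_phages, replace = TRUE)),
      source = "synthetic"
    )

    truth <- dplyr::mutate(
      genes,
      label = ifelse(.data$p_carry_spore_host > .data$p_carry_other,
                     "enriched", "null")
    )

    # presence draws: genes x phages Bernoulli with trait-dependent p
    p_mat <- outer(genes$p_carry_spore_host, as.numeric(trait)) +
      outer(genes$p_carry_other, 1 - as.numeric(trait))
    present <- matrix(
      runif(length(p_mat)) < p_mat,
      nrow = nrow(genes), ncol = n_phages
    )

    hit <- which(present, arr.ind = TRUE)
    ann <- tibble(
      phage_id = phages$phage_id[hit[, "col"]],
      ko_id = genes$ko_id[hit[, "row"]]
    )
    ann <- dplyr::arrange(ann, .data$phage_id, .data$ko_id)
    ann <- dplyr::mutate(
      dplyr::group_by(ann, .data$phage_id),
      idx = dplyr::row_number()
    )
    ann <- dplyr::ungroup(ann)
    annotations <- tibble(
      gene_id = sprintf("%s_g%03d", ann$phage_id, ann$idx),
      scaffold_id = paste0("scaf_", ann$phage_id),
      phage_id = ann$phage_id,
      start = (ann$idx - 1L) * 1000L + 1L,
      end = (ann$idx - 1L) * 1000L + 900L,
      strand = sample(c("+", "-"), nrow(ann), replace = TRUE),
      ko_id = ann$ko_id,
      description = paste0("sporulation-associated protein ", ann$ko_id)
    )

    list(hosts = hosts, phages = phages,
         annotations = annotations, truth = truth)
  })
}

#' Write a simulated population to TSV files
#'
#' Writes `hosts.tsv`, `phages.tsv`, `annotations.tsv` and `truth.tsv` into
#' `dir`, in the dialects the ingest readers expect.
#'
#' @param pop Result of [simulate_population()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_population <- function(pop, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    hosts = file.path(dir, "hosts.tsv"),
    phages = file.path(dir, "phages.tsv"),
    annotations = file.path(dir, "annotations.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  readr::write_tsv(pop$hosts, paths[["hosts"]])
  readr::write_tsv(pop$phages, paths[["phages"]])
  readr::write_tsv(pop$annotations, paths[["annotations"]])
  readr::write_tsv(pop$truth, paths[["truth"]])
  invisible(paths)
}
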