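# One reproducible run: simulate -> ingest -> enrich -> curate -> profile,
# with every stage's outputs written as plain TSV/FASTA before the next
# stage starts, and a final candidate table joining the enrichment and
# curation calls.

#' Read (and complete) a pipeline run configuration
#'
#' A run configuration is a named list (usually from a YAML file) with
#' sections `population`, `scaffolds`, `alignment`, `enrichment`,
#' `curation`, `domain` and top-level `seed`/`outdir`. Any omitted entry
#' falls back to the package default; the fully resolved configuration is
#' echoed into the run report and the output `MANIFEST`.
#'
#' @param path Path to a YAML configuration file, or `NULL` for the
#'   packaged demo configuration.
#' @return A named list of class `run_config`.
#' @export
#' @examples
#' cfg <- read_run_config()
#' cfg$population$n_phages
read_run_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "demo_config.yaml", package = "phagetrait",
                        mustWork = TRUE)
  }
  if (!file.exists(path)) {
    abort(sprintf("configuration file not found: %s", path),
          class = "phagetrait_validation_error")
  }
  user <- yaml::read_yaml(path)
  defaults <- list(
    seed = 1L,
    outdir = NULL,
    population = list(n_phages = 600L, frac_spore_host = 0.3,
                      n_enriched = 8L, n_null = 30L,
                      p_spore = 0.25, p_other = 0.02, p_null = 0.05),
    scaffolds = list(n_per_gene = 6L, n_genes = 20L),
    alignment = list(n_full_length = 57L, n_effector_only = 29L,
                     receiver_span = c(8L, 130L), effector_span = c(140L, 230L),
                     indel_rate = 0.02),
    enrichment = list(alpha_adj = 1e-6, min_n = 30L, adjust_method = "BH"),
    curation = list(),
    domain = list(present_min = 0.5, absent_max = 0.1),
    keep_possible_viral = TRUE
  )
  cfg <- utils::modifyList(defaults, user)
  class(cfg) <- "run_config"
  cfg
}

#' Run the full discovery pipeline on synthetic data
#'
#' Executes the stages in order — simulate the phage population, scaffold
#' maps and regulator alignment; write and re-read all inputs through the
#' TSV/FASTA readers; build the presence matrix; run the enrichment screen;
#' curate every scaffold and roll verdicts up per gene; profile the
#' alignment and call truncations — and writes each stage's outputs into
#' `outdir` before the next stage starts. The final candidate table is the
#' intersection of the enriched gene set with the genes whose curation
#' category is not `"unlikely viral"` ("possible viral" genes are kept,
#' flagged, unless `keep_possible_viral` is `FALSE`).
#'
#' All randomness derives from `config$seed`; the same configuration and
#' seed produce byte-identical output files.
#'
#' @param config A [read_run_config()] list, or a path to a YAML file.
#' @param outdir Output directory (overrides `config$outdir`).
#' @param seed Optional seed override.
#' @return A list of class `pipeline_report`: per-stage record counts, the
#'   enrichment table, per-gene curation summary, truncation tallies, the
#'   candidate table, the resolved configuration and the package version.
#' @export
#' @examples
#' \donttest{
#' report <- run_pipeline(outdir = tempfile("ptrun"))
#' report$candidates
#' }
run_pipeline <- function(config = NULL, outdir = NULL, seed = NULL) {
  if (is.null(config) || is.character(config)) {
    config <- read_run_config(config)
  }
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (!is.null(outdir)) config$outdir <- outdir
  if (is.null(config$outdir)) {
    abort("an output directory is required (`outdir` or config$outdir).",
          class = "phagetrait_validation_error")
  }
  outdir <- config$outdir
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  manifest <- character(0)
  note <- function(...) message(sprintf(...))

  # --- stage 1: simulate ----------------------------------------------------
  note("[simulate] population, scaffolds and alignment (seed %d)", config$seed)
  popc <- config$population
  genes <- gene_spec_table(popc$n_enriched, popc$n_null,
                           p_spore = popc$p_spore, p_other = popc$p_other,
                           p_null = popc$p_null)
  pop <- simulate_population(popc$n_phages, popc$frac_spore_host, genes,
                             seed = derive_seed(config$seed, 1))
  paths <- write_population(pop, outdir)
  manifest <- c(manifest, basename(paths))

  truth <- pop$truth
  scaffc <- config$scaffolds
  kinds <- rep(ifelse(truth$label == "enriched", "viral", "bacterial"),
               each = scaffc$n_per_gene)
  focal_kos <- rep(truth$ko_id, each = scaffc$n_per_gene)
  scaffold_set <- simulate_scaffold_set(kinds, n_genes = scaffc$n_genes,
                                        focal_ko = focal_kos,
                                        seed = derive_seed(config$seed, 2))

  alnc <- config$alignment
  aln <- simulate_regulator_alignment(
    n_full_length = alnc$n_full_length,
    n_effector_only = alnc$n_effector_only,
    receiver_span = as.integer(alnc$receiver_span),
    effector_span = as.integer(alnc$effector_span),
    indel_rate = alnc$indel_rate,
    seed = derive_seed(config$seed, 3)
  )
  aln_paths <- write_alignment(aln, file.path(outdir, "alignment.afa"),
                               file.path(outdir, "labels.tsv"))
  manifest <- c(manifest, basename(aln_paths))

  # --- stage 2: ingest (round-trip through the file dialects) ---------------
  note("[ingest] reading tables back and building the presence matrix")
  annotations <- read_annotations(paths[["annotations"]])
  phages <- read_phages(paths[["phages"]])
  hosts <- read_hosts(paths[["hosts"]])
  catalog <- dplyr::transmute(truth,
                              ko_id = .data$ko_id,
                              locus = .data$ko_id,
                              gene_name = .data$ko_id,
                              reg_type = "U",
                              `function` = "synthetic gene",
                              is_sporulation = .data$is_sporulation)
  pm <- build_presence_matrix(annotations, phages, hosts, catalog)

  # --- stage 3: enrichment ---------------------------------------------------
  note("[enrich] hypergeometric screen over %d genes (N = %d, K = %d)",
       length(pm$genes), pm$N, pm$K)
  enr <- test_enrichment(pm,
                         alpha_adj = config$enrichment$alpha_adj,
                         min_n = config$enrichment$min_n,
                         adjust_method = config$enrichment$adjust_method)
  readr::write_tsv(as_tibble(enr), file.path(outdir, "enrichment.tsv"))
  manifest <- c(manifest, "enrichment.tsv")

  # --- stage 4: curation -----------------------------------------------------
  note("[curate] scoring %d scaffolds", length(scaffold_set$maps))
  cur_config <- do.call(curation_config, config$curation)
  verdicts <- curate_scaffolds(scaffold_set$maps, cur_config)
  gene_summary <- summarize_gene_curation(verdicts, config = cur_config)
  readr::write_tsv(verdicts, file.path(outdir, "verdicts.tsv"))
  readr::write_tsv(gene_summary, file.path(outdir, "gene_summary.tsv"))
  manifest <- c(manifest, "verdicts.tsv", "gene_summary.tsv")

  # --- stage 5: domain profile ----------------------------------------------
  note("[profile] alignment coverage and truncation calls")
  aln_in <- read_alignment(aln_paths[["fasta"]], aln_paths[["labels"]])
  coverage <- column_coverage(aln_in)
  calls <- call_truncation(aln_in,
                           receiver_span = as.integer(alnc$receiver_span),
                           effector_span = as.integer(alnc$effector_span),
                           present_min = config$domain$present_min,
                           absent_max = config$domain$absent_max)
  readr::write_tsv(coverage, file.path(outdir, "coverage_profile.tsv"))
  readr::write_tsv(as_tibble(calls), file.path(outdir, "truncation_calls.tsv"))
  manifest <- c(manifest, "coverage_profile.tsv", "truncation_calls.tsv")

  # --- candidates: enriched AND viral-context --------------------------------
  keep_cats <- if (isTRUE(config$keep_possible_viral)) {
    c("likely viral", "possible viral")
  } else {
    "likely viral"
  }
  candidates <- dplyr::inner_join(
    dplyr::filter(as_tibble(enr), .data$enriched),
    dplyr::filter(gene_summary, .data$category %in% keep_cats),
    by = "ko_id"
  )
  candidates <- dplyr::arrange(candidates, .data$p_adj, .data$ko_id)
  readr::write_tsv(candidates, file.path(outdir, "candidates.tsv"))
  manifest <- c(manifest, "candidates.tsv")

  config_echo <- config
  writeLines(
    c("# phagetrait run manifest",
      paste0("version: ", as.character(packageVersion("phagetrait"))),
      paste0("seed: ", config$seed),
      "complete: true",
      "files:",
      paste0("  - ", sort(unique(manifest)))),
    file.path(outdir, "MANIFEST")
  )

  report <- list(
    counts = tibble(
      stage = c("phages", "annotations", "genes_tested", "genes_enriched",
                "scaffolds_curated", "sequences_profiled", "candidates"),
      records = c(nrow(pop$phages), nrow(annotations), nrow(enr),
                  sum(enr$enriched), nrow(verdicts), nrow(aln_in),
                  nrow(candidates))
    ),
    enrichment = enr,
    gene_summary = gene_summary,
    truncation_tally = dplyr::count(as_tibble(calls), .data$call),
    candidates = candidates,
    truth = truth,
    scaffold_truth = scaffold_set$truth,
    config = config_echo,
    version = as.character(packageVersion("phagetrait"))
  )
  class(report) <- "pipeline_report"
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<phagetrait pipeline report>\n")
  cat(sprintf("  version %s, seed %d\n", x$version, x$config$seed))
  for (i in seq_len(nrow(x$counts))) {
    cat(sprintf("  %-20s %d\n", x$counts$stage[i], x$counts$records[i]))
  }
  invisible(x)
}

#' One-row summary of a pipeline run
#'
#' @param x A `pipeline_report`.
#' @param ... Unused.
#' @export
glance.pipeline_report <- function(x, ...) {
  tibble(
    n_phages = x$counts$records[x$counts$stage == "phages"],
    n_genes_tested = x$counts$records[x$counts$stage == "genes_tested"],
    n_enriched = x$counts$records[x$counts$stage == "genes_enriched"],
    n_candidates = x$counts$records[x$counts$stage == "candidates"],
    seed = x$config$seed
  )
}
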