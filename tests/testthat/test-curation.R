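make_map <- function(descriptions, strands = rep("+", length(descriptions)),
                     focal = ceiling(length(descriptions) / 2)) {
  n <- length(descriptions)
  genes <- tibble::tibble(
    gene_id = sprintf("g%02d", seq_len(n)),
    scaffold_id = "s1",
    start = (seq_len(n) - 1L) * 1000L + 1L,
    end = (seq_len(n) - 1L) * 1000L + 900L,
    strand = strands,
    ko_id = ifelse(seq_len(n) == focal, "K07699", NA_character_),
    description = descriptions
  )
  scaffold_map(genes, genes$gene_id[focal])
}

test_that("gene descriptions classify into hallmark/hypothetical/other", {
  expect_equal(classify_gene_function("Major Capsid Protein"), "hallmark_viral")
  expect_equal(classify_gene_function(""), "hypothetical")
  expect_equal(classify_gene_function(NA_character_), "hypothetical")
  expect_equal(classify_gene_function("DNA gyrase subunit A"), "other_annotation")
  expect_equal(
    classify_gene_function(c("large TERMINASE subunit", "conserved hypothetical protein",
                             "protein of unknown function", "enolase")),
    c("hallmark_viral", "hypothetical", "hypothetical", "other_annotation")
  )
})

test_that("features capture edge position, strand switches and flanking", {
  m_edge <- make_map(c("spo0A", rep("", 9)), focal = 1)
  f <- extract_scaffold_features(m_edge)
  expect_true(f$is_edge)

  m_flat <- make_map(c(rep("", 3), "major capsid protein", "spo0A",
                       "phage tail protein", rep("", 2)), focal = 5)
  f2 <- extract_scaffold_features(m_flat)
  expect_false(f2$is_edge)
  expect_equal(f2$strand_switch_frac, 0)
  expect_true(f2$hallmark_flanked)
  expect_equal(f2$nonviral_density, 0)

  alternating <- make_map(rep("enolase", 8),
                          strands = rep(c("+", "-"), 4), focal = 4)
  f3 <- extract_scaffold_features(alternating)
  expect_equal(f3$strand_switch_frac, 1)
  expect_equal(f3$nonviral_density, 1)
  expect_false(f3$hallmark_flanked)
})

test_that("the verdict rules fire as specified", {
  base <- tibble::tibble(scaffold_id = "s", ko_id = "K07699", n_genes = 20,
                         focal_index = 10, is_edge = FALSE,
                         strand_switch_frac = 0.05, nonviral_density = 0.1,
                         hallmark_flanked = TRUE, hypothetical_frac = 0.7)
  expect_equal(score_scaffold(base)$verdict, "true")

  edge <- dplyr::mutate(base, is_edge = TRUE)
  v_edge <- score_scaffold(edge)
  expect_equal(v_edge$verdict, "false")
  expect_match(v_edge$reasons, "focal_at_edge")

  bact <- dplyr::mutate(base, hallmark_flanked = FALSE,
                        nonviral_density = 0.7, strand_switch_frac = 0.6)
  v_bact <- score_scaffold(bact)
  expect_equal(v_bact$verdict, "false")
  expect_match(v_bact$reasons, "dense_nonviral_and_strand_switches")

  # either signal alone is not decisive
  dense_only <- dplyr::mutate(base, hallmark_flanked = FALSE,
                              nonviral_density = 0.7)
  expect_equal(score_scaffold(dense_only)$verdict, "maybe")
  switch_only <- dplyr::mutate(base, hallmark_flanked = FALSE,
                               strand_switch_frac = 0.6, nonviral_density = 0.3)
  expect_equal(score_scaffold(switch_only)$verdict, "maybe")

  unflanked <- dplyr::mutate(base, hallmark_flanked = FALSE,
                             nonviral_density = 0.3, strand_switch_frac = 0.2)
  expect_equal(score_scaffold(unflanked)$verdict, "maybe")
})

test_that("verdicts are invariant to the stored order of non-focal genes", {
  m <- simulate_scaffold("viral", 20, seed = 21)
  v1 <- curate_scaffold(m)
  withr::with_seed(1, {
    shuffled <- m$genes[sample(nrow(m$genes)), ]
  })
  m2 <- scaffold_map(shuffled, m$focal_gene_id, m$scaffold_id)
  v2 <- curate_scaffold(m2)
  expect_equal(v1$verdict, v2$verdict)
  expect_equal(v1$strand_switch_frac, v2$strand_switch_frac)
})

test_that("per-gene summaries follow the category thresholds and reconcile", {
  mk <- function(n_true, n_false, n_maybe, ko = "K1") {
    tibble::tibble(ko_id = ko,
                   verdict = rep(c("true", "false", "maybe"),
                                 c(n_true, n_false, n_maybe)))
  }
  s0 <- summarize_gene_curation(mk(0, 12, 0))
  expect_equal(s0$category, "unlikely viral")
  s3 <- summarize_gene_curation(mk(3, 2, 1))
  expect_equal(s3$category, "possible viral")
  s40 <- summarize_gene_curation(mk(40, 1, 2))
  expect_equal(s40$category, "likely viral")
  s5 <- summarize_gene_curation(mk(5, 0, 0))
  expect_equal(s5$category, "likely viral")  # threshold is exclusive at 5 "true"
  s4 <- summarize_gene_curation(mk(4, 0, 0))
  expect_equal(s4$category, "possible viral")

  multi <- dplyr::bind_rows(mk(2, 1, 1, "K1"), mk(0, 3, 0, "K2"))
  s <- summarize_gene_curation(multi)
  expect_equal(s$n_true + s$n_false + s$n_maybe, s$n_inspected)
  expect_equal(sort(s$category), sort(c("possible viral", "unlikely viral")))

  det <- tibble::tibble(ko_id = "K1", n_scaffolds_detected = 100L)
  s_det <- summarize_gene_curation(mk(2, 1, 0), n_scaffolds_detected = det)
  expect_equal(s_det$n_scaffolds_detected, 100L)
  expect_lte(s_det$n_inspected, s_det$n_scaffolds_detected)
})

test_that("generator fixtures separate cleanly under the default config", {
  set <- simulate_scaffold_set(rep(c("viral", "bacterial", "chimeric"),
                                   c(20, 10, 10)), seed = 33)
  v <- curate_scaffolds(set$maps)
  expect_gte(mean(v$verdict == set$truth$verdict), 0.95)
})
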