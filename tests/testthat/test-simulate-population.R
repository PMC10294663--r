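test_that("spore-host fraction is rounding-exact and hosts are assigned one-per-phage", {
  pop <- simulate_population(10, 0.5, gene_spec_table(1, 1), seed = 1)
  spore_hosts <- pop$hosts$host_id[pop$hosts$is_spore_former]
  expect_equal(nrow(pop$phages), 10)
  expect_equal(sum(pop$phages$host_id %in% spore_hosts), 5)
  expect_false(anyDuplicated(pop$phages$phage_id) > 0)

  pop2 <- simulate_population(9, 1 / 3, gene_spec_table(1, 1), seed = 1)
  expect_equal(sum(pop2$phages$host_id %in% spore_hosts), 3)
})

test_that("degenerate carriage probabilities put a gene in all and only spore-host phages", {
  genes <- tibble::tibble(ko_id = "K00001", is_sporulation = TRUE,
                          p_carry_spore_host = 1, p_carry_other = 0)
  pop <- simulate_population(40, 0.5, genes, seed = 3)
  spore_hosts <- pop$hosts$host_id[pop$hosts$is_spore_former]
  spore_phages <- pop$phages$phage_id[pop$phages$host_id %in% spore_hosts]
  carriers <- unique(pop$annotations$phage_id[pop$annotations$ko_id == "K00001"])
  expect_setequal(carriers, spore_phages)
})

test_that("observed carriage rates fall within 3 binomial standard errors", {
  genes <- tibble::tibble(ko_id = "Kx", is_sporulation = TRUE,
                          p_carry_spore_host = 0.2, p_carry_other = 0.02)
  pop <- simulate_population(2000, 0.3, genes, seed = 7)
  spore_hosts <- pop$hosts$host_id[pop$hosts$is_spore_former]
  is_spore <- pop$phages$host_id %in% spore_hosts
  carriers <- pop$phages$phage_id %in% pop$annotations$phage_id
  for (grp in c(TRUE, FALSE)) {
    p <- if (grp) 0.2 else 0.02
    n <- sum(is_spore == grp)
    obs <- mean(carriers[is_spore == grp])
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(obs - p), 3 * se)
  }
})

test_that("identical seeds give identical populations and truth labels are consistent", {
  genes <- gene_spec_table(3, 5)
  a <- simulate_population(100, 0.4, genes, seed = 9)
  b <- simulate_population(100, 0.4, genes, seed = 9)
  expect_identical(a, b)
  c <- simulate_population(100, 0.4, genes, seed = 10)
  expect_false(identical(a$annotations, c$annotations))

  expect_true(all(
    (a$truth$label == "enriched") ==
      (a$truth$p_carry_spore_host > a$truth$p_carry_other)
  ))
})

test_that("invalid specifications raise errors naming the field", {
  genes <- gene_spec_table(1, 1)
  expect_error(simulate_population(0, 0.5, genes), "n_phages",
               class = "phagetrait_validation_error")
  expect_error(simulate_population(10, 1.5, genes), "frac_spore_host",
               class = "phagetrait_validation_error")
  bad <- tibble::tibble(ko_id = "K1", is_sporulation = TRUE,
                        p_carry_spore_host = 1.2, p_carry_other = 0)
  expect_error(simulate_population(10, 0.5, bad), "p_carry_spore_host",
               class = "phagetrait_domain_error")
})

test_that("population TSVs round-trip through the ingest readers", {
  pop <- simulate_population(30, 0.5, gene_spec_table(2, 2), seed = 5)
  dir <- withr::local_tempdir()
  paths <- write_population(pop, dir)
  ann <- read_annotations(paths[["annotations"]])
  expect_equal(as.data.frame(ann), as.data.frame(pop$annotations))
  expect_equal(read_hosts(paths[["hosts"]])$is_spore_former,
               pop$hosts$is_spore_former)
  expect_equal(read_phages(paths[["phages"]])$phage_id, pop$phages$phage_id)
})
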