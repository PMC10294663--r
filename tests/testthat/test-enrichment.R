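test_that("upper-tail hypergeometric matches enumeration on known cases", {
  expect_equal(hypergeom_upper_tail(0, N = 100, K = 30, n = 10), 1.0)
  # C(4,3)*C(6,0)/C(10,3) = 4/120 = 1/30
  expect_equal(hypergeom_upper_tail(3, N = 10, K = 4, n = 3), 1 / 30,
               tolerance = 1e-12)
  expect_equal(hyper_upper_enum(3, 10, 4, 3), 1 / 30, tolerance = 1e-12)
  # (36 + 4)/120 = 1/3
  expect_equal(hypergeom_upper_tail(2, N = 10, K = 4, n = 3), 1 / 3,
               tolerance = 1e-12)
  expect_equal(hyper_upper_enum(2, 10, 4, 3), 1 / 3, tolerance = 1e-12)
})

test_that("arguments outside the hypergeometric support raise domain errors", {
  expect_error(hypergeom_upper_tail(4, N = 10, K = 4, n = 3),
               class = "phagetrait_domain_error")
  expect_error(hypergeom_upper_tail(0, N = 10, K = 11, n = 3),
               class = "phagetrait_domain_error")
  expect_error(hypergeom_upper_tail(1, N = 10, K = 4, n = 11),
               class = "phagetrait_domain_error")
})

test_that("the tail probability decreases as k increases at fixed (N, K, n)", {
  withr::with_seed(11, {
    for (rep in 1:25) {
      N <- sample(10:200, 1)
      K <- sample(0:N, 1)
      n <- sample(0:N, 1)
      ks <- seq(max(0, n + K - N), min(n, K))
      p <- hypergeom_upper_tail(ks, N = N, K = K, n = n)
      expect_true(all(diff(p) <= 1e-12))
    }
  })
})

test_that("BH adjustment matches hand-computed and naive step-up values", {
  expect_equal(adjust_pvalues(0.004), 0.004)
  expect_equal(adjust_pvalues(c(0.001, 0.01, 0.02, 0.04)),
               c(0.004, 0.02, 1 / 37.5, 0.04), tolerance = 1e-12)
  withr::with_seed(12, {
    for (rep in 1:20) {
      p <- runif(sample(1:50, 1))
      adj <- adjust_pvalues(p)
      expect_equal(adj, bh_naive(p), tolerance = 1e-12)
      expect_true(all(adj >= p - 1e-15))
    }
  })
  expect_error(adjust_pvalues(c(0.1, 1.2)), class = "phagetrait_domain_error")
})

test_that("the dual threshold excludes significant genes with too few homologs", {
  # K1: 10/10 detections in spore-host phages of a 400-phage universe --
  # wildly significant but n = 10 fails the exclusive n > 30 gate.
  # K2: 60 detections, 50 in spore-host phages -- significant AND abundant.
  hosts <- tibble::tibble(host_id = c("hS", "hN"), taxon = c("B", "E"),
                          is_spore_former = c(TRUE, FALSE))
  phages <- tibble::tibble(phage_id = sprintf("p%03d", 1:400),
                           host_id = rep(c("hS", "hN"), c(40, 360)))
  hits <- dplyr::bind_rows(
    tibble::tibble(phage_id = sprintf("p%03d", 1:10), ko_id = "K1"),
    tibble::tibble(phage_id = sprintf("p%03d", c(1:30, 41:70)), ko_id = "K2")
  )
  pm <- make_universe(hits, phages, hosts, kos = c("K1", "K2", "K3"))
  res <- test_enrichment(pm)

  expect_equal(nrow(res), 2)            # K3 absent everywhere: not tested
  k1 <- res[res$ko_id == "K1", ]
  expect_lt(k1$p_adj, 1e-6)
  expect_false(k1$enriched)             # fails n > 30
  k2 <- res[res$ko_id == "K2", ]
  expect_true(k2$enriched)
  expect_true(all(diff(res$p_adj) >= 0))  # sorted by adjusted p
  expect_true(all(res$p_adj >= res$p_raw))
  expect_equal(res$neg_log10_p, -log10(res$p_raw))
})

test_that("a degenerate host partition warns instead of failing", {
  hosts <- tibble::tibble(host_id = "hS", taxon = "B", is_spore_former = TRUE)
  phages <- tibble::tibble(phage_id = c("p1", "p2"), host_id = "hS")
  hits <- tibble::tibble(phage_id = "p1", ko_id = "K1")
  pm <- make_universe(hits, phages, hosts, "K1")
  expect_warning(res <- test_enrichment(pm), "degenerate")
  expect_equal(res$p_raw, 1)
})

test_that("planted enrichment is recovered and glance() reports the screen", {
  pop <- simulate_population(2000, 0.3, gene_spec_table(20, 200), seed = 7)
  pm <- build_presence_matrix(pop$annotations, pop$phages, pop$hosts, pop$truth)
  res <- test_enrichment(pm)
  joined <- dplyr::left_join(tibble::as_tibble(res),
                             pop$truth[, c("ko_id", "label")], by = "ko_id")
  expect_gte(sum(joined$enriched & joined$label == "enriched"), 19)
  expect_equal(sum(joined$enriched & joined$label == "null"), 0)
  g <- glance(res)
  expect_equal(g$N, 2000)
  expect_equal(g$K, 600)
  expect_equal(g$n_enriched, sum(res$enriched))
  expect_equal(g$adjust_method, "BH")
})
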