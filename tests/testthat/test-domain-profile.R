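hand_aln <- function() {
  tibble::tibble(
    sequence_id = c("a", "b", "c", "d", "v1", "v2"),
    group = c(rep("bacteria", 4), rep("virome", 2)),
    sequence = c("ACDEF", "AC-EF", "AC--F", "ACDE-", "--DEF", "---EF")
  )
}

test_that("per-group column coverage is an exact percentage", {
  cov <- column_coverage(hand_aln())
  bact <- cov[cov$group == "bacteria", ]
  expect_equal(bact$coverage_pct, c(100, 100, 50, 75, 75))
  vir <- cov[cov$group == "virome", ]
  expect_equal(vir$coverage_pct, c(0, 0, 50, 100, 100))
  expect_true(all(cov$coverage_pct >= 0 & cov$coverage_pct <= 100))
})

test_that("group-weighted mean of group coverages equals pooled coverage", {
  aln <- simulate_regulator_alignment(7, 5, indel_rate = 0.1, seed = 9)
  cov <- column_coverage(aln)
  pooled <- column_coverage(dplyr::mutate(aln, group = "all"))
  sizes <- table(aln$group)
  weighted <- dplyr::summarise(
    dplyr::group_by(cov, .data$column),
    w = sum(coverage_pct * as.numeric(sizes[group])) / sum(sizes),
    .groups = "drop"
  )
  expect_equal(weighted$w, pooled$coverage_pct, tolerance = 1e-12)
})

test_that("span coverage handles full, empty and partial spans", {
  expect_equal(span_coverage("ACDEF", c(1, 5)), 1.0)
  expect_equal(span_coverage("-----", c(1, 5)), 0.0)
  expect_equal(span_coverage(paste0(strrep("A", 9), "-"), c(1, 10)), 0.9)
  expect_error(span_coverage("ACDEF", c(2, 9)), class = "phagetrait_validation_error")
})

test_that("truncation calls recover the planted architecture exactly without noise", {
  aln <- simulate_regulator_alignment(6, 4, indel_rate = 0, seed = 10)
  calls <- call_truncation(aln)
  expect_identical(calls$call, aln$truth)
  expect_equal(calls$coverage_receiver[aln$truth == "effector_only"],
               rep(0, 4))
  expect_equal(calls$coverage_effector, rep(1, 10))
})

test_that("calls are invariant to sequence order and residue case", {
  aln <- simulate_regulator_alignment(5, 5, indel_rate = 0.05, seed = 11)
  calls <- call_truncation(aln)
  withr::with_seed(2, {
    perm <- sample(nrow(aln))
  })
  shuffled <- aln[perm, ]
  attr(shuffled, "receiver_span") <- attr(aln, "receiver_span")
  attr(shuffled, "effector_span") <- attr(aln, "effector_span")
  calls2 <- call_truncation(shuffled)
  expect_equal(calls2$call, calls$call[perm])

  lower <- dplyr::mutate(aln, sequence = tolower(sequence))
  calls3 <- call_truncation(lower, attr(aln, "receiver_span"),
                            attr(aln, "effector_span"))
  expect_equal(calls3$call, calls$call)
})

test_that("a sequence that covers neither rule is called 'other'", {
  aln <- tibble::tibble(
    sequence_id = "x", group = "virome",
    sequence = paste0(strrep("A", 3), strrep("-", 7))
  )
  calls <- call_truncation(aln, receiver_span = c(1, 5), effector_span = c(6, 10))
  expect_equal(calls$call, "other")
})

test_that("unlabeled sequences and ragged alignments are rejected", {
  bad <- tibble::tibble(sequence_id = c("a", "b"), group = c("g", NA),
                        sequence = c("AC", "AC"))
  expect_error(column_coverage(bad), class = "phagetrait_validation_error")
  ragged <- tibble::tibble(sequence_id = c("a", "b"), group = "g",
                           sequence = c("AC", "ACD"))
  expect_error(column_coverage(ragged), class = "phagetrait_validation_error")
})
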