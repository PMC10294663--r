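# Per-gene hypergeometric enrichment of detection among phages that infect
# spore-forming hosts, with FDR adjustment and the dual-threshold call
# (adjusted p below alpha AND more than min_n homologs detected).

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X` hypergeometric with population size `N`, `K` marked
#' members and `n` draws without replacement: the probability of seeing at
#' least `k` detections among spore-host phages if the gene's `n` carriers
#' were a random draw from all `N` phages surveyed. Vectorised over `k` and
#' `n`.
#'
#' @param k Observed successes (detections in spore-host phages).
#' @param N Population size (phages surveyed).
#' @param K Marked members (spore-host phages).
#' @param n Draws (phages in which the gene was detected).
#' @return Probability in \[0, 1\].
#' @export
#' @examples
#' hypergeom_upper_tail(3, N = 10, K = 4, n = 3)  # 1/30
hypergeom_upper_tail <- function(k, N, K, n) {
  N <- check_count(N, "N")
  K <- check_count(K, "K")
  if (K > N) {
    abort("`K` must not exceed `N`.", class = "phagetrait_domain_error")
  }
  if (any(is.na(k)) || any(is.na(n)) || any(n < 0) || any(n > N)) {
    abort("`n` must satisfy 0 <= n <= N.", class = "phagetrait_domain_error")
  }
  if (any(k < pmax(0, n + K - N)) || any(k > pmin(n, K))) {
    abort("`k` outside the hypergeometric support max(0, n+K-N) <= k <= min(n, K).",
          class = "phagetrait_domain_error")
  }
  phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment of p-values
#'
#' Step-up false-discovery-rate adjustment, returned in input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param method Adjustment method (passed to [stats::p.adjust()];
#'   default `"BH"`).
#' @return Adjusted p-values, elementwise at least as large as `p`.
#' @export
adjust_pvalues <- function(p, method = "BH") {
  check_probability_vec(p, "p")
  p.adjust(p, method = method)
}

#' Test every catalog gene for enrichment among spore-host phages
#'
#' For each catalog KO detected in at least one phage, computes the
#' upper-tail hypergeometric probability of its spore-host detection count,
#' adjusts across the tested set, and flags genes passing the dual
#' threshold: adjusted p below `alpha_adj` \emph{and} detection count
#' strictly above `min_n`. The plotting coordinate `neg_log10_p` uses the
#' raw hypergeometric p (the volcano y-axis); the enrichment call uses the
#' adjusted p. Both are reported.
#'
#' @param pm A [build_presence_matrix()] object.
#' @param alpha_adj Adjusted-p threshold (default `1e-6`).
#' @param min_n Minimum homolog count; the gate is exclusive (`n > min_n`,
#'   default 30).
#' @param adjust_method Multiple-testing method (default `"BH"`).
#' @return A tibble of class `enrichment_result`, sorted by adjusted p (ties
#'   broken by `ko_id`), with columns `ko_id`, `gene_name`,
#'   `is_sporulation`, `n`, `k`, `K`, `N`, `p_raw`, `p_adj`, `neg_log10_p`,
#'   `enriched`. Test configuration is kept in attributes.
#' @export
#' @examples
#' pop <- simulate_population(200, 0.3, gene_spec_table(2, 5), seed = 1)
#' pm <- build_presence_matrix(pop$annotations, pop$phages, pop$hosts,
#'                             catalog = pop$truth)
#' test_enrichment(pm)
test_enrichment <- function(pm, alpha_adj = 1e-6, min_n = 30,
                            adjust_method = "BH") {
  stopifnot(inherits(pm, "presence_matrix"))
  alpha_adj <- check_fraction(alpha_adj, "alpha_adj")
  if (alpha_adj <= 0 || alpha_adj >= 1) {
    abort("`alpha_adj` must be strictly between 0 and 1.",
          class = "phagetrait_validation_error")
  }
  min_n <- check_count(min_n, "min_n")
  if (pm$K == 0 || pm$K == pm$N) {
    warn(sprintf("degenerate host partition (K = %d of N = %d): the enrichment test carries no information.",
                 pm$K, pm$N))
  }

  n_all <- rowSums(pm$present)
  k_all <- rowSums(pm$present[, pm$spore_host, drop = FALSE])
  tested <- n_all >= 1
  res <- tibble(
    ko_id = pm$genes[tested],
    n = unname(n_all[tested]),
    k = unname(k_all[tested]),
    K = pm$K,
    N = pm$N
  )
  res$p_raw <- hypergeom_upper_tail(res$k, N = pm$N, K = pm$K, n = res$n)
  res$p_adj <- adjust_pvalues(res$p_raw, method = adjust_method)
  res$neg_log10_p <- -log10(res$p_raw)
  res$enriched <- res$p_adj < alpha_adj & res$n > min_n

  # carry human-readable catalog context when available (one name per KO)
  if (all(c("gene_name", "is_sporulation") %in% names(pm$catalog))) {
    name_map <- dplyr::summarise(
      dplyr::group_by(pm$catalog, .data$ko_id),
      gene_name = .data$gene_name[1],
      is_sporulation = any(.data$is_sporulation),
      .groups = "drop"
    )
    res <- dplyr::left_join(res, name_map, by = "ko_id")
  } else {
    res$gene_name <- NA_character_
    res$is_sporulation <- NA
  }
  res <- res[, c("ko_id", "gene_name", "is_sporulation", "n", "k", "K", "N",
                 "p_raw", "p_adj", "neg_log10_p", "enriched")]
  res <- dplyr::arrange(res, .data$p_adj, .data$ko_id)

  class(res) <- c("enrichment_result", class(tibble()))
  attr(res, "alpha_adj") <- alpha_adj
  attr(res, "min_n") <- min_n
  attr(res, "adjust_method") <- adjust_method
  res
}

#' Summarise an enrichment screen
#'
#' One-row overview: genes tested, genes flagged enriched, the test universe
#' (`N`, `K`) and the thresholds used.
#'
#' @param x An `enrichment_result` tibble.
#' @param ... Unused.
#' @export
glance.enrichment_result <- function(x, ...) {
  tibble(
    n_tested = nrow(x),
    n_enriched = sum(x$enriched),
    N = if (nrow(x)) x$N[1] else NA_integer_,
    K = if (nrow(x)) x$K[1] else NA_integer_,
    alpha_adj = attr(x, "alpha_adj"),
    min_n = attr(x, "min_n"),
    adjust_method = attr(x, "adjust_method")
  )
}

#' Volcano plot of an enrichment screen
#'
#' Detection count on the x-axis, `-log10` of the raw hypergeometric p on
#' the y-axis; dashed lines mark the dual enrichment threshold and enriched
#' genes are coloured.
#'
#' @param object An `enrichment_result` tibble from [test_enrichment()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.enrichment_result <- function(object, ...) {
  alpha <- attr(object, "alpha_adj") %||% 1e-6
  min_n <- attr(object, "min_n") %||% 30
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$n, y = .data$neg_log10_p,
                               colour = .data$enriched)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::geom_vline(xintercept = min_n, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50", `TRUE` = "purple")) +
    ggplot2::labs(x = "Homologs detected (n)",
                  y = expression(-log[10] ~ "(hypergeometric P)"),
                  colour = "Enriched") +
    ggplot2::theme_minimal()
}
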