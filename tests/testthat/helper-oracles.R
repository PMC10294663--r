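# Independent oracles, kept deliberately naive.

# upper-tail hypergeometric by exhaustive pmf enumeration with choose()
hyper_upper_enum <- function(k, N, K, n) {
  lo <- max(0, n + K - N)
  hi <- min(n, K)
  i <- seq(lo, hi)
  pmf <- choose(K, i) * choose(N - K, n - i) / choose(N, n)
  sum(pmf[i >= k])
}

# Benjamini-Hochberg step-up by the definition, double loop
bh_naive <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    vals <- numeric(m - i + 1)
    for (j in i:m) {
      vals[j - i + 1] <- p[ord[j]] * m / j
    }
    q_sorted[i] <- min(1, min(vals))
  }
  out <- numeric(m)
  out[ord] <- q_sorted
  out
}

# tiny hand-buildable presence universe: annotations for given hits
make_universe <- function(hits, phages, hosts, kos) {
  ann <- tibble::tibble(
    gene_id = sprintf("g%03d", seq_len(nrow(hits))),
    scaffold_id = paste0("scaf_", hits$phage_id),
    phage_id = hits$phage_id,
    start = 1L + (seq_len(nrow(hits)) - 1L) * 1000L,
    end = 900L + (seq_len(nrow(hits)) - 1L) * 1000L,
    strand = "+",
    ko_id = hits$ko_id,
    description = "x"
  )
  catalog <- tibble::tibble(ko_id = kos)
  build_presence_matrix(ann, phages, hosts, catalog)
}
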