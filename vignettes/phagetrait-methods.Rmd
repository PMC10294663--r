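---
title: "Screening phages for host-trait genes: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening phages for host-trait genes: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagetrait)
library(dplyr)
```

`phagetrait` screens phage genomes and metagenome-assembled viral scaffolds
for genes tied to a host trait — here, bacterial sporulation. This vignette
is the package's own account of the statistics and heuristics it implements,
the parameters that matter, what the synthetic-data generator does and does
not emulate, and the design choices made where more than one reasonable
option existed.

## 1. The enrichment model

The unit of testing is the KEGG ortholog (KO): annotation tables may map
several loci (e.g. a *B. subtilis* and a *C. difficile* gene) to the same KO,
and duplicate detections within one phage collapse to a single presence. The
test universe is **all phages surveyed with a host prediction**: phages with
zero catalog hits still count in `N`, while phages whose host is unknown are
excluded from the universe (their count is retained on the
`presence_matrix`). A phage counts as a *spore-host phage* when **any** of
its predicted hosts is a spore-former, because a phage-carried trait gene can
act whenever at least one of its hosts expresses the trait.

For a gene detected in `n` phages, `k` of them spore-host phages, among `N`
phages of which `K` are spore-host, the p-value is the exact upper tail
`P(X >= k)` of the hypergeometric distribution, computed via
`stats::phyper`. Benjamini–Hochberg adjustment (`stats::p.adjust`) is applied
across exactly the set of tested genes (those with `n >= 1`) **before** any
threshold filtering, so the adjustment is not distorted by pre-selection.
BH is used because it is the standard FDR control for gene-set screens; the
method name is carried in the result's attributes and is configurable.

The enrichment call is dual: `p_adj < alpha_adj` (default `1e-6`) **and**
`n > min_n` (default 30, an exclusive bound). "Sample size" here means the
number of phages in which the gene was detected — the x-axis of the volcano
plot — not the number of loci. The plotting coordinate `neg_log10_p` is
computed from the *raw* hypergeometric p (that is what the volcano y-axis
shows) while the call uses the adjusted p; both are reported so no
information is lost. Degenerate partitions (`K = 0` or `K = N`) produce a
warning and all-ones p-values rather than an error.

```{r enrichment-demo}
pop <- simulate_population(600, 0.3, gene_spec_table(4, 20), seed = 7)
pm <- build_presence_matrix(pop$annotations, pop$phages, pop$hosts, pop$truth)
res <- test_enrichment(pm)
glance(res)
```

## 2. The curation rule engine

Manual curation of viral scaffolds asks whether a focal detection is truly on
a phage genome or on contaminating bacterial sequence. The rule engine makes
those checks explicit and deterministic. Descriptions classify by
case-insensitive substring matching into `hallmark_viral` (virion, capsid,
tail, terminase, baseplate, phage, virus, reverse transcriptase, head),
`hypothetical` (empty, "hypothetical", "uncharacterized", "unknown
function"), or `other_annotation`. Around the focal gene, within a window of
`window = 10` genes per side, we measure: edge position (`edge_margin = 0`:
first/last gene), the strand-switch fraction over adjacent pairs, the
density of `other_annotation` genes (focal excluded), and hallmark flanking
(at least one hallmark gene within `flank_reach = 3` genes on *each* side).

The verdict is `"false"` if the focal gene is at the edge, or if
`nonviral_density > 0.5` **and** `strand_switch_frac > 0.4` — rejection
requires both signals jointly, since either alone is common on genuine phage
scaffolds; `"true"` if not rejected, hallmark-flanked, and the non-viral
density is at most 0.5; `"maybe"` otherwise, and every fired rule is
recorded. The original procedure was human judgment; the numeric thresholds
(window 10, flank reach 3, density 0.5, switch fraction 0.4) are this
package's operationalisation, chosen so that the qualitative criteria become
reproducible, and all are configurable via `curation_config()`. Edge is
defined by gene index, not base-pair distance, since the rejection concerns
the gene map's truncation. Per-gene categories follow the scaffold-count
logic: no "true" verdict → "unlikely viral", 1–4 → "possible viral", 5 or
more → "likely viral".

## 3. Domain-coverage profiling

`column_coverage()` reports, for each source group and alignment column, the
percentage of non-gap characters — the profile that makes a truncated
homolog family visible at a glance. `call_truncation()` reduces each
sequence to its non-gap coverage of two user-supplied column spans (receiver
and effector domains) and calls `full_length` when both are covered at
`present_min = 0.5` or more, `effector_only` when the effector is covered
but the receiver is at `absent_max = 0.1` or less, and `other` otherwise.
The 0.5/0.1 cutoffs are the package's own: a binary call needs explicit
thresholds, and these tolerate ragged alignment ends while still requiring a
receiver span that is essentially absent. Domain spans are supplied in
alignment-column coordinates rather than inferred from a reference sequence,
avoiding any hard-coded species numbering. Gap characters `-`, `.` and the
typographic minus are normalised on read; calls are invariant to residue
case and sequence order.

## 4. What the generator emulates — and what it does not

The synthetic module exists so that every downstream stage can be tested
against known ground truth.

* **Population** (`simulate_population()`): one host per phage (multi-host
  phages are handled by the ingest layer's any-host rule, but planting them
  would blur ground truth); exactly `round(n_phages * frac_spore_host)`
  spore-host phages; per-gene independent Bernoulli carriage with
  host-trait-dependent probability. A gene's truth label is "enriched" iff
  its spore-host carriage probability is strictly greater.
* **Scaffolds** (`simulate_scaffold()`): 900 bp genes with 100 bp spacers
  (coordinates only matter for ordering and edge logic); hallmark and
  housekeeping descriptions drawn from fixed phrase lists so keyword
  matching is exercised on realistic text; strand switches planted at an
  exact count — `floor(rate * pairs)` for viral maps (so the rate is never
  exceeded), `ceiling` and evenly spaced for bacterial maps (so every local
  window shows the bacterial signature). Chimeric maps put the focal gene
  mid-way into a bacterial block (70 % of genes) followed by a viral block.
* **Alignments** (`simulate_regulator_alignment()`): full-length sequences
  cover receiver through effector; effector-only sequences are all-gap
  across the receiver span, and indel noise (per-column gap flips) is never
  applied there, preserving the truth label. Default group sizes are 57
  bacterial and 29 virome sequences, the design of the motivating *spo0A*
  analysis.

Not emulated: sequence evolution (residues are i.i.d. draws — only gap
structure is meaningful), read-level metagenomics, assembly artifacts,
annotation-score columns, phylogenetic correlation between phages sharing
related hosts. Passing tests therefore demonstrate correctness of the
statistics and rule logic under the stated sampling model, not robustness to
real-data annotation noise or host-prediction error.

## 5. Study conditions used by the tests and acceptance script

Problem sizes were chosen as small-but-informative defaults: null
calibration uses 500 phages (30 % spore-host), 1,000 null genes at carriage
0.1 — the observed fraction of raw p-values below 0.05 stays under 0.06
because the discrete hypergeometric test is conservative. Planted recovery
uses 2,000 phages, 600 spore-host, 20 enriched genes (carriage 0.2 vs 0.02)
plus 200 null genes; null genes default to carriage 0.05 in both groups so
that they are genuinely tested (n ≈ 100 > 30) and the zero-false-positive
check is meaningful. Curation separability uses 50 viral + 25 bacterial +
25 chimeric scaffolds of 20 genes. The demo pipeline uses 600 phages, 8
enriched + 30 null genes, 6 scaffolds per gene. All randomness flows from a
single seed through fixed per-stage offsets, which is what makes doubled
runs byte-identical.

## 6. Numerical and degenerate-input choices

* The hypergeometric tail is exact (`phyper`), validated in the tests
  against direct pmf enumeration with `choose()` at relative error below
  1e-12 for all universes with `N <= 25`.
* Ties in the result ordering are broken by `ko_id` so output files are
  stable across platforms.
* Empty KO fields are retained as `NA` and simply never match the catalog;
  genes detected in zero phages are not tested (and so do not dilute the
  FDR adjustment).
* `p_raw` can underflow to 0 for extreme counts, making `neg_log10_p`
  infinite; the enrichment call is unaffected since it uses the adjusted
  p-value comparison directly.
* Windows are clipped at scaffold ends; a window with fewer than two genes
  has strand-switch fraction 0 by convention.

## 7. Final candidate rule and known limitations

The pipeline's final candidate set is the intersection of the enriched genes
with genes whose curation category is not "unlikely viral"; "possible viral"
genes are kept (flagged by their category column) since a handful of
confirmed viral scaffolds is evidence of viral carriage, with
`keep_possible_viral = FALSE` available for a stricter join.

Limitations worth keeping in mind: the enrichment test treats phages as
independent draws, so host-phylogeny-driven correlation will inflate
significance on real data; curation thresholds were tuned for clarity of the
rule logic, not fitted to any labelled corpus; and the coverage-based
truncation call cannot distinguish a genuinely truncated gene from a
fragmented scaffold that merely clips the alignment.
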