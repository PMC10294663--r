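# Synthetic scaffold gene maps emulating the situations seen in manual
# curation of uncultivated viral genomes: cleanly viral scaffolds with the
# focal gene nested among hallmark viral genes, bacterial fragments dense in
# annotated housekeeping genes with frequent strand switches, and chimeras.

.hallmark_phrases <- c(
  "major capsid protein", "phage tail fiber protein", "large terminase subunit",
  "baseplate wedge protein", "phage portal protein", "virion structural protein",
  "minor head protein", "virus attachment protein", "reverse transcriptase",
  "tail sheath protein", "phage integrase"
)

.housekeeping_phrases <- c(
  "DNA gyrase subunit A", "elongation factor Tu", "30S ribosomal protein S4",
  "ATP synthase F1 subunit beta", "citrate synthase", "glyceraldehyde-3-phosphate dehydrogenase",
  "aminopeptidase N", "glutamine synthetase", "peptidoglycan glycosyltransferase",
  "two-component sensor histidine kinase", "ABC transporter permease",
  "50S ribosomal protein L2", "enolase", "triosephosphate isomerase"
)

.hypothetical_phrases <- c("", "hypothetical protein", "uncharacterized protein",
                           "protein of unknown function")

#' Construct a scaffold map
#'
#' A scaffold map bundles the ordered gene annotations along one scaffold
#' with the identity of the focal gene under curation.
#'
#' @param genes Tibble of gene annotations for one scaffold, sorted by
#'   `start`, with at least `gene_id`, `start`, `end`, `strand`, `ko_id`,
#'   `description`.
#' @param focal_gene_id `gene_id` of the focal gene (must appear in `genes`).
#' @param scaffold_id Scaffold identifier.
#' @return An object of class `scaffold_map`.
#' @export
scaffold_map <- function(genes, focal_gene_id, scaffold_id = genes$scaffold_id[1]) {
  check_columns(genes, c("gene_id", "start", "end", "strand", "ko_id", "description"),
                "scaffold gene table")
  if (!focal_gene_id %in% genes$gene_id) {
    abort("`focal_gene_id` not present in the scaffold's gene table.",
          class = "phagetrait_validation_error")
  }
  if (is.unsorted(genes$start)) {
    genes <- dplyr::arrange(genes, .data$start)
  }
  if (any(genes$start > genes$end)) {
    abort("scaffold gene table has start > end.",
          class = "phagetrait_validation_error")
  }
  structure(
    list(scaffold_id = scaffold_id,
         genes = as_tibble(genes),
         focal_gene_id = focal_gene_id),
    class = "scaffold_map"
  )
}

#' @export
print.scaffold_map <- function(x, ...) {
  cat(sprintf("<scaffold_map> %s: %d genes, focal gene %s\n",
              x$scaffold_id, nrow(x$genes), x$focal_gene_id))
  invisible(x)
}

#' @rdname scaffold_map
#' @param x A `scaffold_map`.
#' @param ... Unused.
#' @return `tidy()` returns the gene tibble with an `is_focal` column.
#' @export
tidy.scaffold_map <- function(x, ...) {
  dplyr::mutate(x$genes, is_focal = .data$gene_id == x$focal_gene_id)
}

# choose strand vector with an exact planted number of adjacent switches;
# "even" spacing keeps the local switch fraction close to the global one in
# every window (bacterial fragments), "random" scatters the few viral ones
.strands_with_switches <- function(n_genes, n_switches, spacing = "random") {
  strands <- rep("+", n_genes)
  if (n_genes > 1 && n_switches > 0) {
    at <- if (spacing == "even") {
      n_pairs <- n_genes - 1L
      floor((seq_len(n_switches) - 0.5) * n_pairs / n_switches) + 1L
    } else {
      sort(sample(seq_len(n_genes - 1L), n_switches))
    }
    flip <- cumsum(seq_len(n_genes - 1L) %in% at) %% 2L
    strands[-1] <- ifelse(flip == 1L, "-", "+")
  }
  strands
}

# description pool for a viral gene block; focal slot handled by caller.
# Plants hallmark genes within `flank_reach` on each available side of the
# focal index, fills the rest mostly with hypotheticals.
.viral_descriptions <- function(n, focal_idx, hypothetical_fraction, flank_reach = 3L) {
  desc <- rep(NA_character_, n)
  left <- intersect(seq(focal_idx - flank_reach, focal_idx - 1L), seq_len(n))
  right <- intersect(seq(focal_idx + 1L, focal_idx + flank_reach), seq_len(n))
  planted <- integer(0)
  if (length(left)) planted <- c(planted, sample(left, 1))
  if (length(right)) planted <- c(planted, sample(right, 1))
  desc[planted] <- sample(.hallmark_phrases, length(planted), replace = TRUE)
  rest <- setdiff(seq_len(n), c(focal_idx, planted))
  n_hyp <- round(hypothetical_fraction * length(rest))
  hyp_at <- if (length(rest)) sample(rest, n_hyp) else integer(0)
  desc[hyp_at] <- sample(.hypothetical_phrases, n_hyp, replace = TRUE)
  leftover <- setdiff(rest, hyp_at)
  if (length(leftover)) {
    # split leftovers between extra hallmark genes and sparse other annotation
    extra_hall <- leftover[runif(length(leftover)) < 0.5]
    other <- setdiff(leftover, extra_hall)
    desc[extra_hall] <- sample(.hallmark_phrases, length(extra_hall), replace = TRUE)
    desc[other] <- sample(.housekeeping_phrases, length(other), replace = TRUE)
  }
  desc
}

.bacterial_descriptions <- function(n, focal_idx, hypothetical_fraction) {
  desc <- rep(NA_character_, n)
  rest <- setdiff(seq_len(n), focal_idx)
  n_hyp <- round(hypothetical_fraction * length(rest))
  hyp_at <- if (length(rest)) sample(rest, n_hyp) else integer(0)
  desc[hyp_at] <- sample(.hypothetical_phrases, n_hyp, replace = TRUE)
  annotated <- setdiff(rest, hyp_at)
  desc[annotated] <- sample(.housekeeping_phrases, length(annotated), replace = TRUE)
  desc
}

#' Simulate one scaffold gene map with known viral-origin ground truth
#'
#' Emulates the scaffold situations encountered when curating the origin of a
#' focal gene on an uncultivated viral genome:
#' \describe{
#'   \item{`"viral"`}{The focal gene sits in a phage gene block: flanked
#'     within `flank_reach` genes on each side by at least one hallmark viral
#'     gene, most other genes hypothetical, few strand switches. With
#'     `focal_position = "edge"` the focal gene is placed at the first or
#'     last position instead (the classic rejection case).}
#'   \item{`"bacterial"`}{A bacterial genome fragment: dense housekeeping
#'     annotations (at least 60\% of genes by default), no hallmark viral
#'     genes, frequent strand switches.}
#'   \item{`"chimeric"`}{A bacterial block containing the focal gene followed
#'     by a viral block.}
#' }
#' Coordinates are 1-based inclusive, non-overlapping and ascending
#' (900 bp genes with 100 bp spacers).
#'
#' @param kind `"viral"`, `"bacterial"` or `"chimeric"`.
#' @param n_genes Number of genes (>= 3; >= 5 for chimeric).
#' @param focal_ko KO identifier given to the focal gene.
#' @param focal_position `"interior"` or `"edge"` (viral kind only).
#' @param hypothetical_fraction Fraction of non-focal genes left
#'   hypothetical/unannotated. Defaults to 0.75 for viral blocks and 0.3 for
#'   bacterial blocks.
#' @param strand_switch_rate Target fraction of adjacent gene pairs on
#'   opposite strands. Defaults to 0.1 (viral) or 0.5 (bacterial/chimeric).
#'   The planted switch count is `floor(rate * pairs)` for viral blocks and
#'   `ceiling(rate * pairs)` for bacterial blocks, so viral maps never exceed
#'   and bacterial maps never undershoot the rate.
#' @param focal_description Free-text description of the focal gene.
#' @param scaffold_id Scaffold identifier.
#' @param seed Integer seed.
#'
#' @return A [scaffold_map()] with attribute `truth`: the expected curation
#'   verdict (`"true"` for interior-focal viral scaffolds, `"false"` for
#'   edge-focal, bacterial and chimeric scaffolds).
#' @export
#' @examples
#' m <- simulate_scaffold("viral", n_genes = 20, seed = 1)
#' tidy(m)
simulate_scaffold <- function(kind = c("viral", "bacterial", "chimeric"),
                              n_genes = 20,
                              focal_ko = "K07699",
                              focal_position = c("interior", "edge"),
                              hypothetical_fraction = NULL,
                              strand_switch_rate = NULL,
                              focal_description = "stage 0 sporulation protein A",
                              scaffold_id = NULL,
                              seed = 1L) {
  kind <- match.arg(kind)
  focal_position <- match.arg(focal_position)
  n_genes <- check_count(n_genes, "n_genes", min = 3L)
  if (kind == "chimeric" && n_genes < 5L) {
    abort("`n_genes` must be >= 5 for chimeric scaffolds (two blocks).",
          class = "phagetrait_validation_error")
  }
  if (is.null(hypothetical_fraction)) {
    hypothetical_fraction <- if (kind == "viral") 0.75 else 0.3
  }
  hypothetical_fraction <- check_fraction(hypothetical_fraction, "hypothetical_fraction")
  if (is.null(strand_switch_rate)) {
    strand_switch_rate <- if (kind == "viral") 0.1 else 0.5
  }
  strand_switch_rate <- check_fraction(strand_switch_rate, "strand_switch_rate")
  if (is.null(scaffold_id)) {
    scaffold_id <- sprintf("scaffold_%s_s%d", kind, as.integer(seed))
  }

  withr::with_seed(as.integer(seed), {
    n_pairs <- n_genes - 1L

    if (kind == "viral") {
      focal_idx <- if (focal_position == "edge") {
        sample(c(1L, n_genes), 1L)
      } else {
        sample(seq(2L, n_genes - 1L), 1L)
      }
      desc <- .viral_descriptions(n_genes, focal_idx, hypothetical_fraction)
      strands <- .strands_with_switches(n_genes, floor(strand_switch_rate * n_pairs))
      truth <- if (focal_position == "edge") "false" else "true"
    } else if (kind == "bacterial") {
      focal_idx <- sample(seq(2L, n_genes - 1L), 1L)
      desc <- .bacterial_descriptions(n_genes, focal_idx, hypothetical_fraction)
      strands <- .strands_with_switches(n_genes, ceiling(strand_switch_rate * n_pairs),
                                        spacing = "even")
      truth <- "false"
    } else { # chimeric: bacterial block with focal, then viral block
      n_bact <- max(4L, ceiling(0.7 * n_genes))
      n_vir <- n_genes - n_bact
      focal_idx <- max(2L, ceiling(n_bact / 2))
      desc_b <- .bacterial_descriptions(n_bact, focal_idx, hypothetical_fraction)
      desc_v <- .viral_descriptions(n_vir, focal_idx = 0L,
                                    hypothetical_fraction = 0.75)
      desc <- c(desc_b, desc_v)
      strands <- c(
        .strands_with_switches(n_bact, ceiling(strand_switch_rate * (n_bact - 1L)),
                               spacing = "even"),
        .strands_with_switches(n_vir, floor(0.1 * (n_vir - 1L)))
      )
      truth <- "false"
    }

    desc[focal_idx] <- focal_description
    genes <- tibble(
      gene_id = sprintf("%s_g%03d", scaffold_id, seq_len(n_genes)),
      scaffold_id = scaffold_id,
      start = (seq_len(n_genes) - 1L) * 1000L + 1L,
      end = (seq_len(n_genes) - 1L) * 1000L + 900L,
      strand = strands,
      ko_id = ifelse(seq_len(n_genes) == focal_idx, focal_ko, NA_character_),
      description = desc
    )
    out <- scaffold_map(genes, genes$gene_id[focal_idx], scaffold_id)
    attr(out, "truth") <- truth
    attr(out, "kind") <- kind
    out
  })
}

#' Simulate a labelled set of scaffolds
#'
#' Generates `n` scaffolds per requested kind with sequential seeds derived
#' from `seed`, returning them with their ground-truth verdicts.
#'
#' @param kinds Character vector of scaffold kinds, recycled descriptions of
#'   what to generate, e.g. `rep(c("viral", "bacterial"), c(50, 50))`.
#' @param focal_position Focal placements, recycled against `kinds`.
#' @param n_genes Genes per scaffold (recycled).
#' @param focal_ko Focal KO per scaffold (recycled).
#' @param seed Base integer seed.
#' @return A list with `maps` (list of [scaffold_map()]) and `truth` (tibble
#'   of `scaffold_id`, `kind`, `focal_position`, expected `verdict`).
#' @export
simulate_scaffold_set <- function(kinds, focal_position = "interior",
                                  n_genes = 20, focal_ko = "K07699", seed = 1L) {
  n <- length(kinds)
  focal_position <- rep_len(focal_position, n)
  n_genes <- rep_len(n_genes, n)
  focal_ko <- rep_len(focal_ko, n)
  maps <- purrr::pmap(
    list(kinds, focal_position, n_genes, focal_ko, seq_len(n)),
    function(kind, pos, ng, ko, i) {
      simulate_scaffold(kind, n_genes = ng, focal_ko = ko,
                        focal_position = if (kind == "viral") pos else "interior",
                        scaffold_id = sprintf("scaffold_%04d_%s", i, kind),
                        seed = derive_seed(seed, i))
    }
  )
  truth <- tibble(
    scaffold_id = purrr::map_chr(maps, "scaffold_id"),
    kind = kinds,
    focal_position = focal_position,
    verdict = purrr::map_chr(maps, attr, "truth")
  )
  list(maps = maps, truth = truth)
}
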