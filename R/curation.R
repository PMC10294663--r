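# Automated codification of the manual scaffold-curation rules: classify
# gene descriptions into hallmark-viral / hypothetical / other, extract
# contextual features around the focal gene, and decide whether the focal
# gene is of viral origin ("true"), bacterial contamination ("false") or
# undecidable ("maybe"); then roll verdicts up per gene.

#' Curation rule configuration
#'
#' All thresholds of the scaffold-curation rule engine. The hallmark keyword
#' list is the canonical virion vocabulary (virion, capsid, tail, terminase,
#' baseplate, phage, virus, reverse transcriptase, head); the quantitative
#' thresholds operationalise the qualitative signals used in manual
#' curation and are deliberately configurable.
#'
#' @param hallmark_keywords Lowercase substrings marking hallmark viral genes.
#' @param hypothetical_keywords Substrings (or empty text) marking
#'   hypothetical genes.
#' @param window Genes considered on each side of the focal gene.
#' @param flank_reach Genes on each side within which a hallmark gene counts
#'   as flanking.
#' @param max_nonviral_density Maximum fraction of "other annotation" genes
#'   in the window compatible with a viral context.
#' @param max_strand_switch Maximum fraction of adjacent gene pairs on
#'   opposite strands compatible with a viral context.
#' @param edge_margin Focal gene indices within `edge_margin` of either
#'   scaffold end are treated as edge cases (default 0: first/last gene
#'   only).
#' @param possible_viral_max Exclusive upper bound of "true" scaffolds for
#'   the per-gene category `"possible viral"` (default 5).
#' @return A list of class `curation_config`.
#' @export
curation_config <- function(hallmark_keywords = c("virion", "capsid", "tail",
                                                  "terminase", "baseplate",
                                                  "phage", "virus",
                                                  "reverse transcriptase", "head"),
                            hypothetical_keywords = c("hypothetical",
                                                      "uncharacterized",
                                                      "unknown function"),
                            window = 10L,
                            flank_reach = 3L,
                            max_nonviral_density = 0.5,
                            max_strand_switch = 0.4,
                            edge_margin = 0L,
                            possible_viral_max = 5L) {
  window <- check_count(window, "window", min = 1L)
  flank_reach <- check_count(flank_reach, "flank_reach", min = 1L)
  if (window < flank_reach) {
    abort("`window` must be >= `flank_reach`.",
          class = "phagetrait_validation_error")
  }
  structure(
    list(hallmark_keywords = tolower(hallmark_keywords),
         hypothetical_keywords = tolower(hypothetical_keywords),
         window = window,
         flank_reach = flank_reach,
         max_nonviral_density = check_fraction(max_nonviral_density, "max_nonviral_density"),
         max_strand_switch = check_fraction(max_strand_switch, "max_strand_switch"),
         edge_margin = check_count(edge_margin, "edge_margin"),
         possible_viral_max = check_count(possible_viral_max, "possible_viral_max", min = 1L)),
    class = "curation_config"
  )
}

#' Classify gene descriptions into curation colour classes
#'
#' Case-insensitive substring matching on the free-text description:
#' `"hallmark_viral"` if any hallmark keyword occurs, else `"hypothetical"`
#' if the description is empty/missing or matches a hypothetical keyword,
#' else `"other_annotation"`. Vectorised and total (never errors).
#'
#' @param description Character vector of gene descriptions.
#' @param config A [curation_config()].
#' @return Character vector of classes.
#' @export
#' @examples
#' classify_gene_function(c("Major Capsid Protein", "", "DNA gyrase subunit A"))
classify_gene_function <- function(description, config = curation_config()) {
  d <- tolower(ifelse(is.na(description), "", description))
  has_any <- function(keys) {
    Reduce(`|`, lapply(keys, function(k) grepl(k, d, fixed = TRUE)),
           init = rep(FALSE, length(d)))
  }
  hallmark <- has_any(config$hallmark_keywords)
  hypo <- trimws(d) == "" | has_any(config$hypothetical_keywords)
  ifelse(hallmark, "hallmark_viral",
         ifelse(hypo, "hypothetical", "other_annotation"))
}

#' Extract curation features around the focal gene of a scaffold
#'
#' Computes, within a window of `config$window` genes on each side of the
#' focal gene: whether the focal gene sits at the scaffold edge, the
#' strand-switch fraction over adjacent gene pairs, the density of
#' non-viral annotated genes (focal gene excluded), whether at least one
#' hallmark viral gene lies within `flank_reach` genes on \emph{each} side,
#' and the hypothetical fraction.
#'
#' @param map A [scaffold_map()].
#' @param config A [curation_config()].
#' @return A one-row tibble of features.
#' @export
extract_scaffold_features <- function(map, config = curation_config()) {
  stopifnot(inherits(map, "scaffold_map"))
  genes <- map$genes
  n <- nrow(genes)
  focal_idx <- match(map$focal_gene_id, genes$gene_id)
  classes <- classify_gene_function(genes$description, config)

  is_edge <- focal_idx <= config$edge_margin + 1L ||
    focal_idx >= n - config$edge_margin

  win <- seq(max(1L, focal_idx - config$window),
             min(n, focal_idx + config$window))
  strands <- genes$strand[win]
  n_pairs <- length(strands) - 1L
  strand_switch_frac <- if (n_pairs > 0) {
    mean(strands[-1] != strands[-length(strands)])
  } else 0

  win_classes <- classes[setdiff(win, focal_idx)]
  nonviral_density <- if (length(win_classes)) {
    mean(win_classes == "other_annotation")
  } else 0
  hypothetical_frac <- if (length(win_classes)) {
    mean(win_classes == "hypothetical")
  } else 0

  left <- seq(max(1L, focal_idx - config$flank_reach), focal_idx - 1L)
  left <- left[left >= 1 & left < focal_idx]
  right <- seq(focal_idx + 1L, min(n, focal_idx + config$flank_reach))
  right <- right[right > focal_idx & right <= n]
  hallmark_flanked <- length(left) > 0 && length(right) > 0 &&
    any(classes[left] == "hallmark_viral") &&
    any(classes[right] == "hallmark_viral")

  tibble(
    scaffold_id = map$scaffold_id,
    ko_id = genes$ko_id[focal_idx],
    n_genes = n,
    focal_index = focal_idx,
    is_edge = is_edge,
    strand_switch_frac = strand_switch_frac,
    nonviral_density = nonviral_density,
    hallmark_flanked = hallmark_flanked,
    hypothetical_frac = hypothetical_frac
  )
}

#' Score one scaffold's features into a viral-origin verdict
#'
#' The rule engine: the focal gene is rejected (`"false"`) if it sits at
#' the scaffold edge, or if the window shows both a high non-viral
#' annotation density \emph{and} a high strand-switch fraction (the joint
#' signature of a bacterial genome fragment). It is accepted (`"true"`) if
#' not rejected, flanked by hallmark viral genes on both sides, and the
#' non-viral density is at most the configured maximum. Anything else is
#' `"maybe"`. Every rule that fired is recorded.
#'
#' @param features One-row tibble from [extract_scaffold_features()].
#' @param config The same [curation_config()] used for feature extraction.
#' @return A one-row tibble with `scaffold_id`, `ko_id`, `verdict`, the
#'   features, and a `reasons` string (`";"`-separated rule names).
#' @export
score_scaffold <- function(features, config = curation_config()) {
  stopifnot(nrow(features) == 1)
  reasons <- character(0)
  if (features$is_edge) reasons <- c(reasons, "focal_at_edge")
  bacterial_context <- features$nonviral_density > config$max_nonviral_density &&
    features$strand_switch_frac > config$max_strand_switch
  if (bacterial_context) reasons <- c(reasons, "dense_nonviral_and_strand_switches")

  if (features$is_edge || bacterial_context) {
    verdict <- "false"
  } else if (features$hallmark_flanked &&
             features$nonviral_density <= config$max_nonviral_density) {
    verdict <- "true"
    reasons <- c(reasons, "hallmark_flanked_low_nonviral_density")
  } else {
    verdict <- "maybe"
    reasons <- c(reasons, "no_rule_decisive")
  }

  dplyr::mutate(features,
                verdict = verdict,
                reasons = paste(reasons, collapse = ";"))
}

#' Curate one scaffold or a set of scaffolds
#'
#' `curate_scaffold()` extracts features and scores them in one step;
#' `curate_scaffolds()` maps over a list of scaffold maps and binds the
#' verdicts into one tibble.
#'
#' @param map A [scaffold_map()]; `maps` a list of them.
#' @param maps List of scaffold maps.
#' @param config A [curation_config()].
#' @return A tibble with one verdict row per scaffold.
#' @export
curate_scaffold <- function(map, config = curation_config()) {
  score_scaffold(extract_scaffold_features(map, config), config)
}

#' @rdname curate_scaffold
#' @export
curate_scaffolds <- function(maps, config = curation_config()) {
  purrr::map_dfr(maps, curate_scaffold, config = config)
}

#' Roll scaffold verdicts up into per-gene curation categories
#'
#' Counts `"true"`, `"false"` and `"maybe"` verdicts per KO and assigns the
#' per-gene category: `"unlikely viral"` when a true viral origin was never
#' observed, `"possible viral"` when observed on fewer than
#' `possible_viral_max` scaffolds, and `"likely viral"` otherwise.
#'
#' @param verdicts Verdict tibble from [curate_scaffolds()] (may hold many
#'   KOs).
#' @param n_scaffolds_detected Optional tibble (`ko_id`,
#'   `n_scaffolds_detected`) giving how many scaffolds carried each gene in
#'   total; defaults to the number inspected.
#' @param config A [curation_config()].
#' @return A tibble with one row per KO: counts (`n_inspected`, `n_true`,
#'   `n_false`, `n_maybe`, `n_scaffolds_detected`) and `category`.
#' @export
summarize_gene_curation <- function(verdicts, n_scaffolds_detected = NULL,
                                    config = curation_config()) {
  check_columns(verdicts, c("ko_id", "verdict"), "verdict table")
  bad <- setdiff(unique(verdicts$verdict), c("true", "false", "maybe"))
  if (length(bad) > 0) {
    abort(sprintf("verdicts must be true/false/maybe (got: %s).",
                  paste(bad, collapse = ", ")),
          class = "phagetrait_validation_error")
  }
  out <- dplyr::summarise(
    dplyr::group_by(verdicts, .data$ko_id),
    n_inspected = dplyr::n(),
    n_true = sum(.data$verdict == "true"),
    n_false = sum(.data$verdict == "false"),
    n_maybe = sum(.data$verdict == "maybe"),
    .groups = "drop"
  )
  if (is.null(n_scaffolds_detected)) {
    out$n_scaffolds_detected <- out$n_inspected
  } else {
    check_columns(n_scaffolds_detected, c("ko_id", "n_scaffolds_detected"),
                  "`n_scaffolds_detected`")
    out <- dplyr::left_join(out, n_scaffolds_detected, by = "ko_id")
    out$n_scaffolds_detected <- dplyr::coalesce(out$n_scaffolds_detected,
                                                out$n_inspected)
  }
  out$category <- dplyr::case_when(
    out$n_true == 0 ~ "unlikely viral",
    out$n_true < config$possible_viral_max ~ "possible viral",
    .default = "likely viral"
  )
  out
}
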