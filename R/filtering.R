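#' Filtering thresholds for the quality / functional-rarity cascade
#'
#' Defaults are the cascade applied to buccal-derived exome calls in this kind
#' of study: at least 5 reads supporting the alternate allele and 10 at the
#' position, genotype quality >= 10, mapping quality >= 60, population minor
#' allele frequency < 1% in every panel with data, non-synonymous coding or
#' splice-junction consequence, and at least one deleteriousness prediction
#' when any algorithm produced one. All four quality minima are inclusive.
#'
#' @param min_allele_depth Minimum reads supporting the alt allele (>=).
#' @param min_position_depth Minimum total reads at the position (>=).
#' @param min_genotype_quality Minimum phred genotype quality (>=).
#' @param min_mapping_quality Minimum mapping quality (>=).
#' @param max_maf Variants with panel AF >= this fraction are removed
#'   (strict `<` comparison: a variant at exactly 1% is not rare).
#' @param retained_consequences Consequence classes kept by the functional
#'   filter.
#' @param deleterious_rule How prediction votes combine: `"any_vote"` (>= 1
#'   algorithm calls deleterious), `"majority_vote"` (> half), or
#'   `"all_votes"`. A variant with no predictions (`deleterious_total = 0`)
#'   always passes.
#' @param rarity_mode `"all_panels"`: every panel with data must show
#'   AF < `max_maf` (a variant common in any panel is removed).
#'   `"any_panel"`: one panel below `max_maf` suffices. Absence from all
#'   panels counts as rare in both modes.
#' @return An object of class `filter_thresholds`.
#' @export
filter_thresholds <- function(min_allele_depth = 5L,
                              min_position_depth = 10L,
                              min_genotype_quality = 10L,
                              min_mapping_quality = 60L,
                              max_maf = 0.01,
                              retained_consequences = functional_consequences(),
                              deleterious_rule = c("any_vote", "majority_vote", "all_votes"),
                              rarity_mode = c("all_panels", "any_panel")) {
  deleterious_rule <- match.arg(deleterious_rule)
  rarity_mode <- match.arg(rarity_mode)
  stopifnot(
    min_allele_depth >= 0, min_position_depth >= 0,
    min_genotype_quality >= 0, min_mapping_quality >= 0,
    max_maf > 0, max_maf <= 1,
    length(retained_consequences) > 0
  )
  if (!all(retained_consequences %in% consequence_levels())) {
    stop("retained_consequences contains unknown consequence classes")
  }
  structure(
    list(
      min_allele_depth = as.integer(min_allele_depth),
      min_position_depth = as.integer(min_position_depth),
      min_genotype_quality = as.integer(min_genotype_quality),
      min_mapping_quality = as.integer(min_mapping_quality),
      max_maf = max_maf,
      retained_consequences = retained_consequences,
      deleterious_rule = deleterious_rule,
      rarity_mode = rarity_mode
    ),
    class = "filter_thresholds"
  )
}

#' @export
print.filter_thresholds <- function(x, ...) {
  cat("<filter_thresholds>\n")
  cat(
    "  quality: alt depth >=", x$min_allele_depth,
    "| position depth >=", x$min_position_depth,
    "| GQ >=", x$min_genotype_quality,
    "| MQ >=", x$min_mapping_quality, "\n"
  )
  cat(
    "  rarity: AF <", x$max_maf, "(", x$rarity_mode, ")",
    "| deleterious:", x$deleterious_rule, "\n"
  )
  cat("  consequences:", paste(x$retained_consequences, collapse = ", "), "\n")
  invisible(x)
}

new_filtered_profile <- function(sample_id, variants, counts) {
  structure(
    list(sample_id = sample_id, variants = variants, counts = counts),
    class = "filtered_profile"
  )
}

#' @export
print.filtered_profile <- function(x, ...) {
  cat(
    "<filtered_profile> sample", x$sample_id, "-", nrow(x$variants),
    "variants retained\n"
  )
  cat("  cascade:", paste(names(x$counts), x$counts, sep = "=", collapse = " > "), "\n")
  invisible(x)
}

#' Apply the quality filter cascade to one sample's variants
#'
#' Retains exactly the variants with `alt_depth >= min_allele_depth`,
#' `total_depth >= min_position_depth`, `genotype_quality >=
#' min_genotype_quality` and `mapping_quality >= min_mapping_quality`.
#' Missing (`NA`) metrics fail their stage: a variant whose per-allele depth
#' cannot be established is dropped rather than assumed adequate.
#'
#' @param variants Annotated-variant tibble, all rows from one sample.
#' @param thresholds A [filter_thresholds()] object.
#' @return A `filtered_profile` with per-stage survivor counts in cascade
#'   order (`input`, `allele_depth`, `position_depth`, `genotype_quality`,
#'   `mapping_quality`).
#' @export
apply_quality_filters <- function(variants, thresholds = filter_thresholds()) {
  validate_variant_table(variants)
  sids <- unique(variants$sample_id)
  if (length(sids) > 1) {
    stop("variants span multiple sample_ids: ", paste(sids, collapse = ", "))
  }
  sample_id <- if (length(sids) == 1) sids else NA_character_
  counts <- c(input = nrow(variants))

  keep <- !is.na(variants$alt_depth) &
    variants$alt_depth >= thresholds$min_allele_depth
  variants <- variants[keep, , drop = FALSE]
  counts["allele_depth"] <- nrow(variants)

  keep <- !is.na(variants$total_depth) &
    variants$total_depth >= thresholds$min_position_depth
  variants <- variants[keep, , drop = FALSE]
  counts["position_depth"] <- nrow(variants)

  keep <- !is.na(variants$genotype_quality) &
    variants$genotype_quality >= thresholds$min_genotype_quality
  variants <- variants[keep, , drop = FALSE]
  counts["genotype_quality"] <- nrow(variants)

  keep <- !is.na(variants$mapping_quality) &
    variants$mapping_quality >= thresholds$min_mapping_quality
  variants <- variants[keep, , drop = FALSE]
  counts["mapping_quality"] <- nrow(variants)

  new_filtered_profile(sample_id, variants, counts)
}

# Rarity predicate over the af_* panel columns of a variant table.
is_rare <- function(variants, max_maf, rarity_mode) {
  cols <- af_columns(variants)
  if (length(cols) == 0 || nrow(variants) == 0) {
    return(rep(TRUE, nrow(variants)))
  }
  af <- as.matrix(variants[, cols, drop = FALSE])
  has_data <- !is.na(af)
  below <- has_data & af < max_maf
  if (rarity_mode == "all_panels") {
    # every panel with data must be < max_maf; no data at all counts as rare
    rowSums(has_data & !below) == 0
  } else {
    rowSums(below) > 0 | rowSums(has_data) == 0
  }
}

# Deleteriousness predicate; total == 0 (no prediction available) passes.
is_deleterious <- function(votes, total, rule) {
  no_pred <- total == 0
  hit <- switch(rule,
    any_vote = votes >= 1,
    majority_vote = votes * 2 > total,
    all_votes = votes == total & total > 0
  )
  no_pred | hit
}

#' Apply the functional / rarity / deleteriousness filters
#'
#' Continues the cascade begun by [apply_quality_filters()]: retains variants
#' whose consequence is in `retained_consequences`, that are rare under
#' `rarity_mode` / `max_maf`, and that satisfy `deleterious_rule`.
#'
#' @param profile A `filtered_profile` from [apply_quality_filters()].
#' @param thresholds A [filter_thresholds()] object.
#' @return The profile with stages `consequence`, `rarity`, `deleterious`
#'   appended to its cascade counts.
#' @export
apply_functional_rarity_filters <- function(profile, thresholds = filter_thresholds()) {
  stopifnot(inherits(profile, "filtered_profile"))
  variants <- profile$variants
  counts <- profile$counts

  keep <- variants$consequence %in% thresholds$retained_consequences
  variants <- variants[keep, , drop = FALSE]
  counts["consequence"] <- nrow(variants)

  keep <- is_rare(variants, thresholds$max_maf, thresholds$rarity_mode)
  variants <- variants[keep, , drop = FALSE]
  counts["rarity"] <- nrow(variants)

  keep <- is_deleterious(
    variants$deleterious_votes, variants$deleterious_total,
    thresholds$deleterious_rule
  )
  variants <- variants[keep, , drop = FALSE]
  counts["deleterious"] <- nrow(variants)

  new_filtered_profile(profile$sample_id, variants, counts)
}

#' Run the full filter cascade on one sample's variants
#'
#' Convenience wrapper: [apply_quality_filters()] followed by
#' [apply_functional_rarity_filters()].
#'
#' @inheritParams apply_quality_filters
#' @return A fully filtered `filtered_profile`.
#' @export
filter_variants <- function(variants, thresholds = filter_thresholds()) {
  apply_functional_rarity_filters(
    apply_quality_filters(variants, thresholds), thresholds
  )
}

#' Count candidate-gene variants in a filtered profile
#'
#' @param profile A fully filtered `filtered_profile`.
#' @param gene_set A [gene_set()] of candidate genes.
#' @return List with `candidate_count` (retained variants in candidate
#'   genes), `total_count` (all retained variants) and `variant_gene_set`
#'   (distinct genes carrying >= 1 retained variant).
#' @export
count_candidate_variants <- function(profile, gene_set) {
  stopifnot(inherits(profile, "filtered_profile"), inherits(gene_set, "gene_set"))
  v <- profile$variants
  genes <- v$gene[!is.na(v$gene)]
  list(
    candidate_count = sum(genes %in% gene_set$genes),
    total_count = nrow(v),
    variant_gene_set = sort(unique(genes))
  )
}
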