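#' Build the gene-by-individual variability matrix
#'
#' Counts retained rare, non-synonymous, predicted-deleterious variants per
#' candidate gene per individual — the data behind a "colored square per
#' variant" heatmap. Rows follow the order of `gene_set` genes that carry at
#' least one variant; columns follow the order of `samples`, so matched duos
#' stay aligned when the sample table lists them pairwise.
#'
#' @param profiles Named list of fully filtered `filtered_profile` objects.
#' @param gene_set A [gene_set()] restricting the genes counted.
#' @param samples Sample table (`sample_id`, `role`, `cohort`, `duo_id`);
#'   every profile must appear in it.
#' @return An object of class `variability_matrix`: list with `genes`,
#'   `individuals` (the sample table rows used, in column order) and
#'   `counts` (integer matrix genes x individuals).
#' @export
build_matrix <- function(profiles, gene_set, samples) {
  stopifnot(inherits(gene_set, "gene_set"))
  ids <- names(profiles)
  if (is.null(ids) && length(profiles) > 0) {
    ids <- vapply(profiles, function(p) p$sample_id, character(1))
    names(profiles) <- ids
  }
  unknown <- setdiff(ids, samples$sample_id)
  if (length(unknown) > 0) {
    stop(
      "profiles present for samples missing from the sample table: ",
      paste(unknown, collapse = ", ")
    )
  }
  individuals <- samples[samples$sample_id %in% ids, , drop = FALSE]
  ids <- individuals$sample_id
  tallies <- lapply(ids, function(id) {
    v <- profiles[[id]]$variants
    g <- v$gene[!is.na(v$gene) & v$gene %in% gene_set$genes]
    table(g)
  })
  genes <- sort(unique(unlist(lapply(tallies, names))))
  counts <- matrix(0L,
    nrow = length(genes), ncol = length(ids),
    dimnames = list(genes, ids)
  )
  for (j in seq_along(ids)) {
    tl <- tallies[[j]]
    if (length(tl) > 0) {
      counts[names(tl), j] <- as.integer(tl)
    }
  }
  structure(
    list(genes = genes, individuals = tibble::as_tibble(individuals), counts = counts),
    class = "variability_matrix"
  )
}

#' @export
print.variability_matrix <- function(x, ...) {
  cat(
    "<variability_matrix>", length(x$genes), "genes x",
    nrow(x$individuals), "individuals;",
    sum(x$counts), "variants total\n"
  )
  invisible(x)
}

#' Rank the top variant candidate genes
#'
#' Genes are ordered breadth-first: by the number of individuals carrying at
#' least one retained variant (descending), then by total variant count
#' (descending), then alphabetically — so a gene variant in many individuals
#' outranks one with many variants in few. The ordering is a total order and
#' therefore stable under permutation of the input.
#'
#' @param matrix A `variability_matrix` from [build_matrix()].
#' @param n Number of genes to return (default 50). If fewer genes carry any
#'   variant, all of them are returned.
#' @return Character vector of gene symbols, best first.
#' @export
rank_top_genes <- function(matrix, n = 50L) {
  stopifnot(inherits(matrix, "variability_matrix"), n >= 1)
  cm <- matrix$counts
  if (nrow(cm) == 0) {
    return(character(0))
  }
  n_individuals <- rowSums(cm >= 1)
  totals <- rowSums(cm)
  keep <- totals >= 1
  genes <- rownames(cm)[keep]
  ord <- order(-n_individuals[keep], -totals[keep], genes)
  utils::head(genes[ord], n)
}

#' Correlation between per-gene variant counts and gene size
#'
#' Ordinary least-squares R-squared of total retained variant counts on
#' coding length — the check that an apparent candidate-gene excess is not
#' merely a gene-size artefact. Genes without a model are dropped; genes with
#' a model but no observed variant count as zero only if present in
#' `per_gene_counts`.
#'
#' @param per_gene_counts Named numeric vector (or list) mapping gene symbol
#'   to total variant count.
#' @param gene_models Data frame with columns `gene`, `coding_length`.
#' @return R-squared in `[0, 1]`; counts with zero variance across genes give
#'   0 by definition.
#' @export
gene_size_correlation <- function(per_gene_counts, gene_models) {
  counts <- unlist(per_gene_counts)
  if (is.null(names(counts))) {
    stop("per_gene_counts must be named by gene symbol")
  }
  m <- match(names(counts), gene_models$gene)
  usable <- !is.na(m)
  counts <- counts[usable]
  lengths <- gene_models$coding_length[m[usable]]
  if (length(counts) < 3) {
    stop("need at least 3 genes with both a count and a gene model")
  }
  if (length(unique(lengths)) < 2) {
    stop("need at least two distinct coding lengths")
  }
  if (stats::var(counts) == 0) {
    return(0)
  }
  fit <- stats::lm(counts ~ lengths)
  rss <- sum(fit$residuals^2)
  tss <- sum((counts - mean(counts))^2)
  max(0, min(1, 1 - rss / tss))
}
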