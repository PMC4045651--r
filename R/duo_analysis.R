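#' Attribute infant variants as maternal or non-maternal
#'
#' An infant variant is labelled `maternal` iff its identity key
#' `(chrom, pos, ref, alt)` occurs among the mother's retained variants, and
#' `non_maternal` otherwise. Matching is presence-based: zygosity is ignored
#' because buccal-derived calls at modest per-allele depth do not support
#' confident genotypes, and the downstream compound-heterozygote rule only
#' needs presence. With no father sequenced, `non_maternal` conflates
#' paternal inheritance and de novo mutation.
#'
#' @param infant_profile,mother_profile Fully filtered `filtered_profile`
#'   objects for the infant and the matching mother (same thresholds).
#' @return Tibble of the infant's variants with an added `origin` column
#'   (`"maternal"` / `"non_maternal"`) and the identity `key`.
#' @export
attribute_origin <- function(infant_profile, mother_profile) {
  stopifnot(
    inherits(infant_profile, "filtered_profile"),
    inherits(mother_profile, "filtered_profile")
  )
  if (identical(infant_profile$sample_id, mother_profile$sample_id) &&
      !is.na(infant_profile$sample_id)) {
    stop("infant and mother profiles are from the same sample_id")
  }
  iv <- infant_profile$variants
  mv <- mother_profile$variants
  key_of <- function(v) variant_key(v$chrom, v$pos, v$ref, v$alt)
  iv$key <- if (nrow(iv) > 0) key_of(iv) else character(0)
  mother_keys <- if (nrow(mv) > 0) unique(key_of(mv)) else character(0)
  iv$origin <- ifelse(iv$key %in% mother_keys, "maternal", "non_maternal")
  tibble::as_tibble(iv)
}

#' Call compound-heterozygous genes in one infant
#'
#' A gene is called when the infant carries at least two retained variants at
#' distinct sites in it, at least one maternal and at least one non-maternal.
#' This is the presence-based, unphased surrogate for a true trans
#' configuration: without phase information (no trios were sequenced), one
#' allele demonstrably inherited from the mother plus one demonstrably not
#' present in her is the strongest available evidence that the two hits sit
#' on different haplotypes.
#'
#' @param attributed Tibble from [attribute_origin()] (one infant).
#' @param duo_id Identifier of the mother-infant duo.
#' @return Tibble with one row per called gene, sorted by gene symbol:
#'   columns `duo_id`, `gene`, `n_maternal`, `n_non_maternal`, `n_total`,
#'   and list-columns `maternal_keys`, `non_maternal_keys` holding the
#'   distinct variant identity keys on each side.
#' @export
detect_compound_het <- function(attributed, duo_id) {
  empty <- tibble::tibble(
    duo_id = character(), gene = character(),
    n_maternal = integer(), n_non_maternal = integer(), n_total = integer(),
    maternal_keys = list(), non_maternal_keys = list()
  )
  if (nrow(attributed) == 0) {
    return(empty)
  }
  stopifnot(all(c("gene", "origin", "key") %in% names(attributed)))
  av <- attributed[!is.na(attributed$gene), , drop = FALSE]
  if (nrow(av) == 0) {
    return(empty)
  }
  rows <- lapply(sort(unique(av$gene)), function(g) {
    gv <- av[av$gene == g, , drop = FALSE]
    # distinct sites only: the same key carried twice is one allele observed
    mat <- unique(gv$key[gv$origin == "maternal"])
    non <- unique(gv$key[gv$origin == "non_maternal"])
    if (length(mat) >= 1 && length(non) >= 1 &&
        length(unique(c(mat, non))) >= 2) {
      tibble::tibble(
        duo_id = duo_id, gene = g,
        n_maternal = length(mat), n_non_maternal = length(non),
        n_total = length(mat) + length(non),
        maternal_keys = list(mat), non_maternal_keys = list(non)
      )
    } else {
      NULL
    }
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    return(empty)
  }
  dplyr::bind_rows(rows)
}

#' Recurrence of compound-heterozygous genes across a cohort
#'
#' @param calls_by_infant Named list: one [detect_compound_het()] table per
#'   infant in the cohort (names are infant sample ids; empty tables are
#'   allowed and count as "no call").
#' @param cohort Optional cohort label recorded on the output.
#' @return Tibble with columns `gene`, `n_called`, `n_infants`, `fraction`
#'   (and `cohort` if given), sorted by descending fraction then gene symbol.
#' @export
compound_het_recurrence <- function(calls_by_infant, cohort = NULL) {
  n_infants <- length(calls_by_infant)
  if (n_infants == 0) {
    stop("cohort is empty: recurrence is undefined")
  }
  gene_lists <- lapply(calls_by_infant, function(calls) unique(calls$gene))
  genes <- sort(unique(unlist(gene_lists)))
  if (length(genes) == 0) {
    out <- tibble::tibble(
      gene = character(), n_called = integer(),
      n_infants = integer(), fraction = double()
    )
  } else {
    n_called <- unname(vapply(
      genes,
      function(g) sum(vapply(gene_lists, function(gl) g %in% gl, logical(1))),
      integer(1)
    ))
    out <- tibble::tibble(
      gene = genes, n_called = n_called,
      n_infants = n_infants, fraction = n_called / n_infants
    )
    out <- out[order(-out$fraction, out$gene), , drop = FALSE]
  }
  if (!is.null(cohort)) {
    out$cohort <- rep(as.character(cohort), nrow(out))
  }
  out
}

#' Run attribution and compound-het calling across a set of duos
#'
#' @param profiles Named list of fully filtered `filtered_profile` objects
#'   (names = sample ids).
#' @param samples Sample table with columns `sample_id`, `role`, `cohort`,
#'   `duo_id` (see [simulate_cohort()] for the layout).
#' @return List with `attributed` (named by infant sample id) and `calls`
#'   (named list of per-infant call tables).
#' @export
analyze_duos <- function(profiles, samples) {
  infants <- samples[samples$role == "infant" & !is.na(samples$duo_id), , drop = FALSE]
  attributed <- list()
  calls <- list()
  for (i in seq_len(nrow(infants))) {
    did <- infants$duo_id[i]
    iid <- infants$sample_id[i]
    mid <- samples$sample_id[samples$role == "mother" &
      !is.na(samples$duo_id) & samples$duo_id == did]
    if (length(mid) != 1) {
      stop("duo '", did, "' does not have exactly one mother")
    }
    if (!iid %in% names(profiles) || !mid %in% names(profiles)) {
      stop("missing filtered profile for duo '", did, "'")
    }
    att <- attribute_origin(profiles[[iid]], profiles[[mid]])
    attributed[[iid]] <- att
    calls[[iid]] <- detect_compound_het(att, duo_id = did)
  }
  list(attributed = attributed, calls = calls)
}
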