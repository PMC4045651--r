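#' Normalize a chromosome label
#'
#' Strips a leading `"chr"` (any case) so that `chr7` and `7` key identically.
#'
#' @param chrom Character vector of chromosome names.
#' @return Character vector of normalized names.
#' @export
normalize_chrom <- function(chrom) {
  sub("^[Cc][Hh][Rr]", "", as.character(chrom))
}

#' Normalize a ref/alt allele pair
#'
#' Trims the shared suffix and then the shared prefix of the two allele
#' strings, adjusting the position for any trimmed prefix, so that redundantly
#' padded indel representations collapse to one canonical key. At least one
#' base is always kept on each allele.
#'
#' @param pos Integer vector of 1-based positions.
#' @param ref,alt Character vectors of allele strings.
#' @return A list with elements `pos`, `ref`, `alt`.
#' @export
normalize_alleles <- function(pos, ref, alt) {
  stopifnot(length(pos) == length(ref), length(ref) == length(alt))
  pos <- as.integer(pos)
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  needs <- which(nchar(ref) > 1L | nchar(alt) > 1L)
  for (i in needs) {
    r <- strsplit(ref[i], "", fixed = TRUE)[[1]]
    a <- strsplit(alt[i], "", fixed = TRUE)[[1]]
    # shared suffix first, then shared prefix (keep >=1 base each)
    while (length(r) > 1L && length(a) > 1L && r[length(r)] == a[length(a)]) {
      r <- r[-length(r)]
      a <- a[-length(a)]
    }
    off <- 0L
    while (length(r) > 1L && length(a) > 1L && r[1L] == a[1L]) {
      r <- r[-1L]
      a <- a[-1L]
      off <- off + 1L
    }
    ref[i] <- paste(r, collapse = "")
    alt[i] <- paste(a, collapse = "")
    pos[i] <- pos[i] + off
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Variant identity key
#'
#' The identity of a variant is `(chrom, pos, ref, alt)` after chromosome
#' normalization and allele trimming. The same key on the infant and mother
#' side is what "seen in the matching mother" means operationally.
#'
#' @param chrom,pos,ref,alt Vectors describing the variants.
#' @return Character vector of keys, one per variant.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  nrm <- normalize_alleles(pos, ref, alt)
  paste(normalize_chrom(chrom), nrm$pos, nrm$ref, nrm$alt, sep = ":")
}

# Numerically stable log(sum(exp(x))).
logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  m <- max(x)
  if (!is.finite(m)) {
    return(-Inf)
  }
  m + log(sum(exp(x - m)))
}

# Names of allele-frequency panel columns in a variant table.
af_columns <- function(variants) {
  grep("^af_", names(variants), value = TRUE)
}

# Empty annotated-variant tibble with the canonical column set.
empty_variant_table <- function() {
  tibble::tibble(
    sample_id = character(), chrom = character(), pos = integer(),
    ref = character(), alt = character(), gene = character(),
    consequence = character(), alt_depth = integer(), total_depth = integer(),
    genotype_quality = integer(), mapping_quality = integer(),
    af_1000g = double(), af_dbsnp = double(),
    deleterious_votes = integer(), deleterious_total = integer()
  )
}

# Validate the invariants of an annotated-variant table; returns it invisibly.
validate_variant_table <- function(variants) {
  req <- names(empty_variant_table())
  missing <- setdiff(req, names(variants))
  if (length(missing) > 0) {
    stop("variant table is missing columns: ", paste(missing, collapse = ", "))
  }
  bad_depth <- !is.na(variants$alt_depth) & !is.na(variants$total_depth) &
    (variants$alt_depth < 0 | variants$alt_depth > variants$total_depth)
  if (any(bad_depth)) {
    stop("alt_depth must satisfy 0 <= alt_depth <= total_depth")
  }
  for (col in af_columns(variants)) {
    v <- variants[[col]]
    if (any(!is.na(v) & (v < 0 | v > 1))) {
      stop("allele frequency column '", col, "' has values outside [0, 1]")
    }
  }
  if (any(variants$deleterious_votes > variants$deleterious_total)) {
    stop("deleterious_votes must not exceed deleterious_total")
  }
  if (!all(variants$consequence %in% consequence_levels())) {
    stop(
      "unknown consequence value(s): ",
      paste(unique(setdiff(variants$consequence, consequence_levels())), collapse = ", ")
    )
  }
  invisible(variants)
}
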