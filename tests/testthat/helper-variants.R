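# Shared fixture builders. All fixtures are constructed in code at test time.

# A variant table row with passing defaults; override any field by name.
make_variants <- function(n = 1, ...) {
  over <- list(...)
  base <- tibble::tibble(
    sample_id = rep("S1", n),
    chrom = rep("1", n),
    pos = seq_len(n) * 100L,
    ref = rep("A", n),
    alt = rep("T", n),
    gene = rep("GENEA", n),
    consequence = rep("nonsynonymous_snv", n),
    alt_depth = rep(10L, n),
    total_depth = rep(20L, n),
    genotype_quality = rep(99L, n),
    mapping_quality = rep(60L, n),
    af_1000g = rep(NA_real_, n),
    af_dbsnp = rep(NA_real_, n),
    deleterious_votes = rep(3L, n),
    deleterious_total = rep(5L, n)
  )
  for (nm in names(over)) {
    base[[nm]] <- rep_len(over[[nm]], n)
  }
  base
}

# A fully filtered profile straight from a variant table.
make_profile <- function(variants, thresholds = filter_thresholds()) {
  filter_variants(variants, thresholds)
}

# Write a small VCF; records is a character vector of tab-joined body lines.
write_test_vcf <- function(records, sample_name = "S1",
                           path = tempfile(fileext = ".vcf")) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=MQ,Number=1,Type=Integer,Description=\"MQ\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"AD\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"DP\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"GQ\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample_name)
  )
  writeLines(c(header, records), path)
  path
}

# Write an annotation TSV from a data frame in the dialect's column order.
write_test_annotation <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  path
}

# Hypergeometric upper tail by literal enumeration of every n-subset of 1..N
# (only usable for small N). Counts subsets whose overlap with the candidate
# block {1..K} is >= k.
enumerate_upper_tail <- function(k, K, n, N) {
  if (n == 0) {
    return(as.numeric(k <= 0))
  }
  subsets <- utils::combn(N, n)
  hits <- colSums(subsets <= K)
  mean(hits >= k)
}

# Exact counting oracle: integer-valued choose() ratios (exact in double
# precision for N <= 25), no logs.
counting_upper_tail <- function(k, K, n, N) {
  j <- max(0, k):min(K, n)
  if (k > min(K, n)) {
    return(0)
  }
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}
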