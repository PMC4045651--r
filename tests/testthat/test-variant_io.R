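# Reading VCFs, gene lists, gene models; writing result tables + manifest.

test_that("gene set reading upper-cases, de-duplicates and rejects empties", {
  p <- tempfile()
  writeLines(c("MLL3", "flt3", "MLL3"), p)
  gs <- suppressMessages(read_gene_set(p, "demo"))
  expect_setequal(gs$genes, c("MLL3", "FLT3"))
  expect_length(gs$genes, 2)

  # one-column TSV with a header line
  writeLines(c("gene", "TP53", "TTN"), p)
  expect_setequal(suppressMessages(read_gene_set(p, "h"))$genes, c("TP53", "TTN"))

  writeLines(c("", "   ", ""), p)
  expect_error(suppressMessages(read_gene_set(p, "empty")), "no gene symbols")
})

test_that("two candidate lists sized like ALL/AML share their expected overlap", {
  shared <- sprintf("SHARED%03d", 1:34)
  all_genes <- c(shared, sprintf("ALLG%03d", 1:92)) # 126 total
  aml_genes <- c(shared, sprintf("AMLG%03d", 1:621)) # 655 total
  pa <- tempfile()
  pm <- tempfile()
  writeLines(all_genes, pa)
  writeLines(aml_genes, pm)
  gs_all <- suppressMessages(read_gene_set(pa, "ALL"))
  gs_aml <- suppressMessages(read_gene_set(pm, "AML"))
  expect_length(gs_all$genes, 126)
  expect_length(gs_aml$genes, 655)
  expect_length(intersect(gs_all$genes, gs_aml$genes), 34)
})

test_that("VCF reading handles empty files, AD semantics and decomposition", {
  # zero records
  p <- write_test_vcf(character(0))
  expect_equal(nrow(read_vcf(p, "S1")), 0)

  # biallelic record: AD=12,9 -> alt_depth 9, total_depth 21 (no DP field)
  p <- write_test_vcf(
    "1\t1000\t.\tA\tT\t.\tPASS\tMQ=60\tGT:AD:GQ\t0/1:12,9:80"
  )
  v <- read_vcf(p, "S1")
  expect_equal(nrow(v), 1)
  expect_equal(v$alt_depth, 9L)
  expect_equal(v$total_depth, 21L)
  expect_equal(v$genotype_quality, 80L)
  expect_equal(v$mapping_quality, 60L)

  # multi-allelic record carried het-alt: two rows sharing chrom/pos/ref
  p <- write_test_vcf(
    "chr2\t500\t.\tC\tA,T\t.\tPASS\tMQ=55\tGT:AD:DP:GQ\t1/2:3,7,6:16:50"
  )
  v <- read_vcf(p, "S1")
  expect_equal(nrow(v), 2)
  expect_equal(v$chrom, c("2", "2")) # "chr" stripped
  expect_equal(v$pos, c(500L, 500L))
  expect_equal(v$alt, c("A", "T"))
  expect_equal(v$alt_depth, c(7L, 6L))
  expect_equal(v$total_depth, c(16L, 16L))
})

test_that("multi-allelic decomposition conserves per-record alt counts", {
  recs <- c(
    "1\t100\t.\tA\tT\t.\tPASS\tMQ=60\tGT:AD:DP:GQ\t0/1:5,5:10:60",
    "1\t200\t.\tG\tA,C\t.\tPASS\tMQ=60\tGT:AD:DP:GQ\t1/2:2,4,4:10:60",
    "1\t300\t.\tT\tA,C,G\t.\tPASS\tMQ=60\tGT:AD:DP:GQ\t./.:.:.:.",
    "1\t400\t.\tC\tG\t.\tPASS\tMQ=60\tGT:AD:DP:GQ\t0/1:6,6:12:60"
  )
  p <- write_test_vcf(recs)
  v <- read_vcf(p, "S1")
  # GT-missing record keeps all alts; total rows = 1 + 2 + 3 + 1
  expect_equal(nrow(v), 7)
})

test_that("annotation join fills gaps with consequence 'other' and validates AF", {
  ann <- data.frame(
    chrom = "1", pos = 1000L, ref = "A", alt = "T",
    gene = "TP53", consequence = "stopgain",
    af_1000g = 0.005, af_dbsnp = NA, deleterious_votes = 4L, deleterious_total = 5L
  )
  ap <- write_test_annotation(ann)
  p <- write_test_vcf(c(
    "1\t1000\t.\tA\tT\t.\tPASS\tMQ=60\tGT:AD:DP:GQ\t0/1:10,10:20:90",
    "1\t2000\t.\tG\tC\t.\tPASS\tMQ=60\tGT:AD:DP:GQ\t0/1:10,10:20:90"
  ))
  v <- read_vcf(p, "S1", ap)
  expect_equal(v$consequence, c("stopgain", "other"))
  expect_equal(v$gene, c("TP53", NA))
  expect_equal(v$af_1000g, c(0.005, NA))
  expect_equal(v$deleterious_votes, c(4L, 0L))

  bad <- ann
  bad$af_1000g <- 1.5
  expect_error(read_vcf(p, "S1", write_test_annotation(bad)), "outside \\[0, 1\\]")
})

test_that("malformed VCF lines are reported with their line number", {
  p <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "1\t100\t.\tA\tT\t.\tPASS\tMQ=60",
    "1\tnotanumber\t.\tA\tT\t.\tPASS\tMQ=60"
  ), p)
  expect_error(read_vcf(p, "S1"), "line 4")

  writeLines(c("##fileformat=VCFv4.2", "1\t100\tbroken"), p)
  expect_error(read_vcf(p, "S1"), "line 2")
})

test_that("indel keys are normalized by suffix/prefix trimming", {
  # ACG>AG (deletion of C) written redundantly; pos advances past the prefix
  nrm <- normalize_alleles(100L, "ACG", "AG")
  # suffix G trimmed first -> AC / A; prefix A kept (>=1 base each side)
  expect_equal(nrm$ref, "AC")
  expect_equal(nrm$alt, "A")
  expect_equal(nrm$pos, 100L)
  # fully padded SNV collapses and the position advances
  nrm <- normalize_alleles(100L, "TTAC", "TTGC")
  expect_equal(nrm$ref, "A")
  expect_equal(nrm$alt, "G")
  expect_equal(nrm$pos, 102L)
  expect_equal(
    variant_key("chr1", 100L, "TTAC", "TTGC"),
    variant_key("1", 102L, "A", "G")
  )
})

test_that("gene model reading validates lengths and uniqueness", {
  p <- tempfile()
  utils::write.table(
    data.frame(gene = c("a1", "B2"), coding_length = c(1000L, 2000L)),
    p, sep = "\t", quote = FALSE, row.names = FALSE
  )
  gm <- read_gene_model(p)
  expect_equal(gm$gene, c("A1", "B2"))

  utils::write.table(
    data.frame(gene = c("A", "A"), coding_length = c(10L, 20L)),
    p, sep = "\t", quote = FALSE, row.names = FALSE
  )
  expect_error(read_gene_model(p), "unique")

  utils::write.table(
    data.frame(gene = "A", coding_length = 0L),
    p, sep = "\t", quote = FALSE, row.names = FALSE
  )
  expect_error(read_gene_model(p), "positive")
})

test_that("result writing is deterministic, round-trips, and detects tampering", {
  tab <- tibble::tibble(
    gene = c("TP53", "TTN"), p_value = c(0.000123456789, 1),
    label = c("a b", "c")
  )
  d1 <- file.path(tempfile(), "run1")
  d2 <- file.path(tempfile(), "run2")
  write_results(list(enrichment = tab), d1, config = list(alpha = 0.005), seed = 42)
  write_results(list(enrichment = tab), d2, config = list(alpha = 0.005), seed = 42)
  f1 <- file.path(d1, "enrichment.tsv")
  f2 <- file.path(d2, "enrichment.tsv")
  expect_identical(readBin(f1, "raw", file.size(f1)), readBin(f2, "raw", file.size(f2)))

  back <- read_result_table(f1)
  expect_equal(back$gene, tab$gene)
  expect_equal(back$p_value, tab$p_value)
  expect_equal(back$label, tab$label)

  expect_silent(verify_manifest(d1))
  # empty result set -> manifest only
  d3 <- tempfile()
  m <- write_results(list(), d3)
  expect_length(m$files, 0)
  expect_identical(list.files(d3), "manifest.json")

  # tamper -> integrity error
  writeLines("corrupted", f1)
  expect_error(verify_manifest(d1), "integrity error")
})
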