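# The quality / functional-rarity filter cascade.

test_that("quality thresholds are inclusive at their floors", {
  v <- make_variants(1,
    alt_depth = 5L, total_depth = 10L,
    genotype_quality = 10L, mapping_quality = 60L
  )
  prof <- apply_quality_filters(v, filter_thresholds())
  expect_equal(nrow(prof$variants), 1)

  # one unit below any floor drops the variant
  for (field in c("alt_depth", "total_depth", "genotype_quality", "mapping_quality")) {
    v2 <- v
    v2[[field]] <- v2[[field]] - 1L
    expect_equal(nrow(apply_quality_filters(v2)$variants), 0)
  }
})

test_that("empty input yields an empty profile with all-zero stage counts", {
  prof <- filter_variants(make_variants(0))
  expect_equal(nrow(prof$variants), 0)
  expect_true(all(prof$counts == 0))
  expect_named(prof$counts, c(
    "input", "allele_depth", "position_depth", "genotype_quality",
    "mapping_quality", "consequence", "rarity", "deleterious"
  ))
})

test_that("mixed sample ids are rejected", {
  v <- make_variants(2, sample_id = c("A", "B"))
  expect_error(apply_quality_filters(v), "multiple sample_ids")
})

test_that("quality filtering equals an independent per-row re-check", {
  th <- filter_thresholds()
  set.seed(101)
  for (rep in 1:5) {
    n <- 20
    v <- make_variants(n,
      alt_depth = sample(0:12, n, replace = TRUE),
      total_depth = sample(5:25, n, replace = TRUE),
      genotype_quality = sample(0:30, n, replace = TRUE),
      mapping_quality = sample(50:70, n, replace = TRUE)
    )
    v$alt_depth <- pmin(v$alt_depth, v$total_depth)
    got <- apply_quality_filters(v, th)$variants
    want <- v[
      v$alt_depth >= 5 & v$total_depth >= 10 &
        v$genotype_quality >= 10 & v$mapping_quality >= 60, ,
      drop = FALSE
    ]
    expect_equal(got, want)
  }
})

test_that("rarity is strict: exactly 1% fails, below passes, absent passes", {
  th <- filter_thresholds()
  v <- make_variants(3,
    consequence = "stopgain",
    af_1000g = c(0.005, 0.01, NA),
    af_dbsnp = NA_real_
  )
  out <- filter_variants(v, th)$variants
  expect_equal(out$af_1000g, c(0.005, NA))
})

test_that("rarity modes differ on panel disagreement", {
  v <- make_variants(1, af_1000g = 0.005, af_dbsnp = 0.2)
  # all_panels: common in any panel with data disqualifies
  expect_equal(nrow(filter_variants(v, filter_thresholds(rarity_mode = "all_panels"))$variants), 0)
  # any_panel: one panel below the cutoff suffices
  expect_equal(nrow(filter_variants(v, filter_thresholds(rarity_mode = "any_panel"))$variants), 1)
})

test_that("synonymous variants are removed whatever their frequency", {
  v <- make_variants(1, consequence = "synonymous", af_1000g = NA_real_)
  expect_equal(nrow(filter_variants(v)$variants), 0)
})

test_that("deleteriousness vote rules behave as documented", {
  cases <- expand.grid(votes = 0:5, total = c(0L, 5L))
  cases <- cases[cases$votes <= cases$total | cases$total == 0, ]
  cases <- cases[!(cases$total == 0 & cases$votes > 0), ]
  for (i in seq_len(nrow(cases))) {
    v <- make_variants(1,
      deleterious_votes = cases$votes[i],
      deleterious_total = cases$total[i]
    )
    pass_any <- nrow(filter_variants(v, filter_thresholds(deleterious_rule = "any_vote"))$variants) == 1
    pass_maj <- nrow(filter_variants(v, filter_thresholds(deleterious_rule = "majority_vote"))$variants) == 1
    pass_all <- nrow(filter_variants(v, filter_thresholds(deleterious_rule = "all_votes"))$variants) == 1
    no_pred <- cases$total[i] == 0
    expect_equal(pass_any, no_pred || cases$votes[i] >= 1)
    expect_equal(pass_maj, no_pred || cases$votes[i] * 2 > cases$total[i])
    expect_equal(pass_all, no_pred || cases$votes[i] == cases$total[i])
  }
})

test_that("cascade counts are monotone non-increasing and filtering is idempotent", {
  set.seed(202)
  for (rep in 1:5) {
    cfg <- simulation_config(
      seed = 300 + rep, n_duos_all = 1, n_duos_aml = 0, n_controls = 1,
      n_genes = 150, planted_compound_het_genes = NULL
    )
    ch <- simulate_cohort(cfg)
    v <- ch$variants[ch$variants$sample_id == "ALL01_I", , drop = FALSE]
    prof <- filter_variants(v)
    expect_true(all(diff(prof$counts) <= 0))
    # idempotence: refiltering the retained set changes nothing
    again <- filter_variants(prof$variants)
    expect_equal(again$variants, prof$variants)
    expect_equal(unname(again$counts["deleterious"]), nrow(prof$variants))
  }
})

test_that("the four quality inequalities commute", {
  set.seed(303)
  n <- 50
  v <- make_variants(n,
    alt_depth = sample(0:10, n, TRUE),
    total_depth = sample(8:14, n, TRUE),
    genotype_quality = sample(5:15, n, TRUE),
    mapping_quality = sample(55:65, n, TRUE)
  )
  v$alt_depth <- pmin(v$alt_depth, v$total_depth)
  th <- filter_thresholds()
  checks <- list(
    alt = function(x) !is.na(x$alt_depth) & x$alt_depth >= th$min_allele_depth,
    pos = function(x) !is.na(x$total_depth) & x$total_depth >= th$min_position_depth,
    gq = function(x) !is.na(x$genotype_quality) & x$genotype_quality >= th$min_genotype_quality,
    mq = function(x) !is.na(x$mapping_quality) & x$mapping_quality >= th$min_mapping_quality
  )
  ref <- apply_quality_filters(v, th)$variants
  for (perm in list(c(1, 2, 3, 4), c(4, 3, 2, 1), c(2, 4, 1, 3))) {
    keep <- rep(TRUE, n)
    for (i in perm) keep <- keep & checks[[i]](v)
    expect_equal(v[keep, ], ref)
  }
})

test_that("candidate counting distinguishes list genes and reports the variant gene set", {
  gs <- gene_set(c("TP53", "FLT3"), "demo")
  prof <- make_profile(make_variants(0))
  cc <- count_candidate_variants(prof, gs)
  expect_equal(cc$candidate_count, 0)
  expect_equal(cc$total_count, 0)
  expect_length(cc$variant_gene_set, 0)

  v <- make_variants(10, gene = c("TP53", "TP53", "FLT3", rep("OTHERG", 7)))
  cc <- count_candidate_variants(make_profile(v), gs)
  expect_equal(cc$candidate_count, 3)
  expect_equal(cc$total_count, 10)
  expect_setequal(cc$variant_gene_set, c("TP53", "FLT3", "OTHERG"))
})

test_that("a planted candidate enrichment shows up as an elevated candidate rate", {
  f <- 3
  cfg <- simulation_config(
    seed = 77, n_duos_all = 8, n_duos_aml = 0, n_controls = 0,
    n_genes = 600, candidate_fraction = 0.1,
    enrichment_multiplier_infant = f,
    planted_compound_het_genes = NULL
  )
  ch <- simulate_cohort(cfg)
  pg <- ch$truth$per_gene_rates
  kb_cand <- sum(pg$coding_length[pg$candidate]) / 1000
  kb_non <- sum(pg$coding_length[!pg$candidate]) / 1000
  rate_cand <- sum(pg$infant_variants[pg$candidate]) / kb_cand
  rate_non <- sum(pg$infant_variants[!pg$candidate]) / kb_non
  ratio <- rate_cand / rate_non
  # binomial-scale error around the planted multiplier
  se <- ratio * sqrt(1 / sum(pg$infant_variants[pg$candidate]) +
    1 / sum(pg$infant_variants[!pg$candidate]))
  expect_lt(abs(ratio - f), 4 * se)
})
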