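#' Configuration for the synthetic duo-cohort simulator
#'
#' The defaults describe the study design the analysis targets: mother-infant
#' duos for two infant-leukemia cohorts (12 ALL, 13 AML) plus 12 unaffected
#' pediatric controls; roughly half of each infant's variants inherited from
#' the mother; an enrichment multiplier on candidate genes in infants and a
#' smaller one in mothers; and planted compound-heterozygous genes (two genes
#' in every AML infant, one in half the ALL infants). Gene coding lengths are
#' log-normal; per-gene variant counts are Poisson with mean
#' `coding_length_kb * baseline_rate * multiplier`, the minimal generative
#' model consistent with a weak count/size correlation once multipliers vary
#' by gene class.
#'
#' @param seed Integer seed; the whole cohort is deterministic given it.
#' @param n_duos_all,n_duos_aml Number of mother-infant duos per cohort.
#' @param n_controls Number of unaffected control samples.
#' @param n_genes Number of genes in the synthetic exome.
#' @param candidate_fraction Fraction of genes flagged as leukemia candidates.
#' @param gene_length_meanlog,gene_length_sdlog Log-normal parameters of the
#'   coding-length distribution (bases).
#' @param baseline_rate Expected variants per kilobase of coding sequence per
#'   exome before filtering.
#' @param enrichment_multiplier_infant Rate multiplier (>= 1) on candidate
#'   genes in infants.
#' @param enrichment_multiplier_mother Rate multiplier (>= 1) on candidate
#'   genes in mothers ("to a lesser degree than infants").
#' @param transmission_prob Probability an infant variant is maternal (its
#'   key then appears verbatim in the mother's table).
#' @param planted_compound_het_genes Data frame with columns `cohort`
#'   (`"ALL"`/`"AML"`), `fraction` (of that cohort's infants) and `candidate`
#'   (logical: plant in a candidate gene?). One gene is chosen per row.
#' @param quality_noise List of parameters for the quality-field
#'   distributions: `mean_position_depth`, `mean_allele_fraction`, and per
#'   filter stage the fraction of variants forced to fail it
#'   (`fail_allele_depth`, `fail_position_depth`, `fail_genotype_quality`,
#'   `fail_mapping_quality`).
#' @param common_variant_fraction Fraction of simulated variants given panel
#'   AF >= 1% (rarity-filter decoys).
#' @param af_absent_fraction Among rare variants, fraction with no entry in a
#'   given panel (absence counts as rare).
#' @param no_prediction_fraction Fraction of variants with no deleteriousness
#'   prediction (`deleterious_total = 0`, which passes the vote rule).
#' @param benign_fraction Among predicted variants, fraction with zero
#'   deleterious votes.
#' @param consequence_probs Named probability vector over consequence classes.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_duos_all = 12L,
                              n_duos_aml = 13L,
                              n_controls = 12L,
                              n_genes = 2000L,
                              candidate_fraction = 0.05,
                              gene_length_meanlog = 7.2,
                              gene_length_sdlog = 0.6,
                              baseline_rate = 0.1,
                              enrichment_multiplier_infant = 2.0,
                              enrichment_multiplier_mother = 1.5,
                              transmission_prob = 0.5,
                              planted_compound_het_genes = data.frame(
                                cohort = c("AML", "AML", "ALL"),
                                fraction = c(1.0, 1.0, 0.5),
                                candidate = c(TRUE, FALSE, TRUE)
                              ),
                              quality_noise = list(
                                mean_position_depth = 43,
                                mean_allele_fraction = 0.5,
                                fail_allele_depth = 0.05,
                                fail_position_depth = 0.03,
                                fail_genotype_quality = 0.05,
                                fail_mapping_quality = 0.04
                              ),
                              common_variant_fraction = 0.15,
                              af_absent_fraction = 0.7,
                              no_prediction_fraction = 0.05,
                              benign_fraction = 0.3,
                              consequence_probs = c(
                                nonsynonymous_snv = 0.48, synonymous = 0.30,
                                stopgain = 0.03, stoploss = 0.01,
                                frameshift_indel = 0.05, nonframeshift_indel = 0.04,
                                splice_site = 0.04, other = 0.05
                              )) {
  stopifnot(
    n_duos_all >= 0, n_duos_aml >= 0, n_controls >= 0, n_genes >= 1,
    candidate_fraction >= 0, candidate_fraction <= 1,
    baseline_rate > 0,
    enrichment_multiplier_infant >= 1, enrichment_multiplier_mother >= 1,
    transmission_prob >= 0, transmission_prob <= 1,
    common_variant_fraction >= 0, common_variant_fraction <= 1,
    af_absent_fraction >= 0, af_absent_fraction <= 1,
    no_prediction_fraction >= 0, no_prediction_fraction <= 1,
    benign_fraction >= 0, benign_fraction <= 1
  )
  if (!is.null(planted_compound_het_genes) && nrow(planted_compound_het_genes) > 0) {
    stopifnot(
      all(c("cohort", "fraction", "candidate") %in% names(planted_compound_het_genes)),
      all(planted_compound_het_genes$cohort %in% c("ALL", "AML")),
      all(planted_compound_het_genes$fraction >= 0),
      all(planted_compound_het_genes$fraction <= 1),
      nrow(planted_compound_het_genes) <= n_genes
    )
  }
  if (abs(sum(consequence_probs) - 1) > 1e-8 ||
      !all(names(consequence_probs) %in% consequence_levels())) {
    stop("consequence_probs must be a probability vector over known consequence classes")
  }
  structure(
    list(
      seed = as.integer(seed),
      n_duos_all = as.integer(n_duos_all),
      n_duos_aml = as.integer(n_duos_aml),
      n_controls = as.integer(n_controls),
      n_genes = as.integer(n_genes),
      candidate_fraction = candidate_fraction,
      gene_length_meanlog = gene_length_meanlog,
      gene_length_sdlog = gene_length_sdlog,
      baseline_rate = baseline_rate,
      enrichment_multiplier_infant = enrichment_multiplier_infant,
      enrichment_multiplier_mother = enrichment_multiplier_mother,
      transmission_prob = transmission_prob,
      planted_compound_het_genes = planted_compound_het_genes,
      quality_noise = quality_noise,
      common_variant_fraction = common_variant_fraction,
      af_absent_fraction = af_absent_fraction,
      no_prediction_fraction = no_prediction_fraction,
      benign_fraction = benign_fraction,
      consequence_probs = consequence_probs
    ),
    class = "simulation_config"
  )
}

# Gene block layout: one pseudo-chromosome, each gene in its own 1e5-wide
# block so positions never collide across genes. Coordinates only need to be
# consistent identity keys, not genomic realism.
gene_block_width <- 100000L

other_base <- function(ref, shift) {
  bases <- c("A", "C", "G", "T")
  idx <- match(ref, bases)
  bases[((idx - 1L + shift) %% 4L) + 1L]
}

# Draw quality fields for n variants. clean = TRUE suppresses the forced
# filter failures (used for transmitted maternal copies and planted variants,
# whose presence is the ground truth being tested).
sim_quality <- function(n, qn, clean = FALSE) {
  dp <- stats::rpois(n, qn$mean_position_depth)
  dp <- pmax(dp, 10L)
  alt <- stats::rbinom(n, dp, qn$mean_allele_fraction)
  alt <- pmax(alt, 5L)
  gq <- pmin(99L, 10L + stats::rpois(n, 50))
  mq <- rep(60L, n)
  if (!clean && n > 0) {
    f_alt <- stats::runif(n) < qn$fail_allele_depth
    f_dp <- stats::runif(n) < qn$fail_position_depth
    f_gq <- stats::runif(n) < qn$fail_genotype_quality
    f_mq <- stats::runif(n) < qn$fail_mapping_quality
    alt[f_alt] <- sample(0:4, sum(f_alt), replace = TRUE)
    dp[f_dp] <- sample(5:9, sum(f_dp), replace = TRUE)
    gq[f_gq] <- sample(0:9, sum(f_gq), replace = TRUE)
    mq[f_mq] <- sample(20:59, sum(f_mq), replace = TRUE)
  }
  alt <- pmin(alt, dp)
  list(
    alt_depth = as.integer(alt), total_depth = as.integer(dp),
    genotype_quality = as.integer(gq), mapping_quality = as.integer(mq)
  )
}

# Background variants for one sample. lambda is the per-gene Poisson mean.
sim_sample_variants <- function(sample_id, lambda, genes, lengths, offsets, cfg) {
  counts <- stats::rpois(length(lambda), lambda)
  hit <- which(counts > 0)
  if (length(hit) == 0) {
    out <- empty_variant_table()
    return(out)
  }
  gidx <- rep.int(hit, counts[hit])
  pos_within <- unlist(lapply(hit, function(g) {
    sample.int(lengths[g], counts[g])
  }), use.names = FALSE)
  n <- length(gidx)
  consequence <- sample(names(cfg$consequence_probs), n,
    replace = TRUE, prob = cfg$consequence_probs
  )
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- other_base(ref, sample(1:3, n, replace = TRUE))
  is_fs <- consequence == "frameshift_indel"
  is_nfs <- consequence == "nonframeshift_indel"
  alt[is_fs] <- paste0(ref[is_fs], "T")
  alt[is_nfs] <- paste0(ref[is_nfs], "TTT")

  is_common <- stats::runif(n) < cfg$common_variant_fraction
  draw_af <- function(common) {
    af <- rep(NA_real_, n)
    af[common] <- stats::runif(sum(common), 0.01, 0.5)
    rare <- which(!common)
    present <- rare[stats::runif(length(rare)) >= cfg$af_absent_fraction]
    af[present] <- stats::runif(length(present), 0, 0.0099)
    af
  }
  af_1000g <- draw_af(is_common)
  af_dbsnp <- draw_af(is_common)

  total_pred <- ifelse(stats::runif(n) < cfg$no_prediction_fraction, 0L, 5L)
  votes <- integer(n)
  predicted <- total_pred > 0
  benign <- predicted & stats::runif(n) < cfg$benign_fraction
  scoring <- predicted & !benign
  votes[scoring] <- sample(1:5, sum(scoring), replace = TRUE)

  q <- sim_quality(n, cfg$quality_noise)
  tibble::tibble(
    sample_id = sample_id,
    chrom = "1",
    pos = offsets[gidx] + as.integer(pos_within),
    ref = ref, alt = alt,
    gene = genes[gidx],
    consequence = consequence,
    alt_depth = q$alt_depth, total_depth = q$total_depth,
    genotype_quality = q$genotype_quality, mapping_quality = q$mapping_quality,
    af_1000g = af_1000g, af_dbsnp = af_dbsnp,
    deleterious_votes = votes, deleterious_total = total_pred
  )
}

# A single qualifying (rare, non-synonymous, deleterious, clean-quality)
# variant row at a given site — used for planted compound hets.
sim_planted_variant <- function(sample_id, gene, pos, qn) {
  q <- sim_quality(1, qn, clean = TRUE)
  ref <- sample(c("A", "C", "G", "T"), 1)
  tibble::tibble(
    sample_id = sample_id, chrom = "1", pos = as.integer(pos),
    ref = ref, alt = other_base(ref, sample(1:3, 1)),
    gene = gene, consequence = "nonsynonymous_snv",
    alt_depth = q$alt_depth, total_depth = q$total_depth,
    genotype_quality = q$genotype_quality, mapping_quality = q$mapping_quality,
    af_1000g = NA_real_, af_dbsnp = NA_real_,
    deleterious_votes = 3L, deleterious_total = 5L
  )
}

retag <- function(variants, sample_id, clean_quality = FALSE, qn = NULL) {
  variants$sample_id <- sample_id
  if (clean_quality) {
    q <- sim_quality(nrow(variants), qn, clean = TRUE)
    variants$alt_depth <- q$alt_depth
    variants$total_depth <- q$total_depth
    variants$genotype_quality <- q$genotype_quality
    variants$mapping_quality <- q$mapping_quality
  }
  variants
}

#' Generate a synthetic duo cohort with ground truth
#'
#' Simulates annotated variant tables for infants, their mothers and
#' unaffected controls, with a planted candidate-gene enrichment in cases,
#' maternal transmission of a configurable fraction of infant variants
#' (transmitted variants appear with identical identity keys in the mother's
#' table), planted compound-heterozygous genes, and quality/annotation noise
#' sized so that each filter stage removes something. Deterministic given
#' `config$seed`.
#'
#' Transmitted maternal copies and planted variants are drawn with clean
#' (passing) quality: their presence is the ground truth the pipeline is
#' tested against, while the forced filter failures model per-call assay
#' noise on the remaining background.
#'
#' @param config A [simulation_config()].
#' @return An object of class `duo_cohort`: list with `variants` (one tibble,
#'   all samples), `samples`, `gene_models`, `gene_sets` (named list with the
#'   candidate [gene_set()]), `truth` (per-variant origins, candidate flags,
#'   planted assignments, realized per-gene rates) and `config`.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  n_genes <- cfg$n_genes
  genes <- sprintf("GENE%04d", seq_len(n_genes))
  lengths <- as.integer(pmin(
    pmax(round(stats::rlnorm(n_genes, cfg$gene_length_meanlog, cfg$gene_length_sdlog)), 200L),
    gene_block_width - 10L
  ))
  offsets <- (seq_len(n_genes) - 1L) * gene_block_width
  n_cand <- round(cfg$candidate_fraction * n_genes)
  candidate_idx <- sort(sample.int(n_genes, n_cand))
  is_candidate <- seq_len(n_genes) %in% candidate_idx

  gene_models <- tibble::tibble(gene = genes, coding_length = lengths)
  candidate_set <- gene_set(genes[candidate_idx],
    name = "CANDIDATE",
    provenance = "synthetic candidate gene set"
  )

  duo_ids <- c(
    if (cfg$n_duos_all > 0) sprintf("ALL%02d", seq_len(cfg$n_duos_all)) else character(0),
    if (cfg$n_duos_aml > 0) sprintf("AML%02d", seq_len(cfg$n_duos_aml)) else character(0)
  )
  duo_cohorts <- c(
    rep("ALL", cfg$n_duos_all), rep("AML", cfg$n_duos_aml)
  )
  ctrl_ids <- if (cfg$n_controls > 0) sprintf("CTRL%02d", seq_len(cfg$n_controls)) else character(0)
  samples <- dplyr::bind_rows(
    if (length(duo_ids) > 0) {
      dplyr::bind_rows(
        tibble::tibble(
          sample_id = paste0(duo_ids, "_I"), role = "infant",
          cohort = duo_cohorts, duo_id = duo_ids
        ),
        tibble::tibble(
          sample_id = paste0(duo_ids, "_M"), role = "mother",
          cohort = duo_cohorts, duo_id = duo_ids
        )
      )
    },
    tibble::tibble(
      sample_id = ctrl_ids, role = "control",
      cohort = "control", duo_id = NA_character_
    )
  )

  len_kb <- lengths / 1000
  lambda_base <- len_kb * cfg$baseline_rate
  lambda_infant <- lambda_base *
    ifelse(is_candidate, cfg$enrichment_multiplier_infant, 1)
  lambda_mother <- lambda_base *
    ifelse(is_candidate, cfg$enrichment_multiplier_mother, 1)

  # planted compound-het gene selection: distinct genes, long enough for two
  # distinct sites, matching the requested candidate flag
  planted_cfg <- cfg$planted_compound_het_genes
  planted <- NULL
  if (!is.null(planted_cfg) && nrow(planted_cfg) > 0) {
    taken <- integer(0)
    rows <- list()
    for (i in seq_len(nrow(planted_cfg))) {
      pool <- which(is_candidate == planted_cfg$candidate[i] &
        lengths >= 2L & !(seq_len(n_genes) %in% taken))
      if (length(pool) == 0) {
        stop("infeasible compound-het planting: no eligible gene left (need length >= 2)")
      }
      g <- if (length(pool) == 1) pool else sample(pool, 1)
      taken <- c(taken, g)
      cohort_infants <- duo_ids[duo_cohorts == planted_cfg$cohort[i]]
      k <- round(planted_cfg$fraction[i] * length(cohort_infants))
      designated <- if (k >= length(cohort_infants)) {
        cohort_infants
      } else if (k <= 0) {
        character(0)
      } else {
        sort(sample(cohort_infants, k))
      }
      rows[[i]] <- tibble::tibble(
        gene = genes[g], gene_idx = g,
        cohort = planted_cfg$cohort[i],
        fraction = planted_cfg$fraction[i],
        candidate = planted_cfg$candidate[i],
        infants = list(designated)
      )
    }
    planted <- dplyr::bind_rows(rows)
  }

  all_variants <- list()
  origin_rows <- list()
  planted_variant_rows <- list()

  for (d in seq_along(duo_ids)) {
    did <- duo_ids[d]
    iid <- paste0(did, "_I")
    mid <- paste0(did, "_M")
    iv <- sim_sample_variants(iid, lambda_infant, genes, lengths, offsets, cfg)
    transmitted <- stats::runif(nrow(iv)) < cfg$transmission_prob
    mv <- sim_sample_variants(mid, lambda_mother, genes, lengths, offsets, cfg)
    mv_trans <- retag(iv[transmitted, , drop = FALSE], mid,
      clean_quality = TRUE, qn = cfg$quality_noise
    )
    iv_planted_flag <- rep(FALSE, nrow(iv))

    # planted compound hets for this infant
    if (!is.null(planted)) {
      for (p in seq_len(nrow(planted))) {
        if (!did %in% planted$infants[[p]]) next
        g <- planted$gene_idx[p]
        used <- c(
          iv$pos[iv$gene == genes[g]] - offsets[g],
          mv$pos[mv$gene == genes[g]] - offsets[g]
        )
        free <- setdiff(seq_len(lengths[g]), used)
        if (length(free) < 2) {
          stop(
            "infeasible compound-het planting: gene ", genes[g],
            " has fewer than 2 free sites"
          )
        }
        sites <- sample(free, 2)
        v_mat <- sim_planted_variant(iid, genes[g], offsets[g] + sites[1], cfg$quality_noise)
        v_non <- sim_planted_variant(iid, genes[g], offsets[g] + sites[2], cfg$quality_noise)
        iv <- dplyr::bind_rows(iv, v_mat, v_non)
        transmitted <- c(transmitted, TRUE, FALSE)
        iv_planted_flag <- c(iv_planted_flag, TRUE, TRUE)
        mv_trans <- dplyr::bind_rows(
          mv_trans,
          retag(v_mat, mid, clean_quality = TRUE, qn = cfg$quality_noise)
        )
        planted_variant_rows[[length(planted_variant_rows) + 1]] <- tibble::tibble(
          duo_id = did, gene = genes[g],
          maternal_key = variant_key(v_mat$chrom, v_mat$pos, v_mat$ref, v_mat$alt),
          non_maternal_key = variant_key(v_non$chrom, v_non$pos, v_non$ref, v_non$alt)
        )
      }
    }

    # the mother's table: own background plus transmitted copies, one row per
    # distinct key (transmitted copies win so their clean quality is kept)
    mv_all <- dplyr::bind_rows(mv_trans, mv)
    mkeys <- variant_key(mv_all$chrom, mv_all$pos, mv_all$ref, mv_all$alt)
    mv_all <- mv_all[!duplicated(mkeys), , drop = FALSE]

    # ground-truth origin: a variant is maternal iff present in the mother's
    # emitted table (transmission, or coincidental background sharing)
    ikeys <- variant_key(iv$chrom, iv$pos, iv$ref, iv$alt)
    origin <- ifelse(ikeys %in% unique(variant_key(
      mv_all$chrom, mv_all$pos, mv_all$ref, mv_all$alt
    )), "maternal", "non_maternal")

    origin_rows[[d]] <- tibble::tibble(
      sample_id = iv$sample_id, duo_id = did, key = ikeys,
      gene = iv$gene, origin = origin, transmitted = transmitted,
      planted = iv_planted_flag
    )
    all_variants[[length(all_variants) + 1]] <- iv
    all_variants[[length(all_variants) + 1]] <- mv_all
  }

  for (cid in ctrl_ids) {
    all_variants[[length(all_variants) + 1]] <-
      sim_sample_variants(cid, lambda_base, genes, lengths, offsets, cfg)
  }

  variants <- if (length(all_variants) > 0) {
    dplyr::bind_rows(all_variants)
  } else {
    empty_variant_table()
  }

  # annotations are a property of the variant, not the sample: when two
  # samples independently draw the same key, harmonize the annotation columns
  # to one canonical row per key (planted variants take priority so their
  # qualifying annotation is never overwritten by a background collision)
  if (nrow(variants) > 0) {
    keys <- variant_key(variants$chrom, variants$pos, variants$ref, variants$alt)
    planted_keys <- if (length(planted_variant_rows) > 0) {
      pv <- dplyr::bind_rows(planted_variant_rows)
      unique(c(pv$maternal_key, pv$non_maternal_key))
    } else {
      character(0)
    }
    ord <- order(!(keys %in% planted_keys))
    first_idx <- ord[!duplicated(keys[ord])]
    canon_row <- first_idx[match(keys, keys[first_idx])]
    for (col in c(
      "gene", "consequence", "af_1000g", "af_dbsnp",
      "deleterious_votes", "deleterious_total"
    )) {
      variants[[col]] <- variants[[col]][canon_row]
    }
  }
  validate_variant_table(variants)

  infant_ids <- paste0(duo_ids, "_I")
  infant_tab <- variants[variants$sample_id %in% infant_ids, , drop = FALSE]
  per_gene <- table(factor(infant_tab$gene, levels = genes))
  realized <- tibble::tibble(
    gene = genes, coding_length = lengths, candidate = is_candidate,
    infant_variants = as.integer(per_gene),
    rate_per_kb_per_infant = if (length(infant_ids) > 0) {
      as.integer(per_gene) / (len_kb * length(infant_ids))
    } else {
      NA_real_
    }
  )

  truth <- list(
    origins = if (length(origin_rows) > 0) dplyr::bind_rows(origin_rows) else NULL,
    candidate_genes = genes[candidate_idx],
    planted = planted,
    planted_variants = if (length(planted_variant_rows) > 0) {
      dplyr::bind_rows(planted_variant_rows)
    } else {
      NULL
    },
    per_gene_rates = realized
  )

  structure(
    list(
      variants = variants, samples = samples, gene_models = gene_models,
      gene_sets = list(candidate = candidate_set), truth = truth, config = cfg
    ),
    class = "duo_cohort"
  )
}

#' @export
print.duo_cohort <- function(x, ...) {
  cat(
    "<duo_cohort>", nrow(x$samples), "samples,",
    nrow(x$variants), "variants,", nrow(x$gene_models), "genes\n"
  )
  invisible(x)
}

#' Filter every sample of a cohort
#'
#' @param cohort A `duo_cohort` (or any list with `variants` and `samples`).
#' @param thresholds A [filter_thresholds()].
#' @return Named list of fully filtered `filtered_profile` objects, one per
#'   sample in `cohort$samples` (samples without variants get empty
#'   profiles).
#' @export
filter_cohort <- function(cohort, thresholds = filter_thresholds()) {
  ids <- cohort$samples$sample_id
  out <- lapply(ids, function(id) {
    v <- cohort$variants[cohort$variants$sample_id == id, , drop = FALSE]
    filter_variants(v, thresholds)
  })
  names(out) <- ids
  out
}

#' Write a cohort as an on-disk fixture bundle
#'
#' Emits exactly the external formats the pipeline consumes: one VCF per
#' sample (`vcf/<sample_id>.vcf`, with GT/AD/DP/GQ FORMAT fields and MQ in
#' INFO), a shared annotation TSV in the package dialect, the candidate gene
#' list (one symbol per line), the gene model TSV and the sample table. The
#' bundle round-trips losslessly through [read_vcf()].
#'
#' @param cohort A `duo_cohort` from [simulate_cohort()].
#' @param out_dir Output directory (created if needed).
#' @return Named list of written paths (`vcf` is a named vector per sample).
#' @export
write_fixture_bundle <- function(cohort, out_dir) {
  dir.create(file.path(out_dir, "vcf"), recursive = TRUE, showWarnings = FALSE)
  v <- cohort$variants

  ann <- v[, c(
    "chrom", "pos", "ref", "alt", "gene", "consequence",
    "af_1000g", "af_dbsnp", "deleterious_votes", "deleterious_total"
  )]
  ann <- ann[!duplicated(variant_key(ann$chrom, ann$pos, ann$ref, ann$alt)), , drop = FALSE]
  ann <- ann[order(ann$chrom, ann$pos, ann$ref, ann$alt), , drop = FALSE]
  ann_path <- file.path(out_dir, "annotations.tsv")
  utils::write.table(ann, ann_path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")

  gl_path <- file.path(out_dir, "candidate_genes.txt")
  writeLines(cohort$gene_sets$candidate$genes, gl_path)

  gm_path <- file.path(out_dir, "gene_models.tsv")
  utils::write.table(cohort$gene_models, gm_path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )

  sm_path <- file.path(out_dir, "samples.tsv")
  utils::write.table(cohort$samples, sm_path,
    sep = "\t", quote = FALSE, row.names = FALSE, na = ""
  )

  vcf_paths <- character(0)
  for (id in cohort$samples$sample_id) {
    sv <- v[v$sample_id == id, , drop = FALSE]
    sv <- sv[order(sv$chrom, sv$pos, sv$ref, sv$alt), , drop = FALSE]
    path <- file.path(out_dir, "vcf", paste0(id, ".vcf"))
    header <- c(
      "##fileformat=VCFv4.2",
      "##INFO=<ID=MQ,Number=1,Type=Integer,Description=\"Mapping quality\">",
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
      "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
      "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
      paste0(
        "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", id
      )
    )
    body <- if (nrow(sv) > 0) {
      sprintf(
        "%s\t%d\t.\t%s\t%s\t.\tPASS\tMQ=%d\tGT:AD:DP:GQ\t0/1:%d,%d:%d:%d",
        sv$chrom, sv$pos, sv$ref, sv$alt, sv$mapping_quality,
        sv$total_depth - sv$alt_depth, sv$alt_depth, sv$total_depth,
        sv$genotype_quality
      )
    } else {
      character(0)
    }
    writeLines(c(header, body), path)
    vcf_paths[id] <- path
  }

  list(
    annotations = ann_path, gene_list = gl_path, gene_models = gm_path,
    samples = sm_path, vcf = vcf_paths
  )
}
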