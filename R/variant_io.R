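#' Construct a candidate gene set
#'
#' @param genes Character vector of gene symbols (upper-cased, de-duplicated).
#' @param name Name of the set (e.g. `"ALL"`, `"AML"`).
#' @param provenance Free-text provenance label.
#' @return An object of class `gene_set` with elements `name`, `genes`,
#'   `provenance`.
#' @export
gene_set <- function(genes, name, provenance = "") {
  genes <- unique(toupper(trimws(as.character(genes))))
  genes <- genes[nzchar(genes)]
  if (length(genes) == 0) {
    stop("a gene set must contain at least one symbol")
  }
  structure(
    list(name = as.character(name), genes = genes, provenance = provenance),
    class = "gene_set"
  )
}

#' @export
print.gene_set <- function(x, ...) {
  cat(
    "<gene_set> ", x$name, ": ", length(x$genes), " genes",
    if (nzchar(x$provenance)) paste0(" (", x$provenance, ")") else "", "\n",
    sep = ""
  )
  invisible(x)
}

#' Read a candidate gene list
#'
#' Accepts one symbol per line, or a one-column TSV whose first line is a
#' header (recognised header words: `gene`, `genes`, `symbol`, `gene_symbol`).
#' Symbols are upper-cased and de-duplicated.
#'
#' @param path Path to the gene list file.
#' @param name Name to give the resulting set.
#' @param provenance Optional provenance label recorded on the set.
#' @return A [gene_set()].
#' @export
read_gene_set <- function(path, name, provenance = path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (length(lines) > 0 &&
      tolower(lines[1]) %in% c("gene", "genes", "symbol", "gene_symbol")) {
    lines <- lines[-1]
  }
  if (length(lines) == 0) {
    stop("gene list file '", path, "' contains no gene symbols")
  }
  gs <- gene_set(lines, name = name, provenance = provenance)
  message("read gene set '", name, "': ", length(gs$genes), " unique symbols")
  gs
}

#' Read a gene model table
#'
#' @param path TSV with header columns `gene` and `coding_length`.
#' @return Tibble with columns `gene` (unique, upper-cased) and
#'   `coding_length` (positive integer bases).
#' @export
read_gene_model <- function(path) {
  df <- utils::read.delim(path,
    stringsAsFactors = FALSE, check.names = FALSE,
    colClasses = c(gene = "character")
  )
  if (!all(c("gene", "coding_length") %in% names(df))) {
    stop("gene model table must have columns 'gene' and 'coding_length'")
  }
  df$gene <- toupper(trimws(df$gene))
  df$coding_length <- as.integer(df$coding_length)
  if (any(is.na(df$coding_length)) || any(df$coding_length <= 0)) {
    stop("coding_length must be a positive integer for every gene")
  }
  if (anyDuplicated(df$gene)) {
    stop("gene symbols in the gene model table must be unique")
  }
  tibble::as_tibble(df[, c("gene", "coding_length")])
}

#' Read an annotation table in the package's TSV dialect
#'
#' Tab-separated with a header row and required columns `chrom`, `pos`, `ref`,
#' `alt`, `gene`, `consequence`, `af_1000g`, `af_dbsnp`, `deleterious_votes`,
#' `deleterious_total`. Missing allele frequencies are encoded as empty
#' strings (read as `NA`). Keys are normalized on read.
#'
#' @param path Path to the annotation TSV.
#' @return Tibble of annotations keyed by `key = variant_key(...)`.
#' @export
read_annotation_table <- function(path) {
  req <- c(
    "chrom", "pos", "ref", "alt", "gene", "consequence",
    "af_1000g", "af_dbsnp", "deleterious_votes", "deleterious_total"
  )
  df <- utils::read.delim(path,
    stringsAsFactors = FALSE, check.names = FALSE,
    na.strings = c("NA", ""),
    colClasses = c(
      chrom = "character", ref = "character", alt = "character",
      gene = "character", consequence = "character"
    )
  )
  missing <- setdiff(req, names(df))
  if (length(missing) > 0) {
    stop("annotation table is missing columns: ", paste(missing, collapse = ", "))
  }
  for (col in c("af_1000g", "af_dbsnp")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (any(!is.na(df[[col]]) & is.na(v))) {
      stop("annotation column '", col, "' has non-numeric values")
    }
    if (any(!is.na(v) & (v < 0 | v > 1))) {
      stop("annotation column '", col, "' has allele frequencies outside [0, 1]")
    }
    df[[col]] <- v
  }
  if (!all(df$consequence %in% consequence_levels())) {
    stop(
      "annotation table has unknown consequence value(s): ",
      paste(unique(setdiff(df$consequence, consequence_levels())), collapse = ", ")
    )
  }
  df$gene <- toupper(df$gene)
  df$deleterious_votes <- as.integer(df$deleterious_votes)
  df$deleterious_total <- as.integer(df$deleterious_total)
  df$key <- variant_key(df$chrom, df$pos, df$ref, df$alt)
  tibble::as_tibble(df)
}

# Minimal structural scan of a VCF so that malformed lines are reported with
# their line number (the parser itself does not do this).
validate_vcf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (startsWith(ln, "#") || !nzchar(ln)) next
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 8) {
      stop("malformed VCF line ", i, ": expected >= 8 tab-separated fields")
    }
    if (is.na(suppressWarnings(as.integer(fields[2])))) {
      stop("malformed VCF line ", i, ": POS is not an integer")
    }
  }
  invisible(TRUE)
}

# Split a FORMAT-style field string on ':'; returns NA_character_ padded list.
split_format <- function(x) strsplit(ifelse(is.na(x), "", x), ":", fixed = TRUE)

#' Read annotated variants for one sample from a VCF plus annotation TSV
#'
#' Reads a VCF v4.x file (single- or multi-sample), extracts the requested
#' sample's genotype fields (`GT`, `AD`, `DP`, `GQ`) and the site `MQ` from
#' INFO, decomposes multi-allelic records into one row per alternate allele
#' carried by the sample, normalizes keys, and joins functional annotations
#' from the annotation TSV by `(chrom, pos, ref, alt)`. Records without a
#' matching annotation row get `consequence = "other"`, absent allele
#' frequencies and zero deleteriousness votes.
#'
#' Per-allele depth comes from `AD` when present; when `AD` is absent the
#' allele fraction is unknowable and `alt_depth` is set to `NA`, which fails
#' the per-allele coverage filter downstream (a hard floor, conservatively).
#'
#' @param path Path to the VCF file.
#' @param sample_id Sample column to extract. If the VCF has exactly one
#'   sample column, it is used regardless of its name and rows are labelled
#'   with `sample_id`.
#' @param annotation_table_path Optional path to the annotation TSV; `NULL`
#'   leaves every variant unannotated (`consequence = "other"`).
#' @return Tibble of annotated variants (one row per sample/site/alt allele).
#' @export
read_vcf <- function(path, sample_id, annotation_table_path = NULL) {
  validate_vcf_lines(path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  ann <- if (!is.null(annotation_table_path)) {
    read_annotation_table(annotation_table_path)
  } else {
    NULL
  }
  if (nrow(vcf@fix) == 0) {
    return(empty_variant_table())
  }
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt_mat <- vcf@gt
  if (is.null(gt_mat) || ncol(gt_mat) < 2) {
    stop("VCF '", path, "' has no sample genotype columns")
  }
  sample_cols <- colnames(gt_mat)[-1]
  col <- if (sample_id %in% sample_cols) {
    sample_id
  } else if (length(sample_cols) == 1) {
    sample_cols[1]
  } else {
    stop(
      "sample '", sample_id, "' not found in VCF (samples: ",
      paste(sample_cols, collapse = ", "), ")"
    )
  }

  mq <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, "MQ")))
  fmt <- split_format(gt_mat[, "FORMAT"])
  smp <- split_format(gt_mat[, col])

  rows <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    alts <- alts[!is.na(alts) & nzchar(alts) & alts != "."]
    if (length(alts) == 0) next
    keys <- fmt[[i]]
    vals <- smp[[i]]
    val_of <- function(k) {
      j <- match(k, keys)
      if (is.na(j) || j > length(vals)) NA_character_ else vals[j]
    }
    gt <- val_of("GT")
    ad <- val_of("AD")
    dp <- suppressWarnings(as.integer(val_of("DP")))
    gq <- suppressWarnings(as.integer(val_of("GQ")))
    ad_parts <- if (!is.na(ad)) {
      suppressWarnings(as.integer(strsplit(ad, ",", fixed = TRUE)[[1]]))
    } else {
      NULL
    }
    # keep alt alleles present in the genotype call when GT is available
    carried <- seq_along(alts)
    if (!is.na(gt) && gt != "" && gt != ".") {
      gt_idx <- suppressWarnings(
        as.integer(strsplit(gt, "[/|]")[[1]])
      )
      gt_idx <- gt_idx[!is.na(gt_idx) & gt_idx > 0]
      if (length(gt_idx) > 0) carried <- sort(unique(gt_idx))
      carried <- carried[carried <= length(alts)]
      if (length(carried) == 0) next
    }
    total <- if (!is.na(dp)) {
      dp
    } else if (!is.null(ad_parts)) {
      sum(ad_parts, na.rm = TRUE)
    } else {
      NA_integer_
    }
    for (a in carried) {
      alt_dp <- if (!is.null(ad_parts) && length(ad_parts) >= a + 1) {
        ad_parts[a + 1]
      } else {
        NA_integer_
      }
      rows[[length(rows) + 1]] <- data.frame(
        chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = alts[a],
        alt_depth = alt_dp, total_depth = as.integer(total),
        genotype_quality = gq,
        mapping_quality = as.integer(round(mq[i])),
        stringsAsFactors = FALSE
      )
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    return(empty_variant_table())
  }
  out <- dplyr::bind_rows(rows)
  nrm <- normalize_alleles(out$pos, out$ref, out$alt)
  out$chrom <- normalize_chrom(out$chrom)
  out$pos <- nrm$pos
  out$ref <- nrm$ref
  out$alt <- nrm$alt
  out$key <- paste(out$chrom, out$pos, out$ref, out$alt, sep = ":")

  if (!is.null(ann)) {
    j <- match(out$key, ann$key)
    out$gene <- ifelse(is.na(j), NA_character_, ann$gene[j])
    out$consequence <- ifelse(is.na(j), "other", ann$consequence[j])
    out$af_1000g <- ann$af_1000g[j]
    out$af_dbsnp <- ann$af_dbsnp[j]
    out$deleterious_votes <- ifelse(is.na(j), 0L, ann$deleterious_votes[j])
    out$deleterious_total <- ifelse(is.na(j), 0L, ann$deleterious_total[j])
  } else {
    out$gene <- NA_character_
    out$consequence <- "other"
    out$af_1000g <- NA_real_
    out$af_dbsnp <- NA_real_
    out$deleterious_votes <- 0L
    out$deleterious_total <- 0L
  }
  out$sample_id <- sample_id
  out <- out[, names(empty_variant_table())]
  validate_variant_table(tibble::as_tibble(out))
}

#' Write result tables with a run manifest
#'
#' Each element of `results` (a named list of data frames) is written as
#' `<name>.tsv` in `out_dir`; a `manifest.json` records the configuration,
#' seed, package version and an MD5 checksum per written file. File names are
#' deterministic, so identical inputs produce byte-identical outputs.
#'
#' @param results Named list of data frames.
#' @param out_dir Output directory (created if needed).
#' @param config Optional list of run configuration to record.
#' @param seed Optional integer seed to record.
#' @return Invisibly, the manifest as a list.
#' @export
write_results <- function(results, out_dir, config = list(), seed = NULL) {
  if (length(results) > 0 &&
      (is.null(names(results)) || any(!nzchar(names(results))))) {
    stop("'results' must be a fully named list of data frames")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    stop("cannot create output directory '", out_dir, "'")
  }
  files <- list()
  for (nm in names(results)) {
    path <- file.path(out_dir, paste0(nm, ".tsv"))
    utils::write.table(results[[nm]], path,
      sep = "\t", quote = FALSE,
      row.names = FALSE, na = ""
    )
    files[[nm]] <- list(
      file = basename(path),
      md5 = unname(tools::md5sum(path))
    )
  }
  manifest <- list(
    package = "duoburden",
    version = as.character(utils::packageVersion("duoburden")),
    seed = seed,
    config = config,
    files = files
  )
  jsonlite::write_json(
    manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null"
  )
  invisible(manifest)
}

#' Re-read a result table written by [write_results()]
#'
#' @param path Path to the TSV file.
#' @return Tibble with the table contents.
#' @export
read_result_table <- function(path) {
  tibble::as_tibble(utils::read.delim(path,
    stringsAsFactors = FALSE,
    check.names = FALSE, na.strings = ""
  ))
}

#' Verify the integrity of a results directory against its manifest
#'
#' Recomputes the MD5 checksum of every file listed in `manifest.json` and
#' stops with an integrity error on any mismatch or missing file.
#'
#' @param out_dir Directory previously populated by [write_results()].
#' @return Invisibly, the manifest.
#' @export
verify_manifest <- function(out_dir) {
  mp <- file.path(out_dir, "manifest.json")
  if (!file.exists(mp)) {
    stop("no manifest.json in '", out_dir, "'")
  }
  manifest <- jsonlite::read_json(mp)
  for (nm in names(manifest$files)) {
    entry <- manifest$files[[nm]]
    fp <- file.path(out_dir, entry$file)
    if (!file.exists(fp)) {
      stop("integrity error: file '", entry$file, "' listed in manifest is missing")
    }
    md5 <- unname(tools::md5sum(fp))
    if (!identical(md5, entry$md5)) {
      stop("integrity error: checksum mismatch for '", entry$file, "'")
    }
  }
  invisible(manifest)
}
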