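#' Upper-tail probability of the hypergeometric distribution
#'
#' Computes `P[X >= k]` for `X ~ Hypergeometric(N, K, n)` — drawing `n` genes
#' without replacement from a universe of `N` of which `K` are candidates —
#' as the exact sum `sum_{j=k}^{min(K,n)} C(K,j) C(N-K,n-j) / C(N,n)`,
#' accumulated in log space for numerical stability. This is the analytic
#' (Fisher's exact, one-sided) enrichment test.
#'
#' @param k Observed overlap (integer, `0 <= k <= n`).
#' @param K Number of candidate genes in the universe.
#' @param n Number of genes drawn.
#' @param N Universe size.
#' @return The tail probability, a number in `[0, 1]`.
#' @export
hypergeometric_upper_tail <- function(k, K, n, N) {
  k <- as.integer(k); K <- as.integer(K); n <- as.integer(n); N <- as.integer(N)
  if (anyNA(c(k, K, n, N))) stop("hypergeometric parameters must be integers")
  if (k < 0 || n < 0 || K < 0 || N < 0 || k > n || n > N || K > N) {
    stop(
      "invalid hypergeometric parameters: need 0 <= k <= n <= N and 0 <= K <= N, got ",
      sprintf("k=%d K=%d n=%d N=%d", k, K, n, N)
    )
  }
  lo <- max(0L, n - (N - K)) # smallest achievable overlap
  hi <- min(K, n)            # largest achievable overlap
  if (k <= lo) {
    return(1)
  }
  if (k > hi) {
    return(0)
  }
  j <- k:hi
  lp <- lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)
  min(1, exp(logsumexp(lp)))
}

#' Configuration for permutation enrichment testing
#'
#' @param n_iterations Number of random draws (default 100000).
#' @param alpha Significance level (default 0.005, a stringent threshold for
#'   testing a small number of fixed candidate sets).
#' @param seed Integer seed; identical seeds give bit-identical results.
#' @param scheme `"resample_variant_genes"`: each iteration draws as many
#'   genes as the group's variant-gene universe from the exome universe and
#'   records the overlap with the candidate set. `"random_gene_lists"`: each
#'   iteration draws a random candidate-sized gene list and records its
#'   overlap with the variant-gene universe.
#' @return An object of class `enrichment_config`.
#' @export
enrichment_config <- function(n_iterations = 100000L,
                              alpha = 0.005,
                              seed = 1L,
                              scheme = c("resample_variant_genes", "random_gene_lists")) {
  scheme <- match.arg(scheme)
  stopifnot(n_iterations >= 1, alpha > 0, alpha < 1)
  structure(
    list(
      n_iterations = as.integer(n_iterations), alpha = alpha,
      seed = as.integer(seed), scheme = scheme
    ),
    class = "enrichment_config"
  )
}

new_enrichment_result <- function(...) {
  structure(list(...), class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(
    "<enrichment_result>", x$group_label, "vs", x$gene_set_name,
    sprintf("(scheme %s)", x$scheme), "\n"
  )
  cat(sprintf(
    "  observed overlap %d (universe %d, candidates %d, draw %d)\n",
    x$observed, x$universe_size, x$candidate_size, x$draw_size
  ))
  cat(sprintf(
    "  null mean %.2f sd %.2f over %d iterations\n",
    x$null_mean, x$null_sd, x$n_iterations_run
  ))
  cat(sprintf(
    "  p (hypergeometric) = %.3g ; p (empirical) = %.3g\n",
    x$p_hypergeometric, x$p_empirical
  ))
  invisible(x)
}

#' Permutation test of candidate gene-set enrichment
#'
#' Builds a permutation null for the overlap between a group's variant-gene
#' universe and a candidate gene set by repeated random sampling without
#' replacement from the exome-wide gene universe, under one of two schemes
#' (see [enrichment_config()]). The empirical p-value uses the
#' `(r + 1) / (n + 1)` convention (`r` = iterations with overlap >= observed),
#' so a permutation p is never exactly zero; when no permutation reaches the
#' observed overlap the result is `1 / (n_iterations + 1)`. The analytic
#' hypergeometric upper tail for the same draw is reported alongside.
#'
#' @param variant_gene_universe Character vector: distinct genes with >= 1
#'   retained variant in the group.
#' @param candidate_set A [gene_set()]; must be a subset of
#'   `exome_gene_universe`.
#' @param observed Observed overlap statistic (integer), computed on the same
#'   universe definitions (see [observed_overlap()]).
#' @param config An [enrichment_config()].
#' @param exome_gene_universe Character vector of all genes in the sampling
#'   frame (genes with >= 1 callable position).
#' @param group_label Label recorded on the result.
#' @return An `enrichment_result` with the analytic and empirical p-values,
#'   null summaries, and the full vector of null overlaps
#'   (`$null_overlaps`) for plotting.
#' @export
permutation_enrichment <- function(variant_gene_universe, candidate_set,
                                   observed, config, exome_gene_universe,
                                   group_label = "group") {
  stopifnot(
    inherits(candidate_set, "gene_set"),
    inherits(config, "enrichment_config")
  )
  exome <- unique(as.character(exome_gene_universe))
  vgenes <- unique(as.character(variant_gene_universe))
  cand <- candidate_set$genes
  if (!all(cand %in% exome)) {
    stop("candidate set must be a subset of the exome gene universe")
  }
  if (!all(vgenes %in% exome)) {
    stop("variant gene universe must be a subset of the exome gene universe")
  }
  observed <- as.integer(observed)
  N <- length(exome)
  if (config$scheme == "resample_variant_genes") {
    draw_size <- length(vgenes)
    target <- cand
  } else {
    draw_size <- length(cand)
    target <- vgenes
  }
  if (draw_size > N) {
    stop("draw size (", draw_size, ") exceeds exome universe size (", N, ")")
  }
  is_target <- exome %in% target
  K_target <- sum(is_target)
  if (observed < 0 || observed > min(K_target, draw_size)) {
    stop("observed overlap is outside the achievable range [0, min(K, n)]")
  }

  nulls <- withr::with_seed(config$seed, {
    vapply(
      seq_len(config$n_iterations),
      function(i) sum(is_target[sample.int(N, draw_size)]),
      integer(1)
    )
  })
  r <- sum(nulls >= observed)
  new_enrichment_result(
    group_label = group_label,
    gene_set_name = candidate_set$name,
    scheme = config$scheme,
    observed = observed,
    universe_size = N,
    candidate_size = length(cand),
    draw_size = draw_size,
    p_hypergeometric = hypergeometric_upper_tail(observed, K_target, draw_size, N),
    p_empirical = (r + 1) / (config$n_iterations + 1),
    null_mean = mean(nulls),
    null_sd = stats::sd(nulls),
    n_iterations_run = config$n_iterations,
    null_overlaps = nulls
  )
}

#' Observed overlap between a group's variant genes and a candidate set
#'
#' @param variant_gene_universe Character vector of the group's variant genes.
#' @param candidate_set A [gene_set()].
#' @return Integer overlap.
#' @export
observed_overlap <- function(variant_gene_universe, candidate_set) {
  stopifnot(inherits(candidate_set, "gene_set"))
  length(intersect(unique(variant_gene_universe), candidate_set$genes))
}

#' Group-level enrichment test over a set of filtered profiles
#'
#' Aggregates the distinct variant genes across a group of samples, computes
#' the observed overlap with the candidate set, and runs both the analytic
#' hypergeometric test and the permutation null.
#'
#' @param profiles List of fully filtered `filtered_profile` objects forming
#'   one group.
#' @param candidate_set A [gene_set()].
#' @param exome_gene_universe Character vector of all genes in the sampling
#'   frame.
#' @param config An [enrichment_config()].
#' @param group_label Label for the group.
#' @return An `enrichment_result`.
#' @export
test_group_enrichment <- function(profiles, candidate_set, exome_gene_universe,
                                  config, group_label = "group") {
  stopifnot(length(profiles) >= 1)
  vgenes <- sort(unique(unlist(lapply(profiles, function(p) {
    g <- p$variants$gene
    g[!is.na(g)]
  }))))
  obs <- observed_overlap(vgenes, candidate_set)
  permutation_enrichment(
    vgenes, candidate_set, obs, config, exome_gene_universe,
    group_label = group_label
  )
}

#' Rate ratio of candidate-gene variation between two groups
#'
#' `(case_candidate / case_total) / (ctrl_candidate / ctrl_total)` — how many
#' times more likely a case variant is to fall in candidate genes than a
#' control variant, for whichever numerator/denominator pairs are supplied
#' (per-exome averages, aggregate counts, or candidate vs non-candidate
#' counts).
#'
#' @param case_candidate,case_total Case-group numerator and denominator.
#' @param ctrl_candidate,ctrl_total Control-group numerator and denominator.
#' @return The rate ratio (positive float).
#' @export
enrichment_rate_ratio <- function(case_candidate, case_total,
                                  ctrl_candidate, ctrl_total) {
  vals <- c(case_candidate, case_total, ctrl_candidate, ctrl_total)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all counts must be positive and finite (zero denominators are undefined)")
  }
  (case_candidate / case_total) / (ctrl_candidate / ctrl_total)
}

#' Bootstrap confidence interval for a between-group rate ratio
#'
#' Resamples samples (not variants) with replacement within each group and
#' recomputes the rate ratio from the resampled per-sample counts. Because a
#' ratio is strongly right-skewed at these group sizes, the interval is built
#' on the log scale: `estimate * exp(±z * sd(log bootstrap ratios))`.
#'
#' @param case_counts Data frame with per-sample columns `candidate` and
#'   `reference` for the case group (`reference` is the denominator class,
#'   e.g. non-candidate variants).
#' @param ctrl_counts Same, for the comparison group.
#' @param n_boot Number of bootstrap resamples.
#' @param conf Confidence level (default 0.95).
#' @param seed Integer seed.
#' @return List with `estimate`, `lower`, `upper`, `n_boot`.
#' @export
bootstrap_rate_ratio <- function(case_counts, ctrl_counts, n_boot = 500L,
                                 conf = 0.95, seed = 1L) {
  stopifnot(
    all(c("candidate", "reference") %in% names(case_counts)),
    all(c("candidate", "reference") %in% names(ctrl_counts)),
    nrow(case_counts) >= 2, nrow(ctrl_counts) >= 2
  )
  est <- enrichment_rate_ratio(
    sum(case_counts$candidate), sum(case_counts$reference),
    sum(ctrl_counts$candidate), sum(ctrl_counts$reference)
  )
  nc <- nrow(case_counts)
  nk <- nrow(ctrl_counts)
  boots <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      ci <- sample.int(nc, nc, replace = TRUE)
      ki <- sample.int(nk, nk, replace = TRUE)
      cc <- sum(case_counts$candidate[ci])
      cr <- sum(case_counts$reference[ci])
      kc <- sum(ctrl_counts$candidate[ki])
      kr <- sum(ctrl_counts$reference[ki])
      if (cc <= 0 || cr <= 0 || kc <= 0 || kr <= 0) {
        return(NA_real_)
      }
      (cc / cr) / (kc / kr)
    }, numeric(1))
  })
  boots <- boots[is.finite(boots) & boots > 0]
  z <- stats::qnorm(1 - (1 - conf) / 2)
  se_log <- stats::sd(log(boots))
  list(
    estimate = est,
    lower = est * exp(-z * se_log),
    upper = est * exp(z * se_log),
    n_boot = length(boots)
  )
}
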