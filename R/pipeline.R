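#' Scan configuration
#'
#' Settings for [genome_scan()]: the cis window, the nominal family-wise
#' level, the bootstrap calibration parameters, and whether to run the
#' logistic-regression benchmarks alongside the W-test.
#'
#' @param window_bp cis pairing window in base pairs, boundary inclusive
#'   (default 10000).
#' @param alpha family-wise error rate for the Bonferroni threshold.
#' @param boot_reps bootstrap replicates B for (h, f) calibration.
#' @param subsample_size bootstrap draw size; default `min(n, 1000)`.
#' @param floor per-k sample floor before pooled fallback.
#' @param seed integer seed for the calibration draws.
#' @param run_benchmarks run LR-m1/LR-m2 per pair.
#' @return list of class `scan_config`.
#' @export
scan_config <- function(window_bp = 10000L, alpha = 0.05, boot_reps = 400L,
                        subsample_size = NULL, floor = 50L, seed = 1L,
                        run_benchmarks = TRUE) {
  if (window_bp < 0) stop("window_bp must be non-negative")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  structure(list(window_bp = as.integer(window_bp), alpha = alpha,
                 boot_reps = as.integer(boot_reps),
                 subsample_size = subsample_size, floor = as.integer(floor),
                 seed = as.integer(seed), run_benchmarks = run_benchmarks),
            class = "scan_config")
}

#' Enumerate cis SNP-CpG pairs
#'
#' All same-chromosome pairs whose positions differ by at most `window_bp`
#' (inclusive), in deterministic order by SNP position then CpG position.
#'
#' @param snp_map,cpg_map marker-map data frames (`marker_id`, `chromosome`,
#'   `position`), e.g. from [read_marker_map()] or [simulate_positions()].
#' @param window_bp maximum distance in bp (default 10000).
#' @return data frame with `snp_id`, `cpg_id`, `distance_bp`; empty if no
#'   pair qualifies.
#' @export
enumerate_cis_pairs <- function(snp_map, cpg_map, window_bp = 10000L) {
  stopifnot(all(c("marker_id", "chromosome", "position") %in% names(snp_map)),
            all(c("marker_id", "chromosome", "position") %in% names(cpg_map)))
  empty <- data.frame(snp_id = character(0), cpg_id = character(0),
                      distance_bp = integer(0), stringsAsFactors = FALSE)
  chroms <- intersect(unique(snp_map$chromosome), unique(cpg_map$chromosome))
  parts <- lapply(chroms, function(ch) {
    s <- snp_map[snp_map$chromosome == ch, , drop = FALSE]
    s <- s[order(s$position, s$marker_id), , drop = FALSE]
    cp <- cpg_map[cpg_map$chromosome == ch, , drop = FALSE]
    cp <- cp[order(cp$position, cp$marker_id), , drop = FALSE]
    d <- abs(outer(s$position, cp$position, "-"))
    hit <- which(d <= window_bp, arr.ind = TRUE)
    if (nrow(hit) == 0L) return(empty)
    out <- data.frame(snp_id = s$marker_id[hit[, 1L]],
                      cpg_id = cp$marker_id[hit[, 2L]],
                      distance_bp = d[hit], stringsAsFactors = FALSE)
    out[order(s$position[hit[, 1L]], cp$position[hit[, 2L]]), , drop = FALSE]
  })
  out <- do.call(rbind, c(list(empty), parts))
  rownames(out) <- NULL
  out
}

#' Bonferroni per-test significance level
#'
#' @param alpha family-wise error rate.
#' @param n_tests number of tests performed.
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  if (n_tests < 1) stop("n_tests must be at least 1")
  alpha / n_tests
}

#' Cis-window SNP-CpG interaction scan
#'
#' The full analysis: aligns the cohort by subject id, codes SNPs to the
#' minor allele and binarizes CpGs (skipping monomorphic/constant markers
#' with logged reasons), enumerates cis pairs, calibrates the W-test's
#' (h, f) once on the cohort by bootstrap, tests every cis pair, and
#' optionally runs both logistic-regression benchmarks per pair. Results are
#' ranked by W-test p-value; the summary carries the Bonferroni threshold at
#' the configured family-wise level and the significant-pair count.
#'
#' @param genotype subjects x SNPs matrix of raw additive codes (row names =
#'   subject ids).
#' @param methylation subjects x CpGs beta-value matrix.
#' @param snp_map,cpg_map marker maps.
#' @param phenotype binary response: named vector or data frame with
#'   `subject_id` and `responder`/`response`.
#' @param config a [scan_config()].
#' @return object of class `wtest_scan`: list with `results` (ranked pair
#'   data frame), `calibration`, and `summary` (counts, skip reasons,
#'   Bonferroni threshold, significant pairs).
#' @export
genome_scan <- function(genotype, methylation, snp_map, cpg_map, phenotype,
                        config = scan_config()) {
  stopifnot(inherits(config, "scan_config"))
  cohort <- complete_case_filter(genotype, methylation, phenotype)
  if (length(unique(cohort$response)) < 2L) {
    stop("phenotype has a single class after complete-case filtering")
  }
  pairs <- enumerate_cis_pairs(snp_map, cpg_map, config$window_bp)
  n_enumerated <- nrow(pairs)
  if (n_enumerated == 0L) stop("no cis pairs within ", config$window_bp, " bp")
  pairs <- pairs[pairs$snp_id %in% colnames(cohort$genotype) &
                   pairs$cpg_id %in% colnames(cohort$methylation), , drop = FALSE]
  if (nrow(pairs) == 0L) stop("no cis pair maps onto the genotype/methylation matrices")

  prep <- prepare_cohort(cohort$genotype[, unique(pairs$snp_id), drop = FALSE],
                         cohort$methylation[, unique(pairs$cpg_id), drop = FALSE])
  snp_ok <- colnames(prep$coded)[prep$snp_ok]
  cpg_ok <- colnames(prep$mbin)[prep$cpg_ok]
  skip_mono <- sum(!(pairs$snp_id %in% snp_ok))
  skip_const <- sum(pairs$snp_id %in% snp_ok & !(pairs$cpg_id %in% cpg_ok))
  usable <- pairs$snp_id %in% snp_ok & pairs$cpg_id %in% cpg_ok
  tested_pairs <- pairs[usable, , drop = FALSE]
  if (nrow(tested_pairs) == 0L) stop("no polymorphic cis pairs to test")

  calib_pairs <- unique(tested_pairs[c("snp_id", "cpg_id")])
  if (nrow(calib_pairs) > 500L) {
    calib_pairs <- with_seed(derive_seed(config$seed, 55L),
                             calib_pairs[sample.int(nrow(calib_pairs), 500L), ])
  }
  samples <- bootstrap_null_samples(prep$coded, prep$mbin, cohort$response,
                                    calib_pairs, B = config$boot_reps,
                                    subsample_size = config$subsample_size,
                                    seed = derive_seed(config$seed, 66L))
  calib <- estimate_hf(samples, floor = config$floor)

  y <- as.integer(cohort$response)
  n_pairs <- nrow(tested_pairs)
  res <- vector("list", n_pairs)
  skip_degenerate <- 0L
  for (i in seq_len(n_pairs)) {
    sid <- tested_pairs$snp_id[i]
    cid <- tested_pairs$cpg_id[i]
    g <- prep$coded[, sid]
    mb <- prep$mbin[, cid]
    tab <- tabulate_cells(build_pair_categories(g, mb), y)
    if (tab$k < 2L) {
      skip_degenerate <- skip_degenerate + 1L
      next
    }
    S <- raw_statistic(tab)$S
    w <- wtest_pvalue(S, calib, tab$k)
    lr1 <- lr2 <- NULL
    if (config$run_benchmarks) {
      lr1 <- tryCatch(lr_interaction_test(g, mb, y, "binary"), error = function(e) NULL)
      lr2 <- tryCatch(lr_interaction_test(g, cohort$methylation[, cid], y, "continuous"),
                      error = function(e) NULL)
    }
    res[[i]] <- data.frame(
      snp_id = sid, cpg_id = cid, distance_bp = tested_pairs$distance_bp[i],
      snp_maf = unname(prep$maf[sid]), k = tab$k, S = S, W = w$W,
      p_value = w$p_value,
      lr_m1_p = if (is.null(lr1)) NA_real_ else lr1$p_value,
      lr_m2_p = if (is.null(lr2)) NA_real_ else lr2$p_value,
      correction_applied = tab$correction_applied,
      lr_converged = if (is.null(lr1) || is.null(lr2)) NA else lr1$converged && lr2$converged,
      stringsAsFactors = FALSE
    )
  }
  results <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(results) || nrow(results) == 0L) {
    stop("every cis pair produced a degenerate contingency table")
  }
  # p-values that underflow to exactly 0 are floored and flagged
  floored <- results$p_value == 0
  results$p_value[floored] <- .Machine$double.xmin
  results <- results[order(results$p_value, results$snp_id, results$cpg_id), , drop = FALSE]
  rownames(results) <- NULL

  n_tested <- nrow(results)
  threshold <- bonferroni_threshold(config$alpha, n_tested)
  summary <- list(
    n_subjects = length(cohort$subject_ids),
    removal_log = cohort$removal_log,
    n_pairs_enumerated = n_enumerated,
    n_pairs_tested = n_tested,
    skip_counts = c(monomorphic_snp = skip_mono, constant_cpg = skip_const,
                    degenerate_table = skip_degenerate,
                    unmapped = n_enumerated - nrow(pairs)),
    alpha = config$alpha,
    bonferroni_threshold = threshold,
    n_significant = sum(results$p_value <= threshold),
    n_p_floored = sum(floored),
    window_bp = config$window_bp,
    seed = config$seed
  )
  structure(list(results = results, calibration = calib, summary = summary),
            class = "wtest_scan")
}

#' @export
print.wtest_scan <- function(x, ...) {
  s <- x$summary
  cat(sprintf("cis SNP-CpG W-test scan: %d subjects, %d/%d pairs tested (window %d bp)\n",
              s$n_subjects, s$n_pairs_tested, s$n_pairs_enumerated, s$window_bp))
  cat(sprintf("Bonferroni threshold %.3g at FWER %.2f: %d significant pair(s)\n",
              s$bonferroni_threshold, s$alpha, s$n_significant))
  cat("top pairs:\n")
  print(utils::head(x$results[c("snp_id", "cpg_id", "distance_bp", "snp_maf",
                                "k", "W", "p_value")], 5), row.names = FALSE)
  invisible(x)
}

#' Q-Q plot points and genomic-inflation summary
#'
#' For m p-values, observed order statistics are paired with the uniform
#' expectations (i - 0.5)/m, both on the -log10 scale. The attribute
#' `"lambda"` carries the genomic inflation factor: the median of the
#' chi-squared(1) quantiles of the p-values over the null median.
#'
#' @param p_values p-values in (0, 1]; exact zeros must be floored upstream.
#' @return data frame with `expected`, `observed` (-log10 scale, ascending in
#'   significance) and attribute `lambda`.
#' @export
qq_points <- function(p_values) {
  p <- as.numeric(p_values)
  if (length(p) == 0L) stop("no p-values supplied")
  if (anyNA(p) || any(p <= 0 | p > 1)) {
    stop("p-values must lie in (0, 1]; floor underflowed zeros upstream")
  }
  m <- length(p)
  obs <- sort(p)
  expected <- (seq_len(m) - 0.5) / m
  lambda <- stats::median(stats::qchisq(p, df = 1, lower.tail = FALSE)) /
    stats::qchisq(0.5, df = 1, lower.tail = FALSE)
  structure(data.frame(expected = -log10(expected), observed = -log10(obs)),
            lambda = lambda)
}
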