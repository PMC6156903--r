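# Code every SNP column and binarize every CpG column of a cohort.
# Monomorphic SNPs / constant CpGs are dropped with a reason log.
prepare_cohort <- function(genotype, methylation) {
  snp_ok <- logical(ncol(genotype))
  coded <- genotype
  maf <- numeric(ncol(genotype))
  for (j in seq_len(ncol(genotype))) {
    enc <- encode_additive(genotype[, j])
    snp_ok[j] <- !enc$monomorphic && length(unique(enc$coded[!is.na(enc$coded)])) > 1L
    coded[, j] <- enc$coded
    maf[j] <- enc$maf
  }
  names(maf) <- colnames(genotype)
  mbin <- matrix(NA_integer_, nrow(methylation), ncol(methylation),
                 dimnames = dimnames(methylation))
  cpg_ok <- logical(ncol(methylation))
  for (j in seq_len(ncol(methylation))) {
    bj <- tryCatch(binarize_methylation(methylation[, j]), error = function(e) NULL)
    if (!is.null(bj)) {
      cpg_ok[j] <- TRUE
      mbin[, j] <- as.integer(bj$labels) - 1L
    }
  }
  list(coded = coded, maf = maf, mbin = mbin, snp_ok = snp_ok, cpg_ok = cpg_ok)
}

# candidate pair list for calibration: up to max_pairs random usable combos
calibration_pairs <- function(n_snps, n_cpgs, snp_ok, cpg_ok, max_pairs = 500L, seed = NULL) {
  snps <- which(snp_ok)
  cpgs <- which(cpg_ok)
  if (!length(snps) || !length(cpgs)) stop("no usable SNP-CpG pairs for calibration")
  total <- length(snps) * length(cpgs)
  with_seed(seed, {
    take <- min(total, max_pairs)
    idx <- if (total <= max_pairs) seq_len(total) else sample.int(total, max_pairs)
    data.frame(snp = snps[(idx - 1L) %% length(snps) + 1L],
               cpg = cpgs[(idx - 1L) %/% length(snps) + 1L])[seq_len(take), ]
  })
}

#' Permutation type-I-error study for the W-test (and LR benchmarks)
#'
#' Generates one synthetic cohort, calibrates (h, f) once by bootstrap, then
#' repeatedly permutes the phenotype and tests one SNP-CpG pair, counting the
#' fraction of replicates with p <= alpha. Permuting the phenotype enforces
#' the null regardless of how the cohort's phenotype was generated.
#'
#' @param config a [sim_config()] describing the cohort.
#' @param n_replicates number of phenotype permutations (default 2000).
#' @param alpha nominal per-test level (default 0.05).
#' @param seed integer seed for calibration and permutations; defaults to the
#'   config seed.
#' @param B,subsample_size,floor calibration settings, see
#'   [bootstrap_null_samples()] and [estimate_hf()].
#' @param run_benchmarks also run LR-m1/LR-m2 on each permuted replicate.
#' @param average_over_pairs if `TRUE`, each replicate tests a random usable
#'   pair instead of the one designated pair.
#' @return object of class `sim_study_result`: data frame with one row per
#'   method (`method`, `alpha`, `n_replicates`, `rejections`, `rate`,
#'   `mc_se`); the calibration table is kept in attribute `"calibration"`.
#' @export
type_i_error_experiment <- function(config, n_replicates = 2000L, alpha = 0.05,
                                    seed = config$seed, B = 400L,
                                    subsample_size = NULL, floor = 50L,
                                    run_benchmarks = FALSE,
                                    average_over_pairs = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  n_replicates <- as.integer(n_replicates)
  if (n_replicates < 1L) stop("n_replicates must be at least 1")
  if (n_replicates < 100L) warning("fewer than 100 replicates gives a noisy error-rate estimate")
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")

  cohort <- simulate_cohort(config)
  prep <- prepare_cohort(cohort$genotype, cohort$methylation)
  pairs <- calibration_pairs(config$n_snps, config$n_cpgs, prep$snp_ok, prep$cpg_ok,
                             seed = derive_seed(seed, 55L))
  samples <- bootstrap_null_samples(prep$coded, prep$mbin, cohort$phenotype,
                                    pairs, B = B, subsample_size = subsample_size,
                                    seed = derive_seed(seed, 66L))
  calib <- estimate_hf(samples, floor = floor)

  tested_snp <- config$causal_snp
  tested_cpg <- config$causal_cpg
  if (!average_over_pairs &&
      (!prep$snp_ok[tested_snp] || !prep$cpg_ok[tested_cpg])) {
    stop("the designated test pair is monomorphic/constant in this cohort")
  }
  n <- config$n_subjects
  y <- as.integer(cohort$phenotype)

  with_seed(derive_seed(seed, 77L), {
    rej_w <- rej_m1 <- rej_m2 <- 0L
    nc_m1 <- nc_m2 <- 0L
    for (r in seq_len(n_replicates)) {
      ph <- y[sample.int(n)]
      if (average_over_pairs) {
        i <- sample.int(nrow(pairs), 1L)
        tested_snp <- pairs$snp[i]
        tested_cpg <- pairs$cpg[i]
      }
      g <- prep$coded[, tested_snp]
      cat6 <- 2L * g + prep$mbin[, tested_cpg]
      st <- pair_stat(cat6, ph)
      if (st$k >= 2L) {
        p <- wtest_pvalue(st$S, calib, st$k)$p_value
        if (p <= alpha) rej_w <- rej_w + 1L
      }
      if (run_benchmarks) {
        m1 <- lr_interaction_test(g, prep$mbin[, tested_cpg], ph, "binary")
        m2 <- lr_interaction_test(g, cohort$methylation[, tested_cpg], ph, "continuous")
        if (!m1$converged) nc_m1 <- nc_m1 + 1L
        if (!m2$converged) nc_m2 <- nc_m2 + 1L
        if (isTRUE(m1$p_value <= alpha)) rej_m1 <- rej_m1 + 1L
        if (isTRUE(m2$p_value <= alpha)) rej_m2 <- rej_m2 + 1L
      }
    }
    methods <- c("W-test", if (run_benchmarks) c("LR-m1", "LR-m2"))
    rejections <- c(rej_w, if (run_benchmarks) c(rej_m1, rej_m2))
    rate <- rejections / n_replicates
    out <- data.frame(method = methods, alpha = alpha,
                      n_replicates = n_replicates, rejections = rejections,
                      rate = rate,
                      mc_se = sqrt(rate * (1 - rate) / n_replicates),
                      stringsAsFactors = FALSE)
    structure(out, class = c("sim_study_result", "data.frame"),
              calibration = calib,
              n_nonconverged = c(lr_m1 = nc_m1, lr_m2 = nc_m2))
  })
}

#' Power study of the W-test over a grid of interaction effects
#'
#' For each interaction log-odds in `effect_grid`, redraws the phenotype from
#' the interaction model and tests the designated causal pair, reporting the
#' rejection rate at `alpha`. Calibration is done once on the base cohort
#' (under the permutation null). A zero effect reduces to a type-I-error run.
#'
#' @param config a [sim_config()] with `effect_model = "interaction"`.
#' @param n_replicates phenotype redraws per effect size.
#' @param alpha nominal level.
#' @param effect_grid numeric vector of `beta_int` values.
#' @param seed integer seed.
#' @param B,subsample_size,floor calibration settings.
#' @return `sim_study_result` data frame with one row per effect size
#'   (`beta_int`, `alpha`, `n_replicates`, `rejections`, `rate`, `mc_se`).
#' @export
power_experiment <- function(config, n_replicates = 200L, alpha = 0.05,
                             effect_grid, seed = config$seed, B = 400L,
                             subsample_size = NULL, floor = 50L) {
  stopifnot(inherits(config, "sim_config"))
  if (config$effect_model != "interaction") {
    stop("power_experiment requires an interaction-model config")
  }
  if (missing(effect_grid) || length(effect_grid) == 0L) stop("effect_grid must be non-empty")
  n_replicates <- as.integer(n_replicates)
  if (n_replicates < 1L) stop("n_replicates must be at least 1")

  cohort <- simulate_cohort(config)
  prep <- prepare_cohort(cohort$genotype, cohort$methylation)
  pairs <- calibration_pairs(config$n_snps, config$n_cpgs, prep$snp_ok, prep$cpg_ok,
                             seed = derive_seed(seed, 55L))
  samples <- bootstrap_null_samples(prep$coded, prep$mbin, cohort$phenotype,
                                    pairs, B = B, subsample_size = subsample_size,
                                    seed = derive_seed(seed, 66L))
  calib <- estimate_hf(samples, floor = floor)
  if (!prep$snp_ok[config$causal_snp] || !prep$cpg_ok[config$causal_cpg]) {
    stop("the designated causal pair is monomorphic/constant in this cohort")
  }
  G <- prep$coded[, config$causal_snp]
  Graw <- cohort$genotype[, config$causal_snp]
  M <- cohort$methylation[, config$causal_cpg]
  mb <- prep$mbin[, config$causal_cpg]

  with_seed(derive_seed(seed, 88L), {
    rows <- lapply(effect_grid, function(b_int) {
      eta <- config$beta0 + config$beta_snp * Graw + config$beta_cpg * M +
        b_int * Graw * M
      pr <- stats::plogis(eta)
      rej <- 0L
      for (r in seq_len(n_replicates)) {
        y <- stats::rbinom(length(pr), 1L, pr)
        if (length(unique(y)) < 2L) next
        st <- pair_stat(2L * G + mb, y)
        if (st$k < 2L) next
        p <- wtest_pvalue(st$S, calib, st$k)$p_value
        if (p <= alpha) rej <- rej + 1L
      }
      rate <- rej / n_replicates
      data.frame(beta_int = b_int, alpha = alpha, n_replicates = n_replicates,
                 rejections = rej, rate = rate,
                 mc_se = sqrt(rate * (1 - rate) / n_replicates))
    })
    out <- do.call(rbind, rows)
    structure(out, class = c("sim_study_result", "data.frame"), calibration = calib)
  })
}

#' @export
print.sim_study_result <- function(x, ...) {
  cat("simulation study result\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
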