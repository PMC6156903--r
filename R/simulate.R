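#' Configuration for a synthetic SNP-CpG cohort
#'
#' Describes a cohort emulating the structure of pharmacogenomic
#' case-control data: biallelic SNPs in Hardy-Weinberg proportions with MAF
#' drawn uniformly from `maf_range`, bimodal beta-distributed methylation
#' values (a two-component beta mixture, as typical of array beta values),
#' marker positions on one chromosome arranged so cis pairs exist, and a
#' binary responder phenotype generated from a logistic model on one
#' designated causal SNP-CpG pair.
#'
#' @param n_subjects cohort size (default 680).
#' @param n_snps,n_cpgs marker counts.
#' @param maf_range minor-allele-frequency range, within (0, 0.5].
#' @param beta_shapes_low,beta_shapes_high shape pairs of the low- and
#'   high-methylation beta components (defaults Beta(2,8) and Beta(8,2)).
#' @param p_high mixture proportion of the high-methylation state.
#' @param chrom_length chromosome length in bp.
#' @param effect_model `"null"` (phenotype independent of markers), `"main"`
#'   (SNP and CpG main effects only) or `"interaction"` (adds the product
#'   term).
#' @param beta0 baseline log-odds of response.
#' @param beta_snp,beta_cpg,beta_int log-odds per unit of the additive
#'   genotype code, the beta value, and their product.
#' @param causal_snp,causal_cpg column indices of the designated causal pair.
#' @param seed integer seed governing all draws made from this config.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_subjects = 680L, n_snps = 1L, n_cpgs = 1L,
                       maf_range = c(0.05, 0.5),
                       beta_shapes_low = c(2, 8), beta_shapes_high = c(8, 2),
                       p_high = 0.5, chrom_length = 1e6L,
                       effect_model = c("null", "main", "interaction"),
                       beta0 = 0, beta_snp = 0, beta_cpg = 0, beta_int = 0,
                       causal_snp = 1L, causal_cpg = 1L, seed = NULL) {
  effect_model <- match.arg(effect_model)
  if (n_subjects < 2L) stop("n_subjects must be at least 2")
  if (n_snps < 1L || n_cpgs < 1L) stop("need at least one SNP and one CpG")
  if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    stop("maf_range must satisfy 0 < low <= high <= 0.5")
  }
  if (any(c(beta_shapes_low, beta_shapes_high) <= 0)) {
    stop("beta mixture shape parameters must be positive")
  }
  if (p_high <= 0 || p_high >= 1) stop("p_high must lie in (0, 1)")
  structure(
    list(n_subjects = as.integer(n_subjects), n_snps = as.integer(n_snps),
         n_cpgs = as.integer(n_cpgs), maf_range = as.numeric(maf_range),
         beta_shapes_low = as.numeric(beta_shapes_low),
         beta_shapes_high = as.numeric(beta_shapes_high),
         p_high = p_high, chrom_length = as.integer(chrom_length),
         effect_model = effect_model, beta0 = beta0, beta_snp = beta_snp,
         beta_cpg = beta_cpg, beta_int = beta_int,
         causal_snp = as.integer(causal_snp), causal_cpg = as.integer(causal_cpg),
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "sim_config"
  )
}

sim_subject_ids <- function(n) sprintf("subj_%04d", seq_len(n))
sim_snp_ids <- function(n) sprintf("rs%06d", seq_len(n))
sim_cpg_ids <- function(n) sprintf("cg%08d", seq_len(n))

#' Simulate genotypes under Hardy-Weinberg equilibrium
#'
#' Per SNP, a MAF q is drawn uniformly from the configured range and
#' genotypes are sampled with probabilities ((1-q)^2, 2q(1-q), q^2).
#'
#' @param config a [sim_config()].
#' @return integer matrix (subjects x SNPs) with entries in \{0, 1, 2\};
#'   attribute `"maf_true"` carries the drawn allele frequencies.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, 11L), {
    n <- config$n_subjects
    q <- stats::runif(config$n_snps, config$maf_range[1], config$maf_range[2])
    g <- vapply(q, function(qi) {
      sample.int(3L, n, replace = TRUE,
                 prob = c((1 - qi)^2, 2 * qi * (1 - qi), qi^2)) - 1L
    }, integer(n))
    g <- matrix(g, nrow = n,
                dimnames = list(sim_subject_ids(n), sim_snp_ids(config$n_snps)))
    attr(g, "maf_true") <- q
    g
  })
}

#' Simulate bimodal methylation beta values
#'
#' Per CpG per subject, a methylation state is drawn (high with probability
#' `p_high`) and the beta value is drawn from the corresponding beta
#' component, yielding the bimodal distribution typical of array beta values.
#'
#' @param config a [sim_config()].
#' @return numeric matrix (subjects x CpGs) with entries in (0, 1).
#' @export
simulate_methylation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, 22L), {
    n <- config$n_subjects
    total <- n * config$n_cpgs
    state <- stats::rbinom(total, 1L, config$p_high)
    shape1 <- ifelse(state == 1L, config$beta_shapes_high[1], config$beta_shapes_low[1])
    shape2 <- ifelse(state == 1L, config$beta_shapes_high[2], config$beta_shapes_low[2])
    vals <- stats::rbeta(total, shape1, shape2)
    matrix(vals, nrow = n,
           dimnames = list(sim_subject_ids(n), sim_cpg_ids(config$n_cpgs)))
  })
}

#' Simulate marker positions with guaranteed cis structure
#'
#' SNP positions are uniform on the chromosome. Each CpG is, with probability
#' 0.8, placed within +-10 kb of a randomly chosen SNP (clamped to the
#' chromosome) and otherwise placed uniformly, so cis SNP-CpG pairs always
#' exist.
#'
#' @param config a [sim_config()]; `chrom_length` must be at least 20001 bp.
#' @param chromosome chromosome label used for all markers.
#' @return marker-map data frame (`marker_id`, `marker_kind`, `chromosome`,
#'   `position`) holding both SNP and CpG rows; split with
#'   `subset(map, marker_kind == "SNP")` etc.
#' @export
simulate_positions <- function(config, chromosome = "11") {
  stopifnot(inherits(config, "sim_config"))
  if (config$chrom_length < 20001L) stop("chrom_length must be at least 20001 bp")
  with_seed(derive_seed(config$seed, 33L), {
    snp_pos <- sample.int(config$chrom_length, config$n_snps)
    anchor <- sample.int(config$n_snps, config$n_cpgs, replace = TRUE)
    cis <- stats::runif(config$n_cpgs) < 0.8
    offset <- sample.int(20001L, config$n_cpgs, replace = TRUE) - 10001L
    cpg_pos <- ifelse(cis,
                      pmin(pmax(snp_pos[anchor] + offset, 1L), config$chrom_length),
                      sample.int(config$chrom_length, config$n_cpgs, replace = TRUE))
    rbind(
      data.frame(marker_id = sim_snp_ids(config$n_snps), marker_kind = "SNP",
                 chromosome = chromosome, position = as.integer(snp_pos),
                 stringsAsFactors = FALSE),
      data.frame(marker_id = sim_cpg_ids(config$n_cpgs), marker_kind = "CpG",
                 chromosome = chromosome, position = as.integer(cpg_pos),
                 stringsAsFactors = FALSE)
    )
  })
}

#' Simulate a binary drug-response phenotype
#'
#' Responder status is drawn from a logistic model on the designated causal
#' pair: P(Y=1) = logistic(beta0 + beta_snp*G + beta_cpg*M + beta_int*G*M),
#' with G the additive genotype code and M the beta value. Under the null
#' model all marker coefficients are zero.
#'
#' @param genotype matrix from [simulate_genotypes()].
#' @param methylation matrix from [simulate_methylation()].
#' @param config a [sim_config()].
#' @return named integer 0/1 vector, one entry per subject.
#' @export
simulate_phenotype <- function(genotype, methylation, config) {
  stopifnot(inherits(config, "sim_config"))
  eta <- rep(config$beta0, nrow(genotype))
  if (config$effect_model != "null") {
    if (config$causal_snp > ncol(genotype) || config$causal_cpg > ncol(methylation)) {
      stop("designated causal pair is outside the simulated marker matrices")
    }
    G <- genotype[, config$causal_snp]
    M <- methylation[, config$causal_cpg]
    eta <- eta + config$beta_snp * G + config$beta_cpg * M
    if (config$effect_model == "interaction") eta <- eta + config$beta_int * G * M
  }
  with_seed(derive_seed(config$seed, 44L), {
    y <- stats::rbinom(length(eta), 1L, stats::plogis(eta))
    names(y) <- rownames(genotype)
    y
  })
}

#' Simulate a complete cohort
#'
#' Convenience wrapper drawing genotypes, methylation, marker positions and
#' phenotype from one config.
#'
#' @param config a [sim_config()].
#' @return list with `genotype`, `methylation`, `map`, `phenotype`, `config`.
#' @export
simulate_cohort <- function(config) {
  g <- simulate_genotypes(config)
  m <- simulate_methylation(config)
  map <- simulate_positions(config)
  y <- simulate_phenotype(g, m, config)
  list(genotype = g, methylation = m, map = map, phenotype = y, config = config)
}
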