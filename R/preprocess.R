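#' Additive minor-allele coding of one SNP
#'
#' Codes a biallelic SNP as the count of minor alleles in \{0, 1, 2\}. If the
#' counted allele has observed frequency above 0.5 in the cohort the codes are
#' flipped (g -> 2 - g) so that counts always refer to the dataset minor
#' allele; flipping twice restores the original coding. Missing values are
#' preserved.
#'
#' @param genotypes integer vector with entries in \{0, 1, 2\} or `NA`.
#' @return list with `coded` (vector in \{0,1,2\}/NA), `maf` (observed
#'   frequency of the counted allele after polarization, always <= 0.5),
#'   `flipped` and `monomorphic` flags.
#' @export
encode_additive <- function(genotypes) {
  g <- as.integer(genotypes)
  if (!all(is.na(g) | g %in% 0:2)) stop("genotype entries must be in {0, 1, 2} or NA")
  obs <- g[!is.na(g)]
  if (length(obs) == 0L) stop("monomorphic/empty SNP: all genotypes missing")
  freq <- mean(obs) / 2
  flipped <- freq > 0.5
  if (flipped) {
    g <- 2L - g
    freq <- 1 - freq
  }
  list(coded = g, maf = freq, flipped = flipped, monomorphic = freq == 0)
}

#' Binarize one CpG's beta values by two-mean clustering
#'
#' One-dimensional k-means with k = 2. In one dimension the optimal two-mean
#' partition is a threshold split of the sorted values, so the clustering is
#' solved exactly and deterministically by scanning all splits and taking the
#' one with minimal within-cluster sum of squares (cumulative-sum arithmetic,
#' O(n log n)); no iterative refinement or random initialization is involved.
#' Cluster centers are the two cluster means, and every subject with beta at
#' or below the midpoint of the centers is labeled "low", the rest "high"
#' (the optimal split always satisfies this midpoint rule). Missing values
#' get a missing label and do not influence the fit.
#'
#' @param betas numeric vector of methylation beta values in \[0, 1\].
#' @return object of class `binarized_cpg`: list with `labels` (factor
#'   low/high per subject), `center_low`, `center_high`, and `n_splits`, the
#'   number of candidate threshold splits examined.
#' @export
binarize_methylation <- function(betas) {
  x <- as.numeric(betas)
  if (!all(is.na(x) | (x >= 0 & x <= 1))) stop("beta values must lie in [0, 1]")
  obs <- x[!is.na(x)]
  if (length(unique(obs)) < 2L) stop("constant CpG, cannot binarize")

  xs <- sort(obs)
  n <- length(xs)
  cs <- cumsum(xs)
  cs2 <- cumsum(xs^2)
  i <- seq_len(n - 1L)
  wcss <- (cs2[i] - cs[i]^2 / i) +
    ((cs2[n] - cs2[i]) - (cs[n] - cs[i])^2 / (n - i))
  valid <- xs[i] < xs[i + 1L]  # split only between distinct values
  split_at <- i[valid][which.min(wcss[valid])]
  lo <- cs[split_at] / split_at
  hi <- (cs[n] - cs[split_at]) / (n - split_at)
  assign_high <- obs > (lo + hi) / 2

  labels <- rep(NA_character_, length(x))
  labels[!is.na(x)] <- ifelse(assign_high, "high", "low")
  structure(
    list(labels = factor(labels, levels = c("low", "high")),
         center_low = lo, center_high = hi, n_splits = sum(valid)),
    class = "binarized_cpg"
  )
}

#' Derive binary drug response from triglyceride measurements
#'
#' Pre-treatment TG is the mean of visits 1-2, post-treatment TG the mean of
#' visits 3-4; the fractional change is \eqn{\Delta TG\% = (TG_{pre} -
#' TG_{post}) / TG_{pre}}. A subject is a responder (treatment effective) when
#' the decrease strictly exceeds 30\%; a change of exactly 30\% or less,
#' including any increase, is a non-responder.
#'
#' @param phenotypes data frame with `subject_id` plus either the four TG
#'   visit columns (`tg_visit1`..`tg_visit4`, mg/dL, positive) or a
#'   precomputed binary `response` column (passed through unchanged).
#' @param threshold responder cutoff on the fractional decrease (default 0.30).
#' @return data frame with `subject_id`, `tg_pre`, `tg_post`, `delta_pct`,
#'   `responder`.
#' @export
define_drug_response <- function(phenotypes, threshold = 0.30) {
  stopifnot(is.data.frame(phenotypes), "subject_id" %in% names(phenotypes))
  n <- nrow(phenotypes)
  tg_cols <- paste0("tg_visit", 1:4)
  tg_complete <- if (all(tg_cols %in% names(phenotypes))) {
    stats::complete.cases(phenotypes[tg_cols])
  } else rep(FALSE, n)
  given <- if ("response" %in% names(phenotypes)) phenotypes$response else rep(NA_integer_, n)
  if (!all(is.na(given) | given %in% 0:1)) stop("response values must be 0/1")
  if (!any(tg_complete) && all(is.na(given))) {
    stop("phenotypes must carry four complete TG visits or a response column")
  }

  tg_pre <- tg_post <- delta <- rep(NA_real_, n)
  responder <- as.integer(given)
  if (any(tg_complete)) {
    tg <- as.matrix(phenotypes[tg_complete, tg_cols])
    if (any(tg <= 0)) stop("TG values must be positive")
    tg_pre[tg_complete] <- (tg[, 1] + tg[, 2]) / 2
    tg_post[tg_complete] <- (tg[, 3] + tg[, 4]) / 2
    delta[tg_complete] <- (tg_pre[tg_complete] - tg_post[tg_complete]) / tg_pre[tg_complete]
    responder[tg_complete] <- as.integer(delta[tg_complete] > threshold)
  }
  data.frame(subject_id = phenotypes$subject_id,
             tg_pre = tg_pre, tg_post = tg_post, delta_pct = delta,
             responder = responder,
             stringsAsFactors = FALSE)
}

#' Align cohort tables and drop subjects with missing values
#'
#' Restricts genotype, methylation and phenotype data to the subjects present
#' in all three sources with complete records, matching on subject id (never
#' on row order). Retained subjects are returned in sorted id order so that
#' downstream statistics are invariant to input row shuffles.
#'
#' @param genotype subjects x SNPs matrix with subject ids as row names.
#' @param methylation subjects x CpGs matrix with subject ids as row names.
#' @param phenotype data frame with `subject_id` and `responder` (or
#'   `response`) columns, or a named binary vector.
#' @return list with the aligned `genotype`, `methylation`, `response`
#'   (named integer vector), `subject_ids`, and `removal_log` (named counts
#'   by removal reason).
#' @export
complete_case_filter <- function(genotype, methylation, phenotype) {
  resp <- phenotype_to_vector(phenotype)
  ids_g <- rownames(genotype)
  ids_m <- rownames(methylation)
  if (is.null(ids_g) || is.null(ids_m)) stop("matrices must carry subject ids as row names")
  common <- intersect(intersect(ids_g, ids_m), names(resp))
  all_ids <- unique(c(ids_g, ids_m, names(resp)))
  log <- c(not_in_all_tables = length(all_ids) - length(common))
  if (length(common) == 0L) stop("no subjects shared by genotype, methylation and phenotype tables")

  miss_g <- common[rowSums(is.na(genotype[common, , drop = FALSE])) > 0]
  miss_m <- setdiff(common[rowSums(is.na(methylation[common, , drop = FALSE])) > 0], miss_g)
  miss_p <- setdiff(common[is.na(resp[common])], c(miss_g, miss_m))
  keep <- sort(setdiff(common, c(miss_g, miss_m, miss_p)))
  log <- c(log, missing_genotype = length(miss_g),
           missing_methylation = length(miss_m),
           missing_phenotype = length(miss_p))
  if (length(keep) == 0L) stop("no subjects with complete records remain")
  list(genotype = genotype[keep, , drop = FALSE],
       methylation = methylation[keep, , drop = FALSE],
       response = resp[keep],
       subject_ids = keep,
       removal_log = log)
}

phenotype_to_vector <- function(phenotype) {
  if (is.data.frame(phenotype)) {
    col <- intersect(c("responder", "response"), names(phenotype))[1]
    if (is.na(col)) stop("phenotype data frame needs a responder/response column")
    resp <- as.integer(phenotype[[col]])
    names(resp) <- as.character(phenotype$subject_id)
  } else {
    resp <- as.integer(phenotype)
    names(resp) <- names(phenotype)
  }
  if (is.null(names(resp))) stop("phenotype vector must be named by subject id")
  if (!all(is.na(resp) | resp %in% 0:1)) stop("response values must be 0/1")
  resp
}
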