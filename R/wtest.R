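#' Joint SNP-CpG category index
#'
#' Maps each subject's additive genotype code (0, 1, 2 minor alleles) and
#' binarized methylation state (low/high) to one of six joint categories.
#' The index is stable and zero-based, enumerated as
#' (0,low)=0, (0,high)=1, (1,low)=2, (1,high)=3, (2,low)=4, (2,high)=5.
#'
#' @param snp_coded integer vector with entries in \{0, 1, 2\}, no missing.
#' @param cpg_binary methylation state per subject: a factor/character vector
#'   with levels "low"/"high", a 0/1 numeric vector, or a logical vector
#'   (TRUE = high).
#' @return integer vector of category indices in 0..5.
#' @seealso [tabulate_cells()], [binarize_methylation()]
#' @export
build_pair_categories <- function(snp_coded, cpg_binary) {
  if (length(snp_coded) != length(cpg_binary)) {
    stop("snp_coded and cpg_binary have different lengths (",
         length(snp_coded), " vs ", length(cpg_binary), ")")
  }
  m <- cpg_to01(cpg_binary)
  g <- as.integer(snp_coded)
  if (anyNA(g) || anyNA(m)) stop("missing values are not allowed; apply complete_case_filter first")
  if (!all(g %in% 0:2)) stop("snp_coded entries must be in {0, 1, 2}")
  2L * g + m
}

# normalize the accepted methylation-state encodings to integer 0/1
cpg_to01 <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  if (is.character(x)) {
    out <- match(x, c("low", "high")) - 1L
    if (anyNA(out) && !anyNA(x)) stop('character cpg states must be "low"/"high"')
    return(out)
  }
  if (is.logical(x)) return(as.integer(x))
  x <- as.integer(x)
  if (!all(is.na(x) | x %in% 0:1)) stop("numeric cpg states must be 0/1")
  x
}

#' Tabulate per-category case/control counts for one SNP-CpG pair
#'
#' Builds the contingency table the W statistic is computed from. Categories
#' with zero count in both the case and control group are dropped, so the
#' number of retained categories `k` adapts to the data (at most 6). When any
#' retained category has a zero entry in its cell-vs-rest 2x2 collapse, a
#' Haldane-Anscombe 0.5 continuity correction is applied to that collapse at
#' statistic time and `correction_applied` is set.
#'
#' @param categories integer vector of category indices in 0..5, as produced
#'   by [build_pair_categories()].
#' @param phenotype binary 0/1 vector (1 = case); both classes must be present.
#' @return an object of class `contingency_table`: a list with elements
#'   `k`, `case_counts`, `control_counts`, `n1`, `n0`, `category_labels`
#'   (data frame with `snp_level`, `cpg_level`), and `correction_applied`.
#' @export
tabulate_cells <- function(categories, phenotype) {
  categories <- as.integer(categories)
  phenotype <- as.integer(phenotype)
  if (length(categories) != length(phenotype)) stop("categories and phenotype have different lengths")
  if (anyNA(categories) || anyNA(phenotype)) stop("missing values are not allowed")
  if (!all(categories %in% 0:5)) stop("category indices must be in 0..5")
  if (!all(phenotype %in% 0:1)) stop("phenotype must be binary 0/1")
  if (length(unique(phenotype)) < 2L) stop("phenotype has a single class; need both cases and controls")

  cnt <- tabulate(1L + categories + 6L * phenotype, nbins = 12L)
  n0i <- cnt[1:6]
  n1i <- cnt[7:12]
  keep <- (n0i + n1i) > 0L
  n1i <- n1i[keep]
  n0i <- n0i[keep]
  n1 <- sum(n1i)
  n0 <- sum(n0i)
  labels <- data.frame(
    snp_level = (0:5)[keep] %/% 2L,
    cpg_level = c("low", "high")[(0:5)[keep] %% 2L + 1L],
    stringsAsFactors = FALSE
  )
  zero_cell <- n1i == 0L | (n1 - n1i) == 0L | n0i == 0L | (n0 - n0i) == 0L
  structure(
    list(k = sum(keep), case_counts = n1i, control_counts = n0i,
         n1 = n1, n0 = n0, category_labels = labels,
         correction_applied = any(zero_cell)),
    class = "contingency_table"
  )
}

# Arithmetic core shared by raw_statistic() and the fast scan path.
# For category i the 2x2 collapse is (cell vs rest) x (case vs control):
#   a = n1i, b = n1 - n1i, c = n0i, d = n0 - n0i
# z_i = log[(a/b)/(c/d)] / SE_i,  SE_i = sqrt(1/a + 1/b + 1/c + 1/d)
# with 0.5 added to all four entries of a collapse containing a zero.
stat_from_counts <- function(n1i, n0i) {
  n1 <- sum(n1i)
  n0 <- sum(n0i)
  a <- n1i
  b <- n1 - n1i
  cc <- n0i
  d <- n0 - n0i
  z <- a == 0 | b == 0 | cc == 0 | d == 0
  if (any(z)) {
    a[z] <- a[z] + 0.5
    b[z] <- b[z] + 0.5
    cc[z] <- cc[z] + 0.5
    d[z] <- d[z] + 0.5
  }
  log_or <- log((a * d) / (b * cc))
  se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  z2 <- (log_or / se)^2
  list(S = sum(z2), log_or = log_or, se = se, z2 = z2)
}

# fast path used in bootstrap/permutation loops: category vector + phenotype
# -> raw S and retained-category count, skipping object construction
pair_stat <- function(categories, phenotype) {
  cnt <- tabulate(1L + categories + 6L * phenotype, nbins = 12L)
  n0i <- cnt[1:6]
  n1i <- cnt[7:12]
  keep <- (n0i + n1i) > 0L
  k <- sum(keep)
  if (k < 2L) return(list(S = NA_real_, k = k))
  list(S = stat_from_counts(n1i[keep], n0i[keep])$S, k = k)
}

#' Raw W-test sum statistic
#'
#' Computes the uncalibrated statistic S = sum over retained categories of
#' \eqn{[\log((\hat p_{1i}/(1-\hat p_{1i}))/(\hat p_{0i}/(1-\hat p_{0i}))) / SE_i]^2},
#' where \eqn{\hat p_{1i}} and \eqn{\hat p_{0i}} are the case and control
#' proportions in category i and \eqn{SE_i} is the standard error of the
#' per-category log odds ratio on the cell-vs-rest 2x2 collapse,
#' \eqn{\sqrt{1/n_{1i} + 1/(n_1 - n_{1i}) + 1/n_{0i} + 1/(n_0 - n_{0i})}}.
#' Collapses containing a zero receive the Haldane-Anscombe 0.5 correction.
#'
#' @param table a `contingency_table` from [tabulate_cells()].
#' @return list with `S` (raw statistic, >= 0) and `per_cell`, a data frame of
#'   per-category diagnostics (`snp_level`, `cpg_level`, `log_or`, `se`, `z2`).
#' @export
raw_statistic <- function(table) {
  if (!inherits(table, "contingency_table")) stop("table must be a contingency_table")
  if (table$k < 2L) stop("degenerate table: fewer than 2 retained categories")
  parts <- stat_from_counts(table$case_counts, table$control_counts)
  per_cell <- cbind(table$category_labels,
                    data.frame(log_or = parts$log_or, se = parts$se, z2 = parts$z2))
  list(S = parts$S, per_cell = per_cell)
}

#' Calibrated W-test p-value
#'
#' Scales a raw statistic S by the calibration constant h for its category
#' count k and refers W = h * S to a chi-squared distribution with the
#' calibrated degrees of freedom f, returning the upper-tail probability.
#' If k has no entry in the calibration table the pooled estimate is used.
#'
#' @param S raw statistic (non-negative).
#' @param calibration a `calibration_table` from [estimate_hf()].
#' @param k number of retained categories for this pair.
#' @return an object of class `w_result`: list with `S`, `W`, `h`, `f`, `k`
#'   and `p_value`.
#' @export
wtest_pvalue <- function(S, calibration, k) {
  if (!is.finite(S) || S < 0) stop("S must be a non-negative finite number")
  hf <- lookup_hf(calibration, k)
  W <- hf$h * S
  p <- stats::pchisq(W, df = hf$f, lower.tail = FALSE)
  structure(list(S = S, W = W, h = hf$h, f = hf$f, k = k, p_value = p),
            class = "w_result")
}

#' @export
print.w_result <- function(x, ...) {
  cat(sprintf("W-test: W = %.4f (h = %.4f, f = %.3f, k = %d), p = %.4g\n",
              x$W, x$h, x$f, x$k, x$p_value))
  invisible(x)
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("SNP-CpG contingency table: k = %d categories, %d cases / %d controls%s\n",
              x$k, x$n1, x$n0,
              if (x$correction_applied) " (continuity correction needed)" else ""))
  tab <- cbind(x$category_labels, cases = x$case_counts, controls = x$control_counts)
  print(tab, row.names = FALSE)
  invisible(x)
}
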