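#' Logistic-regression SNP x CpG interaction test
#'
#' The two regression comparators to the W-test. Both fit
#' `Y ~ SNP + CpG + SNP:CpG` by maximum likelihood with the SNP as a single
#' numeric additive term; LR-m1 enters the CpG as its binary two-mean label,
#' LR-m2 as the original continuous beta value. The interaction is tested by
#' a 1-df likelihood-ratio test of the full model against the model without
#' the interaction term. Non-convergence or (quasi-)complete separation is
#' reported via `converged = FALSE` with a missing p-value rather than a
#' spurious number.
#'
#' @param snp_coded additive genotype codes in \{0, 1, 2\}.
#' @param cpg_values binary mode: 0/1 or "low"/"high" labels; continuous
#'   mode: beta values.
#' @param phenotype binary 0/1 outcome, both classes present.
#' @param cpg_mode `"binary"` (LR-m1) or `"continuous"` (LR-m2).
#' @return object of class `lr_result`: list with `model_id`, `p_value`,
#'   `lrt_stat`, `df`, `converged`, `coefficients`.
#' @export
lr_interaction_test <- function(snp_coded, cpg_values, phenotype,
                                cpg_mode = c("binary", "continuous")) {
  cpg_mode <- match.arg(cpg_mode)
  g <- as.numeric(snp_coded)
  y <- as.integer(phenotype)
  m <- if (cpg_mode == "binary") as.numeric(cpg_to01(cpg_values)) else as.numeric(cpg_values)
  if (length(g) != length(y) || length(m) != length(y)) stop("predictor/outcome length mismatch")
  if (anyNA(g) || anyNA(m) || anyNA(y)) stop("missing values are not allowed")
  if (!all(y %in% 0:1) || length(unique(y)) < 2L) {
    stop("phenotype must be binary with both classes present")
  }
  if (stats::var(g) == 0 || stats::var(m) == 0) {
    stop("degenerate design: constant predictor")
  }
  X_full <- cbind(`(Intercept)` = 1, snp = g, cpg = m, `snp:cpg` = g * m)
  X_red <- X_full[, 1:3, drop = FALSE]
  fit_full <- suppressWarnings(stats::glm.fit(X_full, y, family = stats::binomial()))
  fit_red <- suppressWarnings(stats::glm.fit(X_red, y, family = stats::binomial()))

  eps <- 1e-8
  separated <- any(fit_full$fitted.values < eps | fit_full$fitted.values > 1 - eps)
  aliased <- anyNA(fit_full$coefficients)
  converged <- fit_full$converged && fit_red$converged && !separated && !aliased
  lrt <- max(0, fit_red$deviance - fit_full$deviance)
  structure(
    list(model_id = if (cpg_mode == "binary") "LR-m1" else "LR-m2",
         p_value = if (converged) stats::pchisq(lrt, df = 1, lower.tail = FALSE) else NA_real_,
         lrt_stat = lrt, df = 1L, converged = converged,
         coefficients = fit_full$coefficients),
    class = "lr_result"
  )
}

#' @export
print.lr_result <- function(x, ...) {
  cat(sprintf("%s interaction LRT: stat = %.4f (df = %d), p = %s%s\n",
              x$model_id, x$lrt_stat, x$df,
              if (is.na(x$p_value)) "NA" else sprintf("%.4g", x$p_value),
              if (x$converged) "" else " [did not converge]"))
  invisible(x)
}
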