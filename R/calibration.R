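#' Draw bootstrap null samples of the raw W statistic
#'
#' Approximates the null distribution of the raw statistic S on the working
#' data. Each replicate draws subjects with replacement, permutes the
#' phenotype within the draw (enforcing the null of no SNP-CpG association
#' with outcome), picks a random candidate SNP-CpG pair, and records the raw
#' statistic under the number of retained categories k it produced.
#'
#' @param genotype_coded subjects x SNPs integer matrix of additive codes
#'   \{0,1,2\} (see [encode_additive()]); column names identify SNPs.
#' @param methylation_binary subjects x CpGs matrix of 0/1 methylation states
#'   (see [binarize_methylation()]); column names identify CpGs.
#' @param phenotype binary 0/1 vector, one entry per subject row.
#' @param pairs candidate pair list: a two-column data frame or matrix of
#'   (snp, cpg) given as column indices or as column names.
#' @param B number of bootstrap replicates (default 400).
#' @param subsample_size size of each bootstrap draw; default `min(n, 1000)`.
#' @param seed integer seed; the whole draw is reproducible given it.
#' @return object of class `wtest_null_samples`: a list of numeric vectors of
#'   raw S values, named by k.
#' @export
bootstrap_null_samples <- function(genotype_coded, methylation_binary, phenotype,
                                   pairs, B = 400L, subsample_size = NULL,
                                   seed = NULL) {
  n <- nrow(genotype_coded)
  if (is.null(n) || n != nrow(methylation_binary) || n != length(phenotype)) {
    stop("genotype, methylation and phenotype must cover the same subjects")
  }
  if (B < 1L) stop("B must be at least 1")
  if (B < 100L) warning("B < 100 bootstrap replicates gives unstable (h, f) estimates")
  if (is.null(subsample_size)) subsample_size <- min(n, 1000L)
  if (subsample_size > n) stop("subsample_size exceeds the number of subjects")
  pairs <- resolve_pairs(pairs, colnames(genotype_coded), colnames(methylation_binary))
  if (nrow(pairs) == 0L) stop("no candidate pairs supplied")
  phenotype <- as.integer(phenotype)
  mbin <- cpg_matrix_to01(methylation_binary)

  with_seed(seed, {
    out_S <- numeric(B)
    out_k <- integer(B)
    for (b in seq_len(B)) {
      st <- list(S = NA_real_, k = 0L)
      for (try in 1:50) {
        idx <- sample.int(n, subsample_size, replace = TRUE)
        ph <- phenotype[idx][sample.int(subsample_size)]
        if (all(ph == ph[1L])) next
        pr <- pairs[sample.int(nrow(pairs), 1L), ]
        cat6 <- 2L * genotype_coded[idx, pr[[1L]]] + mbin[idx, pr[[2L]]]
        st <- pair_stat(cat6, ph)
        if (st$k >= 2L) break
      }
      if (st$k < 2L) stop("could not draw a non-degenerate bootstrap replicate")
      out_S[b] <- st$S
      out_k[b] <- st$k
    }
    grouped <- split(out_S, out_k)
    structure(grouped, class = "wtest_null_samples",
              B = B, subsample_size = subsample_size)
  })
}

#' Estimate the chi-squared calibration (h, f) by moment matching
#'
#' For each observed category count k, the scaling constant h and degrees of
#' freedom f are chosen so that h * S matches a chi-squared with f degrees of
#' freedom in mean and variance: with m and v the sample mean and variance of
#' the null raw statistics, h = 2m/v and f = 2m^2/v (so that E(hS) = f and
#' Var(hS) = 2f). Groups with fewer than `floor` samples fall back to the
#' pooled estimate over all samples, with a warning.
#'
#' @param null_samples a `wtest_null_samples` object, or a list of numeric
#'   vectors of raw statistics named by k.
#' @param floor minimum per-k sample count before pooling (default 50).
#' @return object of class `calibration_table`: a data frame with columns
#'   `k`, `h`, `f`, `m_boot`, `v_boot`, `n_samples`, `pooled`; the pooled
#'   estimate is kept in attribute `"pooled"` for unseen k.
#' @export
estimate_hf <- function(null_samples, floor = 50L) {
  if (!is.list(null_samples) || is.null(names(null_samples))) {
    stop("null_samples must be a list of numeric vectors named by k")
  }
  all_S <- unlist(null_samples, use.names = FALSE)
  if (length(all_S) < 2L) stop("need at least 2 null samples")
  m_all <- mean(all_S)
  v_all <- stats::var(all_S)
  if (v_all == 0) stop("degenerate null samples: zero variance")
  pooled <- list(h = 2 * m_all / v_all, f = 2 * m_all^2 / v_all,
                 m_boot = m_all, v_boot = v_all, n_samples = length(all_S))

  ks <- as.integer(names(null_samples))
  rows <- lapply(seq_along(ks), function(i) {
    s <- null_samples[[i]]
    if (length(s) < floor) {
      warning("k = ", ks[i], " has only ", length(s),
              " null samples (< ", floor, "); using pooled estimate")
      data.frame(k = ks[i], h = pooled$h, f = pooled$f, m_boot = pooled$m_boot,
                 v_boot = pooled$v_boot, n_samples = length(s), pooled = TRUE)
    } else {
      m <- mean(s)
      v <- stats::var(s)
      if (v == 0) stop("degenerate null samples for k = ", ks[i], ": zero variance")
      data.frame(k = ks[i], h = 2 * m / v, f = 2 * m^2 / v,
                 m_boot = m, v_boot = v, n_samples = length(s), pooled = FALSE)
    }
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$k), , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, class = c("calibration_table", "data.frame"), pooled = pooled)
}

# (h, f) for a given k, falling back to the pooled estimate
lookup_hf <- function(calibration, k) {
  if (!inherits(calibration, "calibration_table")) {
    stop("calibration must be a calibration_table from estimate_hf()")
  }
  i <- match(k, calibration$k)
  if (!is.na(i)) return(list(h = calibration$h[i], f = calibration$f[i]))
  pooled <- attr(calibration, "pooled")
  if (is.null(pooled)) stop("k = ", k, " not in calibration table and no pooled fallback")
  list(h = pooled$h, f = pooled$f)
}

#' Write / read a calibration table as TSV
#'
#' The pooled fallback is stored as an extra row with an empty `k`.
#'
#' @param calibration a `calibration_table`.
#' @param path output file path.
#' @return `write_calibration_table` returns `path` invisibly;
#'   `read_calibration_table` returns a `calibration_table`.
#' @export
write_calibration_table <- function(calibration, path) {
  pooled <- attr(calibration, "pooled")
  df <- as.data.frame(calibration)
  df$k <- as.character(df$k)
  df <- rbind(df, data.frame(k = "", h = pooled$h, f = pooled$f,
                             m_boot = pooled$m_boot, v_boot = pooled$v_boot,
                             n_samples = pooled$n_samples, pooled = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calibration_table
#' @export
read_calibration_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c(k = "character"), stringsAsFactors = FALSE)
  is_pooled_row <- df$k == ""
  pooled_row <- df[is_pooled_row, , drop = FALSE]
  df <- df[!is_pooled_row, , drop = FALSE]
  df$k <- as.integer(df$k)
  rownames(df) <- NULL
  pooled <- if (nrow(pooled_row)) {
    list(h = pooled_row$h[1], f = pooled_row$f[1], m_boot = pooled_row$m_boot[1],
         v_boot = pooled_row$v_boot[1], n_samples = pooled_row$n_samples[1])
  }
  structure(df, class = c("calibration_table", "data.frame"), pooled = pooled)
}

#' @export
print.calibration_table <- function(x, ...) {
  cat("W-test chi-squared calibration (h, f) by category count k\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  pooled <- attr(x, "pooled")
  if (!is.null(pooled)) {
    cat(sprintf("pooled fallback: h = %.4f, f = %.3f (n = %d)\n",
                pooled$h, pooled$f, pooled$n_samples))
  }
  invisible(x)
}

# resolve a 2-column pair spec (names or indices) to integer column indices
resolve_pairs <- function(pairs, snp_names, cpg_names) {
  pairs <- as.data.frame(pairs)
  if (ncol(pairs) < 2L) stop("pairs must have two columns (snp, cpg)")
  to_idx <- function(x, nm, what) {
    if (is.numeric(x)) return(as.integer(x))
    i <- match(as.character(x), nm)
    if (anyNA(i)) stop("unknown ", what, " id(s): ",
                       paste(unique(x[is.na(i)]), collapse = ", "))
    i
  }
  data.frame(snp = to_idx(pairs[[1L]], snp_names, "SNP"),
             cpg = to_idx(pairs[[2L]], cpg_names, "CpG"))
}

# accept a 0/1 matrix or a "low"/"high" character/factor matrix
cpg_matrix_to01 <- function(m) {
  if (is.numeric(m)) {
    storage.mode(m) <- "integer"
    return(m)
  }
  out <- matrix(cpg_to01(as.vector(m)), nrow(m), ncol(m), dimnames = dimnames(m))
  out
}
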