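#' Read a genotype table
#'
#' Reads a subjects x SNPs table of additive genotype codes. Two dialects are
#' supported: plain TSV (header row of SNP ids, first column subject id) and
#' PLINK `.raw` (whitespace-delimited with FID/IID/PAT/MAT/SEX/PHENOTYPE lead
#' columns followed by SNP dosage columns, whose `_ALLELE` suffixes are
#' stripped). Dosages are accepted as minor-allele counts as given; allele
#' polarization is left to [encode_additive()]. Missing-value codes are
#' configurable and mapped to `NA` (never to 0, which is a valid genotype).
#'
#' @param path input file.
#' @param dialect `"tsv"` or `"plink_raw"`.
#' @param missing_codes character vector of tokens read as missing; the
#'   default covers `NA` and PLINK's `-9` in dosage context.
#' @return integer matrix with subject ids as row names and SNP ids as column
#'   names; entries in \{0, 1, 2\} or `NA`.
#' @export
read_genotype_table <- function(path, dialect = c("tsv", "plink_raw"),
                                missing_codes = c("NA", "-9")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "tsv") {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            colClasses = "character", check.names = FALSE,
                            comment.char = "", na.strings = NULL)
    if (ncol(df) < 2L) stop("genotype TSV needs a subject-id column plus >= 1 SNP column")
    subjects <- df[[1L]]
    vals <- as.matrix(df[, -1L, drop = FALSE])
    colnames(vals) <- names(df)[-1L]  # keep duplicates visible to validation
  } else {
    df <- utils::read.table(path, header = TRUE, sep = "",
                            colClasses = "character", check.names = FALSE,
                            na.strings = NULL)
    lead <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (ncol(df) < 7L || !identical(toupper(names(df)[1:6]), lead)) {
      stop("plink_raw file must start with columns ", paste(lead, collapse = " "))
    }
    subjects <- df[["IID"]]
    vals <- as.matrix(df[, -(1:6), drop = FALSE])
    colnames(vals) <- sub("_[A-Za-z0-9]+$", "", colnames(vals))
  }
  if (nrow(vals) == 0L) stop("no subjects in genotype table: ", path)
  if (anyDuplicated(subjects)) stop("duplicate subject id(s): ",
                                    paste(unique(subjects[duplicated(subjects)]), collapse = ", "))
  if (anyDuplicated(colnames(vals))) stop("duplicate SNP id(s): ",
                                          paste(unique(colnames(vals)[duplicated(colnames(vals))]), collapse = ", "))
  vals[vals %in% missing_codes] <- NA_character_
  num <- suppressWarnings(array(as.numeric(vals), dim(vals)))
  bad <- !is.na(vals) & (is.na(num) | !(num %in% c(0, 1, 2)))
  if (any(bad)) {
    ij <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("invalid genotype value %s at row %d (subject %s), column %s: must be 0, 1, 2 or missing",
                 vals[bad][1L], ij[1L], subjects[ij[1L]], colnames(vals)[ij[2L]]))
  }
  out <- array(as.integer(num), dim(vals),
               dimnames = list(subjects, colnames(vals)))
  out
}

#' Read a methylation beta-value table
#'
#' TSV with a header row of CpG ids and subject ids in the first column.
#' Values are validated into \[0, 1\]; missing entries (`NA`) are allowed.
#'
#' @param path input file.
#' @param missing_codes tokens read as missing.
#' @return numeric matrix, subjects x CpGs.
#' @export
read_methylation_table <- function(path, missing_codes = "NA") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          comment.char = "", na.strings = NULL)
  if (ncol(df) < 2L) stop("methylation TSV needs a subject-id column plus >= 1 CpG column")
  if (nrow(df) == 0L) stop("no subjects in methylation table: ", path)
  subjects <- df[[1L]]
  vals <- as.matrix(df[, -1L, drop = FALSE])
  colnames(vals) <- names(df)[-1L]  # keep duplicates visible to validation
  if (anyDuplicated(subjects)) stop("duplicate subject id(s)")
  if (anyDuplicated(colnames(vals))) stop("duplicate CpG id(s): ",
                                          paste(unique(colnames(vals)[duplicated(colnames(vals))]), collapse = ", "))
  vals[vals %in% missing_codes] <- NA_character_
  num <- suppressWarnings(array(as.numeric(vals), dim(vals)))
  bad <- !is.na(vals) & (is.na(num) | num < 0 | num > 1)
  if (any(bad)) {
    ij <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("invalid beta value %s at row %d (subject %s), column %s: must lie in [0, 1]",
                 vals[bad][1L], ij[1L], subjects[ij[1L]], colnames(vals)[ij[2L]]))
  }
  array(num, dim(vals), dimnames = list(subjects, colnames(vals)))
}

#' Read a marker map
#'
#' Tab-delimited table of marker id, chromosome label and 1-based base-pair
#' position (columns named `id`/`marker_id`, `chromosome`/`chr`,
#' `position`/`pos`, or the first three columns in that order).
#'
#' @param path input file.
#' @param kind `"SNP"` or `"CpG"`.
#' @return data frame with `marker_id`, `marker_kind`, `chromosome`,
#'   `position`.
#' @export
read_marker_map <- function(path, kind = c("SNP", "CpG")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          comment.char = "", na.strings = NULL)
  pick <- function(cands, fallback) {
    hit <- intersect(cands, names(df))
    if (length(hit)) df[[hit[1L]]] else df[[fallback]]
  }
  if (ncol(df) < 3L) stop("marker map needs columns (id, chromosome, position)")
  ids <- pick(c("id", "marker_id"), 1L)
  chrom <- pick(c("chromosome", "chr"), 2L)
  pos_raw <- pick(c("position", "pos"), 3L)
  pos <- suppressWarnings(as.integer(pos_raw))
  if (anyNA(pos) || any(pos < 1L)) {
    bad <- which(is.na(pos) | pos < 1L)[1L]
    stop(sprintf("invalid position %s for marker %s: positions are 1-based integers >= 1",
                 pos_raw[bad], ids[bad]))
  }
  if (anyDuplicated(ids)) stop("duplicate marker id(s): ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  data.frame(marker_id = ids, marker_kind = kind, chromosome = chrom,
             position = pos, stringsAsFactors = FALSE)
}

#' Read a phenotype table
#'
#' TSV with a `subject_id` column plus either the four triglyceride visit
#' columns (`tg_visit1`..`tg_visit4`; `tg1`..`tg4` accepted) or a binary
#' `response` column. Each subject must carry one of the two.
#'
#' @param path input file.
#' @return data frame with `subject_id`, `tg_visit1`..`tg_visit4` (NA where
#'   absent) and `response` (NA where absent).
#' @export
read_phenotype_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, comment.char = "",
                          stringsAsFactors = FALSE)
  id_col <- intersect(c("subject_id", "id"), names(df))
  subject_id <- as.character(if (length(id_col)) df[[id_col[1L]]] else df[[1L]])
  if (anyDuplicated(subject_id)) stop("duplicate subject id(s)")
  out <- data.frame(subject_id = subject_id, stringsAsFactors = FALSE)
  for (v in 1:4) {
    col <- intersect(c(paste0("tg_visit", v), paste0("tg", v)), names(df))
    out[[paste0("tg_visit", v)]] <- if (length(col)) as.numeric(df[[col[1L]]]) else NA_real_
  }
  out$response <- if ("response" %in% names(df)) df$response else NA_integer_
  tg <- as.matrix(out[paste0("tg_visit", 1:4)])
  if (any(tg <= 0, na.rm = TRUE)) {
    stop("TG values must be positive (mg/dL); found ", min(tg, na.rm = TRUE))
  }
  if (!all(is.na(out$response) | out$response %in% 0:1)) stop("response values must be 0/1")
  has_tg <- stats::complete.cases(out[paste0("tg_visit", 1:4)])
  orphan <- !has_tg & is.na(out$response)
  if (any(orphan)) {
    stop("subject(s) without four TG visits or a response value: ",
         paste(utils::head(subject_id[orphan], 5), collapse = ", "))
  }
  out
}

#' Write ranked pair results as TSV
#'
#' Writes one row per tested SNP-CpG pair, sorted by W-test p-value ascending
#' with ties broken lexicographically by (snp_id, cpg_id), and a `rank`
#' column. Columns: rank, snp_id, cpg_id, distance_bp, snp_maf, k, W,
#' p_value, lr_m1_p, lr_m2_p.
#'
#' @param results data frame of pair results (e.g. `genome_scan()$results`);
#'   an empty data frame yields a header-only file.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  cols <- c("snp_id", "cpg_id", "distance_bp", "snp_maf", "k", "W",
            "p_value", "lr_m1_p", "lr_m2_p")
  df <- as.data.frame(results)
  for (col in cols) if (is.null(df[[col]])) df[[col]] <- if (nrow(df)) NA else logical(0)
  df <- df[cols]
  if (nrow(df)) {
    df <- df[order(df$p_value, df$snp_id, df$cpg_id), , drop = FALSE]
  }
  df <- cbind(rank = seq_len(nrow(df)), df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a numeric matrix as a subjects-x-markers TSV
#'
#' Inverse of [read_genotype_table()]/[read_methylation_table()] for the TSV
#' dialect: subject ids in the first column, marker ids in the header.
#'
#' @param m matrix with subject row names and marker column names.
#' @param path output file.
#' @param id_col header name for the subject-id column.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path, id_col = "subject_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
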