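write_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

test_that("genotype TSV round-trips and maps missing codes", {
  df <- data.frame(subject_id = c("s1", "s2", "s3"),
                   rs1 = c(0L, 1L, 2L), rs2 = c(2L, 0L, 1L))
  g <- read_genotype_table(write_tsv(df))
  expect_identical(dim(g), c(3L, 2L))
  expect_identical(unname(g[, "rs1"]), c(0L, 1L, 2L))
  expect_identical(rownames(g), c("s1", "s2", "s3"))

  df$rs2[1] <- "NA"
  g <- read_genotype_table(write_tsv(df))
  expect_true(is.na(g["s1", "rs2"]))
  expect_false(anyNA(g[, "rs1"]))
})

test_that("genotype validation rejects out-of-range entries, naming the cell", {
  df <- data.frame(subject_id = c("s1", "s2"), rs1 = c(0L, 3L))
  expect_error(read_genotype_table(write_tsv(df)), "row 2.*rs1")
  df2 <- data.frame(subject_id = c("s1", "s1"), rs1 = c(0L, 1L))
  expect_error(read_genotype_table(write_tsv(df2)), "duplicate subject")
})

test_that("plink_raw dialect parses lead columns, allele suffixes and -9", {
  lines <- c("FID IID PAT MAT SEX PHENOTYPE rs1_A rs2_T",
             "f1 s1 0 0 1 2 0 2",
             "f2 s2 0 0 2 1 -9 1")
  path <- tempfile(fileext = ".raw")
  writeLines(lines, path)
  g <- read_genotype_table(path, dialect = "plink_raw")
  expect_identical(colnames(g), c("rs1", "rs2"))
  expect_identical(rownames(g), c("s1", "s2"))
  expect_true(is.na(g["s2", "rs1"]))
  expect_identical(unname(g[, "rs2"]), c(2L, 1L))
})

test_that("methylation table enforces [0,1] and structure", {
  df <- data.frame(subject_id = c("s1", "s2"), cg1 = c(0.1, 0.5), cg2 = c(0.9, 0.4))
  m <- read_methylation_table(write_tsv(df))
  expect_equal(unname(m), cbind(c(0.1, 0.5), c(0.9, 0.4)))

  df$cg1[2] <- -0.1
  expect_error(read_methylation_table(write_tsv(df)), "\\[0, 1\\]")
  df$cg1[2] <- 1.2
  expect_error(read_methylation_table(write_tsv(df)), "\\[0, 1\\]")

  hdr_only <- tempfile()
  writeLines("subject_id\tcg1", hdr_only)
  expect_error(read_methylation_table(hdr_only), "no subjects")

  dup <- tempfile()
  writeLines(c("subject_id\tcg1\tcg1", "s1\t0.1\t0.2"), dup)
  expect_error(read_methylation_table(dup), "duplicate CpG")
})

test_that("marker map validates positions and ids", {
  df <- data.frame(id = "rs1", chromosome = "11", position = 5000L)
  map <- read_marker_map(write_tsv(df), kind = "SNP")
  expect_identical(map$position, 5000L)
  expect_identical(map$marker_kind, "SNP")

  df$position <- 0L
  expect_error(read_marker_map(write_tsv(df), "SNP"), "1-based")

  df2 <- data.frame(id = c("rs1", "rs1"), chromosome = "11", position = c(1L, 2L))
  expect_error(read_marker_map(write_tsv(df2), "SNP"), "duplicate marker")
})

test_that("phenotype table accepts TG visits or a binary response", {
  df <- data.frame(subject_id = "s1", tg_visit1 = 200, tg_visit2 = 220,
                   tg_visit3 = 120, tg_visit4 = 140)
  ph <- read_phenotype_table(write_tsv(df))
  expect_equal(ph$tg_visit4, 140)
  expect_true(is.na(ph$response))

  df2 <- data.frame(subject_id = "s1", response = 1L)
  ph2 <- read_phenotype_table(write_tsv(df2))
  expect_identical(ph2$response, 1L)

  df$tg_visit2 <- -5
  expect_error(read_phenotype_table(write_tsv(df)), "positive")
  df3 <- data.frame(subject_id = "s1", response = 2L)
  expect_error(read_phenotype_table(write_tsv(df3)), "0/1")
})

test_that("write_results ranks by p-value with lexicographic tie-break", {
  res <- data.frame(snp_id = c("rs2", "rs1", "rs3"), cpg_id = c("cg2", "cg1", "cg0"),
                    distance_bp = c(10L, 20L, 30L), snp_maf = 0.2, k = 6L,
                    W = c(1, 2, 3), p_value = c(1e-3, 1e-5, 1e-3),
                    lr_m1_p = NA_real_, lr_m2_p = NA_real_)
  path <- tempfile(fileext = ".tsv")
  write_results(res, path)
  out <- utils::read.table(path, header = TRUE, sep = "\t")
  expect_identical(out$rank, 1:3)
  expect_identical(out$snp_id, c("rs1", "rs2", "rs3"))  # tie at 1e-3: rs2 < rs3

  write_results(res[0, ], path)
  out0 <- utils::read.table(path, header = TRUE, sep = "\t")
  expect_identical(nrow(out0), 0L)
  expect_true(all(c("rank", "snp_id", "p_value") %in% names(out0)))
})

test_that("matrix write/read round-trip preserves values and ids", {
  set.seed(42)
  m <- matrix(round(runif(12), 6), 3, 4,
              dimnames = list(paste0("s", 1:3), paste0("cg", 1:4)))
  path <- tempfile(fileext = ".tsv")
  write_matrix_tsv(m, path)
  back <- read_methylation_table(path)
  expect_equal(back, m)

  g <- matrix(sample(0:2, 12, replace = TRUE), 3, 4,
              dimnames = list(paste0("s", 1:3), paste0("rs", 1:4)))
  write_matrix_tsv(g, path)
  expect_identical(read_genotype_table(path), g)
})
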