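test_that("additive coding polarizes to the dataset minor allele", {
  e <- encode_additive(c(0L, 0L, 1L, 2L))
  expect_identical(e$coded, c(0L, 0L, 1L, 2L))
  expect_equal(e$maf, 0.375)
  expect_false(e$flipped)

  e2 <- encode_additive(c(2L, 2L, 1L, 2L))
  expect_identical(e2$coded, c(0L, 0L, 1L, 0L))
  expect_equal(e2$maf, 0.125)
  expect_true(e2$flipped)

  e3 <- encode_additive(c(0L, 0L, 0L, 0L))
  expect_equal(e3$maf, 0)
  expect_true(e3$monomorphic)
  expect_identical(e3$coded, c(0L, 0L, 0L, 0L))

  expect_error(encode_additive(c(NA, NA)), "missing")
  expect_error(encode_additive(c(0L, 3L)), "\\{0, 1, 2\\}")
})

test_that("flipping is an involution and maf never exceeds 0.5", {
  set.seed(11)
  for (i in 1:50) {
    g <- sample(c(0:2, NA), 40, replace = TRUE, prob = c(0.1, 0.2, 0.6, 0.1))
    if (all(is.na(g))) next
    e <- encode_additive(g)
    expect_lte(e$maf, 0.5)
    # re-encoding an already-polarized vector changes nothing
    e2 <- encode_additive(e$coded)
    expect_identical(e2$coded, e$coded)
    # missing entries are preserved in place
    expect_identical(is.na(e$coded), is.na(g))
  }
})

test_that("two-mean binarization matches the hand-checkable examples", {
  b <- binarize_methylation(c(0.1, 0.2, 0.8, 0.9))
  expect_identical(as.character(b$labels), c("low", "low", "high", "high"))
  expect_equal(b$center_low, 0.15)
  expect_equal(b$center_high, 0.85)

  b2 <- binarize_methylation(c(0.1, 0.1, 0.9))
  expect_identical(as.character(b2$labels), c("low", "low", "high"))
  expect_equal(c(b2$center_low, b2$center_high), c(0.1, 0.9))

  expect_error(binarize_methylation(c(0.5, 0.5, 0.5)), "constant CpG")
  expect_error(binarize_methylation(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("binarization minimizes within-cluster sum of squares over thresholds", {
  wcss <- function(x, high) {
    sum((x[!high] - mean(x[!high]))^2) + sum((x[high] - mean(x[high]))^2)
  }
  set.seed(7)
  for (i in 1:60) {
    n <- sample(3:12, 1)
    x <- round(runif(n), 3)
    if (length(unique(x)) < 2) next
    b <- binarize_methylation(x)
    got <- wcss(x, b$labels == "high")
    # exhaustive scan over all threshold partitions of the sorted values
    xs <- sort(unique(x))
    best <- min(vapply(xs[-length(xs)], function(t) wcss(x, x > t), numeric(1)))
    expect_equal(got, best, tolerance = 1e-12)
  }
})

test_that("drug response follows the fractional TG decrease with a strict 30% cut", {
  ph <- data.frame(subject_id = c("a", "b", "c"),
                   tg_visit1 = c(200, 100, 100), tg_visit2 = c(220, 100, 100),
                   tg_visit3 = c(120, 70, 120), tg_visit4 = c(140, 70, 120))
  r <- define_drug_response(ph)
  expect_equal(r$tg_pre, c(210, 100, 100))
  expect_equal(r$tg_post, c(130, 70, 120))
  expect_equal(r$delta_pct, c(80 / 210, 0.30, -0.20))
  # 0.38 -> responder; exactly 0.30 -> not (strict inequality); increase -> not
  expect_identical(r$responder, c(1L, 0L, 0L))

  expect_error(define_drug_response(transform(ph, tg_visit1 = -1)), "positive")
})

test_that("responder status is invariant under common rescaling of TG", {
  set.seed(3)
  ph <- data.frame(subject_id = paste0("s", 1:40),
                   tg_visit1 = runif(40, 80, 300), tg_visit2 = runif(40, 80, 300),
                   tg_visit3 = runif(40, 40, 300), tg_visit4 = runif(40, 40, 300))
  base <- define_drug_response(ph)$responder
  for (scale in c(0.01, 7, 1000)) {
    ph2 <- ph
    ph2[-1] <- ph2[-1] * scale
    expect_identical(define_drug_response(ph2)$responder, base)
  }
})

test_that("precomputed response passes through unchanged", {
  ph <- data.frame(subject_id = c("a", "b"), response = c(1L, 0L))
  r <- define_drug_response(ph)
  expect_identical(r$responder, c(1L, 0L))
  expect_true(all(is.na(r$delta_pct)))
  expect_error(define_drug_response(data.frame(subject_id = "a", response = 2)), "0/1")
})

test_that("complete-case filter aligns by id and logs removals", {
  g <- matrix(c(0L, 1L, 2L, NA, 1L, 0L, 1L, 2L, 0L, 1L), 5, 2,
              dimnames = list(paste0("s", 1:5), c("rs1", "rs2")))
  m <- matrix(runif(10), 5, 2, dimnames = list(paste0("s", 1:5), c("cg1", "cg2")))
  ph <- data.frame(subject_id = paste0("s", 1:5), responder = c(1L, 0L, 1L, 0L, 1L))
  out <- complete_case_filter(g, m, ph)
  expect_identical(out$subject_ids, c("s1", "s2", "s3", "s5"))  # s4 has NA genotype
  expect_identical(unname(out$removal_log["missing_genotype"]), 1L)
  expect_identical(names(out$response), out$subject_ids)

  # disjoint subject sets
  rownames(m) <- paste0("x", 1:5)
  expect_error(complete_case_filter(g, m, ph), "no subjects shared")
})

test_that("downstream statistics are invariant to input row order", {
  set.seed(21)
  ids <- paste0("s", 1:60)
  g <- matrix(sample(0:2, 120, replace = TRUE), 60, 2,
              dimnames = list(ids, c("rs1", "rs2")))
  m <- matrix(runif(120), 60, 2, dimnames = list(ids, c("cg1", "cg2")))
  ph <- data.frame(subject_id = ids, responder = rep(c(0L, 1L), 30))
  stat_of <- function(g, m, ph) {
    co <- complete_case_filter(g, m, ph)
    cat6 <- build_pair_categories(encode_additive(co$genotype[, 1])$coded,
                                  binarize_methylation(co$methylation[, 1])$labels)
    raw_statistic(tabulate_cells(cat6, co$response))$S
  }
  base <- stat_of(g, m, ph)
  perm <- sample(60)
  expect_equal(stat_of(g[perm, ], m[rev(perm), ], ph[sample(60), ]), base)
})
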