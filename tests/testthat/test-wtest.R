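test_that("category indices follow the fixed (snp, cpg) enumeration", {
  expect_identical(build_pair_categories(c(0L, 1L, 2L), c("low", "high", "low")),
                   c(0L, 3L, 4L))
  expect_identical(build_pair_categories(rep(0L, 4), rep("low", 4)), rep(0L, 4))
  expect_identical(build_pair_categories(c(2L, 0L), c(1, 0)), c(5L, 0L))
  expect_error(build_pair_categories(0L, c("low", "high")), "length")
  expect_error(build_pair_categories(c(0L, NA), c("low", "low")), "missing")
})

test_that("tabulation drops doubly-empty categories and flags zero cells", {
  tab <- tabulate_cells(c(0L, 0L, 3L, 3L), c(1L, 0L, 1L, 0L))
  expect_identical(tab$k, 2L)
  expect_identical(tab$case_counts, c(1L, 1L))
  expect_identical(tab$control_counts, c(1L, 1L))
  expect_identical(tab$n1, 2L)
  expect_identical(tab$n0, 2L)
  expect_identical(tab$category_labels$snp_level, c(0L, 1L))

  # category 5 absent in both groups is not retained
  tab2 <- tabulate_cells(c(0L, 1L, 2L, 3L, 4L, 0L), c(1L, 0L, 1L, 0L, 1L, 0L))
  expect_identical(tab2$k, 5L)

  # a cell with cases but no controls needs the continuity correction
  tab3 <- tabulate_cells(c(0L, 0L, 0L, 1L, 1L, 1L), c(1L, 1L, 1L, 0L, 0L, 0L))
  expect_true(tab3$correction_applied)
  expect_false(tab$correction_applied)

  expect_error(tabulate_cells(c(0L, 1L), c(1L, 1L)), "single class")
})

test_that("raw statistic matches direct arithmetic on the balanced 2x2 example", {
  # n1 = n0 = 100, case counts (60, 40) vs control (40, 60):
  # per-cell log OR = +-log(2.25), SE = sqrt(1/12), so S = 24 * log(2.25)^2
  cat6 <- rep(c(0L, 1L), times = c(100, 100))
  ph <- c(rep(1L, 60), rep(0L, 40), rep(1L, 40), rep(0L, 60))
  tab <- tabulate_cells(cat6, ph)
  rs <- raw_statistic(tab)
  expect_equal(rs$S, 24 * log(2.25)^2, tolerance = 1e-12)
  expect_equal(rs$S, 15.78259, tolerance = 1e-4)
  expect_equal(rs$per_cell$log_or, c(log(2.25), -log(2.25)), tolerance = 1e-12)
  expect_equal(rs$per_cell$se, rep(sqrt(1 / 12), 2), tolerance = 1e-12)
  expect_equal(rs$S, oracle_w_raw(tab$case_counts, tab$control_counts))
})

test_that("identical case/control distributions give S = 0", {
  cat6 <- rep(0:5, times = 4)
  ph <- rep(c(1L, 0L), each = 12)
  rs <- raw_statistic(tabulate_cells(cat6, ph))
  expect_equal(rs$S, 0)
  expect_equal(rs$per_cell$log_or, rep(0, 6))
})

test_that("raw statistic equals the independent cell-by-cell oracle", {
  set.seed(101)
  for (i in 1:400) {
    kk <- sample(2:6, 1L)
    tb <- random_table(kk, nmax = 30L)
    tab <- structure(list(k = kk, case_counts = tb$case_counts,
                          control_counts = tb$control_counts,
                          n1 = sum(tb$case_counts), n0 = sum(tb$control_counts),
                          category_labels = data.frame(snp_level = seq_len(kk) - 1L,
                                                       cpg_level = "low"),
                          correction_applied = NA),
                     class = "contingency_table")
    expect_equal(raw_statistic(tab)$S,
                 oracle_w_raw(tb$case_counts, tb$control_counts),
                 tolerance = 1e-10)
  }
  # zero-cell tables exercise the continuity correction path
  expect_equal(raw_statistic(tabulate_cells(c(0L, 0L, 1L, 1L, 2L),
                                            c(1L, 1L, 0L, 0L, 1L)))$S,
               oracle_w_raw(c(2L, 0L, 1L), c(0L, 2L, 0L)), tolerance = 1e-12)
})

test_that("S is invariant under case/control label swap", {
  set.seed(5)
  for (i in 1:30) {
    cat6 <- sample(0:5, 50, replace = TRUE)
    ph <- sample(0:1, 50, replace = TRUE)
    if (length(unique(ph)) < 2) next
    s1 <- raw_statistic(tabulate_cells(cat6, ph))$S
    s2 <- raw_statistic(tabulate_cells(cat6, 1L - ph))$S
    expect_equal(s1, s2, tolerance = 1e-12)
  }
})

test_that("concentrating case mass into a cell does not decrease S (interior regime)", {
  # margins fixed at n1 = n0 = 40, k = 2; moving cases away from the even
  # split enlarges |log OR| in both collapses. Monotonicity of S holds while
  # the shrinking margin cell keeps >= 2 subjects; at the boundary the SE
  # term overtakes the log OR and S turns over, so the scan stops at 38.
  s_of <- function(c1) {
    tab <- structure(list(k = 2L, case_counts = c(c1, 40L - c1),
                          control_counts = c(20L, 20L), n1 = 40L, n0 = 40L,
                          category_labels = data.frame(snp_level = 0:1,
                                                       cpg_level = "low"),
                          correction_applied = FALSE),
                     class = "contingency_table")
    raw_statistic(tab)$S
  }
  s_seq <- vapply(20:38, s_of, numeric(1))
  expect_true(all(diff(s_seq) >= -1e-12))
})

test_that("degenerate single-category tables are rejected", {
  tab <- tabulate_cells(rep(3L, 10), rep(c(0L, 1L), 5))
  expect_identical(tab$k, 1L)
  expect_error(raw_statistic(tab), "degenerate")
})
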