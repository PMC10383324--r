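test_that("contrasts are log2 ratios of group means", {
  mat <- make_abundance(list(
    CTRL = matrix(c(10, 10, 8, 10, 10, 12), nrow = 3),
    CASE = matrix(c(20, 10, 30, 20, 10, 10), nrow = 3)))
  ct <- compute_contrast(mat, "CASE")
  expect_equal(unname(ct$logfc[1]), 1)            # 20 vs 10
  expect_equal(unname(ct$logfc[2]), 0)            # identical means
  expect_equal(unname(ct$logfc[3]), 1)            # mean{30,10}=20 vs mean{8,12}=10
  expect_error(compute_contrast(mat, "NOPE"), "unknown group")
  expect_error(compute_contrast(mat, "CTRL"), "control")
})

test_that("proteins with under two usable replicates are flagged missing", {
  vals <- rbind(P1 = c(10, 10, 20, 20), P2 = c(10, NA, 20, 20))
  colnames(vals) <- c("CTRL_1", "CTRL_2", "CASE_1", "CASE_2")
  mat <- abundance_matrix(vals, c(CTRL_1 = "CTRL", CTRL_2 = "CTRL",
                                  CASE_1 = "CASE", CASE_2 = "CASE"), "CTRL")
  ct <- compute_contrast(mat, "CASE")
  expect_true(is.na(ct$logfc["P2"]))
  expect_false(is.na(ct$logfc["P1"]))
  expect_equal(valid_proteins(ct), "P1")
})

test_that("swapping case and control negates the contrast exactly", {
  set.seed(1)
  vals <- list(G1 = matrix(2 ^ rnorm(40, 10), nrow = 10),
               G2 = matrix(2 ^ rnorm(40, 10), nrow = 10))
  m12 <- make_abundance(vals, control = "G1")
  m21 <- make_abundance(vals, control = "G2")
  expect_equal(compute_contrast(m12, "G2")$logfc,
               -compute_contrast(m21, "G1")$logfc)
})

test_that("the 1.5-fold filter uses a strict inequality on the ratio", {
  ratios <- c(2.0, 1.6, 1.5, 1.4, 1.0, 1 / 1.4, 1 / 1.5, 1 / 1.6, 1 / 2.0)
  lfc <- c(log2(ratios), NA)
  names(lfc) <- sprintf("P%02d", 1:10)
  ct <- fake_contrast(lfc)
  sel <- fold_change_filter(ct, 1.5)
  expect_setequal(sel$members, c("P01", "P02", "P08", "P09"))
  expect_equal(length(sel$members), 4)            # boundary 1.5 not selected
  expect_true(fold_change_filter(fake_contrast(c(A = log2(1.6))))$members == "A")
  expect_true(fold_change_filter(fake_contrast(c(A = -log2(1.6))))$members == "A")
  expect_error(fold_change_filter(ct, 1), "> 1")
})

test_that("selection counts shrink monotonically as the fold threshold grows", {
  set.seed(2)
  ct <- fake_contrast(stats::setNames(rnorm(100, 0, 1),
                                      sprintf("P%03d", 1:100)))
  folds <- c(1.2, 1.5, 2, 3, 5)
  counts <- vapply(folds, function(f) {
    length(fold_change_filter(ct, f)$members)
  }, 1L)
  expect_true(all(diff(counts) <= 0))
})

test_that("expression clustering merges near rows first and is order-invariant", {
  lfc_a <- c(P1 = 1, P2 = 1, P3 = -5)
  lfc_b <- c(P1 = 1, P2 = 1.1, P3 = -5)
  cl <- cluster_expression(list(fake_contrast(lfc_a, case = "c1"),
                                fake_contrast(lfc_b, case = "c2")))
  # the two near rows merge before the far one
  expect_setequal(-cl$hclust$merge[1, ], 1:2)

  # identical rows merge at distance zero
  cl0 <- cluster_expression(list(
    fake_contrast(c(P1 = 1, P2 = 1, P3 = 4), case = "c1"),
    fake_contrast(c(P1 = 2, P2 = 2, P3 = 0), case = "c2")))
  expect_equal(cl0$hclust$height[1], 0)

  # leaf order invariant under input permutation
  set.seed(3)
  lfc1 <- stats::setNames(rnorm(20), sprintf("P%02d", 1:20))
  lfc2 <- stats::setNames(rnorm(20), sprintf("P%02d", 1:20))
  perm <- sample(20)
  c_fwd <- cluster_expression(list(fake_contrast(lfc1, case = "c1"),
                                   fake_contrast(lfc2, case = "c2")))
  c_perm <- cluster_expression(list(fake_contrast(lfc1[perm], case = "c1"),
                                    fake_contrast(lfc2[perm], case = "c2")))
  expect_identical(c_fwd$order, c_perm$order)
  expect_identical(c_fwd$order,
                   cluster_expression(list(fake_contrast(lfc1, case = "c1"),
                                           fake_contrast(lfc2, case = "c2")))$order)
})

test_that("set comparison returns exact Venn partition counts", {
  s1 <- differential_set("X", c("A", "B"))
  s2 <- differential_set("Y", c("B", "C"))
  out <- compare_sets(list(s1, s2))
  counts <- stats::setNames(out$count, out$region)
  expect_equal(unname(counts[c("X&Y", "X", "Y")]), c(1, 1, 1))
  expect_equal(sum(out$count), 3)                 # |union|

  disj <- compare_sets(list(differential_set("X", c("A", "B")),
                            differential_set("Y", c("C"))))
  expect_equal(disj$count[disj$region == "X&Y"], 0L)

  same <- compare_sets(list(differential_set("X", c("A", "B")),
                            differential_set("Y", c("A", "B"))))
  expect_equal(same$count[same$region == "X&Y"], 2L)
  expect_equal(sum(same$count), 2)
})
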