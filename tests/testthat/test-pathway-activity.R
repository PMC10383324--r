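test_that("the signed activity sum weights repressors by -1", {
  ct <- fake_contrast(c(A = 1, B = 2, C = 0.5, D = 0, E = 0))
  pw <- signed_pathway("pw1", "toy", c("A", "B", "C"), c(1, 1, -1))
  expect_equal(pathway_score(pw, ct)$activity, 2.5)   # 1 + 2 - 0.5

  pw0 <- signed_pathway("pw0", "flat", c("D", "E"))
  expect_equal(pathway_score(pw0, ct)$activity, 0)

  ct_neg <- fake_contrast(-ct$logfc)
  expect_equal(pathway_score(pw, ct_neg)$activity, -2.5)

  # members without a valid logfc are skipped but counted
  ct_na <- fake_contrast(c(A = 1, B = NA, C = 0.5))
  sc <- pathway_score(pw, ct_na)
  expect_equal(sc$activity, 0.5)
  expect_equal(sc$n_members_used, 2)
  expect_equal(sc$n_members, 3)

  # zero usable members -> undefined
  ct_none <- fake_contrast(c(X = 1))
  expect_true(is.na(pathway_score(pw, ct_none)$activity))
})

test_that("pathway activity is linear in the contrast and in member signs", {
  set.seed(7)
  ids <- sprintf("P%02d", 1:8)
  l1 <- stats::setNames(rnorm(8), ids)
  l2 <- stats::setNames(rnorm(8), ids)
  pw <- signed_pathway("pw", "x", ids[1:5], c(1, 1, -1, 1, -1))
  s1 <- pathway_score(pw, fake_contrast(l1))$activity
  s2 <- pathway_score(pw, fake_contrast(l2))$activity
  s12 <- pathway_score(pw, fake_contrast(l1 + l2))$activity
  expect_equal(s12, s1 + s2)

  # toggling one member's role changes the score by exactly -2 * its logfc
  pw_flip <- signed_pathway("pw", "x", ids[1:5], c(1, 1, -1, -1, -1))
  expect_equal(pathway_score(pw_flip, fake_contrast(l1))$activity,
               s1 - 2 * l1[[ids[4]]])

  # signed logfc summing to zero scores exactly zero
  lz <- stats::setNames(c(1, 2, 3, 4, 2, 0, 0, 0), ids)
  pwz <- signed_pathway("pwz", "z", ids[1:5], c(1, 1, 1, -1, -1))
  expect_equal(pathway_score(pwz, fake_contrast(lz))$activity, 0)
})

test_that("singleton exhaustive null matches direct enumeration", {
  lfc <- c(P1 = 0, P2 = 0, P3 = 0, P4 = 0, P5 = 5)
  ct <- fake_contrast(lfc)
  pw <- signed_pathway("pw", "one", "P5")
  res <- pathway_significance(pw, ct, exhaustive = TRUE)
  # 5 singleton draws, only {P5} is as extreme as the observed activity
  expect_equal(res$empirical_p, 1 / 5)
  expect_equal(res$n_perm, 5)
  expect_equal(res$observed, 5)
})

test_that("a pathway spanning the whole background is never significant", {
  lfc <- c(A = 0.3, B = -0.2, C = 1, D = 0.1)
  ct <- fake_contrast(lfc)
  pw <- signed_pathway("pw", "all", names(lfc))
  res <- pathway_significance(pw, ct, n_perm = 200, seed = 3)
  expect_true(all(res$null == res$observed))
  expect_equal(res$empirical_p, 1)
})

test_that("sampled pathway p agrees with the exhaustive oracle, signs carried", {
  set.seed(8)
  ids <- sprintf("P%02d", 1:10)
  lfc <- stats::setNames(rnorm(10), ids)
  ct <- fake_contrast(lfc)
  pw <- signed_pathway("pw", "mix", ids[1:3], c(1, -1, 1))

  # independent oracle: enumerate subsets x distinct sign placements
  subs <- combn(ids, 3, simplify = FALSE)
  null_oracle <- unlist(lapply(subs, function(s) {
    vapply(1:3, function(neg_at) {
      signs <- c(1, 1, 1); signs[neg_at] <- -1
      sum(signs * lfc[s])
    }, numeric(1))
  }))
  obs <- pathway_score(pw, ct)$activity
  p_oracle <- naive_two_sided_p(obs, null_oracle, exhaustive = TRUE)

  res_ex <- pathway_significance(pw, ct, exhaustive = TRUE)
  expect_equal(res_ex$empirical_p, p_oracle)
  expect_equal(sort(res_ex$null), sort(null_oracle))

  res_s <- pathway_significance(pw, ct, n_perm = 5000, seed = 99)
  mc_se <- sqrt(p_oracle * (1 - p_oracle) / 5000)
  expect_lt(abs(res_s$empirical_p - p_oracle), 3 * mc_se + 1 / 5000)

  res_s2 <- pathway_significance(pw, ct, n_perm = 5000, seed = 99)
  expect_identical(res_s$empirical_p, res_s2$empirical_p)
})

test_that("score_all_pathways yields one stable row per pathway x contrast", {
  set.seed(9)
  ids <- sprintf("P%02d", 1:30)
  cts <- list(
    c1 = fake_contrast(stats::setNames(rnorm(30), ids), case = "c1"),
    c2 = fake_contrast(stats::setNames(rnorm(30), ids), case = "c2"))
  pws <- lapply(1:3, function(i) {
    signed_pathway(sprintf("pw%d", i), "x", sample(ids, 5), c(1, 1, 1, -1, 1))
  })
  tab <- score_all_pathways(pws, cts, n_perm = 99, seed = 4)
  expect_equal(nrow(tab), 6)
  expect_equal(tab$pathway_id, rep(c("pw1", "pw2", "pw3"), each = 2))
  tab2 <- score_all_pathways(pws, cts, n_perm = 99, seed = 4)
  expect_identical(tab, tab2)
})
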