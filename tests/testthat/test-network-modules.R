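test_that("ego-modules are the seed plus measured direct interactors", {
  star <- named_graph(c("H", "A", "H", "B", "H", "C"))
  m <- build_module(star, "H", c("H", "A", "B", "C"))
  expect_setequal(m$members, c("H", "A", "B", "C"))

  lone <- named_graph(c("X", "Y"), isolated = "Z")
  m1 <- build_module(lone, "Z", c("X", "Y", "Z"))
  expect_equal(m1$members, "Z")
  expect_equal(m1$size, 1)

  path <- named_graph(c("A", "B", "B", "C"))
  m2 <- build_module(path, "B", c("A", "B"))
  expect_setequal(m2$members, c("A", "B"))

  expect_error(build_module(path, "Q", c("A", "B")), "not in the network")
  expect_error(build_module(path, "C", c("A", "B")), "background")
})

test_that("module statistics are the arithmetic mean and sample SD", {
  ct <- fake_contrast(c(A = 1, B = 3, C = 5, D = -1, E = 0, F = 1))
  expect_equal(module_stats(c("A", "B"), ct), c(mean = 2, sd = sqrt(2)))
  expect_equal(module_stats("C", ct), c(mean = 5, sd = 0))
  expect_equal(module_stats(c("D", "E", "F"), ct), c(mean = 0, sd = 1))
  ct$logfc[["B"]] <- NA
  expect_error(module_stats(c("A", "B"), ct), "without a valid logfc")
})

test_that("the exhaustive null enumerates all same-size subsets", {
  ct <- fake_contrast(c(A = 1, B = 2, C = 3))
  null <- random_module_null(ct, c("A", "B", "C"), 2, exhaustive = TRUE)
  expect_setequal(round(null$mean, 10), c(1.5, 2.0, 2.5))
  expect_equal(null$n_perm, 3)

  # background size equal to module size: every draw is the full background
  n1 <- random_module_null(ct, c("A", "B", "C"), 3, n_perm = 50, seed = 1)
  expect_true(all(n1$mean == 2))
  expect_equal(stats::sd(n1$mean), 0)

  n2 <- random_module_null(ct, c("A", "B", "C"), 2, n_perm = 100, seed = 9)
  n3 <- random_module_null(ct, c("A", "B", "C"), 2, n_perm = 100, seed = 9)
  expect_identical(n2, n3)
  expect_error(random_module_null(ct, c("A", "B"), 3), "exceeds")
})

test_that("empirical p-values follow the add-one and exhaustive conventions", {
  null <- list(mean = c(-1, 0, 1, 2), sd = c(1, 1, 1, 1), n_perm = 4,
               exhaustive = FALSE, seed = 1)
  # observed at the null centre: every draw is as extreme, p = 1
  sig <- module_significance(c(mean = 0.5, sd = 1), null)
  expect_equal(sig$mean$empirical_p, 1)

  # observed beyond every one of 999 draws: p = 1/1000
  null999 <- list(mean = rnorm(999), sd = abs(rnorm(999)), n_perm = 999,
                  exhaustive = FALSE, seed = 1)
  sig999 <- module_significance(c(mean = 99, sd = 99), null999)
  expect_equal(sig999$mean$empirical_p, 1 / 1000)
  expect_equal(sig999$sd$empirical_p, 1 / 1000)
})

test_that("exhaustive module p matches a brute-force enumeration oracle", {
  lfc <- c(P1 = 0, P2 = 0.1, P3 = -0.1, P4 = 2)
  ct <- fake_contrast(lfc)
  bg <- names(lfc)
  module <- c("P4", "P1")
  obs <- module_stats(module, ct)

  # independent oracle: enumerate all C(4,2) subsets directly
  combos <- combn(bg, 2, simplify = FALSE)
  null_means <- vapply(combos, function(s) mean(lfc[s]), numeric(1))
  p_oracle <- naive_two_sided_p(obs[["mean"]], null_means, exhaustive = TRUE)

  null <- random_module_null(ct, bg, 2, exhaustive = TRUE)
  sig <- module_significance(obs, null)
  expect_equal(sig$mean$empirical_p, p_oracle)
  # hand count: null means {0.05,-0.05,0,1,1.05,0.95}, centre 0.5, observed
  # deviation 0.5 is matched or exceeded by 4 of 6 subsets
  expect_equal(p_oracle, 4 / 6)
})

test_that("sampled p-values agree with exhaustive enumeration within MC error", {
  set.seed(4)
  lfc <- stats::setNames(rnorm(10), sprintf("P%02d", 1:10))
  ct <- fake_contrast(lfc)
  bg <- names(lfc)
  for (size in 2:4) {
    module <- bg[1:size]
    obs <- module_stats(module, ct)
    p_ex <- module_significance(obs,
      random_module_null(ct, bg, size, exhaustive = TRUE))$mean$empirical_p
    p_s <- module_significance(obs,
      random_module_null(ct, bg, size, n_perm = 5000, seed = 77))$mean$empirical_p
    mc_se <- sqrt(p_ex * (1 - p_ex) / 5000)
    expect_lt(abs(p_s - p_ex), 3 * mc_se + 1 / 5000)
  }
})

test_that("module-mean p is invariant to shifting all logfc by a constant", {
  set.seed(5)
  lfc <- stats::setNames(rnorm(30), sprintf("P%02d", 1:30))
  ct <- fake_contrast(lfc)
  ct_shift <- fake_contrast(lfc + 7)
  bg <- names(lfc)
  module <- bg[1:5]
  p1 <- module_significance(module_stats(module, ct),
    random_module_null(ct, bg, 5, n_perm = 500, seed = 3))$mean$empirical_p
  p2 <- module_significance(module_stats(module, ct_shift),
    random_module_null(ct_shift, bg, 5, n_perm = 500, seed = 3))$mean$empirical_p
  expect_equal(p1, p2)
})

test_that("module correlation recovers exact linear relations", {
  ids <- sprintf("P%02d", 1:12)
  set.seed(6)
  a <- stats::setNames(rnorm(12), ids)
  ct_a <- fake_contrast(a, case = "c1")
  module <- ids[1:4]

  r_same <- module_correlation(module, ct_a, ct_a, n_perm = 99, seed = 1)
  expect_equal(r_same$observed, 1)

  ct_neg <- fake_contrast(-a, case = "c2")
  expect_equal(module_correlation(module, ct_a, ct_neg, n_perm = 99,
                                  seed = 1)$observed, -1)

  ct_lin <- fake_contrast(2 * a, case = "c3")
  expect_equal(module_correlation(module, ct_a, ct_lin, n_perm = 99,
                                  seed = 1)$observed, 1)

  # undefined below size 3 or at zero variance
  small <- module_correlation(ids[1:2], ct_a, ct_lin, n_perm = 9, seed = 1)
  expect_true(is.na(small$observed))
  flat <- fake_contrast(stats::setNames(rep(1, 12), ids), case = "c4")
  expect_true(is.na(module_correlation(module, ct_a, flat, n_perm = 9,
                                       seed = 1)$observed))
})

test_that("network-wide selection is calibrated, deterministic and honours alpha", {
  scen <- simulation_scenario(n_proteins = 120, seed = 21)
  g <- generate_network(scen)
  mat <- generate_abundances(g, scen)
  cts <- list(UCCAO = compute_contrast(mat, "UCCAO"))
  res <- select_de_proteins(g, cts, alpha = 0.05, n_perm = 199, seed = 5,
                            pairs = FALSE)
  expect_equal(nrow(res$per_seed), length(valid_proteins(cts$UCCAO)))
  expect_true(all(res$per_seed$p_mean > 0 & res$per_seed$p_mean <= 1))

  res2 <- select_de_proteins(g, cts, alpha = 0.05, n_perm = 199, seed = 5,
                             pairs = FALSE)
  expect_identical(res$per_seed, res2$per_seed)

  res0 <- select_de_proteins(g, cts, alpha = 0, n_perm = 49, seed = 5,
                             pairs = FALSE)
  expect_length(res0$sets$UCCAO$members, 0)
})

test_that("measured proteins absent from the network are reported untestable", {
  g <- named_graph(c("P1", "P2", "P2", "P3"))
  lfc <- c(P1 = 0.1, P2 = -0.2, P3 = 0.3, P9 = 1.5)
  res <- select_de_proteins(g, list(C = fake_contrast(lfc)), n_perm = 19,
                            seed = 1, pairs = FALSE)
  expect_equal(res$untestable$C, "P9")
  expect_false("P9" %in% res$per_seed$seed_protein)
})

test_that("the ego-module null mode falls back gracefully and stays calibrated", {
  scen <- simulation_scenario(n_proteins = 150, mean_degree = 6, seed = 31)
  g <- generate_network(scen)
  mat <- generate_abundances(g, scen)
  cts <- list(UCCAO = compute_contrast(mat, "UCCAO"))
  res <- select_de_proteins(g, cts, n_perm = 99, seed = 2, null = "ego",
                            pairs = FALSE)
  expect_true(all(res$per_seed$p_mean > 0 & res$per_seed$p_mean <= 1))
  res2 <- select_de_proteins(g, cts, n_perm = 99, seed = 2, null = "ego",
                             pairs = FALSE)
  expect_identical(res$per_seed, res2$per_seed)
})

test_that("seed ranking orders by p with deviation tie-breaks", {
  tab <- data.frame(contrast = "C", seed_protein = c("A", "B", "D"),
                    p_mean = c(0.01, 0.01, 0.5),
                    module_mean = c(1, 3, 0.2), null_mean = c(0, 0, 0.1),
                    null_sd = c(0.5, 0.5, 0.5))
  ranked <- rank_module_seeds(tab)
  expect_equal(ranked$seed_protein, c("B", "A", "D"))
})
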