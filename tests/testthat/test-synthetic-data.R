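test_that("network generation hits the complete-graph limit and is reproducible", {
  scen <- simulation_scenario(n_proteins = 4, mean_degree = 3, seed = 11)
  g <- generate_network(scen)
  expect_equal(igraph::ecount(g), 6)            # K4
  expect_equal(igraph::V(g)$name, sprintf("P%06d", 1:4))

  scen2 <- simulation_scenario(n_proteins = 200, mean_degree = 6, seed = 1)
  e1 <- igraph::as_edgelist(generate_network(scen2))
  e2 <- igraph::as_edgelist(generate_network(scen2))
  expect_identical(e1, e2)

  g2 <- generate_network(scen2)
  mean_deg <- mean(igraph::degree(g2))
  expect_gt(mean_deg, 6 * 0.8)
  expect_lt(mean_deg, 6 * 1.2)
  expect_equal(sum(igraph::which_loop(g2)), 0)
  expect_true(igraph::is_simple(g2))
})

test_that("degenerate network parameters are rejected", {
  expect_error(simulation_scenario(mean_degree = 0), "mean_degree")
  expect_error(simulation_scenario(n_proteins = 10, mean_degree = 10),
               "mean_degree")
  expect_error(simulation_scenario(planted_modules = list(
    list(seed_protein = "P000001", group = "NOPE", delta = 1))),
    "group")
})

test_that("null abundances carry no group effect", {
  scen <- simulation_scenario(n_proteins = 200, seed = 3)
  g <- generate_network(scen)
  mat <- generate_abundances(g, scen)
  expect_true(all(mat$values > 0))
  for (grp in c("UCCAO", "UCCAO_MF")) {
    lfc <- compute_contrast(mat, grp)$logfc
    se <- stats::sd(lfc) / sqrt(length(lfc))
    expect_lt(abs(mean(lfc)), 4 * se)
  }
})

test_that("a planted module shifts the seed and its neighbours by delta", {
  delta <- 1.0
  scen <- simulation_scenario(
    n_proteins = 100, seed = 5,
    planted_modules = list(list(seed_protein = "P000010", group = "UCCAO",
                                delta = delta)))
  g <- generate_network(scen)
  mat <- generate_abundances(g, scen)
  members <- c("P000010", igraph::neighbors(g, "P000010")$name)
  lfc <- compute_contrast(mat, "UCCAO")$logfc
  tol <- 3 * scen$noise_sd / sqrt(scen$n_replicates_per_group)
  expect_lt(abs(mean(lfc[members]) - delta), tol)
  # other proteins and the other treated group stay unshifted
  others <- setdiff(names(lfc), members)
  expect_lt(abs(mean(lfc[others])), tol)
  lfc_mf <- compute_contrast(mat, "UCCAO_MF")$logfc
  expect_lt(abs(mean(lfc_mf[members])), tol + 3 * scen$noise_sd / sqrt(10))
})

test_that("zero replicate noise collapses replicates within a group", {
  scen <- simulation_scenario(n_proteins = 10, noise_sd = 0, seed = 2)
  g <- generate_network(scen)
  mat <- generate_abundances(g, scen)
  for (grp in scen$groups) {
    sub <- mat$values[, mat$sample_groups == grp, drop = FALSE]
    expect_true(all(abs(sub - sub[, 1L]) < 1e-9))
  }
})

test_that("pathway generation realizes the repressor fraction and is deterministic", {
  scen <- simulation_scenario(n_proteins = 50, n_pathways = 8,
                              pathway_size_range = c(10, 10),
                              repressor_fraction = 0.3, seed = 4)
  g <- generate_network(scen)
  pws <- generate_pathways(g, scen)
  expect_length(pws, 8)
  for (pw in pws) {
    expect_length(pw$members, 10)
    expect_equal(sum(pw$signs < 0), 3)          # round(10 * 0.3)
    expect_false(anyDuplicated(pw$members) > 0)
  }
  scen0 <- simulation_scenario(n_proteins = 50, repressor_fraction = 0,
                               pathway_size_range = c(5, 8), seed = 4)
  for (pw in generate_pathways(g, scen0)) expect_true(all(pw$signs == 1))
  pws2 <- generate_pathways(g, scen)
  expect_identical(lapply(pws, `[[`, "members"),
                   lapply(pws2, `[[`, "members"))
  expect_error(generate_pathways(
    g, simulation_scenario(n_proteins = 50, pathway_size_range = c(60, 60))),
    "exceeds")
})

test_that("perfect alternators score 100% downstream", {
  bs <- behavior_scenario(alternation_prob = 1, n_animals_per_group = 4,
                          seed = 9)
  beh <- generate_behavior(bs)
  alt <- vapply(beh$arm_entries$entries, spontaneous_alternation, numeric(1))
  expect_true(all(alt == 100))
})

test_that("mean recognition index matches the configured novelty preference", {
  bs <- behavior_scenario(novelty_preference = 0.5,
                          n_animals_per_group = 300, seed = 10)
  beh <- generate_behavior(bs)
  ex <- beh$exploration
  ri <- ex$time_novel / (ex$time_novel + ex$time_familiar)
  expect_lt(abs(mean(ri) - 0.5), 0.02)
})

test_that("the exploration-time scale controls the exclusion rate", {
  # mean total time chosen so P(total < 5 s) = 0.2 under the exponential
  scale <- 5 / -log(0.8)
  bs <- behavior_scenario(exploration_time_scale = scale,
                          n_animals_per_group = 500, seed = 12)
  beh <- generate_behavior(bs)
  ex <- beh$exploration
  excl <- recognition_index(ex$time_novel, ex$time_familiar)$excluded
  expect_lt(abs(mean(excl) - 0.2), 0.04)
})

test_that("behaviour generation is bit-reproducible under a fixed seed", {
  bs <- behavior_scenario(seed = 42)
  b1 <- generate_behavior(bs)
  b2 <- generate_behavior(bs)
  expect_identical(b1, b2)
})

test_that("alternation converges to the generator's analytic expectation", {
  p <- 0.6
  bs <- behavior_scenario(alternation_prob = p, n_animals_per_group = 80,
                          n_entries = 30, seed = 13)
  beh <- generate_behavior(bs)
  alt <- vapply(beh$arm_entries$entries, spontaneous_alternation, numeric(1))
  expected <- expected_alternation_rate(p, 30)
  se <- stats::sd(alt) / sqrt(length(alt))
  expect_lt(abs(mean(alt) - expected), 3 * se)
  expect_equal(expected_alternation_rate(1, 10), 100)
  expect_equal(expected_alternation_rate(0, 10), 0)
})
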