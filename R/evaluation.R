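# Calibration and planted-effect recovery runs on synthetic data: the
# package's own evidence that the permutation machinery is calibrated under
# the null and powerful against the effects it is meant to detect.

#' Null calibration of the ego-module permutation test
#'
#' Simulates no-effect datasets under the default three-group design,
#' runs the full network selection for every treated-vs-control contrast
#' and pools the module-mean empirical p-values.
#'
#' @param n_sims independent simulated datasets.
#' @param n_proteins proteins per dataset.
#' @param n_perm permutations per module.
#' @param alpha nominal level for the rejection-fraction summary.
#' @param seed run seed.
#' @return list with the pooled `p` vector, `fraction` of p < alpha,
#'   `ks_distance` from the uniform distribution and `n` (pooled cells).
#' @export
module_null_calibration <- function(n_sims = 5, n_proteins = 200,
                                    n_perm = 999, alpha = 0.05, seed = 1) {
  p <- unlist(lapply(seq_len(n_sims), function(i) {
    scen <- simulation_scenario(n_proteins = n_proteins,
                                seed = derive_seed(seed, paste0("calib", i)))
    g <- generate_network(scen)
    mat <- generate_abundances(g, scen)
    cases <- setdiff(scen$groups, scen$groups[1L])
    cts <- lapply(cases, function(grp) compute_contrast(mat, grp))
    names(cts) <- cases
    res <- select_de_proteins(g, cts, alpha = alpha, n_perm = n_perm,
                              seed = derive_seed(seed, paste0("sel", i)),
                              pairs = FALSE)
    res$per_seed$p_mean
  }))
  list(p = p, fraction = mean(p < alpha),
       ks_distance = .ks_uniform(p), n = length(p))
}

#' Null calibration of the pathway-activity permutation test
#'
#' One no-effect dataset scored over many pathways and all treated
#' contrasts; under the null the empirical p-values should be approximately
#' uniform.
#'
#' @param n_pathways pathways to generate and score.
#' @param n_proteins proteins in the dataset.
#' @param n_perm permutations per pathway x contrast cell.
#' @param alpha nominal level for the rejection-fraction summary.
#' @param seed run seed.
#' @return list with `p`, `fraction` of p < alpha, `ks_distance`, `n`.
#' @export
pathway_null_calibration <- function(n_pathways = 1000, n_proteins = 200,
                                     n_perm = 999, alpha = 0.05, seed = 1) {
  scen <- simulation_scenario(n_proteins = n_proteins,
                              n_pathways = n_pathways,
                              seed = derive_seed(seed, "pwcalib"))
  g <- generate_network(scen)
  pws <- generate_pathways(g, scen)
  mat <- generate_abundances(g, scen)
  cases <- setdiff(scen$groups, scen$groups[1L])
  cts <- lapply(cases, function(grp) compute_contrast(mat, grp))
  names(cts) <- cases
  tab <- score_all_pathways(pws, cts, n_perm = n_perm,
                            seed = derive_seed(seed, "pwscore"))
  p <- tab$p[!is.na(tab$p)]
  list(p = p, fraction = mean(p < alpha),
       ks_distance = .ks_uniform(p), n = length(p))
}

.ks_uniform <- function(p) {
  n <- length(p)
  s <- sort(p)
  max(abs(s - (seq_len(n) - 1) / n), abs(s - seq_len(n) / n))
}

#' Planted ego-module recovery rate
#'
#' For each replicate, one ego-module (a random seed protein plus its
#' neighbours) is shifted by `delta_factor * noise_sd` on the log2 scale in
#' the lesion group; the replicate scores a success when that seed protein
#' is the top-ranked seed by module-mean empirical p (ties broken by the
#' standardized deviation from the null).
#'
#' @param n_reps simulation replicates.
#' @param n_proteins proteins per dataset.
#' @param delta_factor planted shift in units of the replicate noise SD.
#' @param n_perm permutations per module.
#' @param seed run seed.
#' @return list with `rate`, logical `hits`, `n`.
#' @export
module_recovery_rate <- function(n_reps = 100, n_proteins = 200,
                                 delta_factor = 3, n_perm = 999, seed = 1) {
  hits <- vapply(seq_len(n_reps), function(i) {
    scen0 <- simulation_scenario(n_proteins = n_proteins,
                                 seed = derive_seed(seed, paste0("rec", i)))
    g <- generate_network(scen0)
    set.seed(derive_seed(seed, paste0("pick", i)))
    planted <- sample(igraph::V(g)$name, 1L)
    scen <- simulation_scenario(
      n_proteins = n_proteins,
      planted_modules = list(list(seed_protein = planted, group = "UCCAO",
                                  delta = delta_factor * scen0$noise_sd)),
      seed = derive_seed(seed, paste0("rec", i)))
    mat <- generate_abundances(g, scen)
    cts <- list(UCCAO = compute_contrast(mat, "UCCAO"))
    res <- select_de_proteins(g, cts, n_perm = n_perm,
                              seed = derive_seed(seed, paste0("sel", i)),
                              pairs = FALSE)
    ranked <- rank_module_seeds(res$per_seed, "UCCAO")
    ranked$seed_protein[1L] == planted
  }, logical(1))
  list(rate = mean(hits), hits = hits, n = n_reps)
}

#' Planted pathway-shift recovery rate
#'
#' Each replicate generates equal-sized pathways, shifts every member of
#' one pathway by its role sign times `shift` in the lesion group, and
#' scores a success when that pathway attains the largest absolute
#' activity under the lesion contrast.
#'
#' @param n_reps simulation replicates.
#' @param n_proteins proteins per dataset.
#' @param n_pathways pathways per dataset (all the same size).
#' @param pathway_size common pathway size.
#' @param shift per-member planted log2 shift.
#' @param seed run seed.
#' @return list with `rate`, logical `hits`, `n`.
#' @export
pathway_recovery_rate <- function(n_reps = 100, n_proteins = 200,
                                  n_pathways = 20, pathway_size = 12,
                                  shift = 1, seed = 1) {
  hits <- vapply(seq_len(n_reps), function(i) {
    scen <- simulation_scenario(
      n_proteins = n_proteins, n_pathways = n_pathways,
      pathway_size_range = c(pathway_size, pathway_size),
      planted_pathways = list(list(pathway_id = "pw001", group = "UCCAO",
                                   shift = shift)),
      seed = derive_seed(seed, paste0("pwrec", i)))
    g <- generate_network(scen)
    pws <- generate_pathways(g, scen)
    mat <- generate_abundances(g, scen, pws)
    ct <- compute_contrast(mat, "UCCAO")
    act <- vapply(pws, function(pw) pathway_score(pw, ct)$activity,
                  numeric(1))
    ids <- vapply(pws, `[[`, "", "pathway_id")
    ids[which.max(abs(act))] == "pw001"
  }, logical(1))
  list(rate = mean(hits), hits = hits, n = n_reps)
}
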