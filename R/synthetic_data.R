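# Synthetic-data generator emulating the three-group chronic-hypoperfusion
# study design (control, lesion, lesion + treatment; n = 10 animals per
# group): an Erdos-Renyi interaction network, log-normal protein abundances
# with planted differential ego-modules and pathway shifts, signed pathway
# definitions, and behavioural sessions with tunable alternation and
# novelty-preference rates.

.default_groups <- c("SHAM", "UCCAO", "UCCAO_MF")

#' Proteomics simulation scenario
#'
#' Defines every parameter of the synthetic proteomics inputs. Defaults
#' emulate the study design the pipeline targets: three groups (control
#' first) with 10 replicates each, log-normal abundances on the log2 scale,
#' and an Erdos-Renyi interaction network.
#'
#' @param n_proteins number of proteins (network nodes).
#' @param mean_degree expected edges per node; the network is G(n, p) with
#'   p = mean_degree / (n - 1).
#' @param groups ordered group labels, control first.
#' @param n_replicates_per_group replicates (samples) per group, >= 2.
#' @param baseline_log_mean,baseline_log_sd per-protein baseline
#'   log2-abundance distribution.
#' @param noise_sd replicate noise SD on the log2 scale (label-free
#'   replicate variation; >= 0, 0 only for exact-limit checks).
#' @param planted_modules list of planted differential ego-modules, each a
#'   list with `seed_protein`, `group`, `delta` (log2 shift applied to the
#'   seed and all its direct neighbours in that group).
#' @param planted_pathways list of planted pathway shifts, each a list with
#'   `pathway_id`, `group`, `shift` (per-member log2 shift, applied with
#'   the member's role sign) and optional `repressor_fraction` overriding
#'   the scenario default for that pathway.
#' @param n_pathways,pathway_size_range,repressor_fraction pathway
#'   generation parameters.
#' @param seed RNG seed; sub-streams are derived per operation.
#' @return object of class `simulation_scenario`.
#' @export
simulation_scenario <- function(n_proteins = 200,
                                mean_degree = 6,
                                groups = .default_groups,
                                n_replicates_per_group = 10,
                                baseline_log_mean = 20,
                                baseline_log_sd = 2,
                                noise_sd = 0.3,
                                planted_modules = list(),
                                planted_pathways = list(),
                                n_pathways = 25,
                                pathway_size_range = c(8, 25),
                                repressor_fraction = 0.2,
                                seed = 1) {
  stopifnot(n_proteins >= 3, length(groups) >= 2,
            n_replicates_per_group >= 2, noise_sd >= 0,
            length(pathway_size_range) == 2,
            repressor_fraction >= 0, repressor_fraction <= 1)
  if (mean_degree <= 0)
    stop("mean_degree must be > 0", call. = FALSE)
  if (mean_degree >= n_proteins)
    stop("mean_degree must be < n_proteins", call. = FALSE)
  for (pm in planted_modules) {
    stopifnot(all(c("seed_protein", "group", "delta") %in% names(pm)))
    if (!is.finite(pm$delta)) stop("planted delta must be finite", call. = FALSE)
    if (!pm$group %in% groups)
      stop("planted module group '", pm$group, "' not a scenario group",
           call. = FALSE)
  }
  for (pp in planted_pathways) {
    stopifnot(all(c("pathway_id", "group", "shift") %in% names(pp)))
    if (!pp$group %in% groups)
      stop("planted pathway group '", pp$group, "' not a scenario group",
           call. = FALSE)
  }
  structure(
    list(n_proteins = n_proteins, mean_degree = mean_degree,
         groups = groups, n_replicates_per_group = n_replicates_per_group,
         baseline_log_mean = baseline_log_mean,
         baseline_log_sd = baseline_log_sd, noise_sd = noise_sd,
         planted_modules = planted_modules,
         planted_pathways = planted_pathways,
         n_pathways = n_pathways,
         pathway_size_range = as.integer(pathway_size_range),
         repressor_fraction = repressor_fraction,
         seed = as.integer(seed)),
    class = "simulation_scenario"
  )
}

#' Generate a synthetic protein-interaction network
#'
#' Erdos-Renyi G(n, p) with p = mean_degree / (n - 1): a simple undirected
#' graph with nodes "P000001", ... Deterministic for a fixed scenario seed.
#'
#' @param scenario a [simulation_scenario()].
#' @return an igraph undirected simple graph.
#' @export
generate_network <- function(scenario) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  n <- scenario$n_proteins
  p <- min(scenario$mean_degree / (n - 1), 1)
  set.seed(derive_seed(scenario$seed, "network"))
  g <- igraph::sample_gnp(n, p, directed = FALSE, loops = FALSE)
  igraph::V(g)$name <- sprintf("P%06d", seq_len(n))
  g
}

#' Generate a synthetic abundance matrix
#'
#' log2 abundance = protein baseline + group shift + replicate noise, with
#' abundance = 2^(log2 abundance) > 0. A planted module shifts the seed
#' protein and all its direct network neighbours by `delta` in the stated
#' group only; a planted pathway shifts each member by `sign * shift` in
#' its stated group. The control group never carries shifts.
#'
#' @param network igraph network from [generate_network()].
#' @param scenario a [simulation_scenario()].
#' @param pathways pathways from [generate_pathways()]; required when the
#'   scenario plants pathway shifts.
#' @return an [abundance_matrix()].
#' @export
generate_abundances <- function(network, scenario, pathways = NULL) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  ids <- igraph::V(network)$name
  n <- length(ids)
  groups <- scenario$groups
  reps <- scenario$n_replicates_per_group

  shift <- matrix(0, n, length(groups), dimnames = list(ids, groups))
  for (pm in scenario$planted_modules) {
    if (!pm$seed_protein %in% ids)
      stop("planted module seed '", pm$seed_protein,
           "' is not a network node", call. = FALSE)
    members <- c(pm$seed_protein,
                 igraph::neighbors(network, pm$seed_protein)$name)
    shift[members, pm$group] <- shift[members, pm$group] + pm$delta
  }
  if (length(scenario$planted_pathways)) {
    if (is.null(pathways))
      stop("scenario plants pathway shifts: pass `pathways`", call. = FALSE)
    idx <- stats::setNames(seq_along(pathways),
                           vapply(pathways, `[[`, "", "pathway_id"))
    for (pp in scenario$planted_pathways) {
      if (!pp$pathway_id %in% names(idx))
        stop("planted pathway '", pp$pathway_id, "' not generated",
             call. = FALSE)
      pw <- pathways[[idx[[pp$pathway_id]]]]
      shift[pw$members, pp$group] <-
        shift[pw$members, pp$group] + pw$signs * pp$shift
    }
  }
  if (any(shift[, groups[1L]] != 0))
    stop("control group must carry no planted shifts", call. = FALSE)

  set.seed(derive_seed(scenario$seed, "baseline"))
  baseline <- stats::rnorm(n, scenario$baseline_log_mean,
                           scenario$baseline_log_sd)
  set.seed(derive_seed(scenario$seed, "noise"))
  sample_ids <- as.vector(vapply(
    groups, function(g) paste0(g, "_", seq_len(reps)), character(reps)))
  sample_groups <- stats::setNames(rep(groups, each = reps), sample_ids)
  noise <- matrix(stats::rnorm(n * length(sample_ids), 0, scenario$noise_sd),
                  n, length(sample_ids))
  log2_ab <- baseline + shift[, sample_groups, drop = FALSE] + noise
  dimnames(log2_ab) <- list(ids, sample_ids)
  abundance_matrix(2 ^ log2_ab, sample_groups, groups[1L])
}

# round-half-up, used for repressor counts
.round_half_up <- function(x) floor(x + 0.5)

#' Generate signed pathway definitions
#'
#' Member sets are drawn uniformly from the network's proteins (pathways
#' may overlap); each pathway gets `round(size * repressor_fraction)`
#' repressor members (half rounded up). Deterministic for a fixed seed.
#'
#' @param network igraph network.
#' @param scenario a [simulation_scenario()].
#' @return list of [signed_pathway()] objects with ids `"pw001"`, ...
#' @export
generate_pathways <- function(network, scenario) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  ids <- igraph::V(network)$name
  rng <- scenario$pathway_size_range
  if (max(rng) > length(ids))
    stop("pathway size ", max(rng), " exceeds n_proteins", call. = FALSE)
  frac_override <- list()
  for (pp in scenario$planted_pathways) {
    if (!is.null(pp$repressor_fraction))
      frac_override[[pp$pathway_id]] <- pp$repressor_fraction
  }
  set.seed(derive_seed(scenario$seed, "pathways"))
  lapply(seq_len(scenario$n_pathways), function(i) {
    pw_id <- sprintf("pw%03d", i)
    size <- if (rng[1L] == rng[2L]) rng[1L] else
      sample(seq(rng[1L], rng[2L]), 1L)
    members <- sample(ids, size)
    frac <- frac_override[[pw_id]]
    if (is.null(frac)) frac <- scenario$repressor_fraction
    n_rep <- .round_half_up(size * frac)
    signs <- rep(1, size)
    if (n_rep > 0) signs[sample.int(size, n_rep)] <- -1
    signed_pathway(pw_id, sprintf("synthetic pathway %d", i), members, signs)
  })
}

#' Behavioural simulation scenario
#'
#' Parameters of the synthetic Y-maze and object-recognition sessions.
#' Per-group values may be given as a named vector (one value per group) or
#' a single number shared by all groups. Defaults emulate an impaired
#' lesion group with partial rescue by treatment, and a marker whose
#' correlation with the recognition index matches the effect size reported
#' for hippocampal plasticity markers (r ~ 0.58, R^2 ~ 0.34).
#'
#' @param groups ordered group labels, control first.
#' @param n_animals_per_group animals per group.
#' @param alternation_prob probability that the next arm entry differs from
#'   both previous arms (per group or scalar).
#' @param n_entries arm entries per session, >= 3.
#' @param novelty_preference expected recognition index (per group or
#'   scalar).
#' @param exploration_time_scale mean total exploration time per phase,
#'   seconds (exponential).
#' @param ri_concentration Beta concentration of the per-animal recognition
#'   index around its group mean.
#' @param marker_memory_r target correlation between the synthetic marker
#'   and the recognition index.
#' @param seed RNG seed.
#' @return object of class `behavior_scenario`.
#' @export
behavior_scenario <- function(groups = .default_groups,
                              n_animals_per_group = 10,
                              alternation_prob = c(SHAM = 0.75,
                                                   UCCAO = 0.55,
                                                   UCCAO_MF = 0.70),
                              n_entries = 25,
                              novelty_preference = c(SHAM = 0.70,
                                                     UCCAO = 0.52,
                                                     UCCAO_MF = 0.65),
                              exploration_time_scale = 30,
                              ri_concentration = 10,
                              marker_memory_r = 0.58,
                              seed = 1) {
  expand <- function(x, what) {
    if (length(x) == 1L && is.null(names(x)))
      x <- stats::setNames(rep(x, length(groups)), groups)
    if (!all(groups %in% names(x)))
      stop(what, " must name every group", call. = FALSE)
    x[groups]
  }
  alternation_prob <- expand(alternation_prob, "alternation_prob")
  novelty_preference <- expand(novelty_preference, "novelty_preference")
  stopifnot(all(alternation_prob >= 0 & alternation_prob <= 1),
            all(novelty_preference >= 0 & novelty_preference <= 1),
            n_entries >= 3, exploration_time_scale > 0,
            abs(marker_memory_r) <= 1)
  structure(
    list(groups = groups, n_animals_per_group = n_animals_per_group,
         alternation_prob = alternation_prob, n_entries = n_entries,
         novelty_preference = novelty_preference,
         exploration_time_scale = exploration_time_scale,
         ri_concentration = ri_concentration,
         marker_memory_r = marker_memory_r, seed = as.integer(seed)),
    class = "behavior_scenario"
  )
}

# one arm-entry sequence; first two entries are distinct arms
.gen_arm_sequence <- function(n_entries, p_alt) {
  arms <- c("A", "B", "C")
  seq <- character(n_entries)
  seq[1:2] <- sample(arms, 2L)
  for (i in 3:n_entries) {
    prev <- seq[c(i - 2L, i - 1L)]
    if (prev[1L] != prev[2L]) {
      if (stats::runif(1) < p_alt) {
        seq[i] <- setdiff(arms, prev)           # completes an alternation
      } else {
        seq[i] <- sample(prev, 1L)              # repeats a recent arm
      }
    } else {
      seq[i] <- sample(setdiff(arms, prev[1L]), 1L)
    }
  }
  seq
}

#' Expected spontaneous-alternation rate of the generator
#'
#' Analytic oracle for the arm-entry chain: windows alternate only when the
#' two previous arms differ (state D). From D the next entry completes an
#' alternation with probability p, repeats the immediately previous arm
#' (moving to state E) with probability (1-p)/2, and otherwise stays in D;
#' from E the chain always returns to D. Starting from D (the first two
#' entries are distinct) the exact finite-sequence expectation is the mean
#' of P(D at window t) * p over the n - 2 windows.
#'
#' @param p alternation probability.
#' @param n_entries entries per session.
#' @return expected spontaneous alternation, in percent.
#' @export
expected_alternation_rate <- function(p, n_entries) {
  stopifnot(p >= 0, p <= 1, n_entries >= 3)
  n_win <- n_entries - 2L
  p_d <- numeric(n_win)
  p_d[1L] <- 1
  a <- (1 + p) / 2                     # P(D -> D)
  if (n_win > 1L) for (t in 2:n_win) p_d[t] <- p_d[t - 1L] * a + (1 - p_d[t - 1L])
  100 * mean(p_d * p)
}

#' Generate behavioural session records
#'
#' Arm-entry sequences over \{A, B, C\} with per-group alternation
#' probability; novel-object (NOR) and novel-location (NLR) exploration
#' times whose expected recognition index equals the group's novelty
#' preference, with total exploration time exponential so that short
#' low-exploration sessions occur and are excluded downstream; and a
#' synthetic plasticity marker correlated with the NOR recognition index.
#'
#' @param scenario a [behavior_scenario()].
#' @return list with data.frames `arm_entries` (entries as a list column),
#'   `exploration` (one row per animal and phase) and `marker` (one row per
#'   animal).
#' @export
generate_behavior <- function(scenario) {
  stopifnot(inherits(scenario, "behavior_scenario"))
  set.seed(derive_seed(scenario$seed, "behavior"))
  groups <- scenario$groups
  n <- scenario$n_animals_per_group
  animal_ids <- as.vector(vapply(
    groups, function(g) sprintf("%s_m%02d", g, seq_len(n)), character(n)))
  animal_groups <- rep(groups, each = n)

  entries <- lapply(seq_along(animal_ids), function(i) {
    .gen_arm_sequence(scenario$n_entries,
                      scenario$alternation_prob[[animal_groups[i]]])
  })

  kappa <- scenario$ri_concentration
  expl <- do.call(rbind, lapply(c("NOR", "NLR"), function(phase) {
    np <- scenario$novelty_preference[animal_groups]
    total <- stats::rexp(length(animal_ids),
                         rate = 1 / scenario$exploration_time_scale)
    ri <- stats::rbeta(length(animal_ids), kappa * np, kappa * (1 - np))
    data.frame(animal_id = animal_ids, group = animal_groups,
               phase = phase, time_novel = total * ri,
               time_familiar = total * (1 - ri))
  }))

  # marker = r * standardized NOR recognition index + sqrt(1-r^2) * noise
  nor <- expl[expl$phase == "NOR", ]
  ri_nor <- nor$time_novel / (nor$time_novel + nor$time_familiar)
  r <- scenario$marker_memory_r
  z <- as.vector(scale(ri_nor))
  marker <- r * z + sqrt(1 - r^2) * stats::rnorm(length(z))
  list(
    arm_entries = data.frame(animal_id = animal_ids, group = animal_groups,
                             entries = I(entries), stringsAsFactors = FALSE),
    exploration = expl,
    marker = data.frame(animal_id = animal_ids, group = animal_groups,
                        marker = marker)
  )
}

#' Generate and write every pipeline input
#'
#' Runs the full generator and writes the abundance table + sample sheet,
#' the edge list, the signed GMT and the behaviour TSVs into `dir`.
#'
#' @param scenario a [simulation_scenario()].
#' @param bscenario a [behavior_scenario()] (or NULL to skip behaviour).
#' @param dir output directory (created if needed).
#' @return named character vector of written paths.
#' @export
simulate_inputs <- function(scenario, bscenario = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  network <- generate_network(scenario)
  pathways <- generate_pathways(network, scenario)
  mat <- generate_abundances(network, scenario, pathways)
  paths <- c(
    abundance = file.path(dir, "abundance.tsv"),
    samples = file.path(dir, "samples.tsv"),
    edges = file.path(dir, "edges.tsv"),
    gmt = file.path(dir, "pathways.gmt")
  )
  write_abundance(mat, paths[["abundance"]], paths[["samples"]])
  write_edge_list(network, paths[["edges"]])
  write_signed_gmt(pathways, paths[["gmt"]])
  if (!is.null(bscenario)) {
    beh <- generate_behavior(bscenario)
    paths <- c(paths,
               arm_entries = file.path(dir, "arm_entries.tsv"),
               exploration = file.path(dir, "exploration.tsv"),
               marker = file.path(dir, "marker.tsv"))
    write_behavior(beh, paths[["arm_entries"]], paths[["exploration"]])
    utils::write.table(beh$marker, paths[["marker"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  paths
}
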