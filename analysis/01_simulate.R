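#!/usr/bin/env Rscript
# Stage 1: simulate the study-design inputs.
#
# Three groups (SHAM control, UCCAO lesion, UCCAO_MF treated), 10 replicates
# each, 200 proteins on an Erdos-Renyi interaction network. One ego-module
# (seed P000010 and its direct neighbours) is shifted by +1.2 log2 units in
# the UCCAO group and one pathway (pw001) by +1 per member (sign-weighted)
# in UCCAO, so later stages have known ground truth. Behavioural sessions
# use an impaired lesion group with partial treatment rescue.

library(egoperm)

seed <- 20250925
out <- file.path("results", "run", "inputs")

scenario <- simulation_scenario(
  n_proteins = 200,
  planted_modules = list(
    list(seed_protein = "P000010", group = "UCCAO", delta = 1.2)),
  planted_pathways = list(
    list(pathway_id = "pw001", group = "UCCAO", shift = 1)),
  seed = seed)
bscenario <- behavior_scenario(seed = seed)

paths <- simulate_inputs(scenario, bscenario, out)
net <- read_edge_list(paths[["edges"]])
mat <- read_abundance(paths[["abundance"]], paths[["samples"]])

message(sprintf("wrote %d input files to %s", length(paths), out))
message(sprintf("network: %d proteins, %d interactions (mean degree %.1f)",
                igraph::vcount(net), igraph::ecount(net),
                mean(igraph::degree(net))))
message(sprintf("abundance: %d proteins x %d samples, groups %s",
                nrow(mat$values), ncol(mat$values),
                paste(unique(mat$sample_groups), collapse = "/")))
message("planted: ego-module of P000010 (+1.2 log2 in UCCAO), ",
        "pathway pw001 (+1 per member in UCCAO)")
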