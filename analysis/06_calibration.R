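#!/usr/bin/env Rscript
# Stage 6: statistical health checks of the permutation machinery — null
# calibration of the module and pathway tests and planted-effect recovery.
# Uses smaller replicate counts than scripts/acceptance.R for a quick
# interactive run; the acceptance script is the full version.

library(egoperm)

out <- file.path("results", "run")
seed <- 20250925

cal <- module_null_calibration(n_sims = 2, n_proteins = 200, n_perm = 999,
                               seed = seed)
message(sprintf("module null: %.1f%% of %d p-values < 0.05, KS = %.3f",
                100 * cal$fraction, cal$n, cal$ks_distance))

pc <- pathway_null_calibration(n_pathways = 300, n_perm = 999, seed = seed)
message(sprintf("pathway null: %.1f%% of %d cells < 0.05, KS = %.3f",
                100 * pc$fraction, pc$n, pc$ks_distance))

rec <- module_recovery_rate(n_reps = 25, n_perm = 999, seed = seed)
message(sprintf("planted module top-ranked in %d/%d replicates",
                sum(rec$hits), rec$n))

prec <- pathway_recovery_rate(n_reps = 25, seed = seed)
message(sprintf("planted pathway largest |activity| in %d/%d replicates",
                sum(prec$hits), prec$n))

write_results(
  data.frame(
    check = c("module_null_pct_lt_0.05", "module_null_ks",
              "pathway_null_pct_lt_0.05", "pathway_null_ks",
              "module_recovery_rate", "pathway_recovery_rate"),
    value = c(100 * cal$fraction, cal$ks_distance, 100 * pc$fraction,
              pc$ks_distance, rec$rate, prec$rate),
    n = c(cal$n, cal$n, pc$n, pc$n, rec$n, prec$n)),
  file.path(out, "calibration.tsv"))
message("wrote ", file.path(out, "calibration.tsv"))
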