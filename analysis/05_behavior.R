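#!/usr/bin/env Rscript
# Stage 5: behavioural scoring — Y-maze spontaneous alternation, NOR/NLR
# recognition indices with the < 5 s exclusion, group ANOVA + LSD + Levene
# and the marker vs recognition-index correlation.

library(egoperm)

inputs <- file.path("results", "run", "inputs")
out <- file.path("results", "run")

beh <- read_behavior(file.path(inputs, "arm_entries.tsv"),
                     file.path(inputs, "exploration.tsv"))
marker <- read.delim(file.path(inputs, "marker.tsv"))

summ <- behavior_summary(beh)
write_results(summ$per_animal, file.path(out, "behavior_per_animal.tsv"))

for (m in names(summ$group_stats)) {
  gs <- summ$group_stats[[m]]
  message(sprintf("%s: F(%d,%d) = %.2f, p = %.4g (Levene p = %.3f)",
                  m, gs$anova$df1, gs$anova$df2, gs$anova$F, gs$anova$p,
                  gs$levene$p))
  for (i in seq_len(nrow(gs$lsd)))
    message(sprintf("  LSD %s vs %s: diff %.2f, p = %.4g",
                    gs$lsd$group_a[i], gs$lsd$group_b[i],
                    gs$lsd$diff[i], gs$lsd$p[i]))
}

excl <- sum(summ$per_animal$excluded_nor | summ$per_animal$excluded_nlr)
message(sprintf("%d of %d animals excluded for < 5 s exploration in a phase",
                excl, nrow(summ$per_animal)))

keep <- !summ$per_animal$excluded_nor
mm <- marker_memory_correlation(
  marker$marker[match(summ$per_animal$animal_id[keep], marker$animal_id)],
  summ$per_animal$ri_nor[keep])
write_results(data.frame(r = mm$r, r2 = mm$r2, p = mm$p, n = mm$n),
              file.path(out, "marker_memory.tsv"))
message(sprintf("marker vs NOR recognition index: R2 = %.3f, p = %.4g, n = %d",
                mm$r2, mm$p, mm$n))
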