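#!/usr/bin/env Rscript
# Stage 2: group contrasts, the 1.5-fold differential filter, expression
# clustering and the Venn comparison of the two differential sets.

library(egoperm)

inputs <- file.path("results", "run", "inputs")
out <- file.path("results", "run")

mat <- read_abundance(file.path(inputs, "abundance.tsv"),
                      file.path(inputs, "samples.tsv"))
cases <- setdiff(abundance_groups(mat), mat$control_group)
contrasts <- lapply(cases, function(g) compute_contrast(mat, g))
names(contrasts) <- cases

tab <- data.frame(protein_id = rownames(mat$values))
for (g in cases) tab[[paste0("logfc_", g)]] <- contrasts[[g]]$logfc
write_results(tab, file.path(out, "contrasts.tsv"))

sets <- lapply(contrasts, fold_change_filter, fold = 1.5)
for (s in sets)
  message(sprintf("%s vs SHAM: %d proteins beyond 1.5-fold", s$label,
                  length(s$members)))

overlap <- compare_sets(sets)
write_results(overlap, file.path(out, "set_overlap.tsv"))
message("differential-set overlap: ",
        paste(sprintf("%s=%d", overlap$region, overlap$count),
              collapse = ", "))

union_sel <- sort(unique(unlist(lapply(sets, `[[`, "members"))))
cl <- cluster_expression(contrasts, intersect(union_sel,
                                              valid_proteins(contrasts)))
write_results(data.frame(protein_id = cl$order),
              file.path(out, "cluster_order.tsv"))
write_results(data.frame(merge_a = cl$hclust$merge[, 1],
                         merge_b = cl$hclust$merge[, 2],
                         height = cl$hclust$height),
              file.path(out, "cluster_merges.tsv"))
message(sprintf("clustered %d differential proteins by expression pattern",
                nrow(cl$logfc)))
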