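#!/usr/bin/env Rscript
# Bulk timecourse analysis: which genes diverge between genotypes over
# development, how they cluster into gene groups, how the group signatures
# travel over time, and whether the divergent signature tracks a MYC-target
# signature.

library(mgskit)

data_dir <- "scratch/data"
out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

expr <- read_expression_csv(file.path(data_dir, "timecourse_expr.csv"))
design <- read.csv(file.path(data_dir, "timecourse_design.csv"))
truth <- read.csv(file.path(data_dir, "timecourse_truth.csv"))
sets <- read_gmt(file.path(data_dir, "gene_sets_synthetic.gmt"))

fit <- fit_divergence(expr, design, alpha = 0.05)
recall <- sum(fit$selected & truth$divergent) / sum(truth$divergent)
fdp <- sum(fit$selected & !truth$divergent) / max(1, sum(fit$selected))
message(sprintf("selected %d / %d genes (recall %.1f%%, false-discovery %.1f%%)",
                sum(fit$selected), nrow(fit), 100 * recall, 100 * fdp))
write.csv(fit, file.path(out_dir, "divergence_fit.csv"), row.names = FALSE)

sel <- fit$gene[fit$selected]
cl <- cluster_gene_groups(expr, sel, k = 3)
message("gene-group sizes: ", paste(table(cl$groups), collapse = " / "))
write.csv(data.frame(gene = names(cl$groups), group = cl$groups),
          file.path(out_dir, "gene_groups.csv"), row.names = FALSE)

traj <- do.call(rbind, lapply(sort(unique(cl$groups)), function(g) {
  tr <- group_signature_trajectory(expr, names(cl$groups)[cl$groups == g],
                                   design)
  cbind(group = g, tr)
}))
write.csv(traj, file.path(out_dir, "group_trajectories.csv"),
          row.names = FALSE)

# divergent-signature score vs the synthetic MYC-target signature
div_score <- signature_score(expr, sel)
myc_score <- signature_score(expr, sets$myc_targets_synthetic)
corr <- signature_correlation(div_score, myc_score)
message(sprintf("divergent signature vs MYC-target stand-in: r = %.3f (p = %.2g)",
                corr$r, corr$p_value))

ora <- do.call(rbind, lapply(sort(unique(cl$groups)), function(g) {
  res <- ora_hypergeometric(names(cl$groups)[cl$groups == g],
                            sets[names(sets) != "myc_targets_synthetic"],
                            colnames(expr))
  cbind(group = g, res)
}))
write.csv(ora, file.path(out_dir, "ora_gene_groups.csv"), row.names = FALSE)
top <- ora[which.min(ora$p), ]
message(sprintf("strongest enrichment: group %d in '%s' (overlap %d, q = %.2g)",
                top$group, top$set, top$overlap, top$q))
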