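#!/usr/bin/env Rscript
# Single-cell qPCR analysis: LOD-normalize the Ct matrix, score the marker
# and mitotic signatures, classify cells by the threshold rules, and compare
# MGS expression between cell types and sample ages.

library(mgskit)

data_dir <- "scratch/data"
out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

ct <- read_ct_csv(file.path(data_dir, "scqpcr_ct.csv"), lod = 24)
meta <- read.csv(file.path(data_dir, "scqpcr_meta.csv"))
expr <- normalize_ct(ct)
sigs <- celltype_signatures()

scores <- data.frame(
  cell = rownames(expr),
  neuroblast = signature_score(expr, sigs$neuroblast),
  ganglion = signature_score(expr, sigs$ganglion),
  schwannian = signature_score(expr, sigs$schwannian),
  mgs = signature_score(expr, mgs_signature())
)
scores$label <- classify_cells(scores$neuroblast, scores$ganglion,
                               scores$schwannian)
write.csv(cbind(scores, sample = meta$sample),
          file.path(out_dir, "scqpcr_classification.csv"), row.names = FALSE)

kept <- scores$label != "excluded"
acc <- mean(as.character(scores$label[kept]) == meta$true_type[kept])
message(sprintf("classified %d/%d cells; %.1f%% of kept cells match truth",
                sum(kept), nrow(scores), 100 * acc))
message("type counts: ", paste(names(table(scores$label)),
                               table(scores$label), sep = "=", collapse = " "))

# MGS is higher in neuroblasts than in the other cell types
nb_gg <- scores$label %in% c("neuroblast", "ganglion")
cmp1 <- compare_groups(scores$mgs[nb_gg], droplevels(scores$label[nb_gg]))
message(sprintf("MGS neuroblast vs ganglion: W = %g, p = %.3g",
                cmp1$statistic, cmp1$p_value))

# premalignant day-10 neuroblasts vs day-40 tumor cells: no marked shift
nb10 <- scores$label == "neuroblast" & meta$sample == "ganglion-day10"
t40 <- scores$label == "neuroblast" & meta$sample == "tumor-day40"
cmp2 <- compare_groups(scores$mgs[nb10 | t40],
                       meta$sample[nb10 | t40])
message(sprintf("MGS day-10 neuroblasts vs day-40 tumor cells: p = %.3g",
                cmp2$p_value))

# MGS tracks the immature-neuroblast markers cell by cell
for (marker in c("Phox2b", "hMYCN")) {
  cc <- marker_correlation(scores$mgs, expr[, marker])
  message(sprintf("MGS vs %s: r = %.3f (p = %.2g)", marker, cc$r, cc$p_value))
}

comparisons <- data.frame(
  comparison = c("neuroblast vs ganglion", "day10-neuroblast vs day40-tumor"),
  p_value = c(cmp1$p_value, cmp2$p_value)
)
write.csv(comparisons, file.path(out_dir, "scqpcr_comparisons.csv"),
          row.names = FALSE)
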