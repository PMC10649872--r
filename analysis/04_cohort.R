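#!/usr/bin/env Rscript
# Tumor-cohort stratification: cluster tumors on the divergence gene panel,
# name the classes by MGS level, and relate the strata to overall survival
# and the standard clinical covariates.

library(mgskit)

data_dir <- "scratch/data"
out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

expr <- read_expression_csv(file.path(data_dir, "cohort_expr.csv"))
clinical <- read_clinical_csv(file.path(data_dir, "cohort_clinical.csv"))

cl <- cluster_tumors(expr)
acc <- mean(as.character(cl$classes) == clinical$true_class)
message(sprintf("classes: %s (%.1f%% match planted truth)",
                paste(names(table(cl$classes)), table(cl$classes),
                      sep = "=", collapse = " "), 100 * acc))
write.csv(data.frame(tumor = rownames(expr), class = cl$classes,
                     mgs_score = cl$mgs_score),
          file.path(out_dir, "tumor_classes.csv"), row.names = FALSE)

# MGS scores split by class (boxplot-style summary + pairwise rank-sum)
for (pair in list(c("MGS.High", "MGS.Int"), c("MGS.Int", "MGS.Low"))) {
  sel <- cl$classes %in% pair
  cmp <- compare_groups(cl$mgs_score[sel], droplevels(cl$classes[sel]))
  message(sprintf("MGS %s vs %s: p = %.3g", pair[1], pair[2], cmp$p_value))
}

km <- do.call(rbind, lapply(levels(cl$classes), function(g) {
  cbind(class = g, km_estimate(clinical$time[cl$classes == g],
                               clinical$event[cl$classes == g]))
}))
write.csv(km, file.path(out_dir, "km_by_class.csv"), row.names = FALSE)

lr <- logrank_test(clinical$time, clinical$event, cl$classes)
message(sprintf("log-rank across classes: chi2 = %.1f (df %d), p = %.3g",
                lr$chi2, lr$df, lr$p_value))
final_surv <- tapply(seq_len(nrow(clinical)), cl$classes, function(i)
  min(km_estimate(clinical$time[i], clinical$event[i])$survival))
message("end-of-follow-up survival by class: ",
        paste(names(final_surv), sprintf("%.2f", final_surv),
              sep = "=", collapse = " "))

splits <- clinical_splits(cl$mgs_score, clinical)
write.csv(splits, file.path(out_dir, "clinical_splits.csv"), row.names = FALSE)
for (i in seq_len(nrow(splits)))
  message(sprintf("MGS by %s: p = %.3g", splits$split[i], splits$p_value[i]))
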