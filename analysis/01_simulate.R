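#!/usr/bin/env Rscript
# Generate every input the downstream analyses consume, with known ground
# truth, and write them in the same CSV/TSV dialects the pipeline reads.
# Raw simulated datasets are large and fully regenerable, so they live under
# scratch/data/; the truth labels are written alongside for later scoring.

library(mgskit)

seed <- 20260924L
data_dir <- "scratch/data"
dir.create(data_dir, showWarnings = FALSE, recursive = TRUE)

message("-- bulk timecourse: 2 genotypes x weeks 1/2/6 x 2 replicates")
tc <- simulate_timecourse(
  n_genes = 1000, diverging_fraction = 0.1, effect = 1.5,
  timepoints = c(1, 2, 6),
  config = sim_config(seed, n_replicates = 2, noise_sd = 0.5)
)
write_expression_csv(tc$expr, file.path(data_dir, "timecourse_expr.csv"))
write.csv(cbind(sample = rownames(tc$expr), tc$design),
          file.path(data_dir, "timecourse_design.csv"), row.names = FALSE)
write.csv(data.frame(gene = colnames(tc$expr), divergent = tc$truth),
          file.path(data_dir, "timecourse_truth.csv"), row.names = FALSE)

# gene-set fixtures for ORA and the MYC-target correlation: a mitosis-like
# set enriched in the divergent genes, control sets drawn from the nulls,
# and a synthetic MYC-target stand-in overlapping the divergent trajectory
div_genes <- colnames(tc$expr)[tc$truth]
null_genes <- colnames(tc$expr)[!tc$truth]
set.seed(seed)
sets <- list(
  mitotic_cell_cycle = c(sample(div_genes, 40), sample(null_genes, 10)),
  neuron_differentiation = sample(null_genes, 50),
  axon_guidance = sample(null_genes, 35),
  myc_targets_synthetic = c(sample(div_genes, 30), sample(null_genes, 5))
)
write_gmt(sets, file.path(data_dir, "gene_sets_synthetic.gmt"),
          descriptions = rep("synthetic fixture", length(sets)))

message("-- single-cell qPCR: 1000 cells over the 18-gene panel")
sc <- simulate_ct_matrix(default_ct_archetypes(separation = 3),
                         mix = c(0.45, 0.35, 0.2), n_cells = 1000,
                         config = sim_config(seed + 1L, noise_sd = 1))
write_ct_csv(sc$ct, file.path(data_dir, "scqpcr_ct.csv"))
# cells alternate between the two sampled tissues, mimicking a mixed chip
meta <- data.frame(cell = rownames(sc$ct$ct),
                   sample = rep(c("ganglion-day10", "tumor-day40"),
                                length.out = 1000),
                   true_type = sc$labels)
write.csv(meta, file.path(data_dir, "scqpcr_meta.csv"), row.names = FALSE)

message("-- tumor cohort: 475 tumors, 3 latent classes, HR 3 / 1.5 / 1")
co <- simulate_cohort(n_tumors = 475, class_props = c(0.2, 0.4, 0.4),
                      hazard_ratios = c(3, 1.5, 1),
                      config = sim_config(seed + 2L, noise_sd = 1))
write_expression_csv(co$expr, file.path(data_dir, "cohort_expr.csv"),
                     id_col = "tumor")
write_clinical_csv(cbind(tumor = rownames(co$expr), co$clinical,
                         true_class = as.character(co$classes)),
                   file.path(data_dir, "cohort_clinical.csv"))

message("-- combination plates: 6 antimitotic x pro-apoptotic pairs, 2 MYCN states")
antimitotic <- c(vincristine = 2e-9, barasertib = 3e-8)
proapoptotic <- c(ABT199 = 1e-6, S63845 = 4e-7, "ABT-263" = 8e-7)
# planted Bliss interactions: barasertib+S63845 is the MYCN-selective pair
interaction_of <- function(combo, condition) {
  if (combo == "barasertib+S63845" && condition == "MYCN+") return(0.25)
  if (condition == "MYCN+") return(0.05)
  0.02
}
# every agent's 7-point ladder is centered on its own IC50, so each single
# agent is measured once per condition and shared across its combinations
hill_of <- function(agent, condition) {
  if (agent %in% names(antimitotic)) {
    # MYCN induction sensitizes to the antimitotic agent
    shift <- if (condition == "MYCN+") 0.5 else 1
    list(ic50 = antimitotic[[agent]] * shift, slope = 1.2, floor = 0.05)
  } else {
    list(ic50 = proapoptotic[[agent]], slope = 1, floor = 0.1)
  }
}
ladder_of <- function(agent) {
  base <- c(antimitotic, proapoptotic)[[agent]]
  base * 10^seq(-2, 2, length.out = 7)
}
series <- list()
idx <- 0L
for (agent in c(names(antimitotic), names(proapoptotic))) {
  for (condition in c("MYCN+", "MYCN-")) {
    idx <- idx + 1L
    series <- c(series, list(simulate_dose_response(
      hill_of(agent, condition), ladder_of(agent),
      sim_config(seed + 100L * idx, n_replicates = 3, noise_sd = 0.05),
      agent = agent, condition = condition)))
  }
}
for (am in names(antimitotic)) for (pa in names(proapoptotic)) {
  for (condition in c("MYCN+", "MYCN-")) {
    idx <- idx + 1L
    combo_label <- paste0(am, "+", pa)
    series <- c(series, list(simulate_combination(
      hill_of(am, condition), hill_of(pa, condition), ladder_of(am),
      ratio = proapoptotic[[pa]] / antimitotic[[am]],
      interaction = interaction_of(combo_label, condition),
      config = sim_config(seed + 100L * idx, n_replicates = 3,
                          noise_sd = 0.05),
      agent = combo_label, condition = condition)))
  }
}
write_plates_csv(series, file.path(data_dir, "combination_plates.csv"))

write_run_config(run_config(seed = seed),
                 file.path(data_dir, "run_config.yaml"))
message("wrote all simulated inputs to ", data_dir)
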