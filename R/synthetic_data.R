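#' Simulation configuration
#'
#' Bundles the seed and the shared noise knobs of the synthetic-data
#' generators. The same config always produces byte-identical output; the
#' global RNG state of the caller is left untouched.
#'
#' @param seed integer seed
#' @param n_replicates replicates per condition (plates) or per
#'   genotype-timepoint (timecourses)
#' @param noise_sd Gaussian noise SD, in the units of the generator it is
#'   passed to: viability fraction for plates, cycles for Ct matrices, log2
#'   expression for bulk matrices
#' @return an object of class `sim_config`
#' @export
sim_config <- function(seed, n_replicates = 3, noise_sd = 0.05) {
  if (!isTRUE(noise_sd >= 0)) stop("noise_sd must be >= 0")
  if (!isTRUE(n_replicates >= 1)) stop("n_replicates must be >= 1")
  structure(list(seed = as.integer(seed), n_replicates = as.integer(n_replicates),
                 noise_sd = noise_sd), class = "sim_config")
}

# Run code under the config's seed without disturbing the caller's RNG.
with_sim_seed <- function(config, code) {
  stopifnot(inherits(config, "sim_config"))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(config$seed)
  code
}

hill_viability <- function(d, ic50, slope, floor) {
  floor + (1 - floor) / (1 + (d / ic50)^slope)
}

#' Simulate a single-agent dose-response series
#'
#' Mean viability follows a Hill curve,
#' `floor + (1 - floor) / (1 + (d / ic50)^slope)`; replicates add i.i.d.
#' Gaussian noise truncated at 0 (no upper truncation: control-normalized
#' readings above 1 are realistic and retained).
#'
#' @param hill_params list with `ic50` (molar, > 0), `slope` (> 0), `floor`
#'   (residual viability at saturating dose, in \[0, 1\])
#' @param doses strictly increasing positive dose ladder (molar)
#' @param config a [sim_config()]; `noise_sd` in viability units
#' @param agent,condition labels for the series
#' @return a [dose_response_series()]
#' @export
simulate_dose_response <- function(hill_params, doses, config,
                                   agent = "agentA", condition = "MYCN+") {
  with(hill_params, {
    if (!isTRUE(ic50 > 0) || !isTRUE(slope > 0))
      stop("ic50 and slope must be positive")
    if (!isTRUE(floor >= 0 && floor <= 1)) stop("floor must lie in [0, 1]")
  })
  if (any(doses <= 0) || any(diff(doses) <= 0))
    stop("doses must be strictly increasing and positive")
  mu <- hill_viability(doses, hill_params$ic50, hill_params$slope,
                       hill_params$floor)
  viab <- with_sim_seed(config, {
    noise <- matrix(stats::rnorm(config$n_replicates * length(doses),
                                 sd = config$noise_sd),
                    nrow = config$n_replicates)
    pmax(sweep(noise, 2L, mu, "+"), 0)
  })
  dose_response_series(agent, condition, doses, viab)
}

#' Simulate a constant-ratio combination series
#'
#' Ground-truth generator for Bliss synergy scoring. At ladder position i
#' (agent A at `dA`, agent B at `ratio * dA`) the combined fraction affected
#' is `clamp01(fa + fb - fa*fb + interaction)` computed from the single
#' agents' noiseless Hill means; `interaction = 0` yields exact Bliss
#' additivity, positive values super-additive killing. Replicate noise is
#' added to the resulting viabilities as in [simulate_dose_response()].
#'
#' @param hill_a,hill_b Hill parameter lists of the two single agents (as in
#'   [simulate_dose_response()])
#' @param doses_a agent A's dose ladder; agent B is dosed at `ratio * doses_a`
#' @param ratio positive dose ratio of B to A
#' @param interaction additive shift of the combined fraction affected
#' @param config a [sim_config()]
#' @param agent,condition labels
#' @return a [dose_response_series()] with `ratio_partner` set
#' @export
simulate_combination <- function(hill_a, hill_b, doses_a, ratio, interaction,
                                 config, agent = "A+B", condition = "MYCN+") {
  if (!isTRUE(ratio > 0)) stop("ratio must be positive")
  fa <- 1 - hill_viability(doses_a, hill_a$ic50, hill_a$slope, hill_a$floor)
  fb <- 1 - hill_viability(ratio * doses_a, hill_b$ic50, hill_b$slope,
                           hill_b$floor)
  f_combo <- clamp01(fa + fb - fa * fb + interaction)
  mu <- 1 - f_combo
  viab <- with_sim_seed(config, {
    noise <- matrix(stats::rnorm(config$n_replicates * length(doses_a),
                                 sd = config$noise_sd),
                    nrow = config$n_replicates)
    pmax(sweep(noise, 2L, mu, "+"), 0)
  })
  dose_response_series(agent, condition, doses_a, viab,
                       ratio_partner = list(agent = "B", ratio = ratio))
}

#' Default Ct archetypes for the single-cell panel
#'
#' Mean-Ct vectors over the 18-gene panel for the three cell types. Each
#' marker triplet sits `separation` cycles below (i.e. more expressed than)
#' the off-type baseline in its own cell type; the MGS genes are expressed in
#' neuroblasts and near baseline elsewhere, mirroring the mitotic
#' dysregulation of premalignant neuroblasts.
#'
#' @param separation difference in mean Ct (cycles) between on- and off-type
#'   marker genes; the classifier-recovery checks use 3x the Ct noise SD
#' @param baseline_ct off-type mean Ct (cycles), below the LOD so off genes
#'   are still mostly detected at low expression
#' @return 3 x 18 matrix (celltypes x genes) of mean Ct values
#' @export
default_ct_archetypes <- function(separation = 3, baseline_ct = 22) {
  panel <- scqpcr_panel()
  sigs <- celltype_signatures()
  arch <- matrix(baseline_ct, nrow = 3, ncol = length(panel),
                 dimnames = list(c("neuroblast", "ganglion", "schwannian"),
                                 panel))
  for (type in rownames(arch))
    arch[type, sigs[[type]]] <- baseline_ct - separation
  arch["neuroblast", mgs_signature()] <- baseline_ct - separation
  arch
}

#' Simulate a single-cell Ct matrix with known cell types
#'
#' Each cell draws its type from `mix`, then Ct = archetype mean + Gaussian
#' noise per gene; values at or above the LOD are recorded as not detected.
#' The hidden true label of every cell is returned for downstream scoring.
#'
#' @param archetypes celltypes x genes matrix of mean Ct values (rownames =
#'   type labels, colnames = panel genes); default [default_ct_archetypes()]
#' @param mix named (or archetype-ordered) cell-type proportions summing to 1
#' @param n_cells number of cells
#' @param config a [sim_config()]; `noise_sd` in cycles
#' @param lod limit of detection in cycles
#' @return list with `ct` (a [ct_matrix()]; metadata column `sample` set to
#'   `"ganglion-day10"`/`"tumor-day40"` is left to callers) and `labels`
#'   (character vector of true types)
#' @export
simulate_ct_matrix <- function(archetypes = default_ct_archetypes(),
                               mix = c(0.45, 0.35, 0.2), n_cells = 200,
                               config = sim_config(1, noise_sd = 1),
                               lod = 24) {
  if (abs(sum(mix) - 1) > 1e-9) stop("celltype proportions must sum to 1")
  if (length(mix) != nrow(archetypes))
    stop("mix must have one proportion per archetype")
  types <- rownames(archetypes)
  with_sim_seed(config, {
    labels <- sample(types, n_cells, replace = TRUE, prob = mix)
    ct <- archetypes[labels, , drop = FALSE] +
      matrix(stats::rnorm(n_cells * ncol(archetypes), sd = config$noise_sd),
             nrow = n_cells)
    ct[ct >= lod] <- NA
    # Ct values are cycle counts, strictly positive in any real assay
    ct[!is.na(ct) & ct <= 0] <- 0.1
    rownames(ct) <- sprintf("cell%04d", seq_len(n_cells))
    list(ct = ct_matrix(ct, lod = lod), labels = labels)
  })
}

#' Simulate a two-genotype expression timecourse
#'
#' Emulates bulk profiles of wild-type and transgenic sympathetic ganglia
#' over development. A fixed fraction of genes diverges: the transgenic
#' trajectory rises at `+effect/2` log2 units/week and the wild-type falls at
#' `-effect/2`, so the genotype-by-time interaction equals `effect` exactly.
#' Null genes share one common slope in both genotypes.
#'
#' @param n_genes total genes
#' @param diverging_fraction fraction of genes that diverge; the flagged
#'   count is `round(n_genes * diverging_fraction)` exactly
#' @param effect interaction slope in log2 units/week
#' @param timepoints ages in weeks (>= 2)
#' @param genotypes two genotype labels; the first is wild-type
#' @param config a [sim_config()]; `noise_sd` in log2 units,
#'   `n_replicates` per genotype-timepoint
#' @return list with `expr` (samples x genes), `design` (data.frame
#'   `genotype`, `age`, `replicate`), and `truth` (logical flag per gene)
#' @export
simulate_timecourse <- function(n_genes = 1000, diverging_fraction = 0.1,
                                effect = 1, timepoints = c(1, 2, 6),
                                genotypes = c("wild-type", "transgenic"),
                                config = sim_config(1, n_replicates = 2,
                                                    noise_sd = 0.5)) {
  if (length(timepoints) < 2L || length(genotypes) < 2L)
    stop("need at least 2 timepoints and 2 genotypes")
  design <- expand.grid(replicate = seq_len(config$n_replicates),
                        age = timepoints, genotype = genotypes,
                        stringsAsFactors = FALSE)[, c(3, 2, 1)]
  n_div <- if (effect == 0) 0L else round(n_genes * diverging_fraction)
  truth <- c(rep(TRUE, n_div), rep(FALSE, n_genes - n_div))
  g <- as.numeric(design$genotype != genotypes[1L])
  with_sim_seed(config, {
    base <- stats::rnorm(n_genes, mean = 8, sd = 1)
    common_slope <- stats::rnorm(n_genes, mean = 0, sd = 0.1)
    # diverging genes: slope -effect/2 in wild-type, +effect/2 in transgenic
    slope_wt <- ifelse(truth, -effect / 2, common_slope)
    slope_int <- ifelse(truth, effect, 0)
    mu <- outer(rep(1, nrow(design)), base) +
      outer(design$age, slope_wt) + outer(design$age * g, slope_int)
    expr <- mu + matrix(stats::rnorm(length(mu), sd = config$noise_sd),
                        nrow = nrow(mu))
    colnames(expr) <- sprintf("gene%04d", seq_len(n_genes))
    rownames(expr) <- sprintf("s%02d", seq_len(nrow(design)))
    list(expr = expr, design = design, truth = truth)
  })
}

#' Simulate a tumor cohort with expression, survival and clinical covariates
#'
#' Emulates a several-hundred-tumor neuroblastoma cohort. Tumors belong to
#' three latent classes with deterministic sizes `round(cumsum(props) * n)`;
#' MGS and panel genes are shifted by class (high / intermediate / low);
#' event times are exponential with class-specific hazard ratios over a
#' baseline; censoring is administrative at `horizon` plus uniform dropout
#' on `(0, 2 * horizon)`. MYCN amplification, INSS stage 4 and age > 18
#' months are drawn with class-dependent probabilities so clinical splits of
#' the MGS score carry signal.
#'
#' @param n_tumors cohort size
#' @param class_props proportions of the High / Int / Low classes
#' @param hazard_ratios per-class hazard multipliers (High, Int, Low)
#' @param baseline_hazard events per time unit in the reference (Low) class
#' @param horizon administrative censoring time
#' @param mgs_shift log2 shift of MGS genes per class (High, Int, Low)
#' @param n_filler additional panel genes (shifted at half the MGS shift)
#' @param mycn_probs,stage4_probs,age_probs per-class probabilities of MYCN
#'   amplification, stage 4, and age > 18 months
#' @param prob_unknown_mycn probability a tumor's MYCN status is unrecorded
#' @param config a [sim_config()]; `noise_sd` in log2 units
#' @return list with `expr` (tumors x genes: MGS genes + filler panel),
#'   `clinical` (data.frame `time`, `event`, `mycn_status`, `stage`,
#'   `age_group`), and `classes` (true class factor)
#' @export
simulate_cohort <- function(n_tumors = 475, class_props = c(0.2, 0.4, 0.4),
                            hazard_ratios = c(3, 1.5, 1),
                            baseline_hazard = 0.01, horizon = 120,
                            mgs_shift = c(2, 0, -2), n_filler = 21,
                            mycn_probs = c(0.6, 0.25, 0.05),
                            stage4_probs = c(0.6, 0.35, 0.2),
                            age_probs = c(0.6, 0.45, 0.3),
                            prob_unknown_mycn = 0.05,
                            config = sim_config(1, noise_sd = 1)) {
  if (abs(sum(class_props) - 1) > 1e-9) stop("class proportions must sum to 1")
  stopifnot(length(class_props) == 3, length(hazard_ratios) == 3)
  sizes <- diff(c(0, round(cumsum(class_props) * n_tumors)))
  cls <- rep(1:3, times = sizes)  # 1 = High, 2 = Int, 3 = Low
  genes <- c(mgs_signature(), sprintf("panel%02d", seq_len(n_filler)))
  with_sim_seed(config, {
    mu <- matrix(8, nrow = n_tumors, ncol = length(genes),
                 dimnames = list(sprintf("tumor%03d", seq_len(n_tumors)),
                                 genes))
    mu[, mgs_signature()] <- mu[, mgs_signature()] + mgs_shift[cls]
    if (n_filler > 0)
      mu[, -seq_along(mgs_signature())] <-
        mu[, -seq_along(mgs_signature()), drop = FALSE] + mgs_shift[cls] / 2
    expr <- mu + matrix(stats::rnorm(length(mu), sd = config$noise_sd),
                        nrow = n_tumors)
    event_time <- stats::rexp(n_tumors,
                              rate = baseline_hazard * hazard_ratios[cls])
    cens_time <- pmin(horizon, stats::runif(n_tumors, 0, 2 * horizon))
    time <- pmin(event_time, cens_time)
    event <- as.integer(event_time <= cens_time)
    mycn <- ifelse(stats::runif(n_tumors) < mycn_probs[cls],
                   "amplified", "non-amplified")
    mycn[stats::runif(n_tumors) < prob_unknown_mycn] <- "unknown"
    stage <- ifelse(stats::runif(n_tumors) < stage4_probs[cls], "4",
                    sample(c("1", "2", "3", "4S"), n_tumors, replace = TRUE))
    age_group <- ifelse(stats::runif(n_tumors) < age_probs[cls],
                        ">18m", "<=18m")
    clinical <- data.frame(time = time, event = event, mycn_status = mycn,
                           stage = stage, age_group = age_group,
                           stringsAsFactors = FALSE)
    classes <- factor(c("MGS.High", "MGS.Int", "MGS.Low")[cls],
                      levels = c("MGS.High", "MGS.Int", "MGS.Low"))
    list(expr = expr, clinical = clinical, classes = classes)
  })
}
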