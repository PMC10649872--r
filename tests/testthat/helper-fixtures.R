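# Small in-code fixtures shared across test files.

# A noiseless series with the given mean viabilities replicated verbatim.
flat_series <- function(viab, doses = 10^seq(-8, length.out = length(viab)),
                        agent = "A", condition = "MYCN+", n_rep = 1L) {
  dose_response_series(agent, condition, doses,
                       matrix(rep(viab, each = n_rep), nrow = n_rep))
}

# Matched noiseless single-agent + combination triplet from Hill ground
# truth, for synergy scoring tests.
simulate_panel <- function(seed, interaction, noise_sd = 0,
                           doses = 10^seq(-8, -5, length.out = 7),
                           ratio = 2, n_rep = 3) {
  hill_a <- list(ic50 = 1e-6, slope = 1.2, floor = 0.05)
  hill_b <- list(ic50 = 3e-6, slope = 0.9, floor = 0.1)
  cfg <- function(offset) sim_config(seed + offset, n_replicates = n_rep,
                                     noise_sd = noise_sd)
  list(
    a = simulate_dose_response(hill_a, doses, cfg(0), agent = "drugA"),
    b = simulate_dose_response(hill_b, ratio * doses, cfg(1000000L),
                               agent = "drugB"),
    combo = simulate_combination(hill_a, hill_b, doses, ratio, interaction,
                                 cfg(2000000L), agent = "drugA+drugB"),
    ratio = ratio
  )
}

# Expression matrix (samples x genes) with named genes and iid noise.
random_expr <- function(n_samples, genes, seed, sd = 1, mean = 0) {
  set.seed(seed)
  m <- matrix(rnorm(n_samples * length(genes), mean = mean, sd = sd),
              nrow = n_samples,
              dimnames = list(sprintf("s%03d", seq_len(n_samples)), genes))
  m
}
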