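test_that("noiseless interaction slopes are recovered exactly", {
  design <- data.frame(genotype = rep(c("wild-type", "transgenic"), each = 6),
                       age = rep(c(1, 1, 2, 2, 6, 6), 2))
  g <- as.numeric(design$genotype == "transgenic")
  expr <- cbind(
    div = 5 + 0.5 * design$age + 2 * g * design$age,   # interaction 2
    flat = 3 + 1.5 * design$age                         # interaction 0
  )
  fit <- fit_divergence(expr, design)
  expect_equal(fit$beta_interaction, c(2, 0), tolerance = 1e-12)
  expect_equal(fit$p, c(0, 1))
  expect_true(all(fit$q >= fit$p))
  expect_error(fit_divergence(expr, data.frame(genotype = design$genotype,
                                               age = rep(1, 12))),
               "2 timepoints")
})

test_that("selection is calibrated under permutation and recovers true effects", {
  # permuted labels: the raw interaction p-value is uniform, so p < alpha
  # selects about alpha of the genes
  tc <- simulate_timecourse(n_genes = 400, diverging_fraction = 0.1,
                            effect = 1.5,
                            config = sim_config(31, n_replicates = 2,
                                                noise_sd = 0.5))
  set.seed(99)
  fracs <- vapply(1:30, function(i) {
    perm <- sample(nrow(tc$expr))
    fit <- fit_divergence(tc$expr[perm, ], tc$design)
    mean(fit$p < 0.05)
  }, numeric(1))
  expect_equal(mean(fracs), 0.05, tolerance = 0.3)

  # planted interaction of 3x the noise SD: high recall at alpha 0.05
  noise_sd <- 0.5
  tc2 <- simulate_timecourse(n_genes = 500, diverging_fraction = 0.1,
                             effect = 3 * noise_sd,
                             config = sim_config(32, n_replicates = 2,
                                                 noise_sd = noise_sd))
  fit2 <- fit_divergence(tc2$expr, tc2$design, alpha = 0.05)
  recall <- sum(fit2$selected & tc2$truth) / sum(tc2$truth)
  expect_gte(recall, 0.9)
})

test_that("false selection stays below alpha under the global null", {
  selected <- total <- 0
  for (i in 1:40) {
    tc <- simulate_timecourse(n_genes = 300, diverging_fraction = 0,
                              effect = 0,
                              config = sim_config(400 + i, n_replicates = 2,
                                                  noise_sd = 0.5))
    fit <- fit_divergence(tc$expr, tc$design, alpha = 0.05)
    selected <- selected + sum(fit$selected)
    total <- total + nrow(fit)
  }
  expect_lte(selected / total, 0.05)
})

test_that("gene-group clustering recovers archetype trajectories", {
  design <- data.frame(genotype = rep(c("wild-type", "transgenic"), each = 6),
                       age = rep(c(1, 1, 2, 2, 6, 6), 2))
  g <- as.numeric(design$genotype == "transgenic")
  arch <- cbind(up = design$age * (2 * g - 1),     # up in tg, down in wt
                down = design$age * (1 - 2 * g),   # the mirror image
                both = design$age)                 # shared rise, no divergence
  expr <- arch[, rep(1:3, each = 4)] +
    matrix(rnorm(12 * 12, sd = 0.01), nrow = 12)
  colnames(expr) <- sprintf("g%02d", 1:12)
  cl <- cluster_gene_groups(expr, k = 3)
  truth <- rep(1:3, each = 4)
  expect_equal(length(unique(cl$groups)), 3)
  # same partition up to label permutation
  expect_equal(length(unique(paste(cl$groups, truth))), 3)
  # gene order does not change the partition
  perm <- sample(12)
  cl2 <- cluster_gene_groups(expr[, perm], k = 3)
  expect_equal(length(unique(paste(cl2$groups, truth[perm]))), 3)
  # duplicated genes land together
  dup <- cbind(expr, g13 = expr[, 1])
  cl3 <- cluster_gene_groups(dup, k = 3)
  expect_equal(unname(cl3$groups["g13"]), unname(cl3$groups["g01"]))
  expect_error(cluster_gene_groups(expr[, 1:2], k = 3), "k exceeds")
})

test_that("ward.D2 merge sequence matches the brute-force variance oracle", {
  for (seed in 1:30) {
    set.seed(seed)
    X <- matrix(rnorm(8 * 4), nrow = 8)
    hc <- hclust(dist(X), method = "ward.D2")
    expect_identical(hclust_merge_sets(hc), ward_oracle_merges(X))
  }
})

test_that("signature trajectories aggregate genotype-by-time means of Z", {
  design <- data.frame(genotype = rep(c("wild-type", "transgenic"), each = 4),
                       age = rep(c(1, 1, 6, 6), 2))
  const <- matrix(4, nrow = 8, ncol = 2, dimnames = list(NULL, c("a", "b")))
  expect_warning(tr <- group_signature_trajectory(const, c("a", "b"), design),
                 "zero-variance")
  expect_true(all(tr$mean_score == 0))

  # a single-gene signature reproduces that gene's Z trajectory
  expr <- random_expr(8, c("a", "b"), seed = 2)
  tr1 <- group_signature_trajectory(expr, "a", design)
  z <- (expr[, "a"] - mean(expr[, "a"])) / sd(expr[, "a"])
  manual <- aggregate(z, by = list(design$genotype, design$age), FUN = mean)
  expect_equal(sort(tr1$mean_score), sort(manual$x))

  # diverging genes: transgenic rises while wild-type falls
  tc <- simulate_timecourse(n_genes = 100, diverging_fraction = 0.2,
                            effect = 1,
                            config = sim_config(7, n_replicates = 2,
                                                noise_sd = 0.2))
  div_genes <- colnames(tc$expr)[tc$truth]
  tr2 <- group_signature_trajectory(tc$expr, div_genes, tc$design)
  tg <- tr2[tr2$genotype == "transgenic", ]
  wt <- tr2[tr2$genotype == "wild-type", ]
  expect_true(all(diff(tg$mean_score[order(tg$age)]) > 0))
  expect_true(all(diff(wt$mean_score[order(wt$age)]) < 0))
})

test_that("hypergeometric ORA agrees with the closed-form tail everywhere", {
  # worked case: universe 20, set 5, group 5, overlap 5 -> 1 / C(20, 5)
  universe <- sprintf("u%02d", 1:20)
  res <- ora_hypergeometric(universe[1:5], list(s = universe[1:5]), universe)
  expect_equal(res$p, 1 / choose(20, 5), tolerance = 1e-12)
  # group = set = universe
  expect_equal(ora_hypergeometric(universe, list(s = universe), universe)$p, 1)
  # zero overlap with a small set
  res0 <- ora_hypergeometric(universe[1:2], list(s = universe[19:20]),
                             universe)
  expect_equal(res0$overlap, 0)
  expect_equal(res0$p, 1)
  expect_error(ora_hypergeometric("x", list(s = "u01"), universe),
               "contained")
  expect_error(ora_hypergeometric(universe[1], list(s = character(0)),
                                  universe), "non-empty")

  # exhaustive agreement with exact binomial-coefficient sums (spot universes)
  for (N in c(6, 13, 30)) {
    genes <- sprintf("g%02d", seq_len(N))
    for (g_size in seq_len(N)) {
      group <- genes[seq_len(g_size)]
      sets <- list(); expected <- c()
      for (m in seq_len(N)) {
        for (k in max(0, m - (N - g_size)):min(m, g_size)) {
          if (m - k > N - g_size) next
          nm <- sprintf("m%d_k%d", m, k)
          sets[[nm]] <- c(group[seq_len(k)],
                          genes[setdiff(seq_len(N), seq_len(g_size))][seq_len(m - k)])
          expected[nm] <- hyper_tail_oracle(k, m, g_size, N)
        }
      }
      res <- ora_hypergeometric(group, sets, genes)
      expect_equal(res$p, unname(expected[res$set]), tolerance = 1e-12)
    }
  }
})

test_that("BH adjustment orders q above p across ORA sets", {
  universe <- sprintf("u%02d", 1:25)
  sets <- list(a = universe[1:5], b = universe[3:12], c = universe[20:25])
  res <- ora_hypergeometric(universe[1:6], sets, universe)
  expect_true(all(res$q >= res$p))
  expect_equal(res$q, p.adjust(res$p, "BH"))
})
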