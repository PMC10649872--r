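test_that("dose-response generator follows the Hill curve before noise", {
  doses <- 10^seq(-9, -4, length.out = 6)
  noiseless <- sim_config(7, n_replicates = 2, noise_sd = 0)
  s <- simulate_dose_response(list(ic50 = 1e-6, slope = 1, floor = 0),
                              doses, noiseless)
  # Hill midpoint at d = ic50
  mid <- simulate_dose_response(list(ic50 = 1e-6, slope = 2, floor = 0),
                                c(1e-8, 1e-6), noiseless)
  expect_equal(colMeans(mid$viability)[2], 0.5, ignore_attr = TRUE)
  # untreated limit
  low <- simulate_dose_response(list(ic50 = 1e-6, slope = 1, floor = 0),
                                c(1e-15, 1e-6), noiseless)
  expect_equal(colMeans(low$viability)[1], 1, tolerance = 1e-6,
               ignore_attr = TRUE)
  # hand-derived point: d = 10 * ic50, slope 1 -> 1 / 11
  ten <- simulate_dose_response(list(ic50 = 1e-6, slope = 1, floor = 0),
                                c(1e-8, 1e-5), noiseless)
  expect_equal(colMeans(ten$viability)[2], 1 / 11, tolerance = 1e-12,
               ignore_attr = TRUE)
  # error paths
  expect_error(simulate_dose_response(list(ic50 = 1e-6, slope = 1, floor = 0),
                                      c(1e-6, 1e-7), noiseless),
               "increasing")
  expect_error(sim_config(1, noise_sd = -1), "noise_sd")
})

test_that("combination generator encodes Bliss ground truth exactly", {
  noiseless <- sim_config(3, n_replicates = 1, noise_sd = 0)
  hill <- list(ic50 = 1e-6, slope = 1, floor = 0)
  # at d = ic50 both agents affect 0.5 -> Bliss 0.75, viability 0.25
  s0 <- simulate_combination(hill, hill, c(1e-8, 1e-6), ratio = 1,
                             interaction = 0, config = noiseless)
  expect_equal(s0$viability[1, 2], 0.25, tolerance = 1e-12)
  # additive interaction shift
  s1 <- simulate_combination(hill, hill, c(1e-8, 1e-6), ratio = 1,
                             interaction = 0.1, config = noiseless)
  expect_equal(s1$viability[1, 2], 0.15, tolerance = 1e-12)
  # saturation: agent A fully effective -> combined fraction affected 1
  sat <- simulate_combination(list(ic50 = 1e-12, slope = 4, floor = 0), hill,
                              c(1e-7, 1e-6), ratio = 1, interaction = 0,
                              config = noiseless)
  expect_equal(sat$viability[1, 2], 0, tolerance = 1e-9)
  # clamping keeps fraction affected in [0, 1]
  over <- simulate_combination(hill, hill, c(1e-8, 1e-5), ratio = 1,
                               interaction = 0.9, config = noiseless)
  expect_true(all(over$viability >= 0 & over$viability <= 1))
})

test_that("single-cell generator honors archetypes, LOD and mixing", {
  one_type <- default_ct_archetypes()["neuroblast", , drop = FALSE]
  res <- simulate_ct_matrix(one_type, mix = 1, n_cells = 5,
                            config = sim_config(1, noise_sd = 0))
  expect_true(all(res$labels == "neuroblast"))
  expect_equal(res$ct$ct[1, ], res$ct$ct[5, ])
  # archetype mean at/above LOD -> not detected in noiseless cells
  high <- one_type
  high[1, "Sox10"] <- 24
  res2 <- simulate_ct_matrix(high, mix = 1, n_cells = 3,
                             config = sim_config(1, noise_sd = 0))
  expect_true(all(is.na(res2$ct$ct[, "Sox10"])))

  expect_error(simulate_ct_matrix(mix = c(0.5, 0.3, 0.1), n_cells = 10),
               "sum to 1")

  # label counts near their binomial expectation at n = 1000
  res3 <- simulate_ct_matrix(mix = c(0.5, 0.3, 0.2), n_cells = 1000,
                             config = sim_config(11, noise_sd = 1))
  counts <- table(factor(res3$labels,
                         levels = rownames(default_ct_archetypes())))
  for (i in seq_along(counts)) {
    p <- c(0.5, 0.3, 0.2)[i]
    bounds <- qbinom(c(0.005, 0.995), 1000, p)
    expect_gte(counts[[i]], bounds[1])
    expect_lte(counts[[i]], bounds[2])
  }
})

test_that("timecourse generator plants an exact interaction effect", {
  noiseless <- sim_config(5, n_replicates = 2, noise_sd = 0)
  tc <- simulate_timecourse(n_genes = 40, diverging_fraction = 0.25,
                            effect = 2, config = noiseless)
  fit <- fit_divergence(tc$expr, tc$design)
  expect_equal(fit$beta_interaction[tc$truth], rep(2, sum(tc$truth)),
               tolerance = 1e-10)
  expect_equal(fit$beta_interaction[!tc$truth], rep(0, sum(!tc$truth)),
               tolerance = 1e-10)
  # flag count is exact by construction
  tc2 <- simulate_timecourse(n_genes = 1000, diverging_fraction = 0.1,
                             effect = 1,
                             config = sim_config(1, n_replicates = 2,
                                                 noise_sd = 0.5))
  expect_identical(sum(tc2$truth), 100L)
  # no effect -> no gene is truly divergent
  tc3 <- simulate_timecourse(n_genes = 50, diverging_fraction = 0.1,
                             effect = 0, config = noiseless)
  expect_identical(sum(tc3$truth), 0L)
  expect_error(simulate_timecourse(timepoints = 1), "2 timepoints")
})

test_that("cohort generator fixes class sizes and supports KM", {
  co <- simulate_cohort(n_tumors = 475, class_props = c(0.2, 0.4, 0.4),
                        config = sim_config(2))
  expect_identical(as.vector(table(co$classes)), c(95L, 190L, 190L))
  expect_true(all(co$clinical$time >= 0))
  expect_true(all(co$clinical$event %in% c(0, 1)))
  # degenerate single-class cohort still yields an estimable KM curve
  co1 <- simulate_cohort(n_tumors = 50, class_props = c(1, 0, 0),
                         config = sim_config(3))
  km <- km_estimate(co1$clinical$time, co1$clinical$event)
  expect_true(all(diff(km$survival) <= 1e-12))
  expect_true(all(km$survival >= 0 & km$survival <= 1))
})

test_that("generators are seed-deterministic and leave the caller's RNG alone", {
  cfg <- sim_config(42, n_replicates = 3, noise_sd = 0.1)
  expect_identical(
    simulate_dose_response(list(ic50 = 1e-6, slope = 1, floor = 0),
                           10^seq(-8, -5), cfg),
    simulate_dose_response(list(ic50 = 1e-6, slope = 1, floor = 0),
                           10^seq(-8, -5), cfg))
  expect_identical(simulate_ct_matrix(config = sim_config(9, noise_sd = 1)),
                   simulate_ct_matrix(config = sim_config(9, noise_sd = 1)))
  expect_identical(simulate_cohort(n_tumors = 60, config = sim_config(5)),
                   simulate_cohort(n_tumors = 60, config = sim_config(5)))
  set.seed(123); before <- .Random.seed
  invisible(simulate_timecourse(n_genes = 10,
                                config = sim_config(1, noise_sd = 0.5)))
  expect_identical(.Random.seed, before)
  # different seeds produce different noise
  expect_false(identical(
    simulate_cohort(n_tumors = 60, config = sim_config(5)),
    simulate_cohort(n_tumors = 60, config = sim_config(6))))
})

test_that("replicate spread grows with the configured noise level", {
  spread <- vapply(c(0.01, 0.05, 0.2), function(sd_level) {
    s <- simulate_dose_response(
      list(ic50 = 1e-6, slope = 1, floor = 0.2), 10^seq(-8, -5, 0.5),
      sim_config(8, n_replicates = 50, noise_sd = sd_level))
    mean(apply(s$viability, 2L, sd))
  }, numeric(1))
  expect_true(all(diff(spread) > 0))
})
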