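test_that("phenotype marginals are calibrated at large n", {
  cfg <- cohort_config(n_samples = 100000, seed = 11)
  ph <- simulate_phenotypes(cfg)$phenotypes
  n <- nrow(ph)

  # means of truncated scales hit the configured targets within 3 MC SE
  expect_lt(abs(mean(ph$ctq_total) - 40.5), 3 * sd(ph$ctq_total) / sqrt(n))
  expect_lt(abs(mean(ph$tei) - 4.2), 3 * sd(ph$tei) / sqrt(n))
  expect_lt(abs(mean(ph$age) - 40), 3 * sd(ph$age) / sqrt(n))

  # sds match what the calibrated truncated-normal family attains
  for (sc in c("age", "ctq", "tei")) {
    ach <- cfg[[sc]]$parent$achieved$sd
    col <- switch(sc, age = "age", ctq = "ctq_total", tei = "tei")
    expect_lt(abs(sd(ph[[col]]) - ach), 3 * ach / sqrt(2 * n))
  }

  # ranges respected
  expect_true(all(ph$ctq_total >= 25 & ph$ctq_total <= 93))
  expect_true(all(ph$age >= 19 & ph$age <= 62))
  expect_true(all(ph$tei >= 0))

  # categorical proportions within 3 binomial SE
  p_inc <- as.numeric(table(ph$income) / n)
  for (i in 1:3) {
    p0 <- c(0.30, 0.36, 0.34)[i]
    expect_lt(abs(p_inc[i] - p0), 3 * sqrt(p0 * (1 - p0) / n))
  }
})

test_that("null and planted exposure effects behave under Arm-A style fits", {
  spec <- default_morphometry_specs()
  spec$eff_ctq[spec$outcome == "rmfg_sa"] <- -0.231
  ph <- simulate_phenotypes(cohort_config(n_samples = 100000, seed = 2,
                                          morphometry_specs = spec))$phenotypes
  recs <- fit_arm_a(ph, outcomes = c("rmfg_sa", "sfg_ct"))
  hit <- recs[recs$outcome == "rmfg_sa" & recs$term == "ctq", ]
  expect_lt(abs(hit$beta - (-0.231)), 0.02)
  # untouched outcome: all exposure effects null
  expect_true(all(abs(recs$beta[recs$outcome == "sfg_ct"]) < 0.05))
})

test_that("generators are deterministic under a fixed seed", {
  c1 <- simulate_cohort(cohort_config(n_samples = 40, seed = 5),
                        methylome_config(n_probes = 300, n_cell_probes = 60,
                                         module_sizes = c(10, 10), seed = 5))
  c2 <- simulate_cohort(cohort_config(n_samples = 40, seed = 5),
                        methylome_config(n_probes = 300, n_cell_probes = 60,
                                         module_sizes = c(10, 10), seed = 5))
  expect_identical(c1$beta, c2$beta)
  expect_identical(c1$phenotypes, c2$phenotypes)
  expect_identical(c1$truth$labels, c2$truth$labels)
})

test_that("planted modules drive probe correlations as the factor model predicts", {
  ph <- simulate_phenotypes(cohort_config(n_samples = 500, seed = 3))
  # strong module: loading 3, noise 1 -> pairwise |r| = 9/10
  sim <- simulate_methylome(ph$phenotypes,
    methylome_config(n_probes = 120, module_sizes = 15L, n_cell_probes = 30,
                     n_smoking_probes = 5, bg_structure = "none", seed = 3))
  mvals <- beta_to_m(sim$beta)
  member <- mvals[names(sim$truth$labels)[sim$truth$labels == 1], ]
  r <- cor(t(member))
  expect_gt(mean(abs(r[upper.tri(r)])), 0.8)

  # noiseless module: perfect correlation
  sim0 <- simulate_methylome(ph$phenotypes,
    methylome_config(n_probes = 60, module_sizes = 10L, n_cell_probes = 20,
                     n_smoking_probes = 5, probe_noise_sd = 0,
                     bg_structure = "none", covariate_effects = NULL,
                     seed = 4))
  member0 <- beta_to_m(sim0$beta)[names(sim0$truth$labels)[sim0$truth$labels == 1], ]
  r0 <- cor(t(member0))
  expect_true(all(abs(abs(r0[upper.tri(r0)]) - 1) < 1e-8))
})

test_that("the planted mediation path is encoded in latent factor and outcome", {
  ph <- simulate_phenotypes(cohort_config(n_samples = 10000, seed = 6))
  med <- list(exposure = "ctq_total", module = 1, outcome = "rmfg_sa",
              a = 0.5, b = 0.6, c_prime = 0.2)
  cfg <- methylome_config(n_probes = 150, module_sizes = c(10L, 10L),
                          n_cell_probes = 30, n_smoking_probes = 5,
                          planted_mediation = med, bg_structure = "none",
                          seed = 6)
  sim <- simulate_methylome(ph$phenotypes, cfg)
  f <- sim$truth$latent[, 1]
  xz <- scale(ph$phenotypes$ctq_total)[, 1]
  expect_lt(abs(cor(f, xz) - 0.5), 0.03)
  expect_lt(abs(var(f) - 1), 0.02)

  # b and c' recoverable from the outcome on its configured SD scale
  spec <- default_morphometry_specs()
  y <- (sim$phenotypes$rmfg_sa - spec$mean[spec$outcome == "rmfg_sa"]) /
    spec$sd[spec$outcome == "rmfg_sa"]
  fit <- coef(lm(y ~ f + xz))
  expect_lt(abs(fit[["f"]] - 0.6), 0.05)
  expect_lt(abs(fit[["xz"]] - 0.2), 0.05)

  # null a-path: exposure and latent factor uncorrelated
  cfg0 <- cfg
  cfg0$planted_mediation$a <- 0
  sim0 <- simulate_methylome(ph$phenotypes, cfg0)
  expect_lt(abs(cor(sim0$truth$latent[, 1], xz)), 0.05)
})

test_that("fixture bundles round-trip exactly", {
  sim <- simulate_cohort(cohort_config(n_samples = 25, seed = 9),
                         methylome_config(n_probes = 200, n_cell_probes = 40,
                                          module_sizes = c(10, 10), seed = 9))
  dir <- withr::local_tempdir()
  write_fixture_bundle(sim, dir)
  back <- read_fixture_bundle(dir)
  expect_equal(back$beta, sim$beta)
  expect_equal(back$cell_reference, sim$cell_reference)
  expect_equal(back$phenotypes$ctq_total, sim$phenotypes$ctq_total)
  expect_identical(unlist(back$truth$labels), sim$truth$labels)

  # GMT format: one set per line, name + description + genes
  lines <- readLines(file.path(dir, "gene_sets.gmt"))
  expect_length(lines, length(sim$gene_sets))
  fields <- strsplit(lines[1], "\t")[[1]]
  expect_identical(fields[1], names(sim$gene_sets)[1])
  expect_identical(fields[-(1:2)], unname(sim$gene_sets[[1]]))
})

test_that("configuration errors are caught", {
  expect_error(cohort_config(income_probs = c(0.5, 0.2, 0.2)), "sum")
  expect_error(cohort_config(n_samples = 1), ">= 2")
  expect_error(methylome_config(module_sizes = c(1, 10)), "module size")
  expect_error(methylome_config(planted_mediation = list(
    exposure = "ctq_total", module = 9, outcome = "rmfg_sa",
    a = 1, b = 1, c_prime = 0)), "out of range")
})
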