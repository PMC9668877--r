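test_that("beta to M transform matches the base-2 logit", {
  b <- matrix(c(0.5, 0.8, 0.2, 0), 2, 2)
  m <- beta_to_m(b, epsilon = 1e-6)
  expect_equal(m[1, 1], 0)
  expect_equal(m[2, 1], 2)            # log2(0.8/0.2)
  expect_equal(m[1, 2], -2)
  expect_equal(m[2, 2], log2(1e-6 / (1 - 1e-6)))  # clipped boundary
  expect_error(beta_to_m(matrix(1.2)), "\\[0, 1\\]")
  expect_error(beta_to_m(b, epsilon = 0.6))

  # inverse identity on the interior
  set.seed(1)
  bb <- matrix(runif(200, 0.01, 0.99), 20, 10)
  expect_lt(max(abs(epimediate:::m_to_beta(beta_to_m(bb)) - bb)), 1e-12)
})

test_that("probe filter cascade removes the right probes and is idempotent", {
  ids <- sprintf("p%02d", 1:10)
  ids[3] <- "rs123"
  ann <- data.frame(
    probe_id = ids,
    chrom = c("chrX", "chrX", "chr1", "chr2", "chr3", "chr4", "chr5", "chr6",
              "chr7", "chr8"),
    cross_reactive = c(0, 0, 0, 1, 1, 0, 0, 0, 0, 0),
    bloodbrain_p = c(0.01, 0.01, 0.01, 0.01, 0.01, 0.20, 0.90, 0.01, 0.01,
                     0.001)
  )
  x <- matrix(rnorm(20), 10, 2, dimnames = list(ids, c("s1", "s2")))
  # 2 chrX, 1 rs, 2 cross-reactive, 2 blood-brain failures -> 3 retained
  kept <- filter_probes(x, ann)
  expect_identical(rownames(kept), c("p08", "p09", "p10"))
  expect_identical(filter_probes(kept, ann), kept)

  # identity when nothing is flagged
  ann2 <- data.frame(probe_id = c("a", "b"), chrom = "chr1",
                     cross_reactive = 0, bloodbrain_p = 0.001)
  x2 <- matrix(1:4, 2, 2, dimnames = list(c("a", "b"), NULL))
  expect_identical(filter_probes(x2, ann2), x2)

  # degenerate: everything removed
  ann3 <- data.frame(probe_id = c("a", "b"), chrom = "chrY",
                     cross_reactive = 0, bloodbrain_p = 0.001)
  expect_warning(out <- filter_probes(x2, ann3), "no probes")
  expect_identical(nrow(out), 0L)

  expect_error(filter_probes(x2, ann2[1, , drop = FALSE]), "missing from annotation")
})

test_that("cell deconvolution recovers exact and noisy mixtures", {
  set.seed(2)
  ref <- matrix(runif(6 * 100, 0.05, 0.95), nrow = 6,
                dimnames = list(c("granulocytes", "monocytes", "B", "NK",
                                  "CD4T", "CD8T"),
                                sprintf("cg%03d", 1:100)))
  # exact 0.3 / 0.7 two-type mixture
  mix <- 0.3 * ref["granulocytes", ] + 0.7 * ref["CD4T", ]
  beta <- cbind(s1 = mix, s2 = ref["B", ])
  est <- estimate_cell_proportions(beta, ref)
  expect_lt(abs(est["s1", "granulocytes"] - 0.3), 1e-6)
  expect_lt(abs(est["s1", "CD4T"] - 0.7), 1e-6)
  expect_lt(max(abs(est["s2", ] - c(0, 0, 1, 0, 0, 0))), 1e-6)

  # Dirichlet truth with measurement noise
  ref2 <- matrix(runif(6 * 600, 0.05, 0.95), nrow = 6,
                 dimnames = list(rownames(ref), sprintf("cg9%04d", 1:600)))
  props <- epimediate:::rdirichlet(100, c(30, 4, 2.5, 2, 7.5, 4))
  noisy <- t(props %*% ref2) + matrix(rnorm(600 * 100, 0, 0.02), 600)
  noisy <- pmin(pmax(noisy, 0), 1)
  colnames(noisy) <- sprintf("s%03d", 1:100)
  est2 <- estimate_cell_proportions(noisy, ref2)
  expect_lt(sqrt(mean((est2 - props)^2)), 0.05)

  # invariance to sample order
  est_rev <- estimate_cell_proportions(noisy[, 100:1], ref2)
  expect_equal(est_rev[colnames(noisy), ], est2)

  expect_error(estimate_cell_proportions(beta[1:10, ], ref), "shared")
})

test_that("smoking score is the weighted beta sum over available probes", {
  beta <- matrix(c(0.2, 0.4, 0.1), 3, 1,
                 dimnames = list(c("cgA", "cgB", "cgC"), "s1"))
  tab <- data.frame(probe_id = c("cgA", "cgB", "cgC"),
                    effect = c(0.5, -1.0, 2.0))
  expect_equal(unname(smoking_score(beta, tab)), -0.10)
  tab0 <- transform(tab, effect = 0)
  expect_equal(unname(smoking_score(beta, tab0)), 0)
  # missing probes dropped with a message; zero overlap errors
  tab2 <- rbind(tab, data.frame(probe_id = "cgZZ", effect = 9))
  expect_message(s <- smoking_score(beta, tab2), "missing")
  expect_equal(unname(s), -0.10)
  expect_error(smoking_score(beta, data.frame(probe_id = "x", effect = 1)),
               "no signature probes")
})

test_that("residualization matches the normal equations and removes effects", {
  set.seed(3)
  n <- 60
  design <- cbind(age = rnorm(n, 40, 10), cell = runif(n))
  m <- matrix(rnorm(5 * n), 5, n, dimnames = list(sprintf("p%d", 1:5), NULL))

  # exact fit -> zero residuals
  m_exact <- rbind(lin = 2 * design[, "age"] + 1)
  expect_lt(max(abs(residualize(m_exact, design))), 1e-10)

  # intercept-only design -> centered rows
  r0 <- residualize(m, matrix(numeric(n * 0), n, 0))
  expect_equal(r0, m - rowMeans(m), ignore_attr = TRUE)

  # independent normal-equations oracle
  x <- cbind(1, design)
  proj <- diag(n) - x %*% solve(crossprod(x)) %*% t(x)
  expect_lt(max(abs(residualize(m, design) - m %*% proj)), 1e-8)

  # orthogonality to design columns
  r <- residualize(m, design)
  expect_lt(max(abs(r %*% design)), 1e-8 * n * max(abs(design)))
  expect_lt(max(abs(rowSums(r))), 1e-8)

  expect_error(residualize(m, cbind(design, age2 = design[, "age"])),
               "collinear")
})

test_that("residualization strips a planted age effect from probes", {
  ph <- simulate_phenotypes(cohort_config(n_samples = 1000, seed = 8))
  sim <- simulate_methylome(ph$phenotypes,
    methylome_config(n_probes = 120, module_sizes = integer(0),
                     n_cell_probes = 20, n_smoking_probes = 5,
                     covariate_effects = c(age = 0.5), bg_structure = "none",
                     seed = 8))
  mvals <- beta_to_m(sim$beta)
  bg <- setdiff(rownames(mvals), colnames(sim$cell_reference))
  pre <- apply(mvals[bg, ], 1, cor, y = ph$phenotypes$age)
  expect_gt(max(abs(pre)), 0.3)   # effect present before
  r <- residualize(mvals, cbind(age = ph$phenotypes$age))
  post <- apply(r[bg, ], 1, cor, y = ph$phenotypes$age)
  expect_lt(max(abs(post)), 0.05)
})

test_that("quantile normalization equalizes column distributions", {
  x <- matrix(c(1, 2, 3, 3, 1, 2), 3, 2)   # columns are permutations
  qn <- quantile_normalize(x)
  expect_equal(sort(qn[, 1]), sort(qn[, 2]))
  expect_equal(qn[, 1], x[, 1])            # already the shared distribution

  xx <- cbind(a = c(2, 4, 9), b = c(1, 7, 8))
  # oracle: ranks mapped to across-sample mean order statistics
  oracle <- apply(xx, 2, function(col)
    rowMeans(apply(xx, 2, sort))[rank(col)])
  expect_equal(unname(quantile_normalize(xx)), unname(oracle))

  expect_warning(out <- quantile_normalize(xx[, 1, drop = FALSE]), ">= 2")
  expect_identical(out, xx[, 1, drop = FALSE])
})
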