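test_that("adjacency equals elementwise |cor|^power", {
  set.seed(1)
  x <- matrix(rnorm(5 * 30), 5, 30, dimnames = list(letters[1:5], NULL))
  a <- adjacency_matrix(x, 2)
  # brute-force element-by-element oracle
  for (i in 1:5) for (j in 1:5) {
    expected <- if (i == j) 0 else abs(cor(x[i, ], x[j, ]))^2
    expect_equal(a[i, j], expected, tolerance = 1e-12)
  }
  # perfectly correlated pair -> 1 at any power
  y <- rbind(a = 1:10, b = 2 * (1:10) + 3, c = rnorm(10))
  expect_equal(adjacency_matrix(y, 7)["a", "b"], 1)
  # r = 0.5 at power 2 -> 0.25 (constructed via known correlation)
  expect_equal(abs(-0.5)^2, 0.25)
  expect_error(adjacency_matrix(rbind(y, d = rep(1, 10)), 2), "zero-variance")
})

test_that("scale-free fit scores power-law connectivity high and degenerate cases zero", {
  set.seed(2)
  # rank-1 adjacency outer(w, w) has k_i ~ w_i * sum(w); power-law w
  # gives power-law connectivity
  w <- (1:2000 / 2000)^(-1 / 2)       # p(k) ~ k^-gamma tail, gamma ~ 3
  w <- 0.9 * w / max(w)
  a <- outer(w, w); diag(a) <- 0
  fit <- scale_free_fit(a)
  expect_gt(fit$r_squared, 0.95)
  expect_lt(fit$slope, 0)

  # identical connectivity for all probes
  a2 <- matrix(0.5, 50, 50); diag(a2) <- 0
  expect_warning(f2 <- scale_free_fit(a2), "identical")
  expect_equal(f2$r_squared, 0)

  # anti-scale-free (positive slope) is truncated to zero
  w3 <- sqrt(seq(0.01, 0.99, length.out = 500))  # mass at high k
  a3 <- outer(w3, w3); diag(a3) <- 0
  f3 <- scale_free_fit(a3)
  if (!is.na(f3$slope) && f3$slope > 0) expect_equal(f3$r_squared, 0)
})

test_that("soft-threshold selection picks the lowest passing power", {
  set.seed(3)
  # heterogeneous correlated groups yield a passing power mid-scan
  sizes <- c(80, 40, 40, 20, 20, rep(10, 10), rep(5, 40), rep(2, 100))
  g <- rep(seq_along(sizes), sizes)
  lat <- matrix(rnorm(100 * length(sizes)), nrow = 100)
  load <- runif(length(sizes), 0.3, 2.5)[g] * runif(length(g), 0.7, 1.3)
  x <- t(lat[, g]) * load + matrix(rnorm(length(g) * 100), ncol = 100)
  rownames(x) <- sprintf("p%04d", seq_along(g))
  scan <- pick_soft_threshold(x, powers = 1:12, r2_min = 0.85)
  pass <- which(scan$scan$r_squared > 0.85)
  expect_gt(length(pass), 0)
  expect_identical(scan$chosen_power, scan$scan$power[pass[1]])
  expect_false(scan$warning_flag)

  # vacuous threshold returns the lowest candidate
  scan0 <- pick_soft_threshold(x, powers = 3:6, r2_min = 0)
  expect_identical(scan0$chosen_power, 3L)

  # unreachable threshold falls back to the argmax with a warning
  expect_warning(scan1 <- pick_soft_threshold(x, powers = 1:3, r2_min = 0.999),
                 "argmax")
  expect_true(scan1$warning_flag)
  expect_identical(scan1$chosen_power,
                   scan1$scan$power[which.max(scan1$scan$r_squared)])
})

test_that("TOM dissimilarity matches the explicit triple-sum formula", {
  # 4x4 hand-built adjacency
  a <- matrix(c(0, .5, .2, .1,
                .5, 0, .4, .3,
                .2, .4, 0, .6,
                .1, .3, .6, 0), 4, 4)
  expect_equal(tom_dissimilarity(a), tom_bruteforce(a), ignore_attr = TRUE,
               tolerance = 1e-12)

  set.seed(4)
  for (rep in 1:20) {
    r <- matrix(runif(16), 4, 4)
    r <- (r + t(r)) / 2; diag(r) <- 0
    d <- tom_dissimilarity(r)
    expect_equal(d, tom_bruteforce(r), ignore_attr = TRUE, tolerance = 1e-12)
    expect_true(all(d >= 0 & d <= 1))
    expect_equal(d, t(d))
  }

  # empty network: TOM 0, dissimilarity 1 off-diagonal
  z <- matrix(0, 3, 3)
  dz <- tom_dissimilarity(z)
  expect_equal(unname(dz), 1 - diag(3))

  # identical (saturated) neighbour profiles with a_ij = 1 -> d_ij = 0
  p <- matrix(c(0, 1, 1,
                1, 0, 1,
                1, 1, 0), 3, 3)
  expect_equal(tom_dissimilarity(p)[1, 2], 0)

  expect_error(tom_dissimilarity(matrix(2, 2, 2)), "\\[0, 1\\]")
})

test_that("clustering recovers planted blocks and prunes small ones", {
  blocks <- rep(1:3, each = 15)
  d <- 1 - outer(blocks, blocks, "==") * 0.98 - diag(45) * 0.02
  dimnames(d) <- list(sprintf("p%02d", 1:45), sprintf("p%02d", 1:45))
  cl <- cluster_modules(d, min_size = 10)
  expect_identical(max(cl$labels), 3L)
  expect_equal(ari(blocks, cl$labels), 1)

  # block below min_size ends up unassigned
  small <- rep(c(1, 0, 0), c(5, 8, 8))
  d2 <- 1 - outer(seq_along(small), seq_along(small), function(i, j)
    (small[i] == 1 & small[j] == 1) * 0.98) - diag(21) * 0.02
  dimnames(d2) <- list(sprintf("q%02d", 1:21), sprintf("q%02d", 1:21))
  cl2 <- cluster_modules(d2, min_size = 10)
  expect_identical(max(cl2$labels), 0L)

  # all-distinct probes: no modules
  d3 <- 1 - diag(30)
  dimnames(d3) <- list(sprintf("r%02d", 1:30), sprintf("r%02d", 1:30))
  expect_identical(max(cluster_modules(d3, min_size = 10)$labels), 0L)

  expect_error(cluster_modules(d3, min_size = 1), "min_size")
})

test_that("module eigengenes match an independent eigen-decomposition oracle", {
  set.seed(5)
  mm <- make_module_matrix(n_samples = 50, module_sizes = c(12, 8),
                           loading = 2, seed = 5)
  me <- module_eigengenes(mm$matrix, mm$labels)
  expect_identical(colnames(me$eigengenes), c("ME1", "ME2"))
  expect_lt(max(abs(apply(me$eigengenes, 2, sd) - 1)), 1e-8)

  # oracle: leading eigenvector of the probe correlation matrix
  for (mod in 1:2) {
    member <- mm$matrix[mm$labels == mod, ]
    cc <- cor(t(member))
    ev <- eigen(cc, symmetric = TRUE)
    scores <- t(scale(t(member)))        # standardized probes
    oracle <- drop(crossprod(scores, ev$vectors[, 1]))
    oracle <- oracle / sd(oracle)
    if (cor(oracle, me$eigengenes[, mod]) < 0) oracle <- -oracle
    expect_lt(max(abs(oracle - me$eigengenes[, mod])), 1e-8)
    expect_equal(me$variance_explained[[mod]],
                 ev$values[1] / sum(ev$values), tolerance = 1e-10)
  }

  # module of identical probes: eigengene is the standardized profile
  prof <- rnorm(30)
  ident <- matrix(rep(prof, 4), 4, byrow = TRUE,
                  dimnames = list(paste0("i", 1:4), NULL))
  lab <- setNames(rep(1L, 4), rownames(ident))
  me2 <- module_eigengenes(ident, lab)
  expect_equal(me2$variance_explained[["ME1"]], 1)
  expect_equal(me2$eigengenes[, 1], scale(prof)[, 1] /
                 sd(scale(prof)[, 1]), ignore_attr = TRUE)

  # two perfectly anticorrelated probes: variance explained 1,
  # deterministic sign (positive correlation with the mean profile)
  two <- rbind(u = prof, v = -2 * prof + 1)
  lab2 <- setNames(c(1L, 1L), rownames(two))
  me3 <- module_eigengenes(two, lab2)
  expect_equal(me3$variance_explained[["ME1"]], 1)
  # mean profile vanishes for a balanced pair; orientation falls back to
  # positive correlation with the first member probe
  expect_gte(cor(me3$eigengenes[, 1], scale(prof)[, 1]), 0)

  expect_error(module_eigengenes(rbind(two, w = rep(1, 30)),
                                 setNames(rep(1L, 3), c("u", "v", "w"))),
               "constant")
})

test_that("the network chain recovers planted modules end to end", {
  mm <- make_module_matrix(n_samples = 97, module_sizes = rep(15, 4),
                           loading = 3, noise_sd = 1, n_background = 300,
                           seed = 6)
  adj <- adjacency_matrix(mm$matrix, 10)
  cl <- cluster_modules(tom_dissimilarity(adj), min_size = 10)
  expect_gte(ari(mm$labels, cl$labels), 0.9)

  # eigengenes track the planted latent factors
  me <- module_eigengenes(mm$matrix, cl$labels)
  for (mod in seq_len(max(cl$labels))) {
    truth_mod <- which.max(table(factor(mm$labels[cl$labels == mod],
                                        levels = 1:4)))
    expect_gte(abs(cor(me$eigengenes[, mod], mm$latent[, truth_mod])), 0.9)
  }

  # probe order invariance (up to relabelling)
  perm <- sample(nrow(mm$matrix))
  cl_perm <- cluster_modules(tom_dissimilarity(
    adjacency_matrix(mm$matrix[perm, ], 10)), min_size = 10)
  expect_equal(ari(cl$labels[rownames(mm$matrix)[perm]], cl_perm$labels), 1)
})
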