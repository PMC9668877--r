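# shared helpers for the suite

# adjusted Rand index between two label vectors
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  e <- si * sj / choose(n, 2)
  (sij - e) / ((si + sj) / 2 - e)
}

# brute-force BH step-up: evaluate every k against the definition
bh_bruteforce <- function(p, q, m = length(p)) {
  ord <- order(p)
  ps <- p[ord]
  best <- 0
  for (k in seq_along(ps)) {
    if (ps[k] <= (k / m) * q) best <- k
  }
  if (best == 0) return(logical(length(p)))
  p <= ps[best]
}

# brute-force TOM dissimilarity via the explicit triple sum
tom_bruteforce <- function(a) {
  p <- nrow(a)
  k <- rowSums(a)
  d <- matrix(0, p, p)
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (i == j) next
      l <- 0
      for (u in seq_len(p)) l <- l + a[i, u] * a[u, j]
      d[i, j] <- 1 - (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
  }
  d
}

# small planted-module residual matrix with known labels (no covariates)
make_module_matrix <- function(n_samples = 97, module_sizes = rep(15, 3),
                               loading = 3, noise_sd = 1, n_background = 0,
                               seed = 1) {
  set.seed(seed)
  k <- length(module_sizes)
  n_mod <- sum(module_sizes)
  labels <- c(rep(seq_len(k), module_sizes), rep(0L, n_background))
  latent <- matrix(rnorm(n_samples * k), ncol = k)
  x <- matrix(rnorm((n_mod + n_background) * n_samples, sd = noise_sd),
              ncol = n_samples)
  x[seq_len(n_mod), ] <- x[seq_len(n_mod), ] +
    loading * t(latent[, labels[seq_len(n_mod)], drop = FALSE])
  rownames(x) <- sprintf("p%05d", seq_len(nrow(x)))
  names(labels) <- rownames(x)
  list(matrix = x, labels = labels, latent = latent)
}

# the bundled published-style exposure -> morphometry screening table
example_screen_table <- function() {
  read.delim(system.file("extdata", "example_arm_a_screen.tsv",
                         package = "epimediate"))
}

# mediation triple generated from the linear structural model
# m = a x + e_m, y = c' x + b m + e_y
make_mediation_data <- function(n, a, b, c_prime, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  m <- a * x + rnorm(n)
  y <- c_prime * x + b * m + rnorm(n)
  list(x = x, m = m, y = y)
}
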