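#' Methylome generator configuration
#'
#' Describes an EPIC-like probe universe with planted co-methylated modules,
#' covariate effects, a reference-mixture block for cell-type deconvolution,
#' a polyepigenetic smoking signature, and an optional planted mediation
#' path exposure -> module latent factor -> morphometry outcome.
#'
#' @param n_probes total probes.
#' @param module_sizes integer vector of planted module sizes (each >= 2).
#' @param module_latent_sd loading of member probes on the module latent
#'   factor, in M-value units (the latent factor has unit variance).
#' @param probe_noise_sd per-probe Gaussian noise SD, M-value units.
#' @param planted_mediation `NULL`, or a list with `exposure` (phenotype
#'   column), `module` (index into `module_sizes`), `outcome` (morphometry
#'   column), and standardized paths `a`, `b`, `c_prime`.
#' @param covariate_effects named numeric vector: SD of the per-probe effect
#'   of each (standardized) phenotype covariate on M-values.
#' @param n_cell_probes probes reserved as cell-type discriminating loci,
#'   generated as a noisy mixture of the cell reference profiles.
#' @param cell_alpha Dirichlet concentration for true leukocyte fractions
#'   (granulocytes, monocytes, B, NK, CD4T, CD8T).
#' @param n_smoking_probes probes carrying the smoking signature.
#' @param smoking_prevalence fraction of current smokers.
#' @param bg_structure background correlation structure: `"powerlaw"`
#'   (default) organizes background probes into correlated groups with
#'   power-law-distributed sizes, which reproduces the approximately
#'   scale-free connectivity seen on real arrays and lets the
#'   soft-threshold scan find a passing power; `"none"` leaves the
#'   background as independent noise (clean ground truth for planted-module
#'   recovery studies).
#' @param bg_gamma power-law exponent for background group sizes.
#' @param bg_loading_range uniform range of per-group loadings (probes get
#'   an additional mild jitter around their group loading).
#' @param frac_chrXY,frac_cross_reactive fractions of *background* probes
#'   annotated to sex chromosomes / flagged cross-reactive.
#' @param frac_bloodbrain_pass fraction of background probes with a nominally
#'   significant blood-brain correlation (planted module and cell probes are
#'   always annotated as passing so ground truth survives filtering).
#' @param n_genes size of the gene universe used for probe annotation.
#' @param seed integer RNG seed.
#' @return object of class `methylome_config`.
#' @export
methylome_config <- function(n_probes = 2000,
                             module_sizes = rep(15L, 8),
                             module_latent_sd = 3,
                             probe_noise_sd = 1,
                             planted_mediation = NULL,
                             covariate_effects = c(age = 0.02),
                             n_cell_probes = 300,
                             cell_alpha = c(granulocytes = 30, monocytes = 4,
                                            B = 2.5, NK = 2, CD4T = 7.5, CD8T = 4),
                             n_smoking_probes = 26,
                             smoking_prevalence = 0.3,
                             bg_structure = c("powerlaw", "none"),
                             bg_gamma = 2.5,
                             bg_loading_range = c(0.3, 2.5),
                             frac_chrXY = 0.03,
                             frac_cross_reactive = 0.05,
                             frac_bloodbrain_pass = 0.5,
                             n_genes = 800,
                             seed = 1L) {
  if (any(module_sizes < 2)) stop("each module size must be >= 2", call. = FALSE)
  if (sum(module_sizes) + n_cell_probes + n_smoking_probes > n_probes) {
    stop("module, cell and smoking probes exceed n_probes", call. = FALSE)
  }
  fr <- c(frac_chrXY, frac_cross_reactive, frac_bloodbrain_pass)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0,1]", call. = FALSE)
  if (!is.null(planted_mediation)) {
    need <- c("exposure", "module", "outcome", "a", "b", "c_prime")
    if (!all(need %in% names(planted_mediation))) {
      stop("planted_mediation needs fields: ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    if (planted_mediation$module < 1 ||
        planted_mediation$module > length(module_sizes)) {
      stop("mediation module index out of range", call. = FALSE)
    }
  }
  bg_structure <- match.arg(bg_structure)
  structure(list(
    n_probes = as.integer(n_probes),
    module_sizes = as.integer(module_sizes),
    module_latent_sd = module_latent_sd,
    probe_noise_sd = probe_noise_sd,
    planted_mediation = planted_mediation,
    covariate_effects = covariate_effects,
    n_cell_probes = as.integer(n_cell_probes),
    cell_alpha = cell_alpha,
    n_smoking_probes = as.integer(n_smoking_probes),
    smoking_prevalence = smoking_prevalence,
    bg_structure = bg_structure,
    bg_gamma = bg_gamma,
    bg_loading_range = bg_loading_range,
    frac_chrXY = frac_chrXY,
    frac_cross_reactive = frac_cross_reactive,
    frac_bloodbrain_pass = frac_bloodbrain_pass,
    n_genes = as.integer(n_genes),
    seed = as.integer(seed)
  ), class = "methylome_config")
}

# unique Illumina-style probe ids
make_probe_ids <- function(n) sprintf("cg%08d", sample.int(99999999L, n))

#' Simulate an EPIC-like methylome for a phenotype table
#'
#' Planted module m has a unit-variance latent factor `f_m` per sample;
#' member probe M-values are `baseline + loading * f_m + covariate effects +
#' noise`. For the mediation module, `f_m = a * z(exposure) + sqrt(1-a^2) *
#' noise`, and `b * f_m + c_prime * z(exposure)` is added to the designated
#' morphometry outcome (on its standardized scale) after base generation, so
#' the planted total effect is exactly `a*b + c_prime`. M-values are
#' returned as beta values via the inverse base-2 logit. A reserved block of
#' probes is generated as a noisy mixture of a 6-cell-type reference panel;
#' another block carries a smoking signature.
#'
#' @param pheno phenotype data.frame from [simulate_phenotypes()].
#' @param config a [methylome_config()].
#' @return list with `beta` (probes x samples), `annotation` (data.frame),
#'   `phenotypes` (possibly modified by the planted b-path),
#'   `cell_reference` (cell-type x probe mean betas), `smoking_effects`
#'   (probe_id, effect), and `truth` (module labels, latent factors, planted
#'   paths, true cell fractions, covariate effects).
#' @export
simulate_methylome <- function(pheno, config) {
  stopifnot(inherits(config, "methylome_config"), is.data.frame(pheno))
  n <- nrow(pheno)
  set.seed(config$seed)

  p_total <- config$n_probes
  probe_ids <- make_probe_ids(p_total)
  sizes <- config$module_sizes
  k_mod <- length(sizes)
  idx_module <- seq_len(sum(sizes))
  idx_cell <- sum(sizes) + seq_len(config$n_cell_probes)
  idx_smoke <- sum(sizes) + config$n_cell_probes + seq_len(config$n_smoking_probes)
  idx_bg <- setdiff(seq_len(p_total), c(idx_module, idx_cell, idx_smoke))
  labels <- integer(p_total)
  labels[idx_module] <- rep(seq_len(k_mod), sizes)

  # latent factors, standardized to exact unit sample variance
  latent <- matrix(stats::rnorm(n * k_mod), nrow = n)
  med <- config$planted_mediation
  if (!is.null(med)) {
    x <- pheno[[med$exposure]]
    if (is.null(x)) stop("exposure column not found: ", med$exposure, call. = FALSE)
    xz <- zscore(x)
    latent[, med$module] <- med$a * xz + sqrt(max(0, 1 - med$a^2)) *
      stats::rnorm(n)
  }
  latent <- scale(latent)
  attr(latent, "scaled:center") <- NULL
  attr(latent, "scaled:scale") <- NULL

  # baseline M-values and per-probe covariate effects
  baseline <- stats::rnorm(p_total, 0, 1.5)
  m <- matrix(stats::rnorm(p_total * n, 0, config$probe_noise_sd),
              nrow = p_total) + baseline
  m[idx_module, ] <- m[idx_module, ] +
    config$module_latent_sd * t(latent[, labels[idx_module], drop = FALSE])

  # optional background co-methylation: power-law-sized correlated groups
  bg_groups <- rep(0L, length(idx_bg))
  if (config$bg_structure == "powerlaw" && length(idx_bg)) {
    n_bg <- length(idx_bg)
    sizes_bg <- integer(0)
    while (sum(sizes_bg) < n_bg) {
      sizes_bg <- c(sizes_bg,
                    min(120L, ceiling(stats::runif(1)^(-1 / (config$bg_gamma - 1)))))
    }
    sizes_bg[length(sizes_bg)] <- n_bg - sum(sizes_bg[-length(sizes_bg)])
    sizes_bg <- sizes_bg[sizes_bg > 0]
    bg_groups <- rep(seq_along(sizes_bg), sizes_bg)
    bg_latent <- matrix(stats::rnorm(n * length(sizes_bg)), nrow = n)
    # group-level loading heterogeneity (a continuum of cluster strengths)
    # plus mild per-probe jitter; this is what yields the approximately
    # scale-free connectivity spectrum of real co-methylation networks
    group_load <- stats::runif(length(sizes_bg), config$bg_loading_range[1],
                               config$bg_loading_range[2])
    bg_load <- group_load[bg_groups] * stats::runif(n_bg, 0.7, 1.3)
    m[idx_bg, ] <- m[idx_bg, ] + t(bg_latent[, bg_groups, drop = FALSE]) * bg_load
  }

  cov_true <- list()
  for (cv in names(config$covariate_effects)) {
    v <- pheno[[cv]]
    if (is.null(v)) stop("covariate column not found: ", cv, call. = FALSE)
    eff <- stats::rnorm(p_total, 0, config$covariate_effects[[cv]])
    m <- m + outer(eff, zscore(v))
    cov_true[[cv]] <- eff
  }

  # smoking signature: latent intensity, per-probe effects (M units)
  smoke_status <- stats::rbinom(n, 1, config$smoking_prevalence)
  smoke_intensity <- smoke_status * stats::rnorm(n, 1, 0.25)
  smoke_eff <- stats::rnorm(config$n_smoking_probes, 0, 0.6)
  m[idx_smoke, ] <- m[idx_smoke, ] + outer(smoke_eff, smoke_intensity)

  beta <- m_to_beta(m)

  # cell-type block: noisy mixture of reference profiles, on beta scale
  cells <- names(config$cell_alpha)
  props <- rdirichlet(n, config$cell_alpha)
  colnames(props) <- cells
  ref <- matrix(stats::runif(length(cells) * config$n_cell_probes, 0.05, 0.95),
                nrow = length(cells),
                dimnames = list(cells, probe_ids[idx_cell]))
  mix <- t(props %*% ref) + matrix(stats::rnorm(config$n_cell_probes * n, 0, 0.01),
                                   nrow = config$n_cell_probes)
  beta[idx_cell, ] <- pmin(pmax(mix, 1e-4), 1 - 1e-4)
  dimnames(beta) <- list(probe_ids, pheno$sample_id)

  # b-path injection into the phenotype table (standardized outcome scale)
  if (!is.null(med)) {
    y <- pheno[[med$outcome]]
    if (is.null(y)) stop("outcome column not found: ", med$outcome, call. = FALSE)
    sdy <- stats::sd(y)
    pheno[[med$outcome]] <- y +
      sdy * (med$b * latent[, med$module] + med$c_prime * zscore(pheno[[med$exposure]]))
  }

  annotation <- simulate_annotation(probe_ids, labels, idx_bg, config)
  truth <- list(
    labels = stats::setNames(labels, probe_ids),
    latent = latent,
    planted_mediation = med,
    cell_proportions = props,
    covariate_effects = cov_true,
    background_groups = stats::setNames(bg_groups, probe_ids[idx_bg]),
    smoking = list(intensity = smoke_intensity, effects = smoke_eff)
  )
  list(beta = beta, annotation = annotation, phenotypes = pheno,
       cell_reference = ref,
       smoking_effects = data.frame(probe_id = probe_ids[idx_smoke],
                                    effect = smoke_eff,
                                    stringsAsFactors = FALSE),
       truth = truth)
}

simulate_annotation <- function(probe_ids, labels, idx_bg, config) {
  p_total <- length(probe_ids)
  chrom <- paste0("chr", sample(1:22, p_total, replace = TRUE))
  cross <- integer(p_total)
  bb_p <- stats::runif(p_total, 0, 0.049)
  n_bg <- length(idx_bg)
  # flags and failing blood-brain p-values only on background probes
  chrom[sample(idx_bg, round(config$frac_chrXY * n_bg))] <-
    sample(c("chrX", "chrY"), round(config$frac_chrXY * n_bg), replace = TRUE)
  cross[sample(idx_bg, round(config$frac_cross_reactive * n_bg))] <- 1L
  fail_bb <- sample(idx_bg, round((1 - config$frac_bloodbrain_pass) * n_bg))
  bb_p[fail_bb] <- stats::runif(length(fail_bb), 0.05, 1)

  genes <- sprintf("GENE%04d", seq_len(config$n_genes))
  gene <- sample(genes, p_total, replace = TRUE)
  gene[sample.int(p_total, round(0.1 * p_total))] <- ""

  data.frame(
    probe_id = probe_ids,
    chrom = chrom,
    pos = sample.int(2.4e8, p_total),
    gene = gene,
    cross_reactive = cross,
    bloodbrain_p = bb_p,
    module_truth = labels,
    stringsAsFactors = FALSE
  )
}

#' Simulate gene sets in GMT form
#'
#' Draws random sets from an annotation's gene universe, optionally planting
#' one enriched set built from the genes of designated probes.
#'
#' @param annotation probe annotation with a `gene` column.
#' @param n_sets number of random sets.
#' @param size_range set sizes drawn uniformly in this range.
#' @param planted_genes optional character vector forming an extra set named
#'   `"planted_set"`.
#' @param seed RNG seed.
#' @return named list of gene character vectors.
#' @export
simulate_gene_sets <- function(annotation, n_sets = 40, size_range = c(25, 60),
                               planted_genes = NULL, seed = 1L) {
  set.seed(seed)
  universe <- unique(annotation$gene[annotation$gene != ""])
  sets <- lapply(seq_len(n_sets), function(i) {
    sample(universe, min(length(universe),
                         sample(size_range[1]:size_range[2], 1)))
  })
  names(sets) <- sprintf("SET%03d", seq_len(n_sets))
  if (!is.null(planted_genes)) sets$planted_set <- unique(planted_genes)
  sets
}

#' Simulate a full study bundle
#'
#' Convenience wrapper chaining [simulate_phenotypes()] and
#' [simulate_methylome()] (the returned phenotype table carries any planted
#' b-path) plus gene sets.
#'
#' @param cohort a [cohort_config()].
#' @param methylome a [methylome_config()].
#' @return list as [simulate_methylome()] plus `gene_sets` and
#'   `phenotype_truth`.
#' @export
simulate_cohort <- function(cohort = cohort_config(),
                            methylome = methylome_config()) {
  ph <- simulate_phenotypes(cohort)
  sim <- simulate_methylome(ph$phenotypes, methylome)
  sim$gene_sets <- simulate_gene_sets(sim$annotation, seed = methylome$seed)
  sim$phenotype_truth <- ph$truth
  sim
}
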