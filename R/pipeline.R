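#' Pipeline configuration
#'
#' Collects every tunable parameter of the end-to-end chain. Defaults are
#' the analysis constants used throughout the package: beta clipping
#' epsilon 1e-6, blood-brain gate 0.05, candidate powers 1..20 with
#' scale-free threshold 0.90, minimum module size 10, fixed tree cut at
#' 0.995 of the maximum merge height, FDR q = 0.10, nominal alpha = 0.05
#' and 10,000 quasi-Bayesian draws.
#'
#' @param epsilon beta clipping bound.
#' @param bloodbrain_alpha blood-brain correlation gate.
#' @param powers candidate soft-threshold powers.
#' @param r2_min scale-free fit threshold.
#' @param min_module_size minimum module size.
#' @param cut_height tree-cut fraction.
#' @param fdr_q accepted false discovery rate.
#' @param alpha nominal significance gate.
#' @param n_draws Monte Carlo draws for mediation.
#' @param seed master seed; each stage derives its own seed from it.
#' @param cohort,methylome generator configs used by the simulate stage.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(epsilon = 1e-6, bloodbrain_alpha = 0.05,
                            powers = 1:20, r2_min = 0.90,
                            min_module_size = 10, cut_height = 0.995,
                            fdr_q = 0.10, alpha = 0.05, n_draws = 10000,
                            seed = 1L,
                            cohort = cohort_config(seed = seed),
                            methylome = methylome_config(seed = seed)) {
  stopifnot(fdr_q > 0, fdr_q < 1, alpha > 0, alpha < 1)
  structure(list(
    epsilon = epsilon, bloodbrain_alpha = bloodbrain_alpha,
    powers = powers, r2_min = r2_min, min_module_size = min_module_size,
    cut_height = cut_height, fdr_q = fdr_q, alpha = alpha,
    n_draws = n_draws, seed = as.integer(seed),
    cohort = cohort, methylome = methylome
  ), class = "pipeline_config")
}

#' Serialize / load a pipeline configuration (YAML)
#'
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  strip <- function(x) {
    if (is.data.frame(x)) return(x)
    if (is.list(x)) return(lapply(x, strip))
    x
  }
  yaml::write_yaml(strip(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  rc <- raw$cohort
  cohort <- cohort_config(
    n_samples = rc$n_samples,
    age_mean = rc$age$mean, age_sd = rc$age$sd,
    age_range = unlist(rc$age$range),
    ctq_mean = rc$ctq$mean, ctq_sd = rc$ctq$sd,
    ctq_range = unlist(rc$ctq$range),
    tei_mean = rc$tei$mean, tei_sd = rc$tei$sd,
    tei_range = unlist(rc$tei$range),
    income_probs = unlist(rc$income_probs),
    education_probs = unlist(rc$education_probs),
    employment_probs = unlist(rc$employment_probs),
    n_ancestry_dims = rc$n_ancestry_dims, ancestry_sd = rc$ancestry_sd,
    icv_mean = rc$icv$mean, icv_sd = rc$icv$sd,
    morphometry_specs = as.data.frame(lapply(rc$morphometry_specs, unlist),
                                      stringsAsFactors = FALSE),
    seed = rc$seed)
  rm <- raw$methylome
  methylome <- methylome_config(
    n_probes = rm$n_probes, module_sizes = unlist(rm$module_sizes),
    module_latent_sd = rm$module_latent_sd,
    probe_noise_sd = rm$probe_noise_sd,
    planted_mediation = rm$planted_mediation,
    covariate_effects = unlist(rm$covariate_effects),
    n_cell_probes = rm$n_cell_probes, cell_alpha = unlist(rm$cell_alpha),
    n_smoking_probes = rm$n_smoking_probes,
    smoking_prevalence = rm$smoking_prevalence,
    bg_structure = rm$bg_structure, bg_gamma = rm$bg_gamma,
    bg_loading_range = unlist(rm$bg_loading_range),
    frac_chrXY = rm$frac_chrXY,
    frac_cross_reactive = rm$frac_cross_reactive,
    frac_bloodbrain_pass = rm$frac_bloodbrain_pass,
    n_genes = rm$n_genes, seed = rm$seed)
  pipeline_config(
    epsilon = raw$epsilon, bloodbrain_alpha = raw$bloodbrain_alpha,
    powers = unlist(raw$powers), r2_min = raw$r2_min,
    min_module_size = raw$min_module_size, cut_height = raw$cut_height,
    fdr_q = raw$fdr_q, alpha = raw$alpha, n_draws = raw$n_draws,
    seed = raw$seed, cohort = cohort, methylome = methylome)
}

pipeline_stages <- c("simulate", "preprocess", "network", "screen",
                     "mediate", "enrich")

stage_seed <- function(config, stage) {
  config$seed + 1000L * match(stage, pipeline_stages)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_manifest <- function(outdir, stage, config, files) {
  cfg_path <- file.path(outdir, "config.yaml")
  write_pipeline_config(config, cfg_path)
  manifest <- list(
    stage = stage,
    seed = stage_seed(config, stage),
    master_seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    package_version = as.character(utils::packageVersion("epimediate")),
    files = as.list(files)
  )
  jsonlite::write_json(manifest, file.path(outdir, paste0("manifest_", stage,
                                                          ".json")),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

require_stage <- function(outdir, stage, file) {
  path <- file.path(outdir, file)
  if (!file.exists(path)) {
    stop("missing artifact '", file, "': run stage '", stage, "' first",
         call. = FALSE)
  }
  path
}

#' Run the analysis pipeline
#'
#' Executes the requested stage (or `"all"`) against `outdir`. Stages:
#' `simulate` writes a synthetic study bundle; `preprocess` filters probes,
#' estimates cell fractions and the smoking score, and residualizes
#' M-values; `network` scans soft thresholds, clusters the TOM
#' dissimilarity and writes eigengenes; `screen` fits the three regression
#' arms, applies BH flags and gates mediation candidates; `mediate` runs
#' the quasi-Bayesian mediation on every candidate plus a probe-wise
#' dissection of full-mediator modules; `enrich` runs the probe-wise
#' exposure scan and gene-set over-representation. Every stage records a
#' manifest (stage seed, config hash, file list) so deterministic stages
#' re-run bit-identically.
#'
#' @param stage one of `"simulate"`, `"preprocess"`, `"network"`,
#'   `"screen"`, `"mediate"`, `"enrich"`, `"all"`.
#' @param config a [pipeline_config()].
#' @param outdir working/output directory.
#' @return invisibly, the stage's principal result.
#' @export
run_pipeline <- function(stage = "all", config = pipeline_config(),
                         outdir = ".") {
  stage <- match.arg(stage, c(pipeline_stages, "all"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (stage == "all") {
    for (s in pipeline_stages) run_pipeline(s, config, outdir)
    return(invisible(NULL))
  }
  switch(stage,
    simulate = stage_simulate(config, outdir),
    preprocess = stage_preprocess(config, outdir),
    network = stage_network(config, outdir),
    screen = stage_screen(config, outdir),
    mediate = stage_mediate(config, outdir),
    enrich = stage_enrich(config, outdir)
  )
}

stage_simulate <- function(config, outdir) {
  cohort <- config$cohort
  methylome <- config$methylome
  cohort$seed <- stage_seed(config, "simulate")
  methylome$seed <- stage_seed(config, "simulate")
  sim <- simulate_cohort(cohort, methylome)
  paths <- write_fixture_bundle(sim, outdir)
  write_manifest(outdir, "simulate", config, paths)
  invisible(sim)
}

stage_preprocess <- function(config, outdir) {
  require_stage(outdir, "simulate", "beta.tsv")
  bundle <- read_fixture_bundle(outdir)
  beta <- filter_probes(bundle$beta, bundle$annotation,
                        config$bloodbrain_alpha)
  cells <- estimate_cell_proportions(bundle$beta, bundle$cell_reference)
  smoke <- smoking_score(bundle$beta, bundle$smoking_effects)
  m <- beta_to_m(beta, config$epsilon)
  design <- covariate_design(bundle$phenotypes, cells, smoke)
  resid <- residualize(m, design)
  files <- c(residuals = file.path(outdir, "residual_m.tsv"),
             covariates = file.path(outdir, "covariates.tsv"))
  write_matrix_tsv(resid, files[["residuals"]])
  write_matrix_tsv(`rownames<-`(design, bundle$phenotypes$sample_id),
                   files[["covariates"]], id_col = "sample_id")
  write_manifest(outdir, "preprocess", config, files)
  invisible(resid)
}

stage_network <- function(config, outdir) {
  resid <- read_matrix_tsv(require_stage(outdir, "preprocess",
                                         "residual_m.tsv"))
  scan <- pick_soft_threshold(resid, config$powers, config$r2_min)
  adj <- adjacency_matrix(resid, scan$chosen_power)
  diss <- tom_dissimilarity(adj)
  cl <- cluster_modules(diss, config$min_module_size, config$cut_height)
  mes <- module_eigengenes(resid, cl$labels)
  files <- c(scan = file.path(outdir, "soft_threshold_scan.tsv"),
             modules = file.path(outdir, "module_assignments.tsv"),
             eigengenes = file.path(outdir, "eigengenes.tsv"))
  write_tsv(scan$scan, files[["scan"]])
  write_tsv(data.frame(probe_id = names(cl$labels),
                       module_index = unname(cl$labels),
                       module_color_alias = unname(cl$colors),
                       stringsAsFactors = FALSE), files[["modules"]])
  write_matrix_tsv(mes$eigengenes, files[["eigengenes"]],
                   id_col = "sample_id")
  write_manifest(outdir, "network", config, files)
  invisible(mes)
}

stage_screen <- function(config, outdir) {
  mes <- read_matrix_tsv(require_stage(outdir, "network", "eigengenes.tsv"))
  pheno <- read_fixture_bundle(outdir)$phenotypes
  arm_a <- fit_arm_a(pheno)
  arm_a$bh_significant <- bh_adjust(arm_a$p, config$fdr_q)
  arm_b <- fit_arm_b(mes, pheno)
  arm_b$bh_significant <- unsplit(
    lapply(split(arm_b$p, arm_b$term),
           function(p) bh_adjust(p, config$fdr_q, m = attr(arm_b, "m"))),
    arm_b$term)
  arm_c <- fit_arm_c(mes, pheno)
  arm_c$bh_significant <- bh_adjust(arm_c$p, config$fdr_q)
  cand <- gate_candidates(arm_a, arm_b, arm_c, config$alpha)
  files <- c(arm_a = file.path(outdir, "arm_a.tsv"),
             arm_b = file.path(outdir, "arm_b.tsv"),
             arm_c = file.path(outdir, "arm_c.tsv"),
             candidates = file.path(outdir, "mediation_candidates.tsv"))
  write_tsv(arm_a, files[["arm_a"]])
  write_tsv(arm_b, files[["arm_b"]])
  write_tsv(arm_c, files[["arm_c"]])
  write_tsv(cand, files[["candidates"]])
  write_manifest(outdir, "screen", config, files)
  invisible(list(arm_a = arm_a, arm_b = arm_b, arm_c = arm_c,
                 candidates = cand))
}

# Mediator-model covariates mirror Arm B (other exposures + employment,
# minus the exposure of interest); outcome-model covariates mirror Arm C.
mediation_model_frames <- function(pheno, exposure) {
  pheno <- standardize_continuous(relevel_exposures(pheno))
  anc_z <- paste0(ancestry_cols(pheno), "_z")
  expo_col <- switch(exposure, ctq = "ctq_z", tei = "tei_z",
                     income_low = "income", education_low = "education")
  med_cols <- setdiff(c("income", "education", "ctq_z", "tei_z", "employment"),
                      expo_col)
  list(
    mediator = pheno[, med_cols, drop = FALSE],
    outcome = pheno[, c("age_z", anc_z, "employment"), drop = FALSE],
    pheno = pheno
  )
}

exposure_vector <- function(pheno, exposure) {
  switch(exposure,
    ctq = zscore(pheno$ctq_total),
    tei = zscore(pheno$tei),
    income_low = as.numeric(pheno$income == "income_0_499"),
    education_low = as.numeric(pheno$education == "edu_less_hs"),
    stop("unknown exposure: ", exposure, call. = FALSE))
}

stage_mediate <- function(config, outdir) {
  cand <- utils::read.delim(require_stage(outdir, "screen",
                                          "mediation_candidates.tsv"),
                            stringsAsFactors = FALSE)
  mes <- read_matrix_tsv(file.path(outdir, "eigengenes.tsv"))
  resid <- read_matrix_tsv(file.path(outdir, "residual_m.tsv"))
  assign <- utils::read.delim(file.path(outdir, "module_assignments.tsv"),
                              stringsAsFactors = FALSE)
  labels <- stats::setNames(assign$module_index, assign$probe_id)
  pheno <- read_fixture_bundle(outdir)$phenotypes
  seed0 <- stage_seed(config, "mediate")

  rows <- list(); probe_rows <- list()
  for (i in seq_len(nrow(cand))) {
    expo <- cand$exposure[i]; me <- cand$module[i]; brain <- cand$outcome[i]
    frames <- mediation_model_frames(pheno, expo)
    x <- exposure_vector(pheno, expo)
    y <- zscore(pheno[[brain]], brain)
    mvec <- zscore(mes[, me], me)
    rec <- quasi_bayes_mediate(
      x, mvec, y,
      cov_mediator = frames$mediator,
      cov_outcome = frames$outcome,
      n_draws = config$n_draws, seed = seed0 + i, alpha = config$alpha)
    est <- rec$estimates
    row <- data.frame(exposure = expo, mediator = me, outcome = brain,
                      stringsAsFactors = FALSE)
    for (eff in c("IDE", "DE", "TE")) {
      e <- est[est$effect == eff, ]
      row[[paste0(tolower(eff), "_beta")]] <- e$estimate
      row[[paste0(tolower(eff), "_ci_lower")]] <- e$ci_lower
      row[[paste0(tolower(eff), "_ci_upper")]] <- e$ci_upper
      row[[paste0(tolower(eff), "_p")]] <- e$p
    }
    row$classification <- rec$classification
    row$proportion_mediated <- rec$proportion_mediated
    rows[[i]] <- row
    if (rec$classification == "full") {
      midx <- as.integer(sub("^ME", "", me))
      pw <- probewise_mediate(resid, labels, midx, x, y,
                              cov_mediator = frames$mediator,
                              cov_outcome = frames$outcome,
                              n_draws = config$n_draws,
                              seed = seed0 + 1000L * i, q = config$fdr_q,
                              alpha = config$alpha)
      pw <- cbind(data.frame(exposure = expo, mediator = me, outcome = brain,
                             stringsAsFactors = FALSE), pw)
      probe_rows[[length(probe_rows) + 1]] <- pw
    }
  }
  med <- if (length(rows)) do.call(rbind, rows) else
    data.frame(exposure = character(), mediator = character(),
               outcome = character())
  files <- c(mediation = file.path(outdir, "mediation.tsv"))
  write_tsv(med, files[["mediation"]])
  if (length(probe_rows)) {
    files <- c(files, probewise = file.path(outdir, "mediation_probewise.tsv"))
    write_tsv(do.call(rbind, probe_rows), files[["probewise"]])
  }
  write_manifest(outdir, "mediate", config, files)
  invisible(med)
}

stage_enrich <- function(config, outdir) {
  resid <- read_matrix_tsv(require_stage(outdir, "preprocess",
                                         "residual_m.tsv"))
  bundle <- read_fixture_bundle(outdir)
  med_path <- file.path(outdir, "mediation.tsv")
  exposure <- "ctq"
  if (file.exists(med_path)) {
    med <- utils::read.delim(med_path, stringsAsFactors = FALSE)
    full <- med$exposure[med$classification == "full"]
    if (length(full)) exposure <- full[1]
  }
  ewas <- probewise_ewas(resid, bundle$phenotypes, exposure, config$alpha)
  gene_p <- probes_to_gene_p(stats::setNames(ewas$p, ewas$probe_id),
                             bundle$annotation)
  sets <- gene_set_test(gene_p, bundle$gene_sets, alpha = config$alpha)
  files <- c(ewas = file.path(outdir, "probewise_ewas.tsv"),
             gene_sets = file.path(outdir, "gene_set_results.tsv"))
  write_tsv(ewas, files[["ewas"]])
  write_tsv(sets[, setdiff(names(sets), "driver_genes")], files[["gene_sets"]])
  write_manifest(outdir, "enrich", config, files)
  invisible(sets)
}
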