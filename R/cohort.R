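#' Default fronto-limbic morphometry specification
#'
#' Sixteen outcomes: bilateral-average hippocampus and amygdala gray matter
#' volumes (mm^3) plus surface area (mm^2) and cortical thickness (mm) for
#' seven frontal-cortex subregions (frontal pole, medial/lateral
#' orbito-frontal cortex, superior frontal gyrus, rostral middle frontal
#' gyrus, rostral/caudal anterior cingulate). Means and SDs are plausible
#' adult values; all planted exposure effects default to zero.
#'
#' @return data.frame with columns `outcome`, `mean`, `sd`, `is_volume`, and
#'   one effect column per exposure term (`eff_income_low`, `eff_education_low`,
#'   `eff_ctq`, `eff_tei`), standardized effect sizes.
#' @export
default_morphometry_specs <- function() {
  spec <- data.frame(
    outcome = c("hippocampus_volume", "amygdala_volume",
                "frontal_pole_sa", "medial_ofc_sa", "lateral_ofc_sa",
                "sfg_sa", "rmfg_sa", "rostral_acc_sa", "caudal_acc_sa",
                "frontal_pole_ct", "medial_ofc_ct", "lateral_ofc_ct",
                "sfg_ct", "rmfg_ct", "rostral_acc_ct", "caudal_acc_ct"),
    mean = c(4100, 1650,
             420, 1900, 2800, 7400, 5900, 800, 700,
             2.75, 2.40, 2.65, 2.72, 2.40, 2.85, 2.60),
    sd = c(400, 180,
           60, 230, 330, 800, 700, 140, 140,
           0.25, 0.15, 0.14, 0.14, 0.13, 0.20, 0.20),
    stringsAsFactors = FALSE
  )
  spec$is_volume <- grepl("_volume$", spec$outcome)
  for (eff in c("eff_income_low", "eff_education_low", "eff_ctq", "eff_tei")) {
    spec[[eff]] <- 0
  }
  spec
}

#' Cohort generator configuration
#'
#' Defaults emulate the marginals of an urban, trauma-exposed adult cohort:
#' age 40 (SD 12.5, range 19-62), childhood trauma questionnaire total
#' 40.5 (SD 15.4, range 25-93), traumatic events inventory 4.2 (SD 2.3,
#' left-truncated at 0), household income bands 30/36/34%, educational
#' attainment 15/30/55%, and employment status 33/7/60%
#' (employed / disabled / unemployed). Truncated scales are moment-matched:
#' the parent normal is calibrated so the *truncated* distribution has the
#' stated mean and SD (see [calibrate_truncnorm()]).
#'
#' @param n_samples number of participants.
#' @param age_mean,age_sd,age_range age distribution (years).
#' @param ctq_mean,ctq_sd,ctq_range childhood trauma total score.
#' @param tei_mean,tei_sd,tei_range adult trauma count.
#' @param income_probs,education_probs,employment_probs category probabilities
#'   (low-to-high for income/education; employed/disabled/unemployed).
#' @param n_ancestry_dims number of genomic-ancestry MDS dimensions.
#' @param ancestry_sd per-dimension SD of the MDS coordinates.
#' @param icv_mean,icv_sd intracranial volume (mm^3).
#' @param morphometry_specs as [default_morphometry_specs()].
#' @param seed integer RNG seed.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_samples = 97,
                          age_mean = 40, age_sd = 12.5, age_range = c(19, 62),
                          ctq_mean = 40.5, ctq_sd = 15.4, ctq_range = c(25, 93),
                          tei_mean = 4.2, tei_sd = 2.3, tei_range = c(0, Inf),
                          income_probs = c(0.30, 0.36, 0.34),
                          education_probs = c(0.15, 0.30, 0.55),
                          employment_probs = c(0.33, 0.07, 0.60),
                          n_ancestry_dims = 4, ancestry_sd = 0.03,
                          icv_mean = 1.4e6, icv_sd = 1.3e5,
                          morphometry_specs = default_morphometry_specs(),
                          seed = 1L) {
  if (!is_count(n_samples) || n_samples < 2) {
    stop("n_samples must be an integer >= 2", call. = FALSE)
  }
  assert_simplex(income_probs, "income_probs")
  assert_simplex(education_probs, "education_probs")
  assert_simplex(employment_probs, "employment_probs")
  stopifnot(age_sd > 0, ctq_sd > 0, tei_sd > 0, icv_sd > 0,
            ctq_range[1] < ctq_range[2])
  cfg <- list(
    n_samples = as.integer(n_samples),
    age = list(mean = age_mean, sd = age_sd, range = age_range,
               parent = calibrate_truncnorm(age_mean, age_sd, age_range[1],
                                            age_range[2], warn = FALSE)),
    ctq = list(mean = ctq_mean, sd = ctq_sd, range = ctq_range,
               parent = calibrate_truncnorm(ctq_mean, ctq_sd, ctq_range[1],
                                            ctq_range[2], warn = FALSE)),
    tei = list(mean = tei_mean, sd = tei_sd, range = tei_range,
               parent = calibrate_truncnorm(tei_mean, tei_sd, tei_range[1],
                                            tei_range[2], warn = FALSE)),
    income_probs = income_probs,
    education_probs = education_probs,
    employment_probs = employment_probs,
    n_ancestry_dims = as.integer(n_ancestry_dims),
    ancestry_sd = ancestry_sd,
    icv = list(mean = icv_mean, sd = icv_sd),
    morphometry_specs = morphometry_specs,
    seed = as.integer(seed)
  )
  structure(cfg, class = "cohort_config")
}

income_levels <- c("income_0_499", "income_500_999", "income_1000plus")
education_levels <- c("edu_less_hs", "edu_hs_grad", "edu_more_hs")
employment_levels <- c("employed", "disabled", "unemployed")

# categorical draw returning a factor with the reference level LAST moved
# first is not wanted here: reference = highest income / highest education /
# employed, encoded by relevel at model time.
draw_categorical <- function(n, levels, probs) {
  factor(sample(levels, n, replace = TRUE, prob = probs), levels = levels)
}

#' Simulate a phenotype table
#'
#' Draws exposures, covariates and 16 brain-morphometry outcomes for a
#' synthetic cohort. Each outcome is a linear combination of standardized
#' exposure terms (per `morphometry_specs`) plus unit-variance Gaussian
#' noise, affinely rescaled to the outcome's configured mean/SD.
#'
#' @param config a [cohort_config()].
#' @return list with `phenotypes` (data.frame, one row per sample) and
#'   `truth` (planted standardized effects and the standardized exposure
#'   design actually used).
#' @export
simulate_phenotypes <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_samples
  set.seed(config$seed)

  draw_trunc <- function(p) rtruncnorm(n, p$mu, p$sigma, p$lower, p$upper)
  age <- draw_trunc(config$age$parent)
  ctq <- draw_trunc(config$ctq$parent)
  tei <- draw_trunc(config$tei$parent)
  income <- draw_categorical(n, income_levels, config$income_probs)
  education <- draw_categorical(n, education_levels, config$education_probs)
  employment <- draw_categorical(n, employment_levels, config$employment_probs)
  ancestry <- matrix(stats::rnorm(n * config$n_ancestry_dims, 0, config$ancestry_sd),
                     nrow = n)
  colnames(ancestry) <- paste0("ancestry_", seq_len(config$n_ancestry_dims))
  icv <- stats::rnorm(n, config$icv$mean, config$icv$sd)

  pheno <- data.frame(
    sample_id = sprintf("S%04d", seq_len(n)),
    age = age, income = income, education = education,
    employment = employment, ctq_total = ctq, tei = tei, icv = icv,
    stringsAsFactors = FALSE
  )
  pheno <- cbind(pheno, as.data.frame(ancestry))

  # standardized exposure design used for planting effects
  design <- cbind(
    income_low = as.numeric(income == "income_0_499"),
    education_low = as.numeric(education == "edu_less_hs"),
    ctq = zscore(ctq), tei = zscore(tei)
  )
  spec <- config$morphometry_specs
  effects <- as.matrix(spec[, c("eff_income_low", "eff_education_low",
                                "eff_ctq", "eff_tei")])
  latent <- matrix(stats::rnorm(n * nrow(spec)), nrow = n)
  latent <- latent + design %*% t(effects)
  for (i in seq_len(nrow(spec))) {
    pheno[[spec$outcome[i]]] <- spec$mean[i] + spec$sd[i] * latent[, i]
  }

  truth <- list(
    effects = effects, outcomes = spec$outcome,
    exposure_design = design, seed = config$seed
  )
  list(phenotypes = pheno, truth = truth)
}
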