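# Reference levels: highest income, highest education, employed.
relevel_exposures <- function(pheno) {
  pheno$income <- stats::relevel(factor(pheno$income, levels = income_levels),
                                 ref = "income_1000plus")
  pheno$education <- stats::relevel(factor(pheno$education,
                                           levels = education_levels),
                                    ref = "edu_more_hs")
  pheno$employment <- factor(pheno$employment, levels = employment_levels)
  pheno
}

# Map model-matrix coefficient names to the four exposure terms of interest.
exposure_terms <- c(
  income_low = "incomeincome_0_499",
  education_low = "educationedu_less_hs",
  ctq = "ctq_z",
  tei = "tei_z"
)

# lm with an explicit rank check: aliased columns are an error here, not a
# silent drop, so collinear covariates surface immediately
lm_checked <- function(fml, data) {
  mm <- stats::model.matrix(fml, data = data)
  qx <- qr(mm)
  if (qx$rank < ncol(mm)) {
    bad <- colnames(mm)[qx$pivot[(qx$rank + 1):ncol(mm)]]
    stop("collinear model columns: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  stats::lm(fml, data = data)
}

extract_records <- function(fit, outcome, terms, family) {
  sm <- summary(fit)$coefficients
  miss <- setdiff(unname(terms), rownames(sm))
  if (length(miss)) {
    stop("terms dropped from fit of ", outcome, " (collinearity?): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  data.frame(
    outcome = outcome,
    term = names(terms),
    beta = sm[terms, "Estimate"],
    se = sm[terms, "Std. Error"],
    t = sm[terms, "t value"],
    p = sm[terms, "Pr(>|t|)"],
    family = family,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

ancestry_cols <- function(pheno) grep("^ancestry_[0-9]+$", names(pheno), value = TRUE)

# shared scaffolding: standardized continuous columns added to a model frame
standardize_continuous <- function(pheno) {
  pheno$ctq_z <- zscore(pheno$ctq_total)
  pheno$tei_z <- zscore(pheno$tei)
  pheno$age_z <- zscore(pheno$age)
  pheno$icv_z <- zscore(pheno$icv)
  for (a in ancestry_cols(pheno)) pheno[[paste0(a, "_z")]] <- zscore(pheno[[a]])
  pheno
}

#' Arm A: exposures predict brain morphometry
#'
#' One linear model per morphometry outcome with the four exposure terms of
#' interest fitted jointly: income dummies, education dummies, standardized
#' childhood-trauma total and standardized adult-trauma count. Covariates
#' are genomic ancestry, age and employment dummies; intracranial volume is
#' added only for the volumetric outcomes. Continuous dependent and
#' independent variables are standardized, so coefficients are standardized
#' effects. Dummy predictors are left on their 0/1 scale. The test family
#' counts one test per (outcome, exposure term) pair.
#'
#' @param pheno phenotype table (see [simulate_phenotypes()]).
#' @param outcomes character vector of outcome columns; defaults to the 16
#'   fronto-limbic measures.
#' @param volume_outcomes outcomes that additionally adjust for ICV.
#' @return data.frame of regression records (columns outcome, term, beta,
#'   se, t, p, family) with attribute `m` = family size.
#' @export
fit_arm_a <- function(pheno,
                      outcomes = default_morphometry_specs()$outcome,
                      volume_outcomes = c("hippocampus_volume",
                                          "amygdala_volume")) {
  miss <- setdiff(c(outcomes, "income", "education", "employment",
                    "ctq_total", "tei", "age", "icv"), names(pheno))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  pheno <- standardize_continuous(relevel_exposures(pheno))
  anc_z <- paste0(ancestry_cols(pheno), "_z")
  recs <- lapply(outcomes, function(out) {
    y <- pheno[[out]]
    if (stats::sd(y) == 0) stop("constant outcome: ", out, call. = FALSE)
    pheno$.y <- zscore(y, out)
    covs <- c(anc_z, "age_z", "employment")
    if (out %in% volume_outcomes) covs <- c(covs, "icv_z")
    fml <- stats::reformulate(c("income", "education", "ctq_z", "tei_z", covs),
                              response = ".y")
    extract_records(lm_checked(fml, pheno), out, exposure_terms, "arm_a")
  })
  out <- do.call(rbind, recs)
  attr(out, "m") <- nrow(out)
  out
}

#' Arm B: exposures predict module eigengenes
#'
#' One linear model per module eigengene: `ME ~ income + education + CTQ +
#' TEI + employment`. Covariates are limited to employment because
#' confounders were already removed when probes were residualized. One
#' record per exposure term; the family size follows the one-test-per-module
#' accounting.
#'
#' @param eigengenes samples x modules matrix (or `module_set`).
#' @param pheno phenotype table aligned to the eigengene rows.
#' @return data.frame of records, `outcome` = module name; attribute `m` =
#'   module count.
#' @export
fit_arm_b <- function(eigengenes, pheno) {
  if (inherits(eigengenes, "module_set")) eigengenes <- eigengenes$eigengenes
  stopifnot(nrow(eigengenes) == nrow(pheno))
  pheno <- standardize_continuous(relevel_exposures(pheno))
  recs <- lapply(colnames(eigengenes), function(me) {
    pheno$.y <- zscore(eigengenes[, me], me)
    fml <- stats::reformulate(c("income", "education", "ctq_z", "tei_z",
                                "employment"), response = ".y")
    extract_records(lm_checked(fml, pheno), me, exposure_terms, "arm_b")
  })
  out <- do.call(rbind, recs)
  attr(out, "m") <- ncol(eigengenes)
  out
}

#' Arm C: module eigengenes predict brain morphometry
#'
#' One linear model per (eigengene, outcome) pair: `outcome ~ ME + age +
#' ancestry + employment`, adding ICV for volumetric outcomes. One record
#' per pair; family size = number of pairs tested.
#'
#' @param eigengenes samples x modules matrix (or `module_set`).
#' @param pheno phenotype table aligned to the eigengene rows.
#' @param pairs optional data.frame with columns `module`, `outcome`
#'   restricting the tested pairs; default = full cross product.
#' @param outcomes outcome columns eligible for the cross product.
#' @param volume_outcomes outcomes that additionally adjust for ICV.
#' @return data.frame of records (`term` = module name); attribute `m`.
#' @export
fit_arm_c <- function(eigengenes, pheno, pairs = NULL,
                      outcomes = default_morphometry_specs()$outcome,
                      volume_outcomes = c("hippocampus_volume",
                                          "amygdala_volume")) {
  if (inherits(eigengenes, "module_set")) eigengenes <- eigengenes$eigengenes
  stopifnot(nrow(eigengenes) == nrow(pheno))
  if (is.null(pairs)) {
    pairs <- expand.grid(module = colnames(eigengenes), outcome = outcomes,
                         stringsAsFactors = FALSE)
  }
  pheno <- standardize_continuous(relevel_exposures(pheno))
  anc_z <- paste0(ancestry_cols(pheno), "_z")
  recs <- lapply(seq_len(nrow(pairs)), function(i) {
    me <- pairs$module[i]; out <- pairs$outcome[i]
    pheno$.y <- zscore(pheno[[out]], out)
    pheno$.me <- zscore(eigengenes[, me], me)
    covs <- c("age_z", anc_z, "employment")
    if (out %in% volume_outcomes) covs <- c(covs, "icv_z")
    fml <- stats::reformulate(c(".me", covs), response = ".y")
    rec <- extract_records(lm_checked(fml, pheno), out,
                           c(module = ".me"), "arm_c")
    rec$term <- me
    rec
  })
  out <- do.call(rbind, recs)
  attr(out, "m") <- nrow(pairs)
  out
}

#' Benjamini-Hochberg significance flags
#'
#' The step-up rule: sort p ascending, compare `p_(k)` with critical value
#' `(k/m) * q`, find the largest k whose p-value is at or below its critical
#' value, and flag every record with `p <= p_(k)` (ties share a flag). A
#' literal per-rank variant without the step-up closure (each p compared
#' only with its own critical value) is available for sensitivity checks.
#'
#' @param p numeric vector of nominal p-values.
#' @param q accepted false discovery rate.
#' @param m family size; defaults to `length(p)` but may be larger when the
#'   declared family exceeds the records supplied.
#' @param method `"step_up"` (standard) or `"literal"`.
#' @return logical vector of flags, same order as `p`.
#' @export
bh_adjust <- function(p, q = 0.10, m = length(p),
                      method = c("step_up", "literal")) {
  method <- match.arg(method)
  if (length(p) < 1) stop("empty p-value vector", call. = FALSE)
  if (any(p < 0 | p > 1 | is.na(p))) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  ord <- order(p)
  crit <- (seq_along(p) / m) * q
  ps <- p[ord]
  if (method == "literal") {
    flags_sorted <- ps < crit
    flags <- logical(length(p))
    flags[ord] <- flags_sorted
    return(flags)
  }
  below <- which(ps <= crit)
  if (!length(below)) return(logical(length(p)))
  p >= 0 & p <= ps[max(below)]
}

#' Gate mediation candidates from the three screening arms
#'
#' A triple (exposure, module, outcome) is a mediation candidate when the
#' exposure-outcome association (Arm A), the exposure-module association
#' (Arm B) and the module-outcome association (Arm C) are all nominally
#' significant.
#'
#' @param arm_a,arm_b,arm_c record data.frames from the three fits.
#' @param alpha nominal significance gate.
#' @return data.frame with columns `exposure`, `module`, `outcome`.
#' @export
gate_candidates <- function(arm_a, arm_b, arm_c, alpha = 0.05) {
  a_hits <- arm_a[arm_a$p < alpha, c("term", "outcome")]
  b_hits <- arm_b[arm_b$p < alpha, c("term", "outcome")]  # outcome = module
  c_hits <- arm_c[arm_c$p < alpha, c("term", "outcome")]  # term = module
  out <- do.call(rbind, lapply(seq_len(nrow(a_hits)), function(i) {
    expo <- a_hits$term[i]; brain <- a_hits$outcome[i]
    mods_b <- b_hits$outcome[b_hits$term == expo]
    mods_c <- c_hits$term[c_hits$outcome == brain]
    mods <- intersect(mods_b, mods_c)
    if (!length(mods)) return(NULL)
    data.frame(exposure = expo, module = mods, outcome = brain,
               stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    out <- data.frame(exposure = character(), module = character(),
                      outcome = character(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
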