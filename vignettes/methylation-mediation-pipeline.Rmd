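---
title: "Co-methylation networks and causal mediation: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-methylation networks and causal mediation: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epimediate)
```

# The scientific problem

Adverse social exposures (ASEs) — low household income, low educational
attainment, childhood trauma burden (CTQ total) and adult trauma burden
(TEI) — are associated with variability in fronto-limbic brain morphometry:
hippocampal and amygdala gray matter volume, and surface area (SA) and
cortical thickness (CT) of frontal-cortex subregions. One candidate
mechanism of "biological embedding" is DNA methylation (5mC) measured in
peripheral blood. `epimediate` implements a complete analysis chain for
asking whether *clusters* of co-methylated blood CpG probes statistically
mediate exposure–morphometry associations:

1. **Pre-processing** — beta values are transformed to M-values
   (`M = log2(beta / (1 - beta))`), probes are filtered (sex chromosomes,
   SNP probes, cross-reactive probes, and restriction to probes whose
   blood–brain correlation is nominally significant), leukocyte composition
   is estimated from reference profiles, a polyepigenetic smoking score is
   computed, and every probe is residualized against age, cell fractions,
   genomic ancestry and the smoking score.
2. **Co-methylation network** — an unsigned weighted adjacency
   `|cor|^power` with the soft threshold chosen as the lowest power whose
   scale-free topology fit exceeds R² = 0.90; topological-overlap
   dissimilarity; average-linkage clustering with a minimum module size of
   10; module eigengenes (first principal component of each module's
   standardized probes).
3. **Screening** — three families of standardized linear models: exposures
   → morphometry (Arm A), exposures → module eigengenes (Arm B), eigengenes
   → morphometry (Arm C), with Benjamini–Hochberg control at FDR q = 0.10
   within each family and nominal gating (α = 0.05) of mediation
   candidates.
4. **Mediation** — quasi-Bayesian Monte Carlo mediation (default 10,000
   coefficient draws) for each gated (exposure, eigengene, outcome) triple,
   with full/partial mediator classification, proportion mediated, and
   probe-wise follow-up within full-mediator modules.
5. **Enrichment** — probe-wise exposure association on residualized
   M-values, Šidák minimum-p aggregation to genes, and hypergeometric
   over-representation of gene sets of 25–1,000 genes with BH control.

Because the motivating data (a blood-methylation cohort with
access-restricted neuroimaging) cannot be redistributed, the package ships
a first-class synthetic-cohort generator with planted ground truth, and all
empirical claims in the test suite are made against that truth.

# The synthetic cohort

`cohort_config()` encodes the marginals of an urban, all-female,
trauma-exposed adult cohort: age 40 (SD 12.5, range 19–62), CTQ total 40.5
(SD 15.4, range 25–93), TEI 4.2 (SD 2.3, truncated at 0), income bands
30/36/34%, education 15/30/55%, employment 33/7/60%. Continuous scales are
simulated as truncated normals on their observed ranges.

**Moment matching at the family boundary.** A truncated normal
parameterized naively by the published mean and SD does not *have* that
mean and SD (truncation shifts both). `calibrate_truncnorm()` therefore
solves for parent parameters so that the truncated distribution matches the
target moments. For two of the three scales the published triple
(mean, SD, range) lies slightly outside the truncated-normal moment region:
at mean 40.5 on [25, 93] the SD supremum is ≈ 14.03 (the shifted-exponential
limit of the family), below the published 15.4, and at mean 40 on [19, 62]
the supremum is the uniform limit ≈ 12.41, marginally below 12.5. The
calibration matches the mean exactly — the quantity the downstream analyses
standardize away from — and takes the closest achievable SD; the achieved
moments are stored in the configuration (`cfg$ctq$parent$achieved`). The
boundary solutions place the truncation window deep in the parent normal's
tail, so sampling uses a shifted-exponential rejection sampler there rather
than the inverse CDF (which would round to the boundary).

Morphometry outcomes are linear combinations of standardized exposure terms
plus unit-variance noise, affinely rescaled to plausible region-specific
means and SDs; all planted effects default to zero.

`methylome_config()` builds an EPIC-like probe universe:

* **Planted modules** (default eight modules of 15 probes) follow a
  single-factor model: member M-values are `loading × f_m + noise` with a
  unit-variance latent factor per module and loading/noise SD of 3/1, so
  within-module correlations are ≈ 0.9.
* **A planted mediation path**: for the designated module,
  `f_m = a·z(exposure) + sqrt(1 − a²)·noise`, and
  `b·f_m + c'·z(exposure)` is added to the designated morphometry outcome
  (on its SD scale) *after* base generation, so the planted total effect is
  exactly `a·b + c'` and ground truth is exact rather than approximate.
* **Background structure**: by default, background probes belong to
  correlated groups whose sizes follow a power law and whose loadings vary
  by group. This continuum of cluster strengths is what gives real
  co-methylation networks their approximately scale-free connectivity; with
  it, the soft-threshold scan typically finds a passing power on purely
  background data. Note that at desk scale — 2,000 probes of which ~10%
  sit in uniform-strength planted hub modules — the hub end of the
  connectivity spectrum deviates from a power law and the scan may fall
  back (with a warning) to the best-fitting power; this is the documented
  fallback rule, not an error. `bg_structure = "none"` gives independent
  background noise and clean ground truth for recovery studies.
* **Cell-type block**: a reserved set of probes is generated as a noisy
  mixture of six reference leukocyte profiles with Dirichlet-distributed
  true fractions concentrated on granulocytes, so reference-based
  deconvolution can be validated against truth.
* **Smoking signature**: 26 probes carry effects of a latent smoking
  intensity (prevalence 0.3), mirroring the use of a fixed-panel
  polyepigenetic smoking score as a covariate.
* **Annotation**: chromosome, position, a single gene symbol from a
  configurable gene universe, a cross-reactive flag and a blood–brain
  correlation p-value. Flags and failing blood–brain p-values are applied
  only to background probes so that planted structure survives filtering;
  this is a deliberate generator convenience, not a property of real
  arrays.

What the generator does **not** emulate: raw array intensities and
chemistry, batch/plate structure, probe-type (I/II) differences,
correlations among the exposures themselves (income, education and trauma
co-occur in real cohorts; the default keeps them independent so that
planted-effect recovery is unconfounded), spatial correlation along the
genome, and the bimodal beta-value landscape of real methylomes (baselines
are unimodal on the M scale). Passing tests therefore demonstrate
correctness of the algorithms under the stated factor-model conditions, not
robustness to every artefact of real data.

# Model and procedure details

**M-values and filtering.** Beta values are clipped to
`[epsilon, 1 − epsilon]` with `epsilon = 1e-6` before the base-2 logit, so
boundary betas stay finite without distorting interior values. The filter
cascade removes chrX/chrY probes, `rs`-prefixed probes, and flagged
cross-reactive probes, then keeps probes with blood–brain correlation
p < 0.05; it preserves input order and is idempotent.

**Cell deconvolution.** Each sample's beta profile is projected onto the
reference profiles under nonnegativity with the simplex bound `sum ≤ 1`
(nonnegative least squares, with a penalty row activated only when the
unconstrained solution exceeds the bound). In the interior this coincides
with the classical constrained-projection estimator. Granulocytes are
excluded from downstream covariate designs as the compositional complement.

**Smoking score.** A plain weighted sum of beta values over the supplied
26-probe effect table, computed on the beta scale (the scale on which such
panel effects are typically reported). The operation is generic over any
effect table.

**Residualization.** Per-probe OLS of M on intercept + age + five cell
fractions + ancestry dimensions + smoking score, implemented with a single
QR decomposition shared across probes; residuals are mean-zero and
orthogonal to the design by construction.

**Scale-free fit.** Connectivity is binned into 10 *equal-width* bins and
`log10(frequency)` is regressed on `log10(mean k)` over non-empty bins.
Equal-count binning would make every bin frequency identical and the fit
meaningless. Both the signed R² (negated slope sign, truncated at zero) and
the degrees-of-freedom-adjusted variant are reported; selection uses the
signed R² by default and is configurable.

**Clustering.** A fixed-height cut (default 0.995 of the maximum merge
height) of the average-linkage tree, followed by min-size pruning
(unassigned probes get label 0) and relabelling 1..K by decreasing size,
with color aliases for reporting. A fixed cut is fully deterministic and
specifiable, at the cost of the adaptivity a dynamic tree cut would offer.

**Eigengenes.** Probes are standardized across samples; the first principal
component's scores are sign-aligned to correlate positively with the
module's mean probe profile (for an exactly balanced anticorrelated module,
where that mean vanishes, orientation falls back to the first member
probe), then scaled to unit SD. Variance explained is the first squared
singular value over the total.

**Screening arms.** Continuous dependent and independent variables are
z-scored, so coefficients are standardized effects; category dummies are
left on their 0/1 scale with reference levels = highest income, highest
education, employed. Arm A fits all four exposure terms jointly per outcome
(ICV as covariate only for the volumes; overall CT/SA deliberately not
covariates), giving the 16 × 4 = 64-test family. Arm B fits eigengenes on
exposures with employment as the only covariate (confounders were already
residualized out of the probes); its BH family is counted as one test per
module, applied per exposure term. Arm C fits outcomes on single eigengenes
with age, ancestry, employment (and ICV for volumes); the family is the
number of tested pairs. Model matrices are rank-checked: collinear columns
raise an error naming the offending columns rather than being silently
dropped.

**Benjamini–Hochberg.** The standard step-up rule: the largest k with
`p_(k) ≤ (k/m)·q` flags all records with `p ≤ p_(k)`, ties sharing flags.
A "literal" per-rank variant — each p compared only against its own
critical value, without the step-up closure — is available behind a flag
for sensitivity analysis, since verbal descriptions of the procedure are
sometimes read that way.

**Quasi-Bayesian mediation.** The mediator model `m ~ x + Z_m` and outcome
model `y ~ x + m + Z_y` are fitted by OLS; `n_draws` coefficient vectors
are sampled from each model's estimated multivariate-normal sampling
distribution (independently between models); per draw `IDE = a·b·Δ`,
`DE = c'·Δ`, `TE = IDE + DE`. With no exposure-by-mediator interaction the
product-of-coefficients decomposition is exact, and additivity holds per
draw and in the point estimates to machine precision. Draws use
*antithetic pairing* (each standard-normal vector paired with its
negation): linear coefficients then average exactly to their estimates and
the Monte Carlo error of product terms drops by orders of magnitude, so
point estimates are essentially invariant to `n_draws`. P-values are
`2·min(Pr(draw ≤ 0), Pr(draw ≥ 0))` without continuity correction;
intervals are percentile-based.

The default treat/control contrast is the observed maximum versus minimum
of the exposure, so the total effect reads as "highest versus lowest
exposure"; a unit or 1-SD contrast is available through
`treat_value`/`control_value`. Mediator-model covariates mirror Arm B
(the other exposures and employment) and outcome-model covariates mirror
Arm C, keeping the mediation models consistent with the screens that gated
them. Classification: *full* if TE and IDE are significant while DE is not;
*partial* if all three are; *none* otherwise. Proportion mediated is the
point-estimate ratio IDE/TE (undefined and flagged when TE = 0); the
display convention rounds to integer percent, and unrounded ratios are
always retained alongside.

**Probe-wise mediation** re-runs the same machinery with each member
probe's standardized residual M-value as mediator and applies BH jointly
over the family of all member IDE *and* DE p-values (family size = 2 ×
module size).

**Enrichment.** The probe-wise exposure scan shares one QR decomposition
across probes (identical design), returning the exposure term's p per
probe. Gene p-values are Šidák-corrected minimum probe p-values,
`1 − (1 − min p)^k`, which corrects the advantage of genes with many
probes and is monotone in every probe p. Gene sets are filtered to 25–1,000
genes *after* intersection with the measured universe and tested by the
hypergeometric upper tail of the overlap with the nominally significant
genes; BH-adjusted q-values are reported over the tested sets. This is an
over-representation design (the fully specifiable mode of probe-aware
gene-set testing); a rank-based alternative is possible future work.
Semantic redundancy reduction of related terms is out of scope; the full
BH-controlled table is the output.

# Pipeline, determinism and problem sizes

`run_pipeline()` executes `simulate → preprocess → network → screen →
mediate → enrich` against an output directory, each stage writing TSV
reports plus a JSON manifest (stage seed, config hash, file list). Stage
seeds are derived deterministically from the master seed and the stage
index, so any stage re-runs bit-identically; the determinism contract is
tested byte-for-byte on the mediation report. A YAML round-trip of the full
configuration is provided (`write_pipeline_config()` /
`read_pipeline_config()`).

The test suite exercises the chain at deliberately modest problem sizes
chosen to keep the factor-model asymptotics valid while remaining quick:
cohorts of 97–10,000 samples (100,000 for marginal calibration), 2,000
probes for network recovery, 2,000 Monte Carlo draws and 500 replicates
for mediation coverage, and 200 replicates for null-calibration rates.

# Known limitations

* The fixed-height tree cut requires a sensible `cut_height` when module
  separation is weak; the dynamic hybrid cut used by some practitioners is
  not implemented.
* Mediation here is *statistical* mediation under the usual sequential
  ignorability assumptions; no sensitivity analysis for unmeasured
  confounding is provided, and cross-sectional data cannot establish
  causal order.
* The enrichment stage tests over-representation only, and maps each probe
  to at most one gene symbol.
* Exposure–exposure correlation, batch structure and array chemistry are
  outside the generator's scope (see above), so real-data behaviour of the
  full chain should be validated on real cohorts.
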