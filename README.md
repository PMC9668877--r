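# epimediate

Blood DNA-methylation clusters as statistical mediators between adverse
social exposures and brain morphometry.

## What this package is for

Studies of the "biological embedding" of social adversity ask whether
exposures such as low household income, low educational attainment,
childhood trauma burden (CTQ total) and adult trauma burden (TEI) leave
marks in peripheral epigenetic data that index central-nervous-system
endophenotypes — here, fronto-limbic morphometry (hippocampal and amygdala
volume; surface area and cortical thickness of frontal-cortex subregions).
`epimediate` implements that full analysis chain for EPIC-style blood
methylation:

* **Pre-processing** — beta → M transform `M = log2(β/(1−β))`, probe
  filtering (sex chromosomes, SNP probes, cross-reactive probes,
  blood–brain-correlated subset), reference-based leukocyte deconvolution
  (constrained projection onto six cell-type profiles), a 26-probe
  polyepigenetic smoking score, and per-probe residualization against age,
  cell fractions, genomic ancestry and smoking.
* **Co-methylation network** — unsigned weighted adjacency `|r|^β` with the
  soft threshold β chosen as the lowest power whose scale-free fit exceeds
  R² = 0.90; topological overlap dissimilarity
  `1 − (l_ij + a_ij)/(min(k_i,k_j) + 1 − a_ij)`; average-linkage clustering
  with minimum module size 10; module eigengenes (first principal component
  per module, sign-anchored, unit SD).
* **Screening** — standardized regression arms A (exposures → morphometry,
  a 64-test family), B (exposures → eigengenes) and C (eigengenes →
  morphometry), each with Benjamini–Hochberg step-up control at FDR
  q = 0.10 and nominal gating (α = 0.05) of mediation candidates.
* **Mediation** — quasi-Bayesian Monte Carlo mediation: OLS mediator and
  outcome models, antithetic coefficient draws, `IDE = a·b·Δ`,
  `DE = c′·Δ`, `TE = IDE + DE` (exactly, per draw), percentile intervals,
  full/partial mediator classification, proportion mediated, and probe-wise
  dissection of full-mediator modules with a joint `2 × module size` BH
  family.
* **Enrichment** — probe-wise exposure scans on residualized M-values,
  Šidák minimum-p aggregation to genes (`1 − (1 − min p)^k`), and
  hypergeometric over-representation of 25–1,000-gene sets with BH control.

Because the motivating cohort data are access-restricted, the package
includes a first-class synthetic-cohort generator (`cohort_config()`,
`methylome_config()`, `simulate_cohort()`) that reproduces published
phenotype marginals and plants known co-methylation modules, covariate
effects and an exposure → module → morphometry mediation path, so every
stage is testable against exact ground truth.

## Worked example

Simulate a 97-person cohort with a planted mediation path
(a = 0.35, b = −0.45, c′ = −0.25 from CTQ through module 1 to rostral
middle frontal gyrus surface area) and run the whole pipeline:

```r
library(epimediate)

cfg <- pipeline_config(
  seed = 42,
  n_draws = 2000,
  methylome = methylome_config(
    seed = 42,
    planted_mediation = list(exposure = "ctq_total", module = 1,
                             outcome = "rmfg_sa",
                             a = 0.35, b = -0.45, c_prime = -0.25))
)
run_pipeline("all", cfg, "demo")

mods <- read.delim("demo/module_assignments.tsv")
max(mods$module_index)
#> [1] 10

med <- read.delim("demo/mediation.tsv")
med[, c("exposure", "mediator", "outcome", "ide_beta", "de_beta", "te_beta",
        "classification", "proportion_mediated")]
#>   exposure mediator outcome   ide_beta   de_beta   te_beta classification proportion_mediated
#> 1      ctq      ME3 rmfg_sa -0.5122549 -1.669072 -2.181327        partial           0.2348364
```

Reading the output: clustering found 10 modules; the screening arms gated
exactly one candidate triple (CTQ → ME3 → RMFG SA — ME3 is the planted
module after relabelling by size), and the mediation stage estimates a
standardized indirect effect of −0.51 and a total effect of −2.18 at the
highest-versus-lowest CTQ contrast, classifying the module as a *partial*
mediator (the planted direct path c′ ≠ 0) that carries ~23% of the total
effect. With this seed the soft-threshold scan warns that no candidate
power reaches R² > 0.90 — expected at this desk scale, where 10% of probes
sit in equally strong planted hub modules — and falls back to the
best-fitting power, as documented.

Each stage writes TSV reports (`soft_threshold_scan.tsv`, `arm_a.tsv`,
`mediation.tsv`, `gene_set_results.tsv`, ...) and a JSON manifest with the
stage seed and config hash; re-running with the same seed reproduces the
reports byte for byte. A thin CLI wrapper is available at
`inst/cli/epimediate.R`:

```sh
Rscript inst/cli/epimediate.R all --outdir demo --seed 42
```

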