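---
title: "Genomic versus pedigree evaluation with forward validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic versus pedigree evaluation with forward validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsforward)
```

## The problem this package addresses

Commercial poultry breeding programs select juvenile birds that have no
phenotype of their own for the traits under selection. Their breeding values
must be predicted from relatives: either through the pedigree expectation of
additive relatedness (the numerator relationship matrix **A**, giving
pedigree BLUP) or through realized marker-based relatedness (the VanRaden
genomic relationship matrix **G**, giving GBLUP). The practical questions a
breeder asks are: how accurate are those predictions for the newest
generation, and are they biased — will the best candidates be systematically
over- or under-valued?

`gsforward` implements this evaluation loop for closed populations with
discrete generations, modelled on two commercial Pekin duck lines (labelled
A and D) whose records cover seven traits: juvenile weight (JW, g),
slaughter body weight (BW, g), ultrasonic breast muscle depth (BD, mm),
primary feather length (PRF, mm), gait score (GAIT, ordinal 1–5, a leg
health proxy), average daily gain (ADG, g/day) and foot-pad dermatitis score
(FPD, ordinal 1–5). The real records are commercially confidential, so the
package ships a gene-dropping simulator that generates populations with the
same structure — the published per-line summary tables
(`duck_reference_tables()`) supply trait means, dispersions and
heritability targets — and every stage of the pipeline is exercised and
tested against that synthetic ground truth.

## The model

### Pre-correction

Phenotypes are first corrected for environmental fixed effects by ordinary
least squares:

$$y_{ij} = \mu + S_i + A_j + e_{ij}$$

for JW, PRF, GAIT, FPD (and by default ADG), where $S_i$ is the combined
sex-by-hatch factor ("sexhatch") and $A_j$ the dam-age class, and

$$y_{ijk} = \mu + S_i + A_j + P_k + e_{ijk}$$

for BW and BD, adding the finishing pen $P_k$; BD additionally carries BW as
a covariate (a body-size adjustment; BW obviously cannot be its own
covariate). The residuals $y^*$ are the adjusted phenotypes passed to the
animal model. Pre-correcting in a separate OLS step rather than inside the
mixed model is the standard large-data compromise: it keeps the
variance-component stage a single-random-effect problem. It is fitted on
all generations jointly, before masking — the workflow a breeder actually
runs, accepted here with its known mild leakage of validation information
into the factor-level estimates.

### The single-kernel animal model

For each trait and kernel $K \in \{A, G\}$:

$$y^* = \mu\mathbf{1} + u + e,\qquad
u \sim N(0, \sigma_g^2 K),\qquad e \sim N(0, \sigma_e^2 I).$$

`gblup()` estimates $(\sigma_g^2, \sigma_e^2)$ by restricted maximum
likelihood. With the eigendecomposition $K = U D U'$ of the phenotyped
block, rotating $y^*$ and the intercept by $U'$ makes the covariance
diagonal, and the REML log-likelihood profiles down to a one-dimensional
function of $h^2 = \sigma_g^2/(\sigma_g^2+\sigma_e^2)$:

$$\ell_R(h^2) \propto -\tfrac12\Big[(n-1)\log\hat\sigma_p^2 +
\textstyle\sum_i \log w_i + \log\big(\tilde x' W^{-1} \tilde x\big)\Big],
\qquad w_i = h^2 d_i + (1-h^2),$$

with the scale variance $\hat\sigma_p^2$ profiled out in closed form. The
profile is maximized by bracketed scalar optimization on
$[10^{-4}, 0.9999]$ (tolerance $10^{-6}$; estimates at the bracket ends are
reported with a boundary flag, not errored). This costs one $O(n^3)$
eigendecomposition per fit — exact and simple at desk scale (tests run at
$n \le 3000$; a few minutes and a few GB at $n \approx 15$K). The standard
error of $\hat h^2$ comes from the numerical curvature of the profile
log-likelihood at the optimum (observed information on the $h^2$ scale).

Breeding values are the BLUP
$\hat u = \hat\sigma_g^2\, K[\cdot, \text{train}]\, V^{-1}(y^* - \hat\mu)$
with $V = \hat\sigma_g^2 K_{\text{train}} + \hat\sigma_e^2 I$; individuals
present in $K$ without phenotype are predicted through their relationship
rows. The tests verify this equals the Henderson mixed-model-equation
solution to $10^{-8}$.

### Relationship matrices

* **A** — tabular method, processing parents before offspring:
  $A_{ij} = \tfrac12(A_{i,s(j)} + A_{i,d(j)})$, diagonal
  $1 + \tfrac12 A_{s(j),d(j)}$ (one plus the inbreeding coefficient).
  Verified against a recursive-definition oracle.
* **G** — VanRaden method 1: $Z = M - 2P$ and
  $G = ZZ'/(2\sum_j p_j(1-p_j))$, with allele frequencies observed on the
  full analysis set (all birds, training and validation, are genotyped in
  this design; base-population frequencies are unobservable). Only method 1
  is provided — no marker weighting and no blending with A. The sole
  conditioning device is an explicit diagonal ridge
  (`regularize_kinship()`, default 0.01, applied only when the smallest
  eigenvalue falls below $10^{-8}$, and logged loudly).

### Forward validation

`forward_validate()` masks the newest generation's phenotypes, fits the
animal model on the earlier generations, and reports per trait and kernel:

* $r$ — Pearson correlation between predicted EBV and adjusted phenotype
  over the masked individuals;
* accuracy $= r / \sqrt{\hat h^2_{\text{train}}}$, using the
  training-generation heritability of the matching kernel (the two kernels
  estimate different $h^2$, so each gets its own denominator);
* dispersion slope $b$: the OLS slope of whole-data EBVs ("true" EBVs,
  re-estimated with the validation phenotypes unmasked, same kernel) on the
  masked-fit EBVs, over the masked individuals only — the only internally
  consistent subset, since training EBVs barely move when the validation
  phenotypes are restored;
* standardized bias $\tilde b = 1-b$ for $b<1$, $1/b - 1$ for $b \ge 1$:
  zero is unbiased, positive means overestimation. Both branches meet at 0
  when $b = 1$. For $b \in (0, 2]$ the value lies in $(-1, 1]$; a negative
  $b$ would exceed 1, which the package flags with a warning rather than
  silently clipping.

Note the accuracy column divides the *correlation* (not its square) by
$\sqrt{h^2}$; published tables sometimes label the correlation column
"$r^2$", but the printed values are only mutually consistent when that
column is read as the correlation itself, which is how the package computes
and labels it.

## SNP quality control

`filter_snps()` removes SNPs with minor allele frequency below 0.05 or an
exact Hardy–Weinberg p-value below $10^{-6}$ — both strict inequalities, so
boundary values are retained. The HWE test is the exact conditional test
(enumeration of heterozygote counts given allele counts, no mid-p
correction), checked against a brute-force enumeration oracle and, under
simulated equilibrium, conservative as expected. No call-rate or
per-individual filters are applied: the imputed panels this models are
complete by construction. `describe_trait()` reports the companion
descriptive statistics (n, mean, sample SD, bias-corrected skewness and
excess kurtosis, CV%, SE); excess kurtosis is used because the published
near-zero values for normal-looking traits are only consistent with the
excess convention.

## The synthetic-data generator

`sim_pedigree()`, `sim_genotypes()` and `sim_phenotypes()` generate the
study conditions:

* **Pedigree** — discrete, non-overlapping generations (1-based; founders
  are generation 1); open-pen random mating, each non-founder drawing one
  sire and one dam from the previous generation of its line; sexes
  near-balanced. No selection is applied by default: the real lines are
  under selection of unstated intensity, and unselected simulation keeps
  the parameter-recovery tests interpretable. The line-shaped
  configurations reproduce the published splits — line A: 9,579 birds in
  generations 1–5 predicting 4,066 in generation 6; line D: 8,134
  predicting 4,885. (The line D split sums to 13,019, one short of the
  published line total of 13,020; the split counts are used.) The
  per-generation breakdown inside those totals is invented, as no coherent
  published breakdown exists.
* **Genotypes** — gene dropping with Haldane (no-interference)
  recombination on a uniform genetic map, by default 1 Morgan per
  chromosome with evenly spaced markers (no published duck linkage map is
  assumed). Founder haplotypes are drawn per SNP from uniform founder
  frequencies; the two lines are independent founder pools whose
  frequencies diverge by a logit-scale perturbation (SD 0.8 by default —
  enough for clean PC1 separation of the lines, which is how the simulator
  reproduces the qualitative population-structure picture). No mutation, no
  background linkage disequilibrium beyond map linkage.
* **Phenotypes** — mean + fixed effects + TBV + residual. The TBV is a
  centered dosage-weighted sum of zero-mean normal effects at `n_causal`
  markers, rescaled so its realized variance is exactly
  $h^2 \sigma_P^2$; the residual carries the remainder. Per-level fixed
  effects default to draws with SD 25% (sexhatch) / 10% (dam age, pen) of
  the phenotypic SD — large enough that skipping pre-correction visibly
  corrupts the evaluation, small enough to keep the scale recognisable.
  Dam age is a 5-class categorical factor (no published coding exists; five
  classes cover a breeder-typical parity range). GAIT and FPD are generated
  as Gaussian liabilities cut at equiprobable thresholds into five classes
  and then analysed as linear traits, matching how ordinal scores are
  handled by the evaluation itself.

What the simulator does **not** emulate: selection and the resulting
Bulmer-effect variance erosion, overlapping generations, genotyping or
imputation error (imputation enters only through the masking evaluator and
two deliberately naive baseline imputers), non-additive genetic variance,
and maternal or litter environmental covariance. Passing tests therefore
demonstrate that the estimators are correct under their own model
assumptions — not that real duck data would yield any particular accuracy.

## Numerical and design choices

* Heritability search bracket $[10^{-4}, 0.9999]$; kernels must be
  positive definite on the phenotyped block or `gblup()` refuses and points
  to `regularize_kinship()`.
* PCA is column-centered by default (the visualization convention);
  frequency standardization is available. All post-QC SNPs are used.
* Generation numbering is 1-based so that "generation 6" in a six-
  generation line means the newest birds.
* ADG is not assigned to either published model formula; it defaults to
  the sexhatch + dam-age terms and is configurable.
* `run_pipeline()` funnels all randomness through the configuration seed;
  identical configurations reproduce every TSV report byte-for-byte
  (timestamps appear only in the manifest).
* Problem sizes in the test suite: oracle equivalences at $n = 40$–$200$;
  parameter recovery at $n = 2000$ with 2,000 SNPs over 10 replicate seeds
  (mean $\hat h^2$ within $\pm 0.05$ of the 0.3 target); the GBLUP-versus-
  BLUP forward comparison on two lines of 1,000 birds (750 training, 250
  masked) with 1,000 markers over 10 seeds.

## A worked run

```{r demo, eval = FALSE}
cfg <- run_config(simulation = list(
  n_generations = 3, gen_sizes = c(200, 300, 300), n_lines = 1,
  n_chromosomes = 5, snps_per_chromosome = 200,
  traits = list(list(trait_name = "JW", target_h2 = 0.23, n_causal = 100,
                     phenotypic_mean = 567.15, phenotypic_sd = 86.27))),
  seed = 42)
res <- run_pipeline(cfg, out_dir = file.path(tempdir(), "demo_run"))
res$validation
```

The validation table carries one row per trait and kernel with the
training-fit heritability, the predictive correlation, the accuracy, the
dispersion slope and the standardized bias; `report_wide()` renders the
conventional side-by-side G/A layout.

## Known limitations

* Single random effect only: no multi-trait models, no
  genotype-by-environment, no single-step (H-matrix) evaluation — in this
  design every bird is genotyped for parentage, so single-step machinery
  adds nothing.
* The eigendecomposition REML is exact but $O(n^3)$ per fit; beyond
  $n \approx 15$K an iterative average-information REML would be the right
  tool.
* The bias statistics are regression-based dispersion measures; the
  partial/whole location-bias decomposition of the LR method is
  deliberately out of scope.
* Accuracy recomputed from rounded published inputs can shift in the
  second decimal; the acceptance tests pin the arithmetically stable rows
  exactly and bound the remainder.
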