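---
title: "Methods: genetically predicted biomarkers and the phenome scan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genetically predicted biomarkers and the phenome scan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its statistical machinery:
the model, the sampler, the projection and scan conventions, what the
synthetic cohorts do and do not emulate, and the design choices made where
the design was genuinely open.

## The model

For a quantitative biomarker measured in a genotyped cohort, the trait is
first residualized on covariates (typically age, sex and leading principal
components) by ordinary least squares (`residualize()`). The residual
vector $y$ over $n$ samples and $p$ column-standardized SNP dosages $X$ is
then modelled as a Bayesian sparse linear mixed model:

$$y = X\beta + u + \varepsilon, \qquad
\beta_i \sim \pi\, N(0, \sigma_a^2/\tau) + (1-\pi)\,\delta_0, \qquad
u \sim N(0, \sigma_b^2 K / \tau), \qquad K = XX^\top/p .$$

The polygenic term $u$ lets every SNP contribute a small effect through the
relatedness matrix $K$; the spike-and-slab component lets a few SNPs carry
large effects. Hyperparameters are parameterized as the total proportion of
variance explained $h$, the sparse share $\rho$, and the inclusion rate
$\pi$, with uniform priors: $h, \rho \sim U(0,1)$ and $\log_{10}\pi \sim
U(\log_{10}(1/p),\, 0)$. The variance components follow as
$\sigma_b^2 = h(1-\rho)/(1-h)$ and
$\sigma_a^2 = h\rho\,/\,((1-h)\,\pi p)$.

**Reported estimands.** PVE is summarized by the posterior of $h$, PGE by
$\rho$, and the number of large-effect SNPs by the size of the inclusion
set; all are reported as medians over post-burn-in draws with central 95%
credible intervals. The per-SNP outputs are the polygenic effect posterior
mean $\alpha$, the conditional sparse-effect mean $\beta$, and the
posterior inclusion probability $\gamma$, combined into the projection
weight $w = \alpha + \beta\gamma$ so that $w$ carries the SNP's full
marginal contribution.

## The sampler

The chain is Metropolis-within-Gibbs over $(h, \rho, \log_{10}\pi)$ and the
inclusion set, one of each move per step:

* Effects and the residual precision $\tau$ (Jeffreys prior) are
  integrated out analytically. Working in the eigenbasis $K = UDU^\top$,
  the integrated likelihood for an inclusion set of size $m$ costs
  $O(nm + nm^2 + m^3)$, so the sampler stays fast even at $p$ in the
  thousands.
* Hyperparameter proposals are reflected uniform random walks
  (half-widths 0.08 for $h$, 0.1 for $\rho$, 0.3 for $\log_{10}\pi$);
  inclusion moves are add/remove/swap with weights 0.4/0.4/0.2,
  renormalized over the legal moves and with the exact Hastings
  correction. The set size is capped (default 300).
* Per-SNP $\alpha$ and $\beta$ are accumulated as Rao-Blackwellized
  conditional means over retained draws; $\gamma$ is the retained-draw
  inclusion frequency.

Defaults follow the production schedule: 100,000 steps, the first half
discarded, every 10th retained draw kept. The test suite and the package's
own simulations run 20,000-step chains, which on the desk-scale problem
sizes used there (500–800 samples, 300–1000 SNPs) mix well (hyperparameter
acceptance around 0.5, effective sample size of the $h$ chain in the
hundreds); the chain length, burn-in and thinning are all `bslmm_config()`
parameters. Chains are bit-reproducible for a fixed seed: the C++ core
uses its own 64-bit generator and never touches R's RNG state.

**Numerical choices.** Missing dosages are mean-imputed at twice the
allele frequency before standardization; constant columns are dropped with
a warning and recorded in the fit. $h$ is kept inside $[10^{-4},
1-10^{-4}]$ to avoid boundary overflow. Effects are estimated on the
standardized-genotype scale and back-transformed to per-allele scale
before export, so exported weights apply to raw 0/1/2 dosages. With the
sparse component disabled (`fix_rho = 0`) the model reduces to a pure
linear mixed model and the weights agree with the closed-form BLUP (the
test suite checks correlation above 0.99 against a direct linear-algebra
oracle). An exact-enumeration check at $p = 2$ confirms the sampler's
inclusion probabilities match the true posterior; that check also shows
why a lone overwhelming SNP does not reach $\gamma = 1$ — at tiny $p$ the
polygenic term itself can absorb much of the signal, capping the inclusion
probability near 0.85.

## Out-of-sample explained variance

`estimate_pct_pve()` removes a random holdout (default 500 samples), fits
on the remainder, projects the holdout and reports
$100 \times R^2 / \mathrm{PVE}$, where $R^2$ is the squared correlation
between the held-out residual trait and its predicted score. "Variance
explained" is deliberately the $R^2$ of that univariate regression — the
standard reading — and a posterior-median PVE below $10^{-6}$ yields a
flagged `NA` rather than a division blow-up.

## Projection into a target cohort

`align_alleles()` matches weights to target SNPs by identifier with allele
verification. Swapped coded/other alleles negate the weight; strand
complements (A↔T, C↔G) are reconciled; palindromic SNPs (A/T, C/G pairs)
whose coded-allele frequency lies inside the ambiguity window (default
0.4–0.6) cannot be oriented from frequency and are dropped — the window is
a conservative, configurable default since frequency is the only signal
available. Allele pairs compatible with no orientation are dropped and
logged, never fatal. `project_scores()` evaluates
$\text{score}_j = \sum_i w_i \,\text{dosage}_{ji}$ with mean imputation of
missing dosages, then standardizes to mean 0, SD 1. Centering is a
deliberate strengthening of the SD-1 convention: it makes the score exactly
invariant to allele-coding flips (the intercept of the downstream logistic
model absorbs the constant) and leaves odds ratios untouched.

## The phenome scan

Case/control assembly per phecode: one or more occurrences makes a case;
samples whose only relevant occurrences are of closely related (exclusion)
codes are excluded from both groups; controls must fall inside the cases'
birth-decade range; any site with fewer than 10 cases is excluded wholesale
for that phenotype; single-sex phenotypes are rejected; phenotypes with
fewer than 300 cases (a configurable floor) are rejected. The logistic
model regresses status on the standardized score plus covariates — birth
decade as a categorical factor (it is a cohort-matching variable, not a
trend), site and platform as factors dropped automatically when constant
within the analysis set. Odds ratios are per SD of the predictor.

Separation and non-convergence are detected and flagged
(`converged = FALSE`, estimates withheld); plain maximum likelihood is
used, no penalized fallback. Non-converged rows are retained in results but
excluded from ranking; rank ties break by descending absolute effect, then
phecode.

**Selection.** The experiment-wide Bonferroni threshold is
$\alpha/(\text{biomarkers} \times \text{phenotypes})$ — e.g.
$0.05/(53 \times 1139) \approx 8.28\times10^{-7}$ at the reference scale,
or $0.05/107 \approx 4.67\times10^{-4}$ for a small replication set.
Benjamini–Hochberg q-values are computed within a configurable family,
per biomarker across its phenotypes by default (`fdr_family = "global"`
pools everything); the per-biomarker default matches how a single
predictor's scan is read, and the package's own tests verify the step-up
arithmetic against a brute-force oracle.

**Diagnostics.** The skewness of a scan's coefficients,
$(\sum\beta^3/n)\,/\,(\sum\beta^2/n)^{3/2}$, measures asymmetric enrichment
of risk versus protective associations; it is computed over phenotypes with
more than 150 cases after removing FDR-significant rows, so it reflects the
mass of weak associations rather than a few strong ones.
`stratified_association()` refits within the two levels of a binary
stratifier (removing it from the covariates), and
`direction_concordance()` reports the fraction of sign-concordant
coefficient pairs among those nominally significant ($p < 0.1$) in the
second cohort — the feasibility check used when a cohort is too small for
powered replication.

## The synthetic cohorts

The simulator generates what the paradigm assumes and nothing more:

* **Genotypes** are independent Binomial(2, MAF) draws — linkage
  equilibrium by design, because none of the pipeline's statistics require
  LD and equilibrium keeps the analytic oracles exact.
* **Biomarkers** are built from a large-effect component, a polygenic
  component and Gaussian noise. In the default `"exact"` mode the three
  are orthogonalized in-sample and rescaled so realized PVE and PGE equal
  the request to machine precision (assertable at $10^{-10}$), giving
  estimators a sharp truth; `"sampled"` mode draws effects from the
  implied normals so realized fractions vary, for realism.
* **Diagnoses** follow a liability model with a logistic link on the
  standardized true genetic value, the intercept solved numerically to hit
  the requested prevalence. The logistic (not probit) link is deliberate:
  planted log odds ratios are then recoverable on their own scale by the
  downstream logistic scan. Exclusion codes are planted on a fraction of
  non-case samples so control exclusion is actually exercised. The real
  phenotypes' generative process is of course unknown; this is a test
  harness, not a claim about clinical data.
* **Covariates** are balanced sex, uniform birth decades, categorical
  site/platform and standard-normal PCs.

What the simulations do **not** emulate — LD structure, population
stratification gradients, relatedness, imputation uncertainty, phecode
misclassification — bounds what passing tests show: they validate the
statistical machinery under its stated assumptions, not robustness to the
confounding structure of real biobank data.

## Problem sizes and reproducibility

The package's simulations and checks run at desk scale, chosen once:
parameter-recovery fits at 500 samples × 1000 SNPs with 20,000-step
chains over 20 seeds; the ridge-limit check at 200 × 500; null calibration
over 200 phenotypes of 2000 samples; end-to-end planted-association runs
at 800 × 300 training and 4000-sample targets with 50 phenotypes. The
pipeline driver fans a single global seed out to per-stage seeds via a
stage-name hash, so each stage is individually reproducible and reruns are
byte-identical.

## Known limitations

* The probit/binary-trait variant of the sparse mixed model is not
  implemented; binary phenotypes enter only as scan outcomes.
* Weight alignment is identifier-based with allele verification;
  position-based liftover and multi-allelic sites are out of scope.
* Trace diagnostics report effective sample size without enforcing a
  convergence threshold — short exploratory chains are the user's
  responsibility.
* The false-discovery guarantee of the step-up procedure assumes positive
  regression dependence across phenotypes; strongly antagonistic
  dependence structures would void it.
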