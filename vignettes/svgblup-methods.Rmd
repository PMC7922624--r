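---
title: "Methods: structural-variant imputation evaluation and GBLUP in svgblup"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structural-variant imputation evaluation and GBLUP in svgblup}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svgblup)
```

# The problem

Structural variants (SVs) in cattle are discovered from whole-genome
sequence in a few hundred reference animals, but the cohorts with
phenotypes are genotyped on SNP chips. The analysis chain this package
implements therefore has three linked questions: (i) which SV calls are
trustworthy and how accurately can their genotypes be imputed from
surrounding SNPs; (ii) how much additive variance of dairy traits do the
imputed SVs capture on top of SNPs; and (iii) does adding them to genomic
prediction help. Real data of this kind are access-restricted, so the
package ships a synthetic-population generator that reproduces the
statistical structure the methods rely on, and every stage is exercised
and tested on it.

# The mixed model

All variance estimation, association testing and prediction derive from
one model for a vector of daughter trait deviations $y$:

$$ y = 1_n\mu + Xb + Z_1u_1 + Z_2u_2 + e, \qquad
   u_1 \sim N(0, G_1\sigma^2_{a1}),\;
   u_2 \sim N(0, G_2\sigma^2_{a2}),\;
   e \sim N(0, I\sigma^2_e), $$

where $G_1$ and $G_2$ are genomic relationship matrices built from SNP
and SV dosages respectively, and the fixed design holds an intercept, a
breed fraction (0 = pure Jersey … 1 = pure Holstein, in steps of 0.25)
and, in association scans, the candidate-marker dosage. Both GRMs use the
marker-standardized form
$G_{jk} = m^{-1}\sum_i (x_{ij}-2p_i)(x_{ik}-2p_i)/(2p_i(1-p_i))$ with
allele frequencies computed on the analysis cohort and missing codes
mean-imputed to $2p_i$ (which leaves $p_i$ itself unchanged). Because the
standardized markers are centred, such a GRM is always singular
($G\,1 = 0$); everything downstream is written to tolerate that.

## REML

`remlFit()` estimates one variance per GRM plus a residual by
average-information (AI) REML. Each iteration forms
$V = \sum_k \sigma^2_k G_k + \sigma^2_e I$ by Cholesky factorization, the
projection $P$, the score vector
$-\tfrac12(\mathrm{tr}(PG_k) - y'PG_kPy)$ and the AI matrix
$\tfrac12\, y'PG_kPG_lPy$. The first step and any step where the AI
update would leave the parameter space or reduce the restricted
log-likelihood fall back to EM-REML, whose updates cannot decrease the
likelihood; the whole iteration trace is therefore monotone (a property
the tests assert). Components are bounded below at
$10^{-8}\,\mathrm{var}(y)$ so the AI matrix stays invertible at the
boundary; convergence is a relative log-likelihood change below $10^{-8}$
(cap 200 iterations); standard errors come from the inverse AI matrix.
Values that sit at the numerical floor are reported as the floor, not
rounded to an exact zero — rounding is left to presentation.

## BLUP and prediction

`solveBLUP()` uses the phenotypic-covariance (GLS) form: $\hat b$ is
generalized least squares under $V$ over the phenotyped records and
$\hat u_k = \sigma^2_k G_k[\cdot,\mathrm{obs}]\,V^{-1}(y - X\hat b)$.
This is algebraically Henderson's mixed-model equations but needs no
$G^{-1}$, so it is exact for the (always singular) sample-frequency GRMs;
the returned `residualNorm` plugs the solutions back into the
G-multiplied form of the equations as a solver contract. Individuals
without phenotypes get predictions purely through GRM off-diagonals,
which is how validation folds are predicted in the cross-validation.

## Association and meta-analysis

`mlmaScan()` follows the standard mixed-linear-model association scheme:
variance components are estimated once under the null (no candidate
marker) and held fixed, so each marker test is generalized least squares
with $b = (m'P_0y)/(m'P_0m)$ and $\mathrm{SE}^2 = (m'P_0m)^{-1}$, where
$P_0$ projects out the null fixed effects under the fitted $V$. The whole
scan is a single matrix product. p-values use the standard normal on
$t = b/\mathrm{SE}$. Markers that are monomorphic or aliased with the
covariates (including a conditioning marker in `conditionalScan()`)
return `NA` with a reason. The multi-trait statistic is
$\chi^2 = t'V^{-1}t$ with $V$ the Pearson correlation matrix of signed
t-values across cohort-traits computed over all markers
(pairwise-complete); an ill-conditioned $V$ (condition number above
$10^{10}$) is inverted by Moore–Penrose pseudo-inverse with a warning.
The SV false discovery rate at threshold $P$ with $S$ of $T$ SVs
significant is $P(1-S/T)/((S/T)(1-P))$, undefined (NA) at $S=0$.

## Imputation evaluation

`runImputationCV()` runs the masking design: individuals are split into
$k=5$ seeded folds; each fold's SV genotypes are masked (code 5) and
re-predicted using the other folds as reference, so the reference never
contains a test individual's SV genotypes. The imputer is deliberately a
stand-in for external phasing engines (which are out of scope): each SV,
represented on the scaffold by a single anchor (start by default; middle
and end supported), is regressed on its $w = 20$ nearest flanking SNP
dosages in the reference, ties broken toward the lower position, with
predictions clipped to $[0,2]$; SNPs inside the SV interval can be
excluded from the scaffold. It shares the property that matters for the
evaluation harness — accuracy is driven by SV–SNP LD — and the interface
is pluggable so an external engine can be dropped in. Accuracy per SV is
the squared Pearson correlation between imputed dosage and true code
pooled over all masked individuals (per-fold tables are available as an
option; pooling is the headline estimate). Selection uses the strict
rule $R^2 > 0.5$, and selected sets are merged across SV sets by the
≥ 1 bp same-type overlap rule.

# Interval arithmetic

SV records live in `GRanges` (1-based, inclusive); BED-like files
(0-based, half-open) are converted at the I/O boundary. "Overlap by
≥ 1 bp" is evaluated on the closed ranges, which is equivalent to
intersection length ≥ 1 under half-open arithmetic; merging is type-aware
(deletions only merge with deletions, and so on), collapses multi-way
overlaps transitively, and spans the union of the merged records — a
conservative region for the downstream SNP-in-SV exclusion. The minimum
overlap is exposed as a parameter since larger values are a natural
sensitivity analysis.

# The synthetic population generator

`simulatePopulation()` is a first-class, tested module, not a fixture.
Haplotypes are founder mosaics: each gamete copies one of `nFounders`
(default 16) founder haplotypes per breed and switches to a freshly drawn
founder between adjacent markers with probability
$1-(1-\rho)^{d}$ for distance $d$ bp (`ldRho` = $\rho$, default
$5\times10^{-6}$), so adjacent-marker LD decays with distance and is
tunable from complete ($\rho = 0$: every haplotype is a founder copy) to
none ($\rho$ so large that the founder is redrawn at every marker). An
admixed individual's gametes copy from the Holstein pool with probability
equal to its breed fraction, so admixture itself induces realistic
long-range correlation. SVs are dropped at random positions between
flanking SNPs with interval lengths log-uniform on 100 bp–10 kb and their
alleles ride on the haplotypes exactly like SNP alleles — this is the
property that makes them imputable. Sire–son pairs transmit one
recombinant sire gamete; twice-sequenced duplicates are extra sample
columns with identical genotypes but independently drawn read depths.
Depth is Poisson per call (mean 12 by default, a realistic sequencing
coverage for reference cohorts of this kind; the missingness rule —
depth < 5 ⇒ code 5 — is the substantive part, the law is a modelling
choice). The default cohort (478 individuals, 133 sire–son pairs, 38
duplicates, breed-fraction weights dominated by pure Holstein with a
substantial pure-Jersey minority) mirrors the reference-population
structure of the study design, scaled to 6000 SNPs and 240 SVs on five
10-Mb chromosomes so that the full pipeline runs in seconds.

Phenotypes assign Gaussian effects to a random 10% of SNPs and of SVs
per trait. The SNP component, SV component and residual are made
mutually orthogonal in sample (sequential projection, then rescaling) so
each attains exactly its requested share of the unit phenotypic variance
— the default shares are 0.75 (SNP) and 0.04 (SV), the order of magnitude
reported for production traits — and the variance bookkeeping
$\mathrm{var}(y)=\mathrm{var}(g_{snp})+\mathrm{var}(g_{sv})+\mathrm{var}(e)$
holds to machine precision. The orthogonalization slightly perturbs the
SV component's direction when it correlates with the SNP component by
chance; with random causal sets this is negligible, and it is what makes
the stored "true components" exact rather than approximate.

What the generator does **not** emulate: coalescent site-frequency
spectra, selection and drift across generations, sequencing-read-level
error, caller-specific breakpoint noise, and the real (unknown) MAF
spectrum of cattle SVs — a `mafShape` parameter shapes founder
frequencies instead of guessing that spectrum. Tests passing on this
generator therefore certify the statistical machinery (estimator
identities, calibration, leakage-freedom, monotonicity in LD), not
field performance on real cattle data.

# Numerical choices and degenerate inputs

* Cholesky factorizations that fail get a logged ridge of
  $10^{-6}\times$ mean diagonal; this is the only place a GRM is ever
  perturbed.
* Non-identifiable fits (e.g. a GRM proportional to the identity, or two
  identical GRMs) converge on the flat ridge without crashing; the split
  between the confounded components is then arbitrary but their implied
  covariance $\sum\sigma^2_kG_k$ is stable.
* Monomorphic markers: excluded from GRMs, `NA` in scans and LD windows.
* Imputation: an SV with fewer than two usable flanking SNPs, or fewer
  than three non-missing reference genotypes, yields `NA` predictions;
  accuracy is `NA` when either vector is constant (including the
  boundary case where imputed equals $2-$truth, whose $R^2$ is 1 by the
  sign-blindness of squared correlation — documented, not "fixed").
* Fold plans are seeded uniform partitions with sizes differing by at
  most one; identical seeds give identical partitions, which is what
  makes SNP vs SNP+SV comparisons paired.

# Open design points, resolved

* *Variance components in prediction CV*: re-estimated per training fold
  by default (statistically clean); a reuse-full-data option exists for
  speed and is flagged in the report. Accuracy aggregates fold means
  within a repeat, then mean and SE ($\mathrm{sd}/\sqrt{\mathrm{repeats}}$)
  over repeats.
* *Pooled vs per-fold imputation accuracy*: pooled across folds is the
  headline (every individual is masked exactly once); per-fold tables are
  an option.
* *Single-trait bull/cow meta-analysis*: implemented as the $k=2$ case of
  the $\chi^2$ form; inverse-variance effect pooling would be a possible
  extension.
* *SV dosages vs best-guess genotypes for $G_2$*: the GRM builder accepts
  either; integer codes are the default throughout the pipeline.
* *LD*: computed on dosages (composite LD) rather than haplotypes, since
  phased data are not assumed; windows anchor at the SV midpoint.

# Problem sizes used in the shipped checks

The test suite and the demonstration pipeline use desk-scale sizes chosen
so the whole suite runs in minutes on one core while keeping every
statistical property measurable: REML parameter recovery at $n = 1500$
with 3000 SNPs/300 SVs over 20 replicates; GWAS calibration on 2500 null
markers at $n = 500$; prediction cross-validation at $n = 400$ with
10×10 folds; and an end-to-end demonstration at 500 individuals, 5000
SNPs and 200 SVs that reruns byte-identically. The methods scale as
$O(n^3)$ per REML iteration and $O(n^2 m)$ per scan, so cohorts in the
thousands remain practical.
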