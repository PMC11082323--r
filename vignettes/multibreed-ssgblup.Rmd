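---
title: "Multi-breed single-step GBLUP: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-breed single-step GBLUP: models, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssgblup)
```

This vignette is the package's own account of the science it implements:
the statistical model, what the synthetic-data generator does and does not
emulate, the numerical choices, and the places where the design was
genuinely open and a decision had to be made.

## The evaluation model

Two breeds are reared in separate populations and each expresses the same
biological milk trait (say 305-day milk yield) on its own scale. The
package therefore treats the trait as a **pair of breed-traits** in a
bivariate animal model:

$$
\begin{pmatrix} y_1 \\ y_2 \end{pmatrix} =
\begin{pmatrix} X_1 & 0 \\ 0 & X_2 \end{pmatrix}
\begin{pmatrix} \beta_1 \\ \beta_2 \end{pmatrix} +
\begin{pmatrix} Z_1 & 0 \\ 0 & Z_2 \end{pmatrix}
\begin{pmatrix} a_1 \\ a_2 \end{pmatrix} +
\begin{pmatrix} e_1 \\ e_2 \end{pmatrix}
$$

with $(a_1', a_2')' \sim N(0,\, G_0 \otimes H)$ for a $2\times2$ genetic
(co)variance matrix $G_0$, and residuals independent across breeds
($e_t \sim N(0, I\sigma^2_{e_t})$ — there is no herd in which both breeds
are milked, so a cross-breed residual covariance is structurally
unidentifiable and fixed at zero). Fixed effects are farm, calving
year-class, calving season (breed-specific month-to-season rules) and
parity, dummy-coded with the first observed level per factor as reference
so $X$ is full rank by construction.

$H$ combines pedigree and genomic information. With animals partitioned
into non-genotyped (1) and genotyped (2), the package uses the standard
inverse form

$$
H^{-1} = A^{-1} +
\begin{pmatrix} 0 & 0 \\ 0 & G^{-1} - A_{22}^{-1} \end{pmatrix},
$$

and also assembles the explicit four-block $H$ for cross-checks; the two
agree to $10^{-6}$ on randomized instances (a standing test). Some
presentations print the genotyped-block correction with a "+" between
$G^{-1}$ and $A_{22}^{-1}$ while glossing the term as replacing pedigree
with genomic relationships; the subtraction form is the algebraically
consistent one and is what this package implements.

$G$ is VanRaden's first method, $G = MM'/(2\sum_k p_k(1-p_k))$ with
column $k$ of the dosage matrix centred by $2p_k$. The centring frequency
source is configurable (combined genotyped pool by default, per-breed or
user-supplied as alternatives). Because $G$ from a finite marker panel can
be singular, the genotyped block is blended,
$G_w = (1-w)G + wA_{22}$ with $w = 0.05$ by default ($w = 0$ is allowed and
used in identity tests).

One property worth knowing when reading kinship summaries: when $G$ is
centred with allele frequencies computed from the same combined sample,
every row of $G$ sums to exactly zero, so with two equal-sized breeds the
between-breed block mean is forced to be about as negative as the
within-breed mean is positive. The "between-breed kinship ≈ 0, within-breed
kinship ≫ 0" picture that motivates joint-reference designs corresponds to
centring with frequencies not dominated by the combined sample; the
package's kinship-block diagnostics therefore use ancestral (founder)
frequencies when they are available from the simulator.

## Gibbs sampler

Variance components and breeding values are sampled by a systematic-scan
single-site Gibbs sampler (the same scheme as the classic animal-breeding
Gibbs programs), implemented in compiled code:

* location effects from univariate normal full conditionals, residuals
  maintained incrementally and refreshed every 1,000 iterations against
  numeric drift;
* every animal carries breeding values for **both** traits; animals
  without records on a trait are updated from the prior conditional, which
  is what lets information flow across breeds through $H$ and the genetic
  covariance;
* $G_0$ from an inverted-Wishart full conditional with scale
  $S_g + a'H^{-1}a$ (prior $\nu_g = 4$, scale 30% of each trait's
  phenotypic variance on the diagonal — weakly informative, configurable);
* residual variances from per-trait scaled inverse chi-squares on observed
  records only (prior $\nu_e = 4$, scale 50% of phenotypic variance).

Chain defaults follow the routine protocol: 100,000 iterations, 10,000
burn-in, thinning 50, hence exactly 1,800 retained samples. R's RNG is
used inside the compiled code, so a single seed makes entire runs
bit-reproducible. Convergence is monitored with the Geweke diagnostic
(first 10% vs last 50% of the retained chain, segment variances from the
spectral density at frequency zero via an AIC-selected AR fit); the
pipeline warns — deliberately does not fail — when any variance component
has $|z| > 3$, since a long well-behaved chain occasionally trips a single
diagnostic.

With variance components held fixed, the sampler's posterior means for all
location effects coincide with the direct mixed-model-equation solve; this
dual-route check (sampler vs deterministic dense solver) is part of the
test suite.

Heritability is reported as $h^2 = \sigma^2_a/(\sigma^2_a + \sigma^2_e)$
computed per retained draw; its headline standard error is the empirical
posterior SD of those draws. Two delta-method alternatives are offered:
the textbook first-order propagation (which agrees with the empirical SD
on well-mixed chains) and a variant that circulates in the evaluation
literature lacking the squared-heritability factor and the factor 2 on the
covariance term. The latter is reported verbatim for comparability with
published tables but is not equivalent to the other two — a reader
comparing standard errors across sources should know which formula
produced them.

## The synthetic two-breed study

No real cattle data accompany the package, so the generator reproduces the
*structure* of a two-breed dairy study rather than any observed values:

* **Founder divergence.** An ancestral allele frequency per SNP (uniform
  on 0.1–0.9) diverges into two breed frequencies by the Balding–Nichols
  beta model at Fst = 0.10 by default — enough to give near-zero
  between-breed genomic kinship and a leading principal component that
  separates the breeds, the two structural features that matter for
  joint-reference questions.
* **Ancestral LD.** Founder haplotypes are drawn through a latent AR(1)
  Gaussian copula along each chromosome (exact Bernoulli marginals;
  latent correlation $e^{-d/\lambda}$ with $\lambda$ = 5 cM by default).
  Site-independent founders would carry no linkage disequilibrium at all,
  and two or three generations of gene-drop cannot create the
  distance-dependent $r^2$ that LD-decay diagnostics measure; the copula
  provides it, and $\lambda = 0$ recovers fully independent sites.
* **Recombination.** Haldane model: Poisson crossover counts per
  1-Morgan chromosome, uniform positions, no interference.
* **Trait architecture.** Marker effect pairs are drawn bivariate normal
  with the configured cross-breed genetic correlation (0.5 by default) and
  shared across breeds; each breed-trait's breeding values are rescaled to
  the additive variance implied by its heritability (0.30/0.25) and
  residual scale. Per-breed trait means and phenotypic SDs default to the
  published descriptive scale gap between a dual-purpose mountain breed
  and a specialised dairy breed (≈4,126 ± 1,406 vs ≈10,117 ± 2,045 kg for
  305-day milk yield), so "the same trait on different scales" is a real
  feature of the default data.
* **Records.** One to three lactations per cow; farm (20 levels),
  year-class (2-year bins), season (breed-specific month rules: one
  continental rule with a single autumn month, one standard 3-month rule)
  and parity (1–6). Level effects are drawn once per breed with SDs fixed
  at 10/5/3/5% of the phenotypic SD — large enough that ignoring them
  would visibly bias variance components, small enough not to dominate.

What the generator does **not** emulate: selection and genetic trend,
mutation, genotyping error, sex chromosomes, overlapping generations,
heterogeneous residual variances across herds, and single-parent records
(each animal has either two known parents or none). Passing tests on this
generator therefore demonstrate the *estimator machinery* — QC logic,
relationship algebra, sampler correctness, protocol bookkeeping — not that
any particular field dataset would yield particular values.

With the defaults the pedigree splits each breed's animals evenly across
three discrete generations, founders in generation one; every later animal
draws its sire and dam from the previous generation of its own breed.
`n_animals_per_breed` is the per-breed total. Scaling to a 150K-marker,
multi-thousand-animal study is a configuration change, not a code change.

## Quality control and phenotype screening

QC mirrors routine chip pipelines: animals below 90% call rate out; SNPs
restricted to a configurable chromosome set (1–30 by default, matching the
chip's autosome numbering — the package imposes no opinion on whether a
30th autosome is meaningful for a given species), missingness < 10%,
MAF > 0.01, and Hardy–Weinberg $p > 10^{-6}$ tested **within each breed**
(pooling diverged breeds produces a spurious Wahlund excess of
homozygotes); a Wigginton-style exact test is available behind a flag, the
1-df chi-square being the default because it is cheap and independently
checkable. QC runs per breed before the marker panels are intersected.
Remaining missing dosages are mean-imputed within breed ($2\hat p$), a
deliberate, simple stand-in for haplotype-based imputation that keeps the
allele-frequency structure intact.

Phenotype screening uses closed per-(breed, trait) bounds — a record at a
bound is retained, since a printed range does not specify open intervals —
with defaults encoding typical milk-recording criteria (e.g. 305-day
yields of 2,000–13,000 kg for the smaller breed, 4,000–15,000 kg for the
dairy breed, component percentages 2–7, SCC up to 25,000 thousand
cells/mL). Somatic cell counts transform to scores by
$SCS = \log_2(SCC/100) + 3$, the standard dairy-recording convention; at
the SCC ceiling of 25,000 this gives 10.97, consistent with the score
ranges published for such data. Yield traits can be derived from
percentages as $MFY = 305dMY \times MFP/100$ (likewise protein) when only
percentages are recorded; whether that derivation applies is a
configuration statement, not an assumption baked into code.

## Cross-validation protocol

The joint-reference experiment asks: as 300, 600, … animals of the large
breed join the small breed's 485-strong (by default, its full genotyped
cohort) reference, do the small breed's GEBVs improve? The package
implements it exactly as an evaluation service would:

* **Nested gradient groups.** Added subsets are nested (each scenario
  extends the previous), so the curves differ only by the animals added,
  not by resampling noise; independent redraws are available by flag.
* **Validation group.** The youngest genotyped target-breed cows (born
  within 4 years of the latest birth year; 50 by default), ties broken by
  identifier order for reproducibility.
* **Full vs reduced runs.** The reduced run masks only the validation
  cows' phenotype records; genotypes and pedigree links remain. Both runs
  share the scenario's H matrix. A fixed-effect level present only in
  masked records is dropped with a warning.
* **Metrics.** TBV\* is defined as the full-data GEBV — a proxy, not
  truth; reliability computed against it measures *information recovery*,
  not accuracy against true breeding values, and the package says so in
  its outputs' documentation rather than pretending otherwise. Reliability
  is the Pearson correlation (reported signed, with its square alongside —
  published tables sometimes print signed values under a "squared"
  heading, which a true square cannot produce); bias and inflation are the
  OLS intercept and slope of TBV\* on the reduced-run GEBV. Metrics are
  reported for the whole genotyped target cohort and for the validation
  subset.
* **Base scenario.** With zero added animals the other breed contributes
  no records; its variance components are then prior-driven and only the
  target breed's results are meaningful.

Markers monomorphic within a scenario's genotype pool are dropped for that
scenario (they carry no genomic information and would zero the VanRaden
denominator).

## Numerical choices and degenerate inputs

* Relationship matrices are dense; the tabular A and Henderson $A^{-1}$
  (with inbreeding-adjusted Mendelian sampling variances) are exact to
  $10^{-12}$ against a recursive-kinship oracle, and $AA^{-1} = I$ to
  $10^{-8}$ at $n = 200$. No sparse approximations (APY etc.) — out of
  scope at these sizes.
* The MME solver reports the coefficient-matrix rank when it fails, which
  is almost always level confounding in a small crafted dataset.
* Monomorphic SNPs error out of $G$; entirely-missing-within-breed SNPs
  error out of imputation; zero-variance vectors error out of $r^2$ — all
  are QC's job, and silent NaN propagation would be worse.
* A non-positive-definite sampled $G_0$ (numerically possible at extreme
  configurations) is jittered and logged; persistent failure errors.
* Seeds: one global seed per run; every stage (simulation, grouping,
  chain) derives a named substream, so changing the scenario grid does not
  perturb the simulated data. Derived seeds stay below $2^{31}$.

## Problem sizes used in the shipped checks

The test suite and acceptance script run the full machinery at desk scale:
QC/structure/algebra tests on hundreds of animals and a few hundred
markers; the sampler-vs-solver equivalence on a 50-animal instance with a
60,000-iteration fixed-variance chain; parameter recovery on 500 + 500
animals with 2,000 markers and a 20,000-iteration chain, where the
posterior means recover h² within ±0.05 and the genetic correlation within
±0.15 of the simulation truth. The genetic correlation deserves its wide
tolerance: with near-zero between-breed genomic kinship it is weakly
identified — its posterior SD is ~0.2 even at these sizes — which is
precisely the statistical reason joint reference populations help less
across distant breeds than within them.

## Known limitations

* TBV\* reliability upper-bounds nothing about accuracy against true
  breeding values; use the simulator's stored truth for that question.
* Mean imputation underestimates dosage variance at high missingness;
  keep the missingness QC tight or impute externally.
* The single-site sampler mixes slowly for strongly confounded fixed
  effects; the blocked-by-animal update option helps mixing of breeding
  values but not of $\beta$.
* No metafounders or unknown-parent groups: unknown parents are treated
  as draws from one base population per breed.
* The published-variant heritability SE is reported as printed in the
  literature it mirrors; it is not a calibrated standard error.
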