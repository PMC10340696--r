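---
title: "Heritability, protein composition and marker association in multi-year breeding trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heritability, protein composition and marker association in multi-year breeding trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breedtrial)
```

## The problem

A wheat breeding program screening lines for bread-making quality faces a
recurring question: which of the traits it can afford to measure are under
enough genetic control, and repeatable enough across years, to select on?
Loaf volume is the quality determinant bakers care about, but baking is slow
and expensive; bench proxies (SDS sedimentation volume, a dough
extensibility score, SE-HPLC protein-fraction ratios) and sensory panel
scores are cheaper but noisier. `breedtrial` implements the quantitative
analysis such a program runs on a two-year trial of a fixed line panel:
genotype-by-year ANOVA, broad-sense heritability with confidence limits,
protein-composition ratios, trait correlation/PCA/principal-component
regression, a single-marker association scan with a consensus rule, and a
tie-inclusive check of how often indirect selection recovers the lines
direct selection would have kept.

## The observation model

Each trait is decomposed by the generalized linear model

$$y_{ijk} = \mu + a_i + r_{j:i} + g_k + (ag)_{ik} + e_{ijk},$$

where $a_i$ is the year effect, $r_{j:i}$ the replication (for sensory
traits, the evaluator) within year, $g_k$ the genotype effect, $(ag)_{ik}$
the genotype-by-year interaction and $e_{ijk}$ the residual. `fit_anova()`
produces the sequential (Type I) sums of squares in exactly that term
order. For the balanced or complete designs this package targets, Type I
and Type III coincide, so the choice has no effect on the published-style
mean squares; it is still fixed and recorded because unbalanced evaluator
panels (4--6 tasters) are supported through the same least-squares
decomposition. F statistics for every term are formed against the error
mean square.

Traits measured once per year (loaf volume, loaf height and density, dough
extensibility, protein concentration, the SE-HPLC fraction traits) cannot
separate $(ag)_{ik}$ from $e_{ijk}$: `fit_anova()` then drops to the
reduced model $y = \mu + a_i + g_k + e$, and the interaction is confounded
with error. Reports omit a rep-within-year row for such traits; when the
full model is fitted, pooling that stratum into error is available
(`pool_rep_error = TRUE`) but off by default, since which convention a
given report used is rarely stated and the unpooled table is the more
conservative error definition.

## Two heritability estimators

Both estimators target broad-sense heritability on an entry-mean basis.

**Mean-square ratio** (replicated designs):
$$\hat h^2 = 1 - \frac{MS_{g\times y}}{MS_g},$$
with 90% confidence limits from the F distribution of the mean-square
ratio,
$$UL = 1 - \left[\frac{MS_g}{MS_{g\times y}}
F_{1-\alpha/2;\,df_1,\,df_2}\right]^{-1},\qquad
LL = 1 - \left[\frac{MS_g}{MS_{g\times y}}
F_{\alpha/2;\,df_1,\,df_2}\right]^{-1},$$
where $df_1 = g - 1$ and $df_2 = (g-1)(y-1)$. This is the classical
interval for a heritability defined as one minus a ratio of expected mean
squares: because $F_{\alpha/2} < 1 < F_{1-\alpha/2}$ at any degrees of
freedom, the interval always brackets the point estimate, and under
normality its coverage is exact (the acceptance suite verifies ~0.90
empirically at $g = 76$, $y = 2$). The point estimate can be negative when
the interaction mean square exceeds the genotype mean square; it is
reported raw (intervals crossing zero are informative) with an optional
clamp, and the limits likewise carry a `[0, 1]`-clamped display form.

**Variance components, year as replicate** (unreplicated designs):
$$\hat\sigma_g^2 = \frac{MS_g - MS_e}{r},\qquad
\hat h^2 = \frac{\hat\sigma_g^2}{\hat\sigma_g^2 + \hat\sigma_e^2 / r},$$
with $r$ the number of years. The method-of-moments extraction is not
stated in most trial reports, but it is the unique choice that reproduces
published loaf-volume-type heritabilities from their printed mean squares,
which is how it is validated here (see `quality_reference_ms()` and the
acceptance script). Negative $\hat\sigma_g^2$ is truncated at zero and
flagged, so this estimator always lands in $[0, 1]$.

`estimate_h2()` picks the estimator from the fitted design automatically:
full model → ratio path, reduced model → variance-component path.

## Entry means, BLUPs and the scan environments

GWAS responses are built per trait in four "environments": each year's
entry means (ENV1, ENV2), the across-year entry means (ENV3), and BLUPs
(ENV4). The BLUP here is deliberately simple shrinkage — entry means pulled
toward the grand mean by $k = \hat\sigma_g^2 / (\hat\sigma_g^2 +
\hat\sigma_e^2 / r)$, $k$ clamped to $[0,1]$ — not a REML mixed-model fit,
which is out of scope. Shrinkage never widens the spread of entry means,
and degenerate variance estimates collapse all BLUPs to the grand mean.

## Protein fractions

SE-HPLC profiles split into four fractions: F1 (HMW polymeric protein), F2
(LMW glutenin polymers), F3 (gliadins), F4 (albumins/globulins/
hydrolysates), each measured in the SDS-extractable (E) and unextractable
(U) phases; T = E + U. Area percentages (A%) normalise each set to 100 and
are the traits fed to ANOVA (composition, not protein amount). The
composition ratios are computed from raw areas: Gli:Glu = F3/(F1+F2),
HMW:LMW = F1/F2, and UPP:TPP = U-polymeric over total polymeric, always in
$[0,1]$. F4 enters no ratio. Gli:Glu uses the total fractions by default;
whether a given report used total or extractable-only gliadin is often
ambiguous, so `gliadin_set = "extractable"` is exposed. All ratios are
invariant to uniform rescaling of the chromatogram.

## Correlations, PCA, PCR

`correlation_matrix()` computes pairwise-complete Pearson r with two-sided
t p-values and the significance stars conventional in trial reports
((\*) < 0.1, (\*\*) < 0.05, (\*\*\*) < 0.001), deliberately without
multiplicity correction to match that reporting style. `trait_pca()`
centres and (by default) scales traits, mean-imputes sporadic missing cells
(or drops rows), and fixes each component's sign by making its
largest-magnitude loading positive, so scores are reproducible across
platforms. Both genotype-row and genotype-by-year-row layouts are
legitimate inputs — the caller chooses which matrix to pass, since biplots
separating years require the latter. `pcr_fit()` regresses a response
(typically loaf volume) on the first k scores; `k_for_variance()` picks the
smallest k reaching a cumulative-variance threshold, defaulting to 0.97
because about six components typically carry ~97% of the variance in
protein-fraction panels of this size. PCR $R^2$ is non-decreasing in k and
invariant to the PCA sign convention.

## The association scan

Markers are QC-filtered with the conventional GBS panel gates: missing
fraction ≤ 0.5, minor allele frequency ≥ 0.05, heterozygosity ≤ 0.10 (MAF
and het computed on non-missing calls). The scan itself is a per-marker
ordinary least squares of the response on an intercept, three
genotype-matrix principal components (population-structure covariates;
the count is configurable since conventions differ), and the allele dose,
with a two-sided t test on the dose coefficient. Lines missing a call at a
marker are dropped pairwise; markers left with fewer than `n_pcs + 3`
complete lines, or a dose collinear with the covariates, are skipped with a
recorded reason. Effects are also expressed as a percentage of the trait
mean, the scale on which hit catalogues are reported.

Hit declaration applies two significance gates conjunctively — raw
$p \le 1/n_{\text{markers}}$ and Benjamini–Hochberg adjusted $p < 0.1$ —
plus a minimal effect size (0.1% of the trait mean); whether the 1/n gate
should apply at all is genuinely ambiguous in common practice, so
`raw_cutoff = NULL` disables it. A marker becomes a consensus hit only if
its passing supports span at least two environments or two association
models; result tables from other GWAS programs (BLINK, FarmCPU and the
like) can be imported as CSV and participate identically, since the
consensus rule is model-agnostic. Declared hits are validated by a Welch t
test between the two homozygote classes (heterozygotes excluded, letter
codes a/b at $\alpha = 0.05$), refusing marker-trait pairs where a class
has fewer than two lines.

## Tie-inclusive selection overlap

Breeders select "the top 10", but rounded trait scales tie: `top_k()`
returns every genotype tying or beating the k-th ranked value, the only
reading under which a nominal top-10 can legitimately contain 21 lines.
`overlap()` reports the intersection as a percentage of the *selecting*
set, rounded half-up — the asymmetric denominator matches how coincidence
percentages are quoted in practice (14 of 34 → 41%).
`indirect_selection_report()` emits the four informative comparisons:
proxy(year 1) → target(year 2), proxy(mean) → target(mean), target(year 1)
→ target(year 2) and proxy(year 1) → proxy(year 2), the last two being the
direct-selection and proxy repeatability baselines.

## What the generator emulates — and what it does not

`simulate_phenotypes()` draws every effect of the observation model once
per index combination from independent zero-mean normals with the
configured variances; genotype effects across traits are drawn jointly
under a target genetic correlation matrix (imposed on genotype effects
only, because correlations computed on entry means are dominated by the
genetic component at realistic variance ratios). Sensory scores are
produced by clipping a latent normal to the scale bounds and rounding to
the nearest unit *after* all effects are summed. Defaults mirror the trial
the package is built around: 76 genotypes, 2 years, 4–6 evaluators for
sensory traits (per-year counts may differ; the balanced default keeps
exact-ANOVA tests simple), single observation per year otherwise, and
variance magnitudes consistent with the bundled reference mean squares
(e.g. loaf volume: mean 500 cm³, $\sigma_g^2 = 636.89$,
$\sigma_e^2 = 602.08$).

`simulate_genotypes()` produces a biallelic panel with per-marker allele
frequency drawn from a MAF range, configurable missing and heterozygote
rates, and strictly increasing positions on the 21 wheat chromosomes; it
emulates the *statistical* structure of a filtered GBS panel at reduced
scale (hundreds to thousands of markers rather than ~12,808). It does not
simulate linkage disequilibrium, population structure, reads, or SNP
calling, and the phenotype generator has no weather or agronomy covariates.
Passing tests therefore demonstrate correctness of the estimators under
the stated random-effects model — not robustness to LD between a QTL and
its neighbours, confounding structure, or non-normal residuals in real
panels. `inject_qtl()` plants additive effects as centred dose increments
(so trait means are unchanged), recording each QTL in the truth record
alongside the generating components and the heritabilities they imply for
both estimator paths.

## Numerical choices and degenerate inputs

* Sequential SS come from the QR-based least-squares fit; the test suite
  cross-checks 100 random balanced designs against an independent
  nested-model residual-SS-differencing oracle at 1e-9 relative tolerance.
* Ties in major-allele recoding (frequency exactly 0.5) keep the as-read
  orientation; orientation flips dose d → 2−d and can only flip association
  effect signs, never QC decisions or p-values.
* A constant trait yields an all-zero ANOVA without error; genotypes
  observed in a single year are excluded with a warning before fitting.
* Zero denominators (total absorbance, ratio denominators, variance sums)
  reject or flag per sample rather than emitting NaN silently.
* `h2_vc` truncation happens in the variance-component extraction, so an
  exactly-zero genotypic variance is distinguishable from a truncated
  negative one.

## Validation scale

The shipped suite exercises the stochastic guarantees at the trial's own
scale, chosen to make Monte-Carlo error small relative to each tolerance:
1000 simulated 76×2×2 trials for the 90% interval coverage (±0.04 band),
200 seeds per truth level for estimator recovery (±0.05), 100 seeds of a
76-line, 1000-marker panel for QTL ranking power (≥ 80%), five pooled null
traits over 1000 markers for scan calibration, and 1000 random vectors for
the BH step-up oracle. Larger panels change runtimes, not conclusions,
because every estimator is closed-form given the design.

## Known limitations

* No REML mixed models, kinship correction, or spatial trend adjustment;
  the GLM scan will inherit confounding that a kinship-aware model would
  absorb.
* The F-based interval assumes balanced data and normal effects; with
  heavily unbalanced evaluator panels the mean squares remain well-defined
  (least squares) but the interval's exactness does not.
* Chromatogram peak integration is out of scope: fraction areas are taken
  as given.
* Published dataset-specific quantities (correlation tables, PCA
  percentages, specific hit catalogues) depend on undeposited raw data and
  are not reproduction targets; the property-based suites cover those code
  paths instead.
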