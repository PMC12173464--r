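---
title: "Methods: longitudinal mixed-model QTL mapping in strain panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal mixed-model QTL mapping in strain panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelscan)
```

## The problem

Fixed genetic panels of inbred and recombinant inbred (RI) mouse strains are
a workhorse for mapping behavioral and molecular traits: every genome is
known, immortal, and can be phenotyped repeatedly. `panelscan` implements the
analysis chain for one such design — a panel of ~84 strains, ~6 mice per
strain, tested in daily operant self-administration sessions for 10 days,
with pooled RNA-seq (one library per strain × sex × brain region) for
transcript abundance, exon percent-spliced-in (ψ) and A-to-I RNA-editing
ratios (ϕ) in a 41-strain subset.

The central statistical idea is to use the whole longitudinal trajectory in
one mixed model rather than mapping each day separately: day enters both as a
fixed slope and as a random, individually varying slope, and both the random
intercepts and random slopes carry a kinship-structured component that
corrects for population structure.

## The longitudinal model

For mouse $i$ (strain $s(i)$) on day $j$:

$$Y_{ij} = \alpha_0 + \sum_k \gamma_k \mathrm{SNP}_{k,s(i)} + \alpha_1
\mathrm{Age}_i + \alpha_2 \mathrm{Sex}_i + \alpha_3 \mathrm{Lever}_i +
\alpha_4 \mathrm{Chamber}_i + \alpha_5 \mathrm{Cohort}_i + \alpha_6 d_j +
\beta_{0i} + \beta_{1i} d_j + \varepsilon_{ij}$$

with $\beta_0 \sim N(0, \sigma_1^2 G_n + \sigma_2^2 I)$, $\beta_1 \sim N(0,
\sigma_3^2 G_n + \sigma_4^2 I)$, $\mathrm{Cov}(\beta_0, \beta_1) = \sigma_5^2
G_n + \sigma_6^2 I$ and $\varepsilon_{ij} \sim N(0, \sigma^2)$, where $G_n$
expands the strain-level GRM to individuals. Marginally,

$$\mathrm{Cov}(Y_{ij}, Y_{i'j'}) = K_0[i,i'] + K_5[i,i'](d_j + d_{j'}) +
K_3[i,i'] d_j d_{j'} + \sigma^2 \delta_{ii'} \delta_{jj'},$$

with $K_0 = \sigma_1^2 G_n + \sigma_2^2 I$ and so on. Admissibility requires
the two 2×2 component matrices (genetic and individual) to be positive
semi-definite; `variance_components()` enforces this, and the REML optimizer
works on a transformed scale (log variances, `tanh` correlations) that can
only produce admissible points.

**Spectral fitting.** For balanced designs (every mouse observed on the same
day grid, the design the generator produces) the eigendecomposition $G_n = U
\Lambda U'$ block-diagonalizes the marginal covariance into $T \times T$
blocks $V_l = \sigma^2 I + F D_l F'$ with $F = [\mathbf{1}\; d]$ and $D_l$ a
2×2 matrix linear in $\lambda_l$. Rank-2 Woodbury identities reduce a REML
evaluation to vectorized 2×2 arithmetic across eigenvalues, so a fit on 504
mice × 10 days takes well under a second. Unbalanced data fall back to a
dense-covariance path (used in tests as the reference implementation; the two
paths agree to 10⁻⁸ and the dense covariance matches a brute-force
construction from explicit random-effect design matrices to 10⁻¹⁰). The REML
log-likelihood matches `lme4` exactly when the kinship is the identity, which
is the model-equivalence oracle in the test suite.

**Wald scans.** Variance components are estimated once under the null and
held fixed across markers — the standard two-stage economy in
population-structure GWAS; the model source does not state whether components
were re-estimated per SNP, and two-stage is the convention of the panel
literature. Each marker's strain genotype is broadcast to its mice,
mean-imputed for missing calls (heterozygous calls enter as 0.5 dosage), and
its effect estimated by partitioned GLS on the rotated system; the Wald
$Z = \hat\gamma/\mathrm{se}$ gets a two-sided normal p-value. Markers
collinear with the covariates are flagged and excluded.

**Day coding.** Day enters as 1…10 uncentered by default (`center_day`
switches this); centering changes the interpretation of the intercept-slope
covariance but not the Wald test.

## Permutation thresholds

Genome-wide 5% thresholds come from the empirical quantile of the scan's
minimum p-value under resampling. The naive scheme — permuting the
strain-to-genotype assignment — turned out to be **anticonservative** here
(family-wise error ≈ 0.12–0.15 instead of 0.05 in 200-replicate null
calibrations, even with the true variance components): the phenotype
covariance is aligned with the kinship built from the same markers, and
permuted genotypes lose that alignment, so permuted scans are systematically
tamer than real null scans. The default scheme is therefore a
whitened-residual (multivariate-normal) permutation: residuals $y - X\hat\alpha$
are whitened by $V^{-1/2}$ on the spectral blocks, permuted at the
observation level, re-colored by $V^{1/2}$, and each resampled phenotype is
rescanned against the *original* genotypes. This preserves both the
longitudinal/covariate structure and the marker–kinship geometry. Calibration
on 200 null panels at $B = 500$ gives a family-wise error of 0.03 — at
nominal level within Monte-Carlo error, on the conservative side. The
strain-label scheme remains available (`scheme = "strain_label"`) for
comparison.

One geometry caveat the calibration experiments exposed: when the GRM is
computed from only a few hundred markers and those same markers are scanned,
each marker contributes a non-negligible share of its own effect to the
kinship ("proximal contamination"), which deflates its statistic. The
calibration and examples therefore compute the kinship from a genome-wide
marker set and scan a subset, matching the real geometry (hundreds of
thousands of GRM markers). Leave-one-chromosome-out kinship is available via
`compute_kinship(exclude_chrom = )`.

## Phenotype normalization and time courses

Daily endpoints are normalized per day by the rank-based inverse normal
transform with Blom's constant 3/8 (configurable), ties sharing the mean of
their ranks. Percent active presses with zero total presses is recorded as
missing — neither 0 nor 100 is defensible for 0/0. Note that per-day
normalization forces each day's cross-sectional distribution to standard
normal, so aggregate day trends in the population mean are removed by
construction; in real data, ties, attrition and missing sessions leave
detectable day effects, whereas on clean synthetic data the fixed-day
estimate is zero to numerical precision.

Endpoint time courses are tested with a mouse-level mixed model (random
intercept and day slope per mouse, unstructured 2×2 covariance, no kinship)
via `lmerTest`; the fixed-day t statistic uses the **Satterthwaite**
denominator df rather than Kenward–Roger — at ~477 mice the two are
practically identical, and Satterthwaite is available in a maintained,
well-tested implementation. A singular unstructured fit is automatically
refit with independent intercept and slope and flagged.

## Molecular traits

* **Expression**: TPM from counts and lengths; a transcript is retained if it
  has ≥ 6 reads and TPM > 0.1 in ≥ 20% of libraries of *every*
  infusate × region stratum; retained `log2(TPM + 1)` rows are quantile
  normalized within stratum. Plain quantile normalization stands in for
  conditional (GC/length-covariate) quantile normalization; the GC machinery
  is out of scope and the substitution is switch-visible in the code path.
  The in-package quantile normalization maps ranks onto an interpolated
  common reference so that missing values keep their rank position; on
  complete matrices it agrees with `limma::normalizeQuantiles` (a test
  cross-checks this). With ties, equal inputs map to equal outputs, which is
  preferred over making sorted columns exactly identical.
* **Splicing**: ψ = inclusion/(inclusion+exclusion), missing when no reads;
  exons need ≥ 5 total reads in all libraries and non-zero ψ standard
  deviation; the exon with the largest ψ standard deviation represents each
  transcript.
* **Editing**: ϕ = edited/total where total > 0 ("has data"); a site is
  retained when ≥ 10% of libraries have data (boundary inclusive), and the
  ascertainment rate is the mean fraction of libraries with data across
  retained sites. The generator exposes the per-library detectability, so a
  thinning probability of 0.367 reproduces the ~36.7% ascertainment scale of
  real A-to-I surveys.

Molecular QTLs are mapped per trait with the single-kinship mixed model on
the eigenbasis of the library-level GRM, one shared eigendecomposition for
all complete traits (per-pattern decompositions for traits with missing
libraries; traits in fewer than 10 libraries are skipped). The variance ratio
is optimized by profile REML in one dimension; markers are tested by Wald t
with the residual variance re-profiled per marker (df = n − p − 1), which
reduces *exactly* to ordinary linear regression when the kinship is the
identity — the equivalence oracle in the tests. The per-trait significance
default is Bonferroni across markers at 0.05; the panel literature does not
publish a universal molecular threshold, and the Bonferroni default is
conservative and reproducible. Cis means within 2 Mb of the nearest feature
edge (boundary inclusive); QTL-QTL *coincidence* is strict (< 2 Mb between
peaks).

Because all retained traits are quantile-normalized jointly per library, a
planted trans-regulator that shifts a large *fraction* of the transcriptome
leaks into other genes through the normalization itself. This is a property
of global normalization, not of the mapper; in real data hotspot targets are
a fraction of a percent of transcripts. Synthetic annotations therefore use
enough genes (hundreds) that hotspot targets stay a small fraction.

## Integration layer

Hotspots: distinct trans genes per marker against a Poisson null with rate
(total trans associations)/(markers), BH-adjusted; a hotspot needs ≥ 20 genes
and q < 0.05. The hotspot counting unit is the single marker; LD makes counts
blocky, so flagged markers typically come in clumps around the causal one.
Fisher enrichments report the cross-product odds ratio (with
Haldane-corrected estimate alongside for degenerate tables) and the exact
two-sided hypergeometric p (via `fisher.test`, verified against full
enumeration for all tables with margins ≤ 12). The editing-region enrichment
contrasts mature-mRNA categories (5'UTR, 3'UTR, CDS) against intron/intergenic
among coincident vs non-coincident sites. LD statistics treat inbred strains
as haploid; D' uses Lewontin's normalization, and the chi-square p comes from
$n r^2$. The SNP-by-infusate interaction test stacks two cohorts, holds each
cohort's covariance at its null REML estimate, and Wald-tests the interaction
coefficient in the joint GLS; cohort label swaps flip its sign exactly.

## The synthetic panel generator

The generator is first-class, tested code and defines the study conditions:

* 84 strains (32 inbred + 52 RI), ~6 mice per strain (sex balanced within
  strain), 10 daily sessions; pooled libraries per strain × sex (× region ×
  infusate) for molecular traits, batches assigned by strain.
* Inbred haplotypes follow a stationary two-state process along each
  chromosome (allele correlation $e^{-d/L}$, default $L$ = 5 Mb), RI genomes
  are two-founder mosaics with a Poisson number of breakpoints per chromosome
  — together producing block LD, realistic relatedness, and the LD decay that
  the tests verify directly. Two-founder (BXD-like) mosaics suffice for block
  LD; eight-founder mosaics are not modeled.
* Default variance components: $\sigma_1^2 = 0.3$, $\sigma_2^2 = 0.2$,
  $\sigma_3^2 = \sigma_4^2 = 0.02$, $\sigma_5^2 = \sigma_6^2 = 0$,
  $\sigma^2 = 0.5$. The strain-level intercept heritability implied
  (~0.3) matches the narrow-sense heritability scale reported for saline
  self-administration in this kind of panel. Covariates the design literature
  leaves unspecified are fixed once: age uniform 9–14 weeks, lever/chamber
  counterbalanced by random assignment, cohorts in contiguous blocks
  (~13 mice each).
* Planted truths are recorded in a `truth_record` so downstream stages can be
  tested for recovery: behavioral SNP effects (demonstration effects use
  markers mostly orthogonal to the leading kinship eigenvectors, because
  effects confounded with structure are absorbed by the model *by design* and
  say nothing about marker-level power), cis effects with allelic fold change
  4 (log2 scale for expression, logit shifts for ψ/ϕ), and one trans hotspot
  whose targets get an 8-fold allelic change — a strong master-regulator, so
  that the ≥ 20-gene flag is a meaningful smoke property. Hotspot targets
  never overlap planted cis genes.
* Negative binomial counts (size 8) for expression, binomial counts around
  strain-level logits for ψ and ϕ, log-normal library size factors, and
  per-library detectability thinning for editing sites.

**What the generator does not emulate:** real mouse genome coordinates and
gene density, sex-chromosome dosage, read-level sequencing artifacts, GC and
length biases (the reason conditional quantile normalization exists),
attrition/missing sessions, and the long-tailed count distributions of real
behavioral endpoints. Passing tests therefore demonstrate that the machinery
is correct and calibrated under the stated generating model, not that any
particular biological result would replicate.

## Numerical choices and degenerate inputs

* REML: Nelder-Mead on the transformed scale with a polish restart; moment
  starts from per-mouse OLS. Zero-variance truths land at the boundary
  (estimates < 0.05 on a unit scale). Constant phenotypes give exact-zero
  marker effects.
* Identical inputs in `blom_transform` return 0 with a warning (a single tie
  group maps to the median rank); `zscore` refuses constant input.
* `call_loci` merges suprathreshold markers with gaps < 2 Mb by single
  linkage; the peak is the minimum p, ties broken toward the lower position.
  Tied gene distances in `locus_report` are broken by gene id.
* BED is the only 0-based, half-open surface; it is converted at the boundary
  (`read_bed`/`write_bed`), with per-line errors and empty intervals
  rejected. All internal coordinates are 1-based inclusive. TSV dialect:
  tab-separated, UTF-8, `NA` for missing, no quoting.

## Problem sizes used by the test and acceptance suites

Parameter recovery runs 20 replicates of 100-strain × 6-mouse × 10-day
panels; permutation calibration runs 200 null scans of 200 markers at
B = 500 on 40-strain panels with a 1000-marker GRM; planted-truth recovery
runs 20 seeds of a 40-strain, 200-marker, 300-gene molecular panel. These
sizes were chosen so the full battery completes in a few minutes while
keeping Monte-Carlo error well inside the asserted bands.

## Known limitations

* Exact Kenward–Roger df, score tests, TWAS weight training, Bayesian
  fine-mapping/colocalization posteriors are out of scope; proximity-based
  coincidence stands in for colocalization.
* The Wald scan's normal reference is asymptotic in the number of strains;
  with very few strains the flagged-collinearity guard matters more than the
  p-values.
* The whitened-residual permutation conditions on the estimated
  $\hat V$; its slight conservatism (0.03 vs 0.05 in calibration) is the
  price of that plug-in.
* Per-trait variance-ratio estimation in the molecular mapper has an
  O(1/n libraries) overfitting bias, visible only as a percent-level
  deflation of the null p-value distribution at tiny library counts.
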