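---
title: "Modelling environment-induced heritable variation across generations"
author: "heritvar maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling environment-induced heritable variation across generations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heritvar)
```

## The scientific question

Parental and ancestral environments can induce phenotypic and
gene-expression changes in offspring that persist after the environmental
trigger is gone. Whether such induced changes are *heritable* — still
detectable several generations later under common-garden conditions — is a
question that can only be answered by large multigenerational experiments:
many genotypes, many ancestral environments, several offspring generations,
and replicate lines propagated by single-seed descent.

`heritvar` implements the full analysis chain for this kind of experiment
in *Arabidopsis thaliana*-style designs:

1. **Design construction and simulation** — replicate lines per genotype
   and ancestral environment, randomized positions in a layered growth
   room, and synthetic phenotypes, counts, annotations and metadata with
   known planted ground truth.
2. **Effect-size estimation** — genotype-specific ancestral-environment
   effects from Gaussian linear mixed models, per phenotype, treatment and
   generation.
3. **Heritability classification** — conversion of effect sizes to binary
   occurrence and classification of each induced change as transient,
   heritable or persistent across the four offspring generations.
4. **Predictability and reproducibility** — a binomial GLMM for the
   determinants of occurrence, single-step multiple-comparison adjustment,
   regressions of occurrence frequency on climate, methylation and
   transposon abundance, and paired effect-size correlations between
   generations and tests.
5. **Differential expression** — a negative-binomial Wald test per
   genotype × treatment × generation with a heritable-DEG rule.
6. **Transposon enrichment** — a resampling null for transposon abundance
   in the promoter-plus-gene-body regions of susceptible genes.

## The phenotype model

For the ancestral generation the package fits, per phenotype,

$$Y_{\mathrm{Anc}} \sim G + E + G{:}E + (1\mid A.\mathrm{Layer}) +
  (1\mid A.\mathrm{Row})$$

and for each offspring generation

$$Y_{\mathrm{Off}} \sim O.\mathrm{Layer} + G + A.E + G{:}A.E +
  (1\mid A.\mathrm{Layer}) + (1\mid A.\mathrm{Row}),$$

where $G$ is the genotype, $E$ (or $A.E$) the (ancestral) environment,
$O.\mathrm{Layer}$ the plant's own growth-room layer, and the random
intercepts capture the spatial structure of the ancestral generation. Rows
are numbered uniquely across layers. Fits use REML (`lme4::lmer`); fixed
terms are tested with Type-II Wald chi-square statistics (`car::Anova`).
When a random term's variance estimate collapses to zero the model is refit
without it and the component reported as exactly zero; with no random term
left the fit is ordinary least squares, and the package tests assert exact
agreement with a normal-equations oracle in that case.

The **per-genotype effect size** of treatment $t$ in generation $f$ is the
treatment-vs-reference contrast "treatment main effect + genotype:treatment
interaction deviation", with its standard error from the coefficient
covariance and a two-sided Wald (normal) P value. Two points deserve
emphasis:

* Phenotypes are z-standardized within (test, generation) before the
  contrast is estimated, so effect sizes are in within-phenotype SD units
  and comparable across phenotypes; raw-scale estimates are retained in
  `estimate_raw`.
* The jasmonic-acid treatment is contrasted against its own solvent
  control (`JA_control`), all other treatments against the global control.

Wald-normal P values are slightly liberal in small fits; at the arm sizes
of the full design (14 genotypes, 12 control and 6 treatment replicates)
the package's calibration suite measures a null occurrence rate of about
0.05–0.06 at a nominal 0.05.

## From effect sizes to heritability calls

An induced change *occurs* when its two-sided P is strictly below
`alpha = 0.05`; a *marginal* occurrence uses `alpha_marginal = 0.1` (the
conventional band; the marginal cutoff is a package choice, exposed as a
parameter). Per (genotype, treatment, phenotype) key the occurrence vector
over F1–F4 is classified:

| significant generations | category |
|---|---|
| 0 | none |
| 1 | transient |
| ≥ 2 | heritable |
| ≥ 3 including F4 | persistent (default reading) |
| 4 | four-generation |

The phrase behind "persistent" is ambiguous between "any three of four
plus the fourth" and "all four"; the package defaults to the former and
ships the latter as `persistent = "all_four"`. Categories nest by
construction, and the classifier is provably monotone: adding a
significant generation never demotes a key.

Under independent null tests at $\alpha = 0.05$ the heritable rate has the
closed form $1 - 0.95^4 - 4 \cdot 0.05 \cdot 0.95^3 \approx 0.014$ — the
pipeline's false-heritability floor, asserted by simulation at 6000 keys.

## Occurrence modelling and reproducibility

Occurrence is modelled with a logistic mixed model
$Y \sim G + A.E + F + \mathrm{Trait} + (1 \mid \mathrm{group})$, where a
group is the six-replicate set behind one genotype × treatment ×
generation cell (all phenotypes of a group share its random intercept).
Complete separation (a factor level with all-0 or all-1 outcomes) is
detected up front and the model downgraded to a Firth-penalized
fixed-effects logistic regression — written in-package — with a logged
message.

Pairwise level comparisons are adjusted with the **single-step max-|z|
method**: each standardized contrast is referred to the distribution of
the maximum absolute component of the joint normal implied by the contrast
covariance. The package evaluates this by seeded Monte Carlo (100,000
draws by default) and reports the Monte-Carlo standard error; with one
contrast, or perfectly correlated contrasts, the adjusted P provably
equals the unadjusted one, and the test suite anchors the two-independent-
contrast case to the Šidák closed form.

Occurrence frequency per genotype is arcsine-square-root transformed and
regressed on one predictor at a time: climate variables untransformed,
methylation untransformed, transposon counts log transformed. No
cross-predictor adjustment is applied (matching per-predictor reporting);
a BH column is appended for reference.

Reproducibility is quantified as Pearson correlations of matched effect
sizes between generation pairs, between the ancestral response and each
generation, and between the two tests — for all pairs, for pairs
significant in either member, and for the complement. In stable-
transmission simulations the ordering r(significant) > r(all) >
r(nonsignificant) is recovered in well over 90% of runs; scaling the
analysis down to a single genotype or treatment lowers the share of
significant generation-pair correlations, mirroring the value of scale in
such experiments.

## The count stage

Genes enter a genotype's treatment analysis when the **sum of CPM over the
treatment and control samples is strictly greater than one**. Library
sizes are normalized with **median-of-ratios** size factors (the median,
over genes expressed everywhere, of count / gene geometric mean,
normalized to geometric mean one; a positive-count pseudo-reference is an
explicit opt-in fallback).

The DE test is a per-gene negative-binomial GLM with log link on the
treatment indicator, offset by the log size factor. Dispersions are
method-of-moments estimates $\hat\alpha = \max(0, (s^2 - \bar m)/\bar
m^2)$ shrunk halfway toward a smooth $a_0 + a_1/\mu$ trend — a deliberate,
documented simplification relative to empirical-Bayes machinery; there is
no independent filtering or outlier replacement. The treatment coefficient
is tested with a two-sided Wald test, BH-adjusted within the (genotype,
treatment, generation) family, and a gene is a DEG when |log2FC| > 1.5
(strict) and adjusted P < 0.05. A gene differentially expressed in **at
least two generations** of a genotype × treatment is a heritable DEG.
Calibration suites assert a null FDR far below the band, power ≈ 1 for
planted |log2FC| = 3 at baseline mean 100 with dispersion 0.05 (3 vs 3),
and near-perfect recovery of genes planted in two generations, while
one-generation genes are never called heritable.

Because the generation arithmetic of a shared-control transcriptome design
is ambiguous, both layouts are constructed (`transcriptomeSamples("full")`
with 192 samples, `"compact"` with 144 treatment samples plus a shared
control arm), and `nbWaldTest(control_pairing=)` supports generation-
matched and pooled control pairing. The contrast partition — 12 genotype ×
treatment sets — is identical in both.

## Transposon enrichment

Each gene's region is its body extended 2 kb upstream of the transcription
start (strand-aware, truncated at chromosome bounds; 1-based closed
coordinates as in GFF3). A transposon counts for a gene when it shares at
least one base with the region, and a TE spanning several regions counts
once per gene. The enrichment statistic is the summed count over a gene
set; its null distribution comes from repeatedly drawing equally many
genes, without replacement, from the background universe (the post-filter
DE gene set). The empirical P is the proportion of null draws **strictly
greater** than the observed total, so ties favour enrichment and P = 0 is
possible; a (k+1)/(N+1) estimator is available but non-default. Copies are
counted by default; a base-pair mode sums intersection widths. On a
six-gene toy background the Monte-Carlo P agrees with exhaustive
enumeration over all 20 subsets to within 0.01 at 100,000 draws, and under
a TE-uniform annotation the P values are uniform.

## What the generators emulate — and what they do not

The synthetic design reproduces the experiment's arithmetic exactly: 14
genotypes × (12 control + 10 × 6 treatment replicates) = 1008 lines
followed for four generations (4032 offspring plants); the
uniform-conditions test with 10 genotypes × 6 environments × 6 replicates
= 360 lines, all generations planted together (1440 plants); and a
transcriptomic sub-design of 4 genotypes × 3 treatments (plus control) × 4
generations × 3 replicates.

Phenotypes are simulated on a standardized latent scale — genotype mean +
direct treatment response (ancestral generation only) + planted effect ×
a per-generation transmission multiplier + layer + row + line + residual —
then mapped to natural units (flowering time ≈ 32 ± 3 d, plant height ≈
30 ± 4 cm, biomass ≈ 0.8 ± 0.15 g, rosette diameter ≈ 9 ± 1.2 cm, fruit
number ≈ 120 ± 25, rounded and floored at zero). Default nuisance SDs
(layer 0.15, row 0.10, line 0.25, residual 1) give spatial variance shares
typical of growth-room experiments. Ancestral lines die before seed set
with probability 0.0258, and their descendants are drawn from a random
surviving replicate of the same cell and flagged `replaced` — mirroring
the replacement practice of such experiments without modelling biology.
Transmission is a phenomenological multiplier; there is no mechanism
(methylation dynamics, small RNAs, seed provisioning) behind it, so
passing recovery tests says the *statistical pipeline* is sound, not that
any mechanistic model fits real data. Counts are NB with log-normal
baselines and planted fold changes; annotations place TEs uniformly except
for a configurable intensity multiplier inside susceptible-gene windows;
metadata plant a log-linear link between one superfamily's copy number and
genotype susceptibility. Real data differ in ways the generators do not
attempt: correlated phenotypes, mean–variance relationships beyond NB,
non-uniform TE landscapes, climate collinearity.

## Numerical choices and problem sizes

* Random streams are split per artifact from one master seed
  (`subSeed`), so regenerating any single artifact is independent of the
  others and every object is bit-reproducible given its seed.
* Strict inequalities everywhere a threshold is applied (P < 0.05,
  |log2FC| > 1.5, sum CPM > 1, null > observed): boundary cases fall on
  the conservative side, and the tests pin each one.
* NB GLM fits use a vectorized two-parameter IRLS with clamped means and
  coefficients; genes with degenerate data return NA statistics and leave
  the BH family.
* Monte-Carlo sizes are chosen so sampling error is well below the
  decision bands: 500 seeds for effect-size coverage, ≥ 2000 tests for
  type-I calibration, 6000 keys for the heritability floor, 200 runs for
  the reproducibility ordering, 50 × 2000 genes for DE calibration,
  100,000 permutation draws against exact enumeration. The whole suite
  runs in a few minutes on one CPU.

## Known limitations

* Degrees-of-freedom corrections (Kenward–Roger, Satterthwaite) are out of
  scope; Wald-normal P values are slightly liberal in small fits.
* The dispersion shrinkage is a fixed-weight compromise, not an
  empirical-Bayes posterior; exact agreement with DESeq2 is a non-goal
  (a cross-check test asserts close fold-change agreement).
* GO/KEGG enrichment requires annotation databases and is out of scope;
  only set-overlap summaries over supplied term/gene sets are provided.
* Genotype-specific genome assemblies are not modelled; the TE analysis
  assumes one shared annotation.
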