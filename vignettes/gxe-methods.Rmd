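---
title: "Detecting QTL-by-environment interaction in multi-environment RIL trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting QTL-by-environment interaction in multi-environment RIL trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A recombinant inbred line (RIL) population grown at several locations
lets one ask not only *where* trait-controlling loci sit, but *whether
their effects change with the environment*. `gxescan` implements a
linear-mixed-model comparison approach to that question for biparental
RIL populations (near-homozygous lines derived by single seed descent,
e.g. F2 to F9) phenotyped as line means in a small number of
environments, together with the surrounding machinery: variance
decomposition, broad-sense heritability, per-locus SNP-by-environment
(SxE) variance shares, and tests that attribute a detected interaction
to measured environmental factors.

## Models

All phenotypes for one trait and one year are stacked into a single
vector `y` (ordered environment-major), with incidence matrices `Z`
(observation to line), `W` (observation to environment), `V`
(observation to line-environment cell) and the per-observation SNP
covariate `X` holding parental-origin codes (+1 common parent, -1
alternate parent). `K` is the additive genomic relationship matrix.

**Variance decomposition.** A trait is decomposed as

    y = mu + Z u + W e + V x + eps,
    u ~ N(0, K su2),  e ~ N(0, se2 I),  x ~ N(0, (Z K Z' o W W') sx2),
    eps ~ N(0, seps2 I)

where `o` is the Hadamard (elementwise) product: the GxE kernel couples
lines through kinship within an environment and is independent across
environments. Broad-sense heritability on a line-mean basis over `ne`
locations is

    H2 = su2 / (su2 + se2/ne + sx2/ne + seps2/ne).

**GxE scan.** Per marker, two nested models are compared:

    Model 1: y = mu + X b + Z u + W e + eps
    Model 2: y = mu + X (b + W e1) + Z u + W e0 + eps,
             (e0_j, e1_j) ~ N(0, [[se0^2, se01], [se01, se1^2]])

Model 2 lets the SNP effect deviate by environment through the random
slope `e1`, correlated with the random environment intercept `e0`. The
likelihood-ratio statistic `-2 log Lambda = 2 (ll2 - ll1)` is referred
to chi-squared with df = 2, the difference in parameter counts (the
slope variance and the intercept-slope covariance). Benjamini-Hochberg
FDR is applied across all scanned markers and SNPs with q < 0.01 are
candidates; candidate regions are maximal runs of candidate markers per
chromosome, bridged across a gap of at most one empty thinning window.
A companion association scan tests `b = 0` (Model 1 against the same
model without the SNP term, df = 1) for effects that are *consistent*
across environments.

**SxE share.** At a candidate locus, `y = mu + X b + Z u + W e + S g +
eps` with iid per-environment slopes `g ~ N(0, sg2 I)` and a fixed SNP
effect quantifies how much phenotypic variance the locus-by-environment
interaction explains; the reported share is `sg2` over the sum of the
four random components, i.e. the denominator excludes the fixed SNP
effect's contribution.

**Environmental factors.** For a measured factor `E` (a windowed
weather mean or a soil property),

    Model 3: y = mu + X b + E bE + Z u + eps
    Model 4: y = mu + X (b + E bi) + E bE + Z u + eps

are compared by an LRT with df = 1 on the fixed interaction `bi`.
Weather covariates are means of daily values over the closed windows
0-30, 15-45 and 30-60 days before each line's heading date (both ends
inclusive, so each window spans 31 days); heading date is anchored per
line as sowing date plus observed days to heading in that environment
and year. Per the model statements these fits carry only the polygenic
and residual random terms - the covariate itself carries the
environment structure. BH FDR is applied across the full factor family
within a trait and year.

## Statistical and numerical choices

* **ML for all LRTs, REML for variance reporting.** Models 3/4 differ
  in fixed effects, where REML likelihoods are not comparable; Models
  1/2 share fixed effects, so ML keeps parameter counting uniform
  across every scan. The variance-reporting functions
  (`estimate_variance_components()`, `sxe_variance()`) default to REML
  instead: with only a handful of environments the ML estimate of a
  variance with so few levels is biased low by the usual
  denominator-n effect, and REML removes exactly that bias. Either
  criterion can be selected everywhere via `reml`.
* **Boundary null.** The true null distribution of a
  variance-component LRT is a chi-squared mixture; the plain
  chi-squared(df = 2) reference is deliberately conservative, which the
  type-I calibration test confirms empirically. `df_override` exposes
  other choices.
* **Optimization.** The fixed effects are profiled out by GLS and the
  overall scale is profiled analytically, so the search runs over
  component-to-residual variance ratios only (log scale; the
  slope-block covariance via atanh of the correlation, which keeps the
  2x2 block PSD by construction). Nelder-Mead with a method-of-moments
  start plus jittered restarts, deterministic given the seed; a
  one-dimensional search uses golden-section `optimize()`. Model 2 is
  warm-started at the Model 1 solution, and since the Model 1 optimum
  is the boundary point `se1^2 = 0, se01 = 0` of Model 2's closure,
  the returned Model 2 likelihood is never below Model 1's and the LRT
  statistic is exactly nonnegative.
* **Fast path.** For balanced complete designs (every line observed in
  every environment - the line-mean convention makes this the common
  case) all model kernels become, after rotating by the eigenvectors
  of `K` within lines and an orthogonal contrast basis across
  environments, diagonal matrices plus rank-at-most-2 updates per
  environment block. One likelihood evaluation then costs O(n_lines)
  instead of O(N^3). The dense path remains the reference (tests
  assert agreement to 1e-8) and handles unbalanced designs.
* **Genotype coding.** The +-1 parental-origin coding makes the SNP
  effect half the homozygote contrast and keeps the slope-block
  covariance interpretable. Residual heterozygous or missing calls are
  coded 0 and such lines are excluded per marker rather than imputed
  (F9 RILs carry well under 1% heterozygosity, so the per-marker loss
  is negligible); for the kinship matrix only, zeros are mean-imputed
  per marker.
* **Kinship.** VanRaden-style: `K = M M' / c` with `M` column-centered
  codes and `c = sum 2 p (1 - p)`; the spectrum is clipped at zero.
  Any symmetric PSD matrix can be supplied from a TSV instead.
* **Thinning.** One SNP per fixed 10-kb bin anchored at position 0,
  keeping the first marker per bin; idempotent by construction.
* **Degenerate inputs.** Constant phenotypes abort a scan; monomorphic
  markers are skipped (or raise an error when focal); a factor constant
  across environments is unidentifiable and rejected; with few
  environments a location-constant factor is confounded with the
  environment labels, which is logged as a caveat but not an error.

## The simulator

`simulate_ril_genotypes()` descends each line independently from a
fully heterozygous F1: one meiosis pair to the F2, then (by default) 7
rounds of single-seed selfing to the F9. Crossovers follow a
no-interference model, i.e. recombination between adjacent markers at
map distance d cM is Haldane's `r = (1 - exp(-2d/100))/2`. Expected
per-locus heterozygosity halves each meiosis, so the F9 rate is
(1/2)^8 before the final coin-flip resolution that mimics
post-imputation homozygous calls, and the recombinant fraction between
linked markers approaches the inbred-line limit `R = 2r/(1 + 2r)`; the
test suite checks both against independent closed forms.
`simulate_phenotypes()` is the generative twin of Model 2 plus an
optional generic GxE term drawn per environment from `N(0, K sx2)`,
and records the full truth (realized polygenic values, environment
intercepts, QTL effects) for parameter-recovery tests.

The canonical fixture (`make_fixture_suite()`) uses 200 lines, 2
chromosomes of 100 cM carrying 250 markers each at ~10-kb spacing, 3
environments with fixed intercepts (-1, 0, +1), a constant-effect QTL
(beta = 1.0) and a GxE QTL with environment slopes (+0.6, 0, -0.6)
around beta = 0, with unit polygenic and residual variances. These
effect sizes were calibrated once so each designed-in locus is
reliably but not trivially detectable at FDR 0.01 (the kinship term
absorbs part of any single-marker effect, so a weaker additive QTL is
flagged only in some replicates) and so the interaction stays
localized: much stronger interaction slopes make the per-environment
variance heterogeneity itself detectable at unlinked markers, which is
a property of the model, not a bug, but would muddy the fixture's role
in examples and tests.

What the simulator does *not* emulate: crossover interference,
segregation distortion, selection during inbreeding, informative
missingness, spatial field trends, or year-to-year correlation -
passing tests therefore demonstrate correctness of the machinery under
the stated generative model, not robustness to every feature of real
trials.

## Problem sizes used in the checks

The test suite exercises the pipeline at the scale it is designed for
while staying quick to run: likelihood oracles on N = 30 subsets
against dense brute-force evaluation; a 500-marker x 200-line null
scan for type-I calibration; 25 replicates of a 300-line single-QTL
scan (environment slope sd 0.75) for power and localization; 30
replicates of a 300-line equal-components simulation for
variance-component recovery; 200 replicates for the null calibration
of the environmental-factor test; and 2000 lines x 25 chromosome
pairs for the simulator's genetic expectations. The acceptance script
(`scripts/acceptance.R`) re-runs the main pipeline end to end on a
fresh 200-line study and writes the quantities it computes as JSON.

## Limitations

* Plain chi-squared reference at a variance boundary sacrifices some
  power for simplicity and transparency.
* Variance components are point estimates (ML/REML); no posterior
  uncertainty is reported.
* With three environments, a location-constant covariate has three
  distinct values; the factor tests then have little resolution to
  separate correlated factors, and the FDR ranking should be read as a
  screening device.
* Single-locus models only: no multi-QTL joint fits or epistasis.
* Kinship is computed once from all (thinned) markers; proximal
  contamination is not corrected (a leave-one-chromosome-out option
  would be the natural extension).
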