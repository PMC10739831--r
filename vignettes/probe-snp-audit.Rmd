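---
title: "Auditing methylation-array probes for ancestry-differentiated SNPs"
author: "probesnpaudit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing methylation-array probes for ancestry-differentiated SNPs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(probesnpaudit)
```

## Scope and model

A methylation BeadChip reads each CpG through a 50-bp hybridization probe and
one single-base-extension (SBE) step, so every assay has a 51-position
genomic footprint. This package audits those footprints for population
variants and quantifies three signatures of technical bias in downstream
meQTL analyses of admixed cohorts: probe-SNP enrichment among
meQTL-associated CpGs, elevated between-population differentiation
(Weir–Cockerham F~st~) of those probe SNPs, and dependence of meQTL effect
magnitudes on the probe SNP's distance from the target cytosine. It does not
perform meQTL discovery, local-ancestry inference, heritability estimation,
or any modelling of hybridization chemistry; it diagnoses existing meQTL
tables against existing genotype references.

## Probe-region coordinate system

Every probe is described by the 1-based plus-strand coordinate of the CpG's
plus-strand cytosine (MAPINFO convention, for both targeted strands), its
targeted strand (F/R) and Infinium chemistry (I/II). Internally positions are
addressed by a signed *probe index*: index 0 is the targeted cytosine and
index 1 the other base of the CpG dinucleotide, on either strand. The
plus-strand position of index $i$ is $t + i$ for forward-targeted and $t - i$
for reverse-targeted probes, where $t$ is the targeted cytosine
($t = p$ for F, $t = p + 1$ for R — the C of the minus strand).

This makes the classic failure mode structurally impossible: a variant at
plus-strand $p + 1$ *is* index 0 of every reverse-targeted probe, and the
regression test suite asserts exactly that.

Window placement: a Type II probe body covers indices 1..50 with the
extension interrogating index 0; a Type I body covers 0..49 with its SBE at
index $-1$. Both yield 51 positions with the CpG at indices 0 and 1. Because
vendor documentation draws the Type I extension base differently in
different places, the placement is a configurable convention
(`type1_window = "sbe_minus1"`, default, or `"target_at_0"`), not a claim of
fact; all internal arithmetic is 0-based half-open with conversions
centralized, and user-facing coordinates are 1-based inclusive.

At the Type I SBE position only SNPs that switch fluorescence color channel
(allele pairs other than A/T and C/G) are retained, since same-channel
substitutions there do not corrupt the readout. A hit at the SBE index
reports distance $|{-1}| = 1$ but keeps an `at_sbe_position` flag so the lost
sign is recoverable and such hits can be excluded from distance analyses if
desired.

## Variant handling

Only biallelic single-nucleotide variants are used; indels, multiallelic and
symbolic records are skipped with counts logged rather than decomposed,
because allele-matching policy for decomposition is not part of this audit.
Phased and unphased genotypes are equivalent; any genotype containing a
missing allele (including half-calls) is excluded from that site's counts.
The default retention rule keeps SNPs with minor-allele frequency at least
0.05 — inclusively — in *either* of the two reference populations;
segregation checks in a single cohort use minor-allele frequency too, since
segregation is symmetric in allele labels. Frequencies are always computed
from genotypes, not taken from INFO fields, so the same rule applies to any
VCF regardless of annotation provenance.

## Weir–Cockerham estimation

Per-site variance components for two populations use observed heterozygote
frequencies (no Hardy–Weinberg assumption), with $r = 2$,
$\bar n = (n_1+n_2)/2$, $n_c$, $\bar p$, $s^2$ and $\bar h$ as in the classic
variance-components formulation, giving $a$, $b$, $c$ and
$\theta = a/(a+b+c)$. Three numerical policies matter:

* negative estimates are **not** clamped, so medians and group tests see the
  estimator's true distribution;
* a site monomorphic in both samples has $a+b+c = 0$ and returns an explicit
  `NA`, never a silent zero;
* per-site estimates are the report's unit (the diagnostics are about
  distributions of per-SNP differentiation), but the multi-locus aggregate
  $\sum a / \sum (a+b+c)$ is provided as `wc_fst_global()` because the
  arithmetic mean of per-site ratios is downward biased — the expectation of
  a ratio is not the ratio of expectations, and low-information sites
  contribute noisy ratios. In our Balding–Nichols simulations at
  $F = 0.3$ (100 diploids per population) the mean per-site ratio stabilizes
  near 0.21 while the ratio of sums recovers 0.30; parameter-recovery checks
  therefore use the aggregate.

"Strongly differentiated" means $\theta \ge 0.1$, inclusive; the threshold is
a parameter everywhere it is used.

## Bias diagnostics

*Enrichment.* The fraction of CpGs with at least one retained probe SNP,
among meQTL-associated CpGs versus all other audited CpGs.

*Group comparisons.* Welch's unequal-variance two-sided t-test with
Welch–Satterthwaite confidence intervals, for F~st~ (meQTL vs non-meQTL probe
SNPs, one value per distinct SNP) and for effect magnitudes ($|\beta|$, or
the ancestry difference $\Delta = |\beta_{EUR} - \beta_{AFR}|$) between CpGs
with and without probe SNPs. Welch rather than the pooled test is the safer
default when only "t-test" is specified; effect sizes are compared as
magnitudes because the diagnostics concern effect *size*, not direction. No
multiple-testing correction is applied inside the report; raw p-values are
reported.

*Distance regression.* One point per CpG: $x$ is the representative
(nearest retained) hit distance, $y$ the mean effect magnitude across that
CpG's associations (a CpG can carry several; averaging keeps one point per
probe). Ties for nearest are broken by higher F~st~, then lexicographic SNP
id, so results are input-order invariant. Ordinary least squares with
intercept is fitted for degrees 1–3 (raw polynomial basis) and the degree is
chosen by sequential nested F-tests,
$F = \frac{(RSS_{k-1}-RSS_k)/1}{RSS_k/(n-k-1)}$, ascending from the linear
model at $\alpha = 0.05$ and stopping at the first non-significant step;
degree 1 is the floor. A perfect higher-degree fit reports infinite $F$ and
$p = 0$; equal RSS reports $F = 0$.

*Disruption accounting.* A meQTL CpG is counted as disrupted when a retained
hit lies on the CpG dinucleotide itself (index 0 or 1) **and** its $\theta$
reaches the threshold: for those CpGs a genotype can erase the CpG, so an
unmethylated readout is not an epigenetic state. The summary reports CpG- and
association-level fractions and the median $\theta$ of the implicated SNPs.

## The synthetic generator

The generator exists so the full pipeline can be exercised offline against
known truth. Defaults define the study conditions and are deliberately fixed:

| parameter | default | why |
|---|---|---|
| probes | 3000, 31% meQTL-designated | yields ≈350 meQTL CpGs with probe SNPs, the scale at which the distance regression is meant to operate |
| probe-SNP carriage | 37.5% (meQTL) / 16.1% (other) | the enrichment contrast the audit must detect |
| divergence | Balding–Nichols $F = 0.35$ (meQTL probe SNPs) / 0.07 (rest) | a strong-vs-weak differentiation contrast on the scale real EUR/AFR panels show |
| samples | 100 diploids per population | reference-panel scale, enough that genotype sampling noise is secondary |
| ancestral frequency | Uniform(0.2, 0.8) planted, Uniform(0.05, 0.95) background | planted probe SNPs emulate variants that survive a common-variant screen |
| $|\beta|$ model | cubic in distance, coefficients (2.2908, −0.18308, 0.0057298, −5.7328e−05), $\sigma = 0.5859$ | least-squares cubic approximation of an exponential decay $0.4 + 2.1 e^{-d/7}$ with noise set so distance explains ≈42% of variance |
| $\Delta$ model | quadratic (1.3936, −0.059006, 7.6729e−04), $\sigma = 0.5858$ | analogous decay with ≈25% of variance explained |

Population frequencies follow the Balding–Nichols beta around a uniform
ancestral frequency; genotypes are binomial (Hardy–Weinberg within
populations); planted SNPs occupy a uniform probe index in the full window,
so indices 0, 1 and the Type I SBE index all occur; at most one SNP is
planted per probe and probes are spaced so regions never overlap. A single
RNG stream keyed by one seed makes every emitted file byte-reproducible.

What the generator does *not* emulate: linkage disequilibrium between sites,
local-ancestry tracts, intensity-level array chemistry, cross-reactive
probes, or the empirical joint distribution of frequency and differentiation
in real panels. Passing tests therefore demonstrate that the pipeline's
logic and estimators are correct under the stated model, not that any
particular real dataset is clean.

Two deliberate consequences of the model are worth knowing. First, effect
magnitudes are floored at zero; where the mean curve approaches the floor
(large distances in the $\Delta$ model) the truncation both shrinks residual
variance and bends the mean curve, so with several hundred points the
selected $\Delta$ degree can exceed the nominal quadratic — with only a few
dozen $\Delta$ points this does not occur. Second, uniform
index placement puts only ≈2/51 of planted SNPs on the CpG dinucleotide, so
synthetic disruption fractions are small by construction; the disruption
logic is exercised by targeted unit fixtures rather than by the default
simulation's volume.

## Problem sizes and numerical checks

The shipped test suite runs everything at desk scale: estimator agreement
with an independent transcription over 10⁴ random genotype configurations
(tolerance 1e−12), coordinate properties over randomized manifests, an
enumerated 12-site VCF for the frequency filter, the exhaustive
allele-pair × probe-type extension-rule table, 200 replicates of cubic-truth
degree recovery and 1000 replicates of the linear-truth type-I rate at
n = 350, Balding–Nichols parameter recovery at 500 sites × 100 diploids, and
a byte-level reproducibility check of the default-scale end-to-end audit.
These sizes were chosen so the full suite completes in well under a minute of
compute per property while leaving sampling error far smaller than the
tolerances asserted.

## Known limitations

* Two populations only; no multi-population ($r > 2$) estimator, confidence
  intervals on $\theta$, or haploid mode.
* Multiallelic sites are skipped, not decomposed.
* The regressions are unweighted ordinary least squares; no robust loss.
* Whether a Type I SBE hit should contribute distance 0, 1, or be excluded
  from distance regressions is genuinely ambiguous in array documentation;
  the `at_sbe_position` flag records the information instead of guessing.
* The audit assumes manifest and VCF share a chromosome naming convention
  (an optional `chr`-prefix normalization is applied to both).
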