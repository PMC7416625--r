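---
title: "Models and methods in genomescapes"
author: "genomescapes authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in genomescapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages({
  library(GenomicRanges)
  library(genomescapes)
})
```

`genomescapes` implements the statistical machinery used to characterize
the evolutionary landscape of large, repeat-rich plant genomes — the kind
of genome in which two thirds of the DNA is recently inserted long
terminal repeat retrotransposons (LTR-RTs), genes sit in small clusters
("insulae") separated by long transposon seas, and recombination is
confined to the distal ends of multi-hundred-megabase chromosomes.  This
vignette explains each model, its assumptions, the tunable parameters,
and what the synthetic-data generators do and do not emulate.

## Dating LTR retrotransposon insertions

The two LTRs of one element are identical upon insertion and diverge
neutrally afterwards.  For an element with LTR length $l$ (bp) inserted
$Y$ years ago, the number of mismatches between the LTR pair is modelled
as

$$N \mid Y \sim \mathrm{Poisson}(2 r l Y),$$

with $r = 1.3\times10^{-8}$ substitutions per site per year, the
conventional rate for repeat DNA in grasses.  `pointAge()` inverts the
mean: $\hat Y = N / (2 r l)$, reported in Myr.  Internally all times are
Myr so that rate parameters stay $O(1)$; $r$ is converted at the
boundary.

### Family age distributions by maximum likelihood

Within a family, ages are modelled as gamma distributed,
$Y \sim \Gamma(\alpha, \beta)$ ($\beta$ per Myr).  Marginally each
mismatch count is then negative binomial.  Because LTR lengths vary
between elements, `fitAgeDistribution()` maximizes the exact gamma-mixed
Poisson likelihood with per-element exposure $e_i = 2 r l_i \cdot 10^6$:

$$N_i \sim \mathrm{NB}\!\left(\alpha,\; p_i = \frac{\beta}{\beta + e_i}\right),$$

which reduces to a common negative binomial when all $l_i$ are equal but
remains correctly specified when they are not.  Optimization is over
$(\log\alpha, \log\beta)$ from three starting points (moment estimates
from point ages, a unit-scale start, and a neutral start); the implied
mean age is $\alpha/\beta$ Myr.  A family in which every element has zero
mismatches sits on the boundary (mean age $\to 0$) and is flagged rather
than fitted.

### Survival and insertion intensity

Elements are removed over time (illegitimate and unequal recombination);
survivorship is modelled as $S(t) = e^{-\delta t}$.  `fitSurvival()`
histograms point ages and regresses log counts on age over the declining
flank (at and beyond the modal bin) of a user-configurable window,
$\hat\delta = \max(0, -\text{slope})$.  This estimator targets $\delta$
when insertion intensity is approximately flat over the window — which is
why survival should be estimated from a large pooled cohort, not from a
single bursting family, whose histogram decline confounds burst shape
with deletion.  The default window is $[0, 3]$ Myr with 30 bins.

The insertion intensity $t$ Myr ago is the observed age density
corrected for survival,

$$I(t) = g(t) / S(t),$$

with $g$ the fitted gamma density; `insertionRateProfile()` evaluates it
on a grid (default $[0, 3]$ Myr, step 0.01) and by default normalizes to
unit maximum for cross-family comparison.  Note one consequence of the
model worth keeping in mind when interpreting fits: thinning an age
distribution $\Gamma(\alpha, \beta)$ by $e^{-\delta t}$ yields exactly
$\Gamma(\alpha, \beta + \delta)$, so the age fit of a surviving cohort
estimates $\beta + \delta$, and the division by $S(t)$ in $I(t)$ is what
undoes the tilt.

Positional contrasts use standard machinery: `proximalDistalAgeTest()`
splits families at the median of their median centromere distances into
equal halves and applies a two-sided pooled-variance t-test (Welch by
flag), and `familyPositionAnova()` runs a one-way ANOVA of element
distance to the centromere by family with Tukey HSD pairwise contrasts.

## Gene insulae: an exponential-mixture test of homogeneity

If gene starts follow a homogeneous Poisson process, intergenic
distances $x$ are exponential, $f(x) = \lambda e^{-\lambda x}$, with MLE
$\hat\lambda = 1/\bar x$.  The insulae alternative is a $K$-component
exponential mixture — a fast rate for short intra-insular gaps, slower
rates for inter-insular gaps.  The default $K = 2$ reflects the
two-scale nature of the claim; larger $K$ is available.

`fitExpMixture()` runs EM (closed-form E and M steps, compiled) to a
relative log-likelihood tolerance of $10^{-9}$ or 2,000 iterations, from
5 quantile-anchored jittered starts, plus a hierarchical start that
splits a small component off the $(K-1)$-component fit so the attained
likelihood is never below the smaller model's.  Components collapsing
below weight $10^{-6}$ trigger a refit with $K-1$ and a flag.

Because the single-exponential null lies on the boundary of the mixture
parameter space, the likelihood-ratio statistic
$\Lambda = 2(\ell_{mix} - \ell_{exp})$ does not have a standard
chi-square null.  `lrtHomogeneity()` calibrates it by parametric
bootstrap from the fitted exponential, with
$p = (1 + \#\{\Lambda_b \ge \Lambda\})/(B+1)$ and $B = 999$ by default.
Two numerical choices matter: the EM effort (restarts, iteration cap
500) is applied *identically* to the observed and every bootstrap fit —
asymmetric effort demonstrably biases the calibration — and the
statistic is clamped at 0.  At $n = 2000$ gaps and $B = 199$ the
empirical size at nominal 5% is 0.05 over 200 replicates.  A Pearson
chi-square goodness-of-fit test against the fitted exponential
(equal-probability bins, df = bins − 2) is provided for ad hoc checks.

For the distal-shortening summary, gaps with posterior probability
above 0.5 on the long-gap component are classified inter-insular and
averaged within distal/middle/proximal thirds of the
centromere–telomere axis.  The posterior threshold truncates the
inter-insular distribution from below, which *attenuates* the measured
distal/proximal ratio relative to the generative shortening factor
(under the generator defaults, a factor-3 distal shortening yields a
measured mean ratio near 0.6, not 1/3); the ordering of the three
regional means is recovered reliably.

## Colinearity and rearrangement classification

Colinearity is the shared order of gene starts between a query and a
subject genome, irrespective of gene orientation, computed on the
hit-bearing subsequence of an ordered best-hit table (genes without hits
are transparent).  A colinear run requires at least `minGenes = 3` genes
on one subject chromosome in strictly ascending or descending subject
order with adjacent subject gaps below `maxGapBp = 0.5` Mb (the
self-synteny preset is 5 genes / 5 Mb).  Ties in subject position are
broken by subject gene id and flagged.  `colinearityPercent()` reports
the percentage of genes inside runs — against hit-bearing genes by
default, against all genes by flag, since the natural denominator is
ambiguous — together with a 50-gene-window profile.

`classifyEvents()` reconstructs rearrangements by strip analysis: hit
rows are ranked by subject position per subject chromosome and cut into
maximal strips of constant rank step $+1$ or $-1$.  A maximum-weight
increasing chain of ascending strips forms the colinear frame; every
non-frame strip is an event.  A descending strip whose ranks fill the
gap between its frame neighbours exactly is an in-place inversion
(codes A/B/C for 2/3/>3 genes); a displaced same-chromosome strip is a
within-chromosome translocation (D/E/F); a strip on another subject
chromosome is an intercalated (iT) or, at a query terminus, terminal
(T) translocation; a block of rows whose subject interval repeats
another block's (2 or more genes) is a duplication (Dup), pruned before
strip analysis; a run of 2 or more consecutive query genes without
subject hits is a deletion (Del).  The 2-gene minimums for Dup and Del
are explicit choices where the code table gives no minimum sizes.

`assignBranch()` treats each event as a binary character (derived order
shared or not with each subject genome) on the fixed four-taxon
topology (((query, Bd), Os), Sb) and finds the minimal edge set by
exhaustive Fitch parsimony: a unique minimal edge names the branch,
patterns requiring two changes are flagged homoplasy.

## Recombination landscape

A Marey map plots genetic position (cM) against physical position (bp);
its first derivative is the local recombination rate.  `mareyMap()`
averages duplicate marker positions, enforces monotonicity by isotonic
(pool-adjacent-violators) projection — idempotent on already monotone
maps — and `recombinationRate()` differentiates a local polynomial fit
(degree 2, Gaussian kernel, via KernSmooth) evaluated anywhere on the
chromosome.  Degree 2 makes the derivative an odd-order-above estimand,
the textbook choice; the default bandwidth is chromosome length / 20.
Negative derivative estimates are clipped to zero, rare after the
isotonic step.  On simulated 200-marker U-shaped maps the estimated
rate integrates back to the map length within 5% and rank-correlates
with the true rate above 0.9.

Gene density uses fixed 10-Mb bins anchored at the short-arm tip, with
two 3-bin sliding means running in opposite directions from the two
chromosome tips (truncated at the edges) and averaged per bin — a rule
that conserves raw counts exactly and commutes with mirroring the
chromosome.  `densityRecombCorrelation()` correlates per-bin density
with the rate at bin midpoints (Pearson, two-sided t transform).
Resistance-gene-analogue (RGA) summaries implement the published
conventions: multi-gene loci are single-linkage chains of at least 3
same-class genes with adjacent distances strictly below 300 kb, and RGA
density is the RGA-to-gene ratio in 10-Mb windows stepped by 8 Mb
(2 Mb overlap), which controls for the distal gene-density gradient.

## Sequence scanners

- **Telomeric arrays** (`scanTelomereArrays()`): exact TTTAGGG unit
  matches (both orientations) chained when separated by at most 7
  unmatched bases; chains of at least 5 units are reported, may end
  mid-unit, and carry matched-bases/span identity.  Chaining reproduces
  the repeat-count decision rule without an aligner; ambiguous bases
  break chains.
- **Microsatellites** (`scanSsrs()`): maximal perfect tandem tracts of
  unit 1–6 bp and total length at least 15 bp.  Maximality is symmetric
  (tracts may begin or end mid-unit), tracts whose unit is a repetition
  of a smaller unit are reported once at the smallest unit, and motifs
  are canonicalized to the lexicographically minimal rotation.  Compound
  and imperfect microsatellite rules are deliberately out of scope.
- **k-mer uniqueness** (`kmerUniquenessRatio()`): the percentage of
  genome positions covered by at least one k-mer occurring exactly once
  — non-decreasing in k, because a unique k-mer always extends to a
  unique (k+1)-mer covering the same positions.  Forward-strand
  counting by default; start-position counting by flag.
- **Organellar hits** (`mergeOrganellarHits()`): hits encompassed by
  other hits are removed, then hits within 200 bp of one another are
  merged ("within 200 bp" is read inclusively; strict mode by flag).
  The operation is idempotent.

## What the synthetic generators emulate

The generators produce every input the pipeline consumes, with ground
truth, under one hierarchically seeded stream per generator (adding a
generator to a workflow never perturbs another's draws):

- **TE cohorts**: burst-like ages (Gaussian truncated at 0 — the
  functional form of real bursts is unknown, so a two-parameter bump is
  used), gamma or uniform ages; survival thinning $e^{-\delta Y}$;
  Poisson mismatches.  Defaults: bursts within the last 3 Myr,
  $l = 1$ kb, $\delta = 1$/Myr, $r = 1.3\times10^{-8}$.
- **Gene positions**: exponential gaps under the null; under the
  alternative a 0.7/0.3 mixture of 5-kb and 100-kb mean gaps, with the
  inter-insular rate increased up to 3-fold at the chromosome ends,
  decaying linearly to the centre.
- **Genetic maps**: recombination density
  $d(u) = \epsilon + (1-\epsilon)\,((2u-1)^2)^p$ of relative position
  $u$, integrated in closed form and scaled to the map length (default
  150 cM, $p = 2$, $\epsilon = 0.02$); flat at $p = 0$.
- **Ortholog tables**: identity order with exponential spacing (10-kb
  mean) and planted, non-overlapping, well-separated events of all ten
  codes.
- **Sequences**: i.i.d. uniform background with planted telomeric
  arrays, SSR tracts and organellar-fragment copies; uniform base
  composition is used because none of the implemented statistics
  depends on GC structure.

They do **not** emulate: annotation error, assembly gaps or chimaeras,
tandem gene families, GC heterogeneity, TE nesting, genetic-map
genotyping error beyond an optional additive noise flag, or
lineage-specific mutation-rate variation.  Passing recovery tests on
these genomes therefore demonstrates correctness of the estimators
under their stated models, not robustness to real-data artefacts.

## Problem sizes and numerical conventions

Validation uses cohorts of 5,000–16,000 elements, gap samples of
2,000–5,000, 1,000-gene ortholog tables (100 random plans), 200-marker
maps, and 10-kb scanner sequences — sizes at which every recovery band
quoted above was measured.  EM tolerance is $10^{-9}$ relative (cap
2,000 iterations; 500 inside the bootstrap LRT); the age-model
optimizer uses relative tolerance $10^{-10}$ in log-parameter space;
ties in subject position are broken by gene id; all percentages are on
0–100 scales.

## Known limitations

- The strip-based classifier assumes planted-style separation between
  events; overlapping or nested rearrangements can merge or mask
  strips, and inverted *and* displaced segments are coded as
  translocations with a note.
- The survival estimator requires a flat insertion intensity over the
  fit window; applying it to a single bursting family conflates burst
  decline with deletion.
- The bootstrap LRT's iteration cap trades a slight, symmetric
  underestimate of both observed and null statistics for runtime; the
  measured size is nominal.
- `kmerUniquenessRatio()` materializes all k-mers in memory and is
  intended for megabase-scale synthetic genomes, not full 4-Gb
  assemblies.

## A short worked example

```{r example}
cohort <- simulateTeCohort(3000, ageDist = "gamma", gammaShape = 2,
                           gammaRate = 2, deletionRate = 0, seed = 1)
fit <- fitAgeDistribution(cohort$elements)
fit
genes <- simulateGenePositions(1e8, distalShortening = 3, seed = 2)
gaps <- intergenicGaps(genes)
lrt <- lrtHomogeneity(gaps, B = 199, seed = 3)
c(statistic = lrt$statistic, p = lrt$p.value)
```
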