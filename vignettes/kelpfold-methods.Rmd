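---
title: "kelpfold: models and methods"
author: "kelpfold authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{kelpfold: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kelpfold)
```

kelpfold analyses the three-dimensional folding of small, compact genomes
(the scale of algal or fungal assemblies: tens of chromosomes, a few hundred
Mb or less) from Hi-C contact data. Its target architecture is the one seen
in organisms whose interphase nuclei show *clustered centromeres and
telomeres without a Rabl polarisation and without conspicuous TADs*:
chromosome territories, A/B compartments tracking GC and activity, strong
centromere-centromere and telomere-telomere trans contacts, and occasional
strongly insulated domains such as a non-recombining sex-determining region
or a large endogenous viral insertion. This vignette explains each model,
its parameters, the numerical choices, and what the synthetic benchmark does
and does not demonstrate.

## Contact-map model

A `GenomeSpec` fixes an ordered chromosome set and a bin size; bins tile
each chromosome exactly (the last bin may be short) and carry contiguous
global indices. A `ContactMatrix` stores the symmetric binned counts plus
two pieces of metadata that never modify the raw counts: a per-bin mask and
per-bin balancing weights.

* **Masking** (`maskLowCoverage`): bins whose marginal falls below
  `minFrac` (default 0.02) of the median non-zero marginal are excluded
  from every downstream statistic. The default is deliberately permissive;
  at the sequencing depths this package targets, aggressive masking costs
  more signal than it removes noise.
* **Balancing** (`iceBalance`): iterative correction over unmasked bins
  until the balanced marginals agree to a relative tolerance (default
  `1e-5`, at most 200 iterations; non-convergence is an error carrying the
  last residual). Weights are scaled so the *mean* balanced marginal is
  exactly 1, which makes observed/expected values scale-free: doubling all
  counts changes neither weights' ratios nor O/E.
* **Expected and O/E** (`expectedProfile`, `observedOverExpected`): the cis
  expectation is the per-chromosome mean balanced contact at each diagonal
  distance; the trans expectation is the per-chromosome-pair mean. Cells
  with zero or undefined expectation propagate as `NA`, never as 0.
  One deliberate exception: `transEnrichmentByPair` measures *pair-level*
  enrichment, which a per-pair expectation would cancel identically, so
  that table alone uses the global mean balanced trans value as its
  expectation.
* **Coordinates**: intervals are 1-based and closed in R (the
  GRanges convention); BED and bedGraph files are read and written in their
  native 0-based half-open convention via rtracklayer. Pairs positions are
  1-based on input.

## Contact decay and the interaction decay exponent

`contactProbability` computes P(s) as observed contact per possible
unmasked bin pair within a distance band; bands are logarithmic at 8 per
decade by default (stabilising sparse long-range diagonals), or native bin
distances when `logBinsPerDecade = NULL` (used for exact closed-form
checks). `fitIDE` is an ordinary least-squares fit of log10 P on log10 s
over a distance range, by default 10 kb to 500 kb at 10 kb bins -- the
standard window in which compact genomes show a clean power law. Zero bands
are dropped, not imputed, and the exponent is reported as the signed slope.
OLS in log-log space was chosen because no more specific estimator is
standard for this quantity; the choice is recorded in outputs.

## A/B compartments

`callCompartments` computes E1 as the leading eigenvector of either the
per-chromosome Pearson correlation map of cis O/E rows (`mode = "cis"`) or
the genome-wide mean-centred trans O/E matrix with cis blocks excluded
(`mode = "trans"`). Numerical details that matter:

* Eigenvalues are ordered *algebraically*, not by magnitude: a
  two-chromosome trans-only matrix is bipartite, so its spectrum is
  symmetric about zero and magnitude ordering would always tie. A genuine
  tie between the top two eigenvalues (within `1e-9`) raises an
  "ambiguous E1" error rather than returning an arbitrary vector.
* The eigenvector sign is arbitrary, so each chromosome's segment is
  oriented to correlate positively with GC; when |corr(E1, GC)| is below
  `signTol` (0.05) the orientation falls back to gene density if supplied,
  else keeps the computed sign with a warning. This documented rule
  replaces any manual per-chromosome validation.
* Bins with |E1| below `1e-12` are treated as masked rather than assigned
  a spurious label; borders are placed at the bin edge between consecutive
  unmasked bins of opposite sign.

`compareCompartments` merges per-bin joint labels into maximal runs and
reports switching as a fraction of unmasked bp at the working bin size
(10 kb), the most conservative of the plausible conventions (bins, bp, or
merged regions) because it weights partial terminal bins correctly.
`subcompartmentPCA` repeats the eigenvector analysis on the trans affinity
restricted to one compartment's bins and splits it by sign; a leading
eigenvalue below `max(2 * RMS(other eigenvalues), 1e-6)` is reported as "no
sub-structure" instead of an arbitrary split.

## Aggregate chromosomal analysis and configuration calls

`aca` rescales each chromosome arm linearly to `nPseudo/2` pseudo-bins
(area-weighted averaging of O/E cells, which keeps flat maps exactly flat)
so the centromere sits at the centre regardless of arm asymmetry, then
averages over chromosomes (intra) and ordered chromosome pairs (inter).
Arm-wise rescaling -- rather than whole-chromosome rescaling -- is what
makes "the centromere at the centre" exact.

`clusterScores` reduces the inter aggregate to three ratios against the
background (the aggregate excluding centromere and telomere windows,
window default 5 pseudo-bins of 100): centre window (C-C), four corner
windows (T-T), and the main-diagonal band excluding both (arm alignment,
the Rabl belt). `classifyConfiguration` uses thresholds tauC = tauR = 1.5:
a 50% enrichment over background is the point at which these features are
visually conspicuous on an aggregate map. Rabl-like takes precedence (the
belt passes through the centre, so centromere scores ride along with it);
clustered-non-Rabl requires both C-C and T-T above tauC with the belt
below tauR.

`regionTelomereContact` scores a query region's mean trans O/E against
telomere bins on other chromosomes and compares it with matched-length
control regions (user-supplied, e.g. domains carrying the same chromatin
mark, topped up with seeded random placements to `nPerm` draws). The
empirical p uses the add-one rule and is never 0.

## Insulation and TAD assessment

The insulation score at bin i is the log2 ratio of the mean balanced
contact in the w x w diamond spanning the bin edge 5' of i to the
chromosome's mean diamond value; the default window is 100 kb at 10 kb
bins, standard diamond-insulation practice. Boundaries are local minima
with prominence (depth below the smaller flanking maximum within one
window) of at least 0.5 log2 units. `assessTadPresence` converts strong
boundaries into a density per Mb and calls "no conspicuous TADs" below
1 per Mb -- an explicit, quantitative stand-in for what is otherwise a
visual judgement, and flagged as such in its output.
`regionInsulationContrast` uses O/E, not raw counts, so genomic-distance
decay does not masquerade as insulation.

## Centromere and telomere annotation

`locateCentromeresHiC` finds, per chromosome, the bin tuple maximising
total pairwise trans O/E -- the fixed point of the update
`c_i <- argmax_b sum_j O/E(b, c_j)`. Two implementation details are
essential in practice. First, plain coordinate ascent from the
maximal-total-trans start has genuine local optima: the telomere cluster
is itself a strong trans structure, and balancing inflates end bins' trans
values because their missing cis contacts must be compensated. The
implementation therefore (i) bars terminal bins (default 2 per end) from
candidacy and (ii) restarts deterministically from every interior bin of
the first chromosome, keeping the fixed point with the best total score --
on small instances this provably returns the global maximiser. Second,
the operation is intended for coarse maps (the pipeline uses 50 kb): at
fine bin sizes single cells hold too few counts for single-bin argmax
localisation to be meaningful. A converged score below 1.2x the mean over
the chromosome's bins is flagged "no enrichment".

`scanCentromericFamilies` then closes the loop with annotation: families
at least 90% of whose copies fall inside +-200 kb windows around the Hi-C
calls, on all windowed chromosomes, are reported (midpoint-in-window rule,
ranked by specificity x in-window copies). `defineCentromereSpans` takes
the first-to-last copy span per chromosome; a single copy is a valid span.
`centromereComposition` reports base fractions with precedence selected
family > tandem > other interspersed, so fractions sum to at most 1, plus
span-vs-rest GC and overlapping gene counts.

`detectTelomericTracts` scans the outer 2 kb of each chromosome end for at
least 5 tandem copies of TTAGGG (CCCTAA at 5' ends); both-ended
chromosomes are telomere-to-telomere. The copy-number and offset defaults
are explicit configuration, reported with the results, since no community
standard exists for "fully resolved".

## Integration with chromatin marks and expression

Peaks and genes are assigned to the compartment of the bin containing
their midpoint (configurable in principle to majority-overlap; midpoint is
the default because peak and gene sizes here are well below the bin size).
Group comparisons use a two-sample Wilcoxon rank-sum test on
log2(fold enrichment) or log2(TPM + 1): exact split enumeration (tie-aware)
whenever `choose(n, n1) <= 50000`, otherwise the normal approximation with
tie and continuity corrections. Sex-biased genes are classified from
consumed differential-expression statistics at padj <= 0.01 and
|log2FC| >= 1 (boundary-inclusive); the negative-binomial model fitting
that produces those statistics is out of scope by design. The SBG x
compartment-switching association is a plain Pearson chi-square on the
gene-level 2x2 table, df = 1, no continuity correction (Yates available by
flag); an expected cell below 1 aborts with advice to use an exact test.

## The synthetic generator

`syntheticTruth` fixes the study conditions: 4 chromosomes x 2 Mb at 10 kb
bins; cis intensity `s^-alpha` with alpha = 0.9 (a smooth, realistic
decay); a 200 kb A/B checkerboard with factors fAA = fBB = 1.6,
fAB = 0.7; ~5% trans contacts; centromere clustering betaC = 5 over a
+-50 kb plateau (centromeres of such compact genomes typically span tens
of kb, occasionally over 100 kb); telomere clustering betaT = 3 over
100 kb ends; one 300 kb
insulated domain on chr3 with cross-boundary attenuation delta = 0.3 and
a 4x trans-telomere boost; a Rabl arm-alignment boost that is off by
default; and a centromere-confined repeat family. Counts are independent
Poisson draws scaled so the expected total equals the requested depth
(an overdispersion knob is deliberately absent from the default model;
Poisson is the minimal model consistent with count data).

Three design choices keep the planted signals *separately* recoverable,
mirroring how these signals coexist in real nuclei:

* the compartment factor acts only beyond 200 kb -- short-range contact is
  dominated by polymer decay in real maps, and a genome with compartments
  but no domains should be flat at the insulation scale;
* the domain attenuation acts only up to 600 kb -- insulation is a local,
  sub-Mb phenomenon, and must not dominate the chromosome-scale
  correlation structure that carries the compartment signal;
* the combined cis modulation is divided by its exact per-distance mean,
  so the planted alpha remains the true slope of P(s).

The trans intensity is `t0 * boost(i, j)` with no compartment factor, so
on synthetic maps the compartment signal lives in cis; recovery tests use
`mode = "cis"`, and trans mode is exercised on constructed checkerboard
matrices instead. `simulateFeatureTracks` produces the matched side
channels: GC at Normal(0.55, 0.01) for A bins vs Normal(0.50, 0.01) for B
(strong enough that sign orientation is unambiguous), A-shifted log-normal
TPM, compartment-shifted activation/repressive mark peaks, a planted
centromeric repeat family with scattered background families, and random
sequences with TTAGGG tracts planted at chosen ends. The sequences'
base composition does *not* reproduce the GC track, and the generator
plants no read-level artefacts (duplicates, fragment geometry): passing
the benchmark demonstrates the correctness of the measurement chain on
clean count data, not robustness to upstream processing problems.

## Problem sizes and reproducibility

The test suite and the acceptance script work at desk scale: depth 1e6 on
the 8 Mb default genome for recovery checks (5 seeds), depth 1e5 for the
20-map TAD-free calibration, 200 replicates for null-uniformity
(Kolmogorov-Smirnov at alpha = 0.01), and 50-bin instances for
brute-force oracle equivalence. All randomness flows through explicit
seeds; `runPipeline` fans a single global seed out per stage through a
fixed affine rule and stamps every run with the configuration hash.

## Known limitations

* Balancing edge effects at chromosome ends are compensated, not removed;
  terminal bins are excluded from centromere candidacy for this reason and
  should be treated cautiously in any fine-scale trans analysis.
* The TAD verdict is a density threshold on insulation boundaries, not a
  domain caller; hierarchical domain structure is out of scope.
* Sub-compartment splitting is a single sign split of one eigenvector, not
  a multi-state HMM.
* DE statistics, peak calls and repeat annotations are consumed as tables;
  none of the upstream inference is reimplemented or validated here.
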