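# kelpfold

Hi-C analysis of three-dimensional genome architecture in compact genomes —
the kind of interphase organisation seen in small algal and fungal nuclei:
chromosome territories, clustered centromeres and telomeres **without** a
Rabl polarisation, A/B compartments that track GC and activity, no
conspicuous TADs, and occasional strongly insulated domains (a
non-recombining sex-determining region, a large endogenous viral
insertion). It is written for genomicists who have binned contact data (4DN
pairs or COO text) plus the usual side tables — GC or FASTA, repeat
annotations, ChIP peak tables, gene/expression tables — and want the whole
measurement chain in one tested R package.

## What it computes

* **Matrix core** — binning of read pairs, low-coverage masking, iterative
  balancing to equal marginals (`counts[i,j] / (w_i w_j)`, unit mean
  marginal), distance-expected profiles, observed/expected (O/E) and
  per-chromosome correlation maps, multi-resolution coarsening.
* **Contact decay** — P(s) = observed contacts per possible pair at
  separation s, log-banded; the interaction decay exponent (IDE) as the OLS
  slope of log10 P vs log10 s over 10–500 kb.
* **A/B compartments** — E1, the leading eigenvector of the cis O/E
  correlation map (or of the trans O/E matrix), sign-oriented by GC so
  E1 > 0 is A; borders at sign changes; sub-compartment splitting; and a
  male/female switch table with the switched fraction in bp.
* **Aggregate chromosomal analysis (ACA)** — arms rescaled to a common
  pseudo-length with the centromere at the centre; centromere–centromere,
  telomere–telomere and Rabl-belt scores against background; configuration
  calls (clustered-non-Rabl / Rabl-like / dispersed); per-pair trans
  enrichment; and a permutation test for region-to-telomere contact.
* **Insulation** — diamond insulation tracks, prominence-based boundary
  detection, a quantitative "no conspicuous TADs" verdict, and O/E
  insulation contrast of named regions.
* **Centromeres & telomeres** — Hi-C centromere localisation from trans
  clustering (global maximiser of total pairwise trans O/E), scanning
  repeat annotations for centromere-specific, all-chromosome families,
  first-to-last-copy centromere spans with composition and GC, and
  (TTAGGG)n telomeric tract detection with T2T status.
* **Integration** — compartment assignment by midpoint, Wilcoxon
  comparisons of mark enrichment and expression between A and B, sex-biased
  gene classification (padj ≤ 0.01, |log2FC| ≥ 1), and a chi-square test of
  SBG enrichment in compartment-switching regions.
* **Synthetic data** — a seeded generator that plants all of the above
  (decay exponent, checkerboard, clustering boosts, insulated domain,
  centromeric repeat family, telomeric tracts) so every stage is testable
  without downloads.

## Worked example

Simulate the default study conditions (4 × 2 Mb chromosomes, 10 kb bins,
10⁶ contacts), then run the analysis chain:

```r
library(kelpfold)

truth <- syntheticTruth(seed = 42)
m <- simulateContactMap(truth, depth = 1e6, seed = 42)
m <- iceBalance(maskLowCoverage(m))
m
#> ContactMatrix: 800 bins on 4 chromosomes; 1,001,058 contacts; 0 bins masked; balanced

fitIDERegion(m, "chr1")
#> DecayFit: exponent -0.9024 (r2 1.000) over [10000, 500000] bp, 13 bands

tracks <- simulateFeatureTracks(truth, fasta = FALSE, seed = 43)
callCompartments(m, gc = tracks$gc, mode = "cis")
#> CompartmentTrack (mode cis): 397 A bins, 403 B bins, 0 masked; 44 borders

clusterScores(aca(m, truth@centromeres)$inter)
#> ClusterScores: C-C 4.54, T-T 3.23, arm alignment 0.98 -> clustered-non-Rabl

boundaries(detectBoundaries(insulationTrack(m, window = 1e5)))
#>   chrom bin     pos strength
#> 1  chr3 521 1200000 1.445015
#> 2  chr3 551 1500000 1.500193
```

Reading the output: the fitted IDE (−0.90) recovers the planted decay
exponent; the compartment caller labels half the bins A and half B with
borders every ~200 kb (the planted checkerboard); the ACA scores say
centromeres cluster at ~4.5× background and telomeres at ~3.2× with no
Rabl belt (arm alignment ≈ 1), hence "clustered-non-Rabl"; and the two
insulation boundaries sit exactly at the planted domain edges on chr3
(1.2 and 1.5 Mb). The planted domain's elevated telomere contact is
significant under the permutation test:

```r
rtc <- regionTelomereContact(m, list(chrom = "chr3", start = 1.2e6 + 1,
                                     end = 1.5e6), nPerm = 199, seed = 44)
#> region-telomere score 4.72, empirical p = 0.005
```

For real data, start from `readPairsFile()` / `readCOO()` +
`readChromSizes()`, or drive everything from a YAML config with
`runPipeline()` (see `defaultRunConfig()` for every stage's parameters).

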