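---
title: "Mapping sRNA expression QTLs in immortalized F2 populations: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping sRNA expression QTLs in immortalized F2 populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srnaqtl)
```

## The experimental design being modelled

An immortalized F2 (IMF2) population is built by paired crosses of
recombinant inbred lines (RILs): each RIL is a homozygous mosaic of the
two founder genomes (here labelled ZS for Zhenshan 97 and MH for
Minghui 63), and crossing two RILs yields a hybrid whose genotype at any
locus is `AA`, `Aa` or `aa` depending on which founder each parental RIL
carries there. Genetically the hybrids behave like F2 individuals —
segregating at 1:2:1 — but the population can be regrown indefinitely,
which is what makes population-scale RNA profiling feasible. The study
design this package targets has 98 hybrids from 196 RILs, profiled for
sRNAs and mRNAs.

Because RIL genotypes change only at recombination breakpoints, the union
of all breakpoints partitions the genome into **bins** inside which every
individual's genotype is constant. Bins are the markers: no genotype is
ever missing, so interval mapping between markers reduces exactly to
marker regression at bins, with no pseudomarker imputation or EM step.
This is a deliberate design decision — the scan is exact and fast, and
nothing of scientific interest happens between bins in this population.

## The synthetic population generator

The generator is first-class, tested code: every downstream stage is
validated against populations with known architecture.

* **RIL simulation.** Single seed descent from the founder F1. Each
  meiosis draws a Poisson number of crossovers per chromosome with mean
  `length_Mb × rate / 100` and uniform positions — the Haldane map
  function, i.e. no crossover interference. Interference changes
  breakpoint spacing slightly but nothing downstream depends on it, so
  the simplest standard model is used. After `n_generations` (default 8)
  of selfing the line is fixed by taking one haplotype; residual
  heterozygosity (~1% after 8 generations) is resolved to zero because
  the bin-genotype deduction for the hybrids treats RILs as homozygous.
* **Pairing.** Hybrid parent pairs are drawn without replacement from the
  set of distinct RIL pairs; a RIL may parent several hybrids, as in real
  paired-crossing designs whenever hybrids outnumber lines/2.
* **Expression.** A trait's expectation per individual is
  `mu + Σ(a·x + d·z)` over its effect loci, with `x ∈ {−1, 0, +1}` for
  `{aa, Aa, AA}` and `z = 1` for heterozygotes; `A` is the ZS allele, so
  positive `a` means the ZS homozygote expresses more. Noise is either
  Gaussian on the expression scale (the model under which the scan's
  statistics are derived; used for calibration and recovery tests) or
  negative binomial on counts with dispersion `phi`
  (variance `mu + phi·mu²`), scaled by simulated library totals — the
  overdispersed count regime of real sRNA-seq. Negative expectations are
  clipped at zero with a warning. Mother-gene mRNA levels can be coupled
  to a trait's genetic expectation through a configurable coefficient.

**Defaults as study conditions.** `sim_config()` defaults to 196 RILs,
98 hybrids, 12 chromosomes × 25 Mb and 1.3 cM/Mb. The recombination rate
is calibrated so the expected bin count (≈ 196 RILs × 2 × genome Morgans)
matches the ~1568 bins of the real map; the real rice genome is smaller
per cM, but the bin count is what the scan sees.

**What the generator does not emulate:** sequencing reads and their
errors, mapping ambiguity, segregation distortion, epistasis, and
LD between physically unlinked regions beyond what shared RIL parents
induce. Passing tests demonstrate the statistical machinery is correct
under the stated model, not that real sRNA data meet that model.

## Quantification and thresholds

All expression thresholds are inclusive (`≥`), matching their
definitions: RPM ≥ 0.6 (sRNA), median-of-ratios normalized count ≥ 6
(cluster), FPKM ≥ 1 (mRNA). An entity expressed in **more than 25** of
the 98 hybrids — i.e. ≥ 26 — becomes an expression trait; the strict
reading of "more than" is used. RPM divides a record's count by the
library's total genome-mapped reads in millions; the library total is
carried with the table rather than recomputed from retained records,
because filtered-out reads still count toward sequencing depth.

Trait anchors are the 5′-most genomic coordinate of the alignment
(forward-strand minimum); at ≤ 26 nt the choice cannot move an anchor
across a bin, but fixing it makes region tallies reproducible. Region
annotation assigns exactly one primary class per anchor — exon (CDS), UTR
(exonic non-coding, when CDS intervals are annotated), intron,
2-kb-upstream, 500-bp-downstream, intergenic — with precedence
genic > upstream > downstream > intergenic and ties broken by nearest
TSS. Windows are strand-aware: upstream means 5′ of the TSS.

## sRNA clusters

Coverage is pooled over **all** libraries (parents, F1 and hybrids),
islands are maximal runs of positions with pooled coverage ≥ 30×, and
islands separated by ≤ 1000 nt (end-to-start in half-open coordinates)
merge transitively into clusters named `chrNN-start-end`. Cluster
membership of a record is by anchor containment, unambiguous for short
reads. No minimum island span is imposed, matching the absence of such a
parameter in the cluster definition; `merge_islands()` exposes an
optional span filter. Size factors follow the median-of-ratios estimator:
rows containing any zero are excluded, ratios are taken to the row
geometric mean, and the per-library factor is the column median — the
estimator is implemented in closed form here and cross-checked in the
test suite against DESeq2's `estimateSizeFactorsForMatrix` on random
matrices.

## The genome scan

At test bin *b* with retained cofactors *C*,
`LOD(b) = (n/2)·log10(RSS(1, C) / RSS(1, C, x_b, z_b))`. The profile is
invariant to affine transforms of the trait and is zero wherever a bin is
monomorphic (flagged); at two-class bins the model drops collinear codes
and tests the remaining degree of freedom.

* **Cofactor selection** is forward stepwise on additive codes under the
  *modified* BIC, penalty `log(n) + 2·log(B)` per marker (B = number of
  bins). Plain BIC ignores that the entering marker is the best of
  hundreds of candidates and admits a spurious cofactor for most
  pure-noise traits; the multiplicity-adjusted penalty leaves null traits
  with an empty cofactor set with high probability, which the test suite
  checks. Default cap: 3 cofactors at n = 98.
* **The exclusion window** (default 10 Mb) drops cofactors on the test
  bin's chromosome within that distance, so a cofactor never absorbs the
  signal it is being tested for.
* **Permutation significance**: trait values are permuted across
  individuals and the genome-wide maximum LOD recorded per permutation;
  the threshold is the empirical `1 − α` quantile (inverse-ECDF
  quantile, so `α = 1` gives the minimum) and the trait p-value is
  `(1 + #{max_perm ≥ max_obs}) / (1 + n_perm)`, never exactly zero.
  Permutation scans reuse the cofactors selected on the observed trait:
  under permutation the cofactors are noise in both the reduced and full
  models, so calibration is preserved, and re-selection per permutation
  would multiply runtime by the selection cost for no inferential gain.
  Each trait gets a deterministic RNG substream derived from the master
  seed, making whole-matrix scans reproducible regardless of trait order
  or parallel grouping.
* **FDR across traits**: Benjamini–Hochberg at q = 0.05 on the per-trait
  permutation p-values; QTLs are then called within significant traits at
  each trait's own 5% threshold.
* **Peaks** are local maxima at or above threshold; a plateau yields one
  peak at its lowest coordinate; maxima closer than 5 bins collapse onto
  the higher one unless the profile dips ≥ 1.5 LOD below the lower
  maximum between them. **Support intervals** take the contiguous run
  within 1.5 LOD of the peak, extended one bin each side and clipped at
  chromosome ends.
* **Local vs distant**: local if the trait anchor lies in the support
  interval or within 250 kb of the peak bin's nearest boundary on the
  same chromosome. The source analysis applies the 250-kb fallback only
  in "recombination sparse regions" without operationalizing that term;
  here it is applied unconditionally, which can only widen the local
  class and is the documented deviation.

## Genetic effects and dominance

Effects come from unweighted genotype-class means:
`a = (m_AA − m_aa)/2`, `d = m_Aa − (m_AA + m_aa)/2`. The dominance test
(h-test) permutes residuals of the additive-only fit, adds them back to
the additive fitted values and recomputes `d`; the two-sided permutation
p-value isolates dominance from the additive signal. The original h-test
is specified in cited prior work rather than in the analysis being
reimplemented; residual permutation was chosen because it conditions on
the estimated additive structure exactly. Dominance classes: significant
`d < 0` is negative dominance, and `d < −|a|` — heterozygote below both
homozygotes — is negative overdominance (mirrored for positive). Ties at
`d = 0` classify as none.

## Hotspots and correlation analyses

Density is count per Mb per bin; the genome average is total count over
total genome Mb; hotspots require density **strictly greater** than
multiplier × average (3× traits, 6× QTLs, 2× sc-traits), so a bin at
exactly the multiple is not a hotspot. QTLs are anchored at their peak
bin only, not their support interval. Consecutive hotspot runs never
cross chromosome boundaries.

Correlation significance uses a simulated null — the `1 − α` quantile of
`|r|` between independent standard-normal vectors of the shared sample
length — rather than a hard-coded threshold; at n = 98 and 10⁵
simulations this lands within Monte-Carlo error of the analytic critical
value `t/√(t² + n − 2) ≈ 0.199`, which the acceptance suite verifies.
The ±0.3 strength boundary is applied inclusively (|r| = 0.3 is strong);
the dividing points are descriptive and silent on ties, so the inclusive
convention is fixed here. Co-regulation of two mapped traits: both QTLs
local → shared-local; both distant within 2 Mb on one chromosome
(peak-midpoint distance) → nearby-distant; both distant otherwise →
far-distant; one each → mixed.

## Pipeline

`run_pipeline()` executes simulate → quantify → cluster → scan (with
effects) → hotspots → correlations → report, logging each stage's record
counts so the filtering cascade is auditable. A completed artifact
directory is identified by the MD5 of its configuration and reused on
rerun; anything finer-grained would buy little, since all stages are
deterministic under the master seed and a full desk-scale run takes
seconds. Outputs are plain TSV/GFF3/JSON/YAML and byte-identical across
reruns with one seed.

## Problem sizes in the test and acceptance suites

The statistical tests run at the population size of the study design
(n = 98 hybrids) on desk-scale genomes chosen per question:

* *Null calibration*: 200 null traits on a ~200-bin map
  (24 RILs, 4 × 25 Mb, 3.5 cM/Mb), 200 permutations each.
* *Planted-QTL recovery*: 100 traits with a local additive effect of one
  residual standard deviation on a coarse ~33-bin map (0.6 cM/Mb).
  The coarse map is deliberate: peak localization to ±1 bin is limited
  by linkage disequilibrium between neighbouring bins, not by the
  implementation — adjacent bins differ by a single RIL breakpoint
  (~8 of 98 hybrids here), so on dense maps the peak wanders several
  bins at this effect size whatever estimator is used. Bins several
  centimorgans apart make ±1-bin recovery a meaningful statement about
  the scan rather than about map density.
* *Dominance*: powers and type-I error measured by direct simulation at
  planted `d = −a`, `d = −2a` and `d = 0` (500 traits, 1000 permutations
  for type-I).
* *Geometry*: islands/clusters checked against brute-force per-position
  scans on 100 random tracks; size factors against hand-computed values.

## Known limitations

* The scan tests bins marginally; multi-QTL models and epistasis are out
  of scope, and closely linked QTLs on one chromosome may merge into one
  peak or split into satellites depending on the LOD valley between them.
* Local/distant classification inherits the unconditional 250-kb rule;
  in very dense maps this is conservative toward "local".
* The h-test's residual permutation assumes exchangeable residuals under
  the additive fit; strong variance heterogeneity across genotype classes
  would distort its calibration.
* Count-scale traits are scanned after normalization on the linear
  scale, as in the source analysis; no variance-stabilizing transform is
  applied.
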