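---
title: "Methods: array design, genotype QC, linkage mapping and ICIM in cicerArrayQTL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: array design, genotype QC, linkage mapping and ICIM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cicerArrayQTL)
```

This vignette is the package's account of its methods: the models and
procedures each stage implements, the assumptions behind them, the
parameters that matter, and the choices made where a published
description leaves the design open. Nothing here states an empirical
result beyond what the test suite and `scripts/acceptance.R` themselves
compute.

## Probe design

A SNP is a candidate for an Axiom-style array if a 71-mer probe centred
on it (35 bp of flank each side) behaves predictably during
hybridisation. The filters implement that idea directly, in a fixed
order; each removed SNP is charged to the *first* filter it fails, which
makes the attrition report additive (input = survivors + sum of
removals) while the surviving *set* is order-invariant (a SNP survives
iff it passes every filter, which the per-filter flags in the probe
sheet expose for testing).

| filter | rule | default |
|---|---|---|
| edge | the probe window must fit on the chromosome | 35 bp flank |
| isolation | no other SNP within the flank on either side; a pair at distance ≤ 35 bp removes both | 35 bp |
| SSR | no perfect tandem repeat overlapping the window | motif 1–6 bp; min copies 10/6/5/5/5/5 |
| indel | no indel record overlapping the window | — |
| biallelic | exactly one alternate allele | — |
| MAF | minor allele frequency ≥ threshold | 0.05, inclusive |
| GC | window GC within band | 0.40–0.70, inclusive |
| ambiguity | no character outside A/C/G/T in the window | — |
| quality | site quality ≥ threshold | 30, inclusive |

Decisions worth recording:

* **All comparisons are inclusive on the passing side** (MAF = 0.05
  passes, GC = 0.40 or 0.70 passes, QUAL = 30 passes, score = 0.3
  passes). Published filter lists write two of these as explicit `>=`;
  the rest are made consistent with them rather than mixing strict and
  non-strict boundaries.
* **"Flanking region" means the 71-mer window** for the SSR and indel
  filters, the same context the isolation rule uses — one probe context
  throughout rather than a second, undocumented window.
* **SSR thresholds** follow the MISA convention (10 copies for
  mononucleotide motifs, 6 for di-, 5 for tri- through hexa-), since
  repeat-screening pipelines in this field rarely print their settings.
  Motifs must be primitive, so a poly-A run is one mononucleotide tract,
  not also an AA and AAA tract; only whole copies count, and ambiguity
  characters terminate tracts. The detector is run genome-wide and
  overlapped against probe windows, so tracts extending past a window
  edge still disqualify it.
* **Triallelic sites fail the biallelic filter outright**, even when the
  second alternate allele is rare: the cluster model downstream is
  three-cluster.
* **Region annotation is three-way** (coding = inside a CDS exon,
  intronic = inside a gene but no exon, everything else intergenic). A
  UTR position annotates as intergenic unless it is inside a CDS — the
  three-way split has no UTR class and unannotated flanks cannot support
  one.
* **Coding effects** use strand-aware codon reconstruction and the
  standard genetic code. In the first codon, a substitution that leaves
  a recognised start codon (ATG/CTG/TTG) is `synonymous start`,
  otherwise `start lost`; in the stop codon, `synonymous stop` or `stop
  lost`; elsewhere `stop gained`, `synonymous coding` or `nonsynonymous
  coding`. The first and last two intron bases take splice
  donor/acceptor labels with precedence over everything else at those
  positions.
* **Deduplication** keeps one record per (chrom, pos): highest quality,
  ties by lexicographically smallest alternate allele — deterministic
  without reference to input order.
* The vendor's probe-conversion model is out of scope; `scoreHook`
  exposes its interface (a per-candidate score in [0, 1], retained at
  ≥ 0.3) with a constant-1 default so pipelines that have such a model
  can plug it in.

## Genotype QC

Samples fail first on DQC < 0.82, then on call rate < 97% among DQC
passers; both thresholds are strict less-than, so a sample exactly at
threshold is retained. DQC itself is a platform statistic computed from
raw intensities; it is consumed, never computed, here.

Per-SNP metrics come from per-cluster summaries in the
(contrast, size) plane. The published workflow names its cutoffs but not
its formulas, so the package states testable definitions that follow the
Axiom cluster-geometry conventions:

* **FLD** = min over present homozygote clusters of
  |μx(het) − μx(hom)| / σ_pooled, σ_pooled = √(mean within-cluster
  contrast variance over the present genotype clusters). Scale-invariant.
  A homozygote-pair analogue (`computeHomFld`) gates the two-cluster,
  no-het case.
* **HetSO** = size-axis offset of the het cluster mean from the chord
  joining the homozygote cluster means; zero when collinear, negative
  below the chord. Undefined (error) when the homozygote contrasts
  coincide.
* **HomRO** = signed minimum over homozygote clusters of the contrast
  distance from zero, positive on the expected side (AA positive, BB
  negative).

Classification is a fixed-order decision tree: call-rate failure; OTV
(an extra low-size cluster holding ≥ 5% of samples whose chord offset is
below −0.3); one cluster → MonoHighResolution at HomRO ≥ 0.6; het + one
homozygote → NoMinorHom at FLD ≥ 3.6 and HomRO ≥ 0.3; two homozygote
clusters → HomHomResolution at homozygote-pair FLD ≥ 6.5; three
clusters → PolyHighResolution at FLD ≥ 3.6, HetSO ≥ −0.1, HomRO ≥ 0.3
and ≥ 2 minor homozygotes; then the AA/BB variance classes; else Other.
Numbers not printed in published workflows — the hom-pair FLD gate
(6.5), the minor-homozygote minimum (2), the variance ceilings (0.8) and
the 5% OTV-cluster floor — are package choices, exposed in
`qcThresholds()`. `HomHomResolution` is defined from its class name (two
clean homozygote clusters, no het); the vendor's exact precedence among
the variance classes is not documented, so variance failures are checked
after the main gates, in the fixed order AAvarX, AAvarY, BBvarX, BBvarY.
The tree is exhaustive and exclusive, and improving any single metric
can never move a SNP from a passing class to a failing one (a property
the suite checks by perturbation).

## Linkage mapping

The mapping model is a population of fully inbred selfed RILs: two
homozygote classes segregating 1:1, heterozygous and missing calls
excluded from pairwise counts. The observed recombinant fraction between
two loci relates to the meiotic fraction by R = 2r/(1 + 2r); the
package corrects estimates back to r = R/(2(1 − R)), capped at 0.4999,
and applies the grouping cutoff (r ≤ 0.35, LOD ≥ 6) to the *corrected*
r, since the cutoff describes meiotic linkage. The pairwise LOD is the
binomial likelihood ratio n(R log₁₀R + (1 − R)log₁₀(1 − R) + log₁₀2)
with 0·log 0 = 0 and R capped at 0.5.

Segregation filtering uses χ² = (nA − nB)²/(nA + nB) on 1 df with
removal at p < 0.01. Duplicate binning treats two markers as identical
when they agree on every jointly non-missing call *and* share at least
50% joint coverage; each marker joins the first matching bin's
representative (genome order), a deterministic rule because wildcard
identity is not transitive. Grouping is single-linkage transitive
closure. Ordering minimises the sum of adjacent recombination fractions:
groups of ≤ 3 are solved exhaustively, larger groups by greedy
nearest-neighbour seriation from the best start followed by a ripple
pass that exhaustively permutes every sliding window of four markers
until no improvement — window 4 balances the O(w!) cost per window
against the local errors seriation actually makes. Orientation is
canonicalised so the marker with the smallest genome coordinate
(`anchor`) sits nearest 0 cM. Distances between adjacent markers are
Kosambi transforms of the adjacent-pair r (not multipoint likelihood):
tractable, deterministic, and exactly the model the rf estimator uses,
which keeps recovery tests sharp. Map summaries round densities and
averages half-up to two decimals, the convention of published map
tables.

## ICIM-ADD

Genotypes are coded +1/−1 (het 0, missing imputed at the marker mean).
Cofactors come from forward–backward stepwise regression with
partial-F entry at p ≤ 0.001 and exit at p = 2·p_in = 0.002 —
IciMapping-style defaults for an "all defaults" analysis; collinear
candidates (a duplicate of a selected marker) cannot enter. For each
scanned interval the phenotype is adjusted by all selected cofactors
except the two flanking markers, then a 1-cM walk (marker positions
included in the grid) computes, per position, the expected QTL genotype
by flanking-marker interpolation under no double crossover (weights
proportional to the RIL-observed recombinant fractions of the two
sub-intervals), LOD = (n/2)log₁₀(RSS₀/RSS₁) from the simple regression,
the additive effect as its slope, and PVE = 100(1 − RSS₁/RSS₀). The
regression LOD is used instead of an EM mixture likelihood: with
near-complete homozygosity in RILs the two agree closely, and the
regression form is deterministic and directly testable against an lm()
oracle.

Thresholds come from permuting the phenotype against the genotype rows
(1000 permutations, α = 0.05 by default), re-running cofactor selection
and the scan per permutation, and taking the 95th percentile of the
genome-wide maximum LOD; the threshold is reproducible under a fixed
seed and invariant to location/scale changes of the phenotype. Peaks
above threshold become QTLs, merged within 5 cM (the higher peak wins)
and given 1-LOD support intervals. Across environments a QTL is *robust*
at PVE strictly > 10%, *stable* when a same-trait peak co-locates
within 10 cM in ≥ 2 locations, *consistent* likewise across ≥ 2 years.
The 5 cM merge radius and 10 cM co-location window are not stated in
published analyses of this kind and are exposed as configuration;
published cross-environment QTL counts therefore cannot be reproduced
exactly and are not targets of this package.

## The synthetic-data generator

The generator's job is ground truth, and its defaults are the study
conditions the tests run under: a reference of 8 chromosomes (200 kb
each at desk scale) with planted genes, SSR tracts and an N tract; a
panel with SNPs at 10⁻³ per base over 50 accessions, a Beta(0.5, 0.5)
allele-frequency spectrum, quality scores N(45, 10), ~1% triallelic
sites, indels, and one planted violator per design filter (each clean
with respect to every earlier filter, so attrition accounting is
checkable); RIL populations from two founders under a known true map
(near-even marker spacing with ±30% jitter so every adjacent interval
stays well inside the linkage range); phenotypes y = Σaₖxₖ + env shift +
N(0, σ²) with planted additive QTLs at a = 1, σ = 1 (PVE 50%) and
n = 300 for recovery runs; and cluster signals at separation 8 (cluster
means ±1/0/−1 in contrast, SD 1/separation) with a 2% low-DQC tail.

Two modelling decisions matter for interpretation. Recombination is
simulated marker-to-marker with independent intervals (no interference)
at the RIL-observed R per interval — exactly the pairwise estimator's
model, which makes recovery tests sharp but means the simulations cannot
probe interference effects on multipoint orders. RILs are F∞ (fully
selfed) by default, matching the 1:1 two-genotype segregation the χ²
test assumes; `residualHetRate` is the knob for the residual
heterozygosity real RILs retain (the generation number of real
populations is typically unstated), and the pipeline's QC stage runs at
2% residual heterozygosity because a three-cluster PolyHighResolution
call requires a het cluster to exist at all. What passing tests show is
therefore that each stage recovers the parameters of its own model on
data generated from that model with realistic noise; they do not show
robustness to segregation distortion, genotyping-error hotspots,
population structure in the panel, or linkage disequilibrium beyond the
biparental cross, none of which the generator emulates.

## Numerical choices, degenerate inputs, problem sizes

* Rounding for printed tables is half-up (via `roundHalfUp`), not
  banker's rounding, to match how published tables are typeset.
* `estimateRfRil` errors with no jointly informative pair; a zero pooled
  SD makes FLD an error rather than infinity; a degenerate homozygote
  chord makes HetSO an error; a single-marker group has length 0 and
  undefined (NA) density; a constant phenotype yields an empty cofactor
  selection; a zero-variance adjusted phenotype is an error in the scan.
* Ties in ordering resolve to the first minimum (deterministic);
  orientation ties fall back to marker-id comparison.
* The permutation threshold uses the type-7 sample quantile of the null
  maxima; `alpha = 1` degenerates to the minimum, which the suite pins.
* Test problem sizes are chosen to make the statistical checks sharp at
  desk scale: n = 2000 RILs for segregation/rf convergence bounds,
  n = 300 for map and QTL recovery (20 and 50 seeds), 200 null
  replicates with 200 permutations each for the type-I check, 100 random
  instances per brute-force oracle. The full pipeline smoke runs at 2
  chromosomes × 60 kb with 60 RILs and 100 permutations.

## Known limitations

Multipoint maximum-likelihood ordering, epistatic or multi-environment
joint QTL models, dominance (absent in RILs), raw-intensity allele
calling and DQC computation, and GO annotation are all out of scope.
`HomHomResolution` and the variance-class precedence are inferred
definitions, as discussed above. The three-way region split ignores
UTRs by construction. Published end-to-end counts that depend on
unpublished raw data (panel sizes, polymorphic-SNP counts,
cross-environment QTL totals) are outside what a synthetic rebuild can
or should reproduce; what is reproduced exactly is the summary
arithmetic of the published tables and the method's closed forms, and
what is reproduced statistically is parameter recovery under the
generator's conditions.
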