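---
title: "Methods: capture QC, dosage calling and homoeolog analysis in polycap"
author: "polycap maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: capture QC, dosage calling and homoeolog analysis in polycap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polycap)
```

## The problem

Targeted sequence capture enriches a set of genomic regions with
hybridization baits before sequencing. In an allopolyploid such as
*Brassica napus* (genome AACC, formed from *B. rapa* and *B. oleracea*),
every targeted gene is typically present as several homoeologous and
paralogous copies that are 90--99% identical to one another. Three
consequences dominate the analysis and motivate this package:

* **Dosage is informative.** Because capture depth is roughly proportional
  to template copy number, copy-number variation (CNV) and complete
  presence--absence variation (PAV) between genotypes can be read off
  normalized per-locus read depth.
* **Cross-mapping creates hemi-SNPs.** Reads from two divergent but
  co-captured copies can collapse onto one mapping position. In a fully
  inbred line, a heterozygous call is therefore not residual
  heterozygosity but a *hemi-SNP* -- the signature of collapsed
  homoeologous loci -- and must be separated from true locus-specific
  homozygous SNPs before any functional interpretation.
* **Copy bookkeeping needs its own arithmetic.** Comparing the detected
  copy set against the progenitor expectation yields counts of lost,
  duplicated, functional and non-functional copies, and gene dosage
  ratios between regulators (e.g. the floral activator *CO* against the
  repressor *TEM1*).

## Coverage normalization

All depth comparisons go through one dimensionless quantity. For a
constant-depth segment of a bedGraph track ("equally covered region")
with depth $d$, on a genome of total length $G$, in a library with $N$
aligned reads of length $r_\ell$:

$$\mathrm{cov_{norm}} = \frac{d \cdot G}{N \cdot r_\ell},$$

i.e. depth divided by the expected genome-wide mean coverage
$N r_\ell / G$. A region's normalized coverage is the length-weighted mean
of its segments' values, with uncovered bases counting as depth zero.
The formula is invariant under library-size rescaling (doubling every
depth together with $N$ changes nothing), which is the property the
cross-genotype comparisons rely on; the test suite asserts it exactly.

The genome length $G$ comes from a two-column genome index file rather
than from the observed track, so chromosomes without a single aligned
read still enter the denominator. All 0-based/1-based coordinate
conversions (bedGraph/BED are 0-based half-open, VCF and `GRanges`
1-based) happen inside the I/O layer and nowhere else.

## Capture QC metrics

`captureMetrics()` reports, per genotype: mean genome-wide coverage, mean
target coverage, their ratio (the **enrichment factor**), normalized mean
target coverage, the fraction of target bases covered at depth $\ge 1$
(**capture sensitivity**), the fraction covered at depth $\ge k$
(default $k = 10$), the percentage of sequenced bases on target
(**specificity**) and the genome fraction at depth $\ge k$. Choices worth
stating:

* "Covered by more than $k$ reads" is implemented as $\ge k$ (a minimum
  coverage of $k$), with `strict_gt = TRUE` switching to $> k$.
* Specificity is computed over *bases*, not reads: a depth track does not
  record which read contributed which base. The object's metadata records
  this.
* Enrichment factor and normalized mean target coverage coincide exactly
  when $N r_\ell$ equals the track's total base count; with externally
  supplied alignment totals they differ, and both are reported rather
  than reconciled.

## CNV and PAV calling

For each target copy and genotype, `locusNormalizedMatrix()` computes the
normalized coverage over the copy's full span; `callCnv()` then forms the
ratio of the focal genotype's value to a panel reference and applies
fixed thresholds with **strict** inequalities:

* ratio $< 0.05$: **absent** (PAV, the extreme of loss, checked first);
* ratio $< 0.5$: **loss**;
* ratio $> 1.5$: **gain**;
* otherwise **normal**. A ratio exactly at a threshold is normal.

Two reference conventions are implemented because the choice matters in
small panels. With the *panel mean* (focal genotype included), a
4-genotype panel dilutes a half-dose event to a ratio of
$0.5/0.875 \approx 0.57$ -- above the loss threshold, so the event is
invisible. The *leave-one-out* (LOO) mean removes this dilution and is
the default for panels of up to six genotypes; both modes are exported
and recorded in the call set.

**The half-dose knife-edge.** LOO has its own degeneracy: a clean
multiplier-0.5 event against three unaffected genotypes has expected
ratio exactly $0.5/\mathrm{mean}(1,1,1) = 0.5$ -- precisely the strict
loss threshold. Detection of a half-dose event is therefore a coin flip
at *any* sequencing depth: noise, not signal, decides which side of the
threshold the ratio lands on. The symmetric situation occurs at PAV loci,
where the partners of an absent genotype have expected LOO ratio
$1/\mathrm{mean}(0,1,1) = 1.5$, the strict gain threshold; occasional
false gain calls at PAV loci are the expected failure mode and the test
suite characterizes both edges explicitly. Duplications (ratio 2 vs gain
threshold 1.5) and absences (ratio 0 vs 0.05) sit far from their
thresholds and are recovered essentially always. We deliberately keep the
published threshold values and strict comparisons rather than nudging
either; users calling half-dose events in small panels should widen the
loss threshold or enlarge the panel.

Loci carrying heterozygous SNPs in a genotype are excluded from that
genotype's calls (reason recorded), because cross-mapping between
homoeologs confounds depth exactly where hemi-SNPs appear; a zero panel
reference likewise excludes the locus.

## SNP classification and coding consequences

`classifyZygosity()` implements the inbred-line logic: `hom_alt` is a
locus-specific homozygous SNP, `het` is a hemi-SNP; for samples not
declared inbred the hemi interpretation is withheld
(`heterozygous_unresolved`). Only homozygous SNPs should feed downstream
functional analyses. The inbred assumption is an *assumption*, recorded
in the panel object, not inferred from the data.

Variants are located against target spans, promoter ranges and CDS
features; exonic variants are mapped onto CDS coordinates (CDS parts
concatenated in transcription order, minus-strand genes
reverse-complemented, alleles complemented) and the affected codon is
translated with the standard nuclear genetic code before and after the
substitution. Degenerate inputs (CDS length not divisible by three,
reference/CDS mismatch) yield `not_applicable` with a reason rather than
a guess. The classifier is checked against an independent translation
oracle over all 576 single-base codon substitutions.

Panel summaries follow the convention of reporting per-genotype class
counts as percentages of the *panel-wide distinct site totals* (all
genotypes pooled), for both all SNPs and target SNPs; the per-genotype
alternative is available behind a flag. SNP density is target length
divided by the panel-wide target site count, rounded to the nearest bp.

## Copy inventory accounting

`summarizeInventory()` derives: detected copies; non-functional copies
and their percentage (nearest integer by default); progenitor-expected
copies lost; detected copies that are post-polyploidization duplications;
functional duplications (duplicated minus non-functional duplicated); and
the mean number of functional copies per gene (one decimal). "Functional"
is an input flag -- deciding functionality (translation, database hits,
expression) is upstream of this package. The packaged reference inventory
for the 30 *B. napus* flowering-time gene families uses 30 as the divisor
because the capture also pulled in the close paralog family *CO-like 2*,
which was analysed alongside the 29 intended genes; the tetraploid:diploid
ratio is reported as `NA` because its diploid denominator is not derivable
from the available counts. `dosageRatio()` adjusts reference copy counts
by $-1$ per loss, $+1$ per gain, and removal of all reference copies at a
locus per absence, erroring if a count would go negative.

## Bait tiling

`tileBaits()` places 120-mers end-to-end (1x tiling) within each
unmasked run (lowercase and `N` both count as masked). Runs shorter than
the bait length yield nothing. When a run leaves an uncovered tail, a
terminal bait anchored at the run end is added only if it would overlap
the previous bait by at most the overlap allowance (default 20 bp) --
our reading of a vendor parameter whose exact semantics are proprietary;
the rule is declared, configurable, and not claimed identical to the
original tool. The strand rule of capture design is honored: plus-strand
genes get antisense baits (reverse complement of the genomic window),
minus-strand genes sense baits; both end up antisense to the mRNA.

## Promoter clustering

`pDistance()` computes pairwise mismatch fractions over gap-free columns
(Jukes--Cantor correction by flag; promoters of homoeologs are close
enough that the raw p-distance is the default). `njTree()` is canonical
Saitou--Nei neighbor joining with two determinism guarantees: ties in the
Q-criterion break toward the lexicographically smallest label pair, and
negative branch lengths are clamped to zero with a warning and a flag.
On additive matrices the generating tree is recovered exactly (asserted
against an independent implementation). `bootstrapTree()` resamples
alignment columns with replacement (default 100 replicates, seeded) and
annotates internal edges with the percentage of replicates containing
the bipartition.

## The synthetic experiment generator

`simulateExperiment()` emulates the statistical structure the analysis
assumes, not reads or mapping:

* **Design.** Default: 25 genes x 2 copies per subgenome = 100 loci of
  2 kb (600 bp promoter + 900 bp CDS) on 10 chromosomes, 4 fully inbred
  genotypes, 100 bp single-end reads. A/C homoeolog pairs descend from a
  common ancestral sequence at 97% identity.
* **Depth.** On-target expected depth at a locus with copy multiplier
  $m$ is $m \times E \times b$ with enrichment $E = 760$ and background
  mean $b = 0.5$; off-target depth is $b$. Noise is negative binomial per
  constant-depth bin (50 bp on target, 50 kb off target) with dispersion
  0.1 -- capture depth is strongly overdispersed relative to Poisson, and
  a Poisson model would make the dosage-recovery results look better
  than real data warrants.
* **Genome size.** $G = 4 \times 10^9$ bp, deliberately larger than the
  *B. napus* genome so that the 200 kb target is a negligible genome
  fraction and the measured enrichment factor (mean target over mean
  genome-wide coverage) agrees with the configured on/off depth ratio to
  within a few percent. At realistic target:genome ratios on-target reads
  inflate the genome-wide mean substantially, and enrichment factor and
  on/off ratio part ways; one consequence of our choice is that simulated
  on-target specificity (~4% of bases) is far below the ~50% typical of
  real capture experiments. No result in this package depends on
  specificity.
* **Events.** Per-genotype copy multipliers on the grid
  $\{0, 0.5, 1, 1.5, 2\}$; the default random assignment places 5 losses
  (0.5), 5 gains (2), 2 absences (0) and one homoeologous replacement
  (one copy 0, its partner 2 in the same genotype) at distinct loci.
* **Variants.** Locus-specific homozygous SNPs at 0.002/bp per genotype.
  A subset of the divergent sites between each homoeolog pair
  (0.001/bp) surfaces in the calls: heterozygous at both partners when
  the genotype carries both copies; homozygous-alternate at the surviving
  locus when one partner is absent (the caller's consensus follows the
  cross-mapped allele); silent when both are absent. Record depths are the
  locus mean, so default events stay above the depth-10 filter. No indels
  are simulated.
* **Determinism.** One seed drives everything; identical seeds produce
  bitwise-identical output files.

What the generator does **not** emulate -- mapping-quality structure,
ambiguous-mapping depth suppression at duplicated loci (a depth-bleed
parameter exists but defaults to 0), GC and bait-affinity bias, indels,
real promoter homology structure -- bounds what passing tests show about
real data: they validate the arithmetic and the calling logic under the
stated generative model, not the upstream alignment pipeline.

## Problem sizes and numerical choices

Unit tests run on reduced designs (typically 4--8 genes, 1 kb loci, a
0.4 Gb genome) so the full suite stays fast; the dosage-recovery and
acceptance checks use the default 100-locus, 4-genotype design over 20
seeds (tests) or 10 seeds (the acceptance script). Brute-force per-base
oracles operate on small genomes where whole-chromosome depth vectors are
affordable. Tolerances: interval arithmetic is checked against oracles at
1e-12 (identical arithmetic, different route); NJ recovery of additive
matrices at 1e-8; Monte-Carlo convergence checks at the 2--5% the
relevant statistic's sampling noise supports. All randomness flows from
explicit seeds, and functions that need internal randomness
(`bootstrapTree()`, `simulateExperiment()`) save and restore the caller's
RNG state.

## Known limitations

* The half-dose/LOO knife-edge described above is inherent to the fixed
  0.5 threshold with strict comparison; the package characterizes it
  honestly instead of hiding it.
* `summarizeInventory()` trusts its input flags; it cannot detect an
  inconsistent inventory beyond its structural checks.
* VCF handling targets single-sample files with GT and DP; multi-sample
  VCFs use the first sample.
* The bait terminal-rescue rule is a declared interpretation of an
  undocumented vendor parameter.
* `bootstrapTree()` supports only distance-based NJ; replicate trees that
  fail (e.g. a resampled alignment with no comparable columns for a
  pair) are dropped from the support denominator.
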