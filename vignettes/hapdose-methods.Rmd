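---
title: "Direct haplotype phasing and relative haplotype dosage for X-linked NIPD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Direct haplotype phasing and relative haplotype dosage for X-linked NIPD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hapdose)
```

## The diagnostic problem

A woman who carries a pathogenic mutation on one X chromosome — the
motivating case is a *DMD* mutation, where a male fetus inheriting the
mutant haplotype will develop Duchenne muscular dystrophy — wants a
prenatal diagnosis without amniocentesis. Her plasma contains cell-free
DNA, a few percent of which is fetal. At any heterozygous maternal SNP,
the fetal contribution tilts the allelic balance very slightly toward
the alleles the fetus inherited. No single SNP is informative at 4–9%
fetal fraction and 200× depth, but several hundred phased SNPs are:
if we know which alleles lie together on the mutant-linked maternal
haplotype (**HapA**) and which on the wild-type-linked one (**HapB**),
the *relative haplotype dosage* (RHDO) — the pooled fraction of
HapA-supporting reads — sits above 0.5 when the fetus inherited HapA
and below 0.5 otherwise.

The crux is obtaining the maternal phase *directly*, without genotyping
an affected male relative. Targeted linked-read sequencing provides it:
high-molecular-weight gDNA fragments (~50 kb) are partitioned into
droplets ("gems"), all reads from one gem share a barcode, and
co-barcoded alleles at nearby het SNPs reveal which alleles are in *cis*.

`hapdose` implements this workflow end to end — barcode phasing,
linkage of the pathogenic mutation (point, large deletion, or large
duplication) to one haplotype, and the plasma dosage analysis with
changepoint-based recombination adjustment — together with a simulator
that generates linked-read and plasma data with known truth.

## The dosage model

Let $f$ be the fetal fraction of plasma cfDNA defined on autosomal
genome equivalents. For a **male** fetus on chrX the mother contributes
two X copies per genome equivalent and the fetus one, so the fetal
share of X-derived reads is

$$\varphi = \frac{f}{2 - f}.$$

At a copy-neutral maternal het SNP $i$, the expected fraction of reads
carrying the haplotype-1 allele is

$$p_i = \frac{1-\varphi}{2} + \varphi\,\mathbf{1}[\text{fetal allele}_i = \text{hap1 allele}_i],$$

i.e. $\tfrac{1+\varphi}{2}$ on the transmitted haplotype's side and
$\tfrac{1-\varphi}{2}$ on the other. At $f = 9.25\%$ (the highest
concentration in the emulated cohort), $\varphi \approx 0.0485$ and
$p \approx 0.524$; at $f = 4.1\%$, $p \approx 0.510$ — an imbalance of
one to two percent, resolvable only by pooling.

The simulator generalises this with site copy numbers: inside a
carrier duplication the maternal site has three copies (the duplicated
haplotype two, the other one), giving pooled fractions near $2/3$ vs
$1/3$; inside a carrier deletion the mutant haplotype has zero copies.
The copy-neutral formula above is the special case with all copy
numbers equal to one.

Inverting the same mixture yields the fetal-fraction estimator used by
`estimate_fetal_fraction()`: with pooled HapA fraction $\hat{F}$,
$\hat\varphi = |2\hat{F} - 1|$ and $\hat f = 2\hat\varphi/(1+\hat\varphi)$,
with a bootstrap CI over SNPs. The source study defers its
fetal-fraction methodology to earlier work, so this X-dosage inversion
is this package's own declared construction; on simulated data it
recovers the generating $f$ to within ±0.5 percentage points (mean of
20 draws; verified by the test suite and the acceptance script).

## Synthetic data: the stated world

The generator emulates the sequencing regime of the study it mirrors.
Defaults are fixed once and are not tuning knobs:

| parameter | default | origin |
|---|---|---|
| target region | chrX, 2.2 Mb | the *DMD* locus scale |
| informative het SNPs | 850 | midpoint of the reported 700–1,000 |
| molecule length | exponential, mean 52.7 kb | reported average HMW length |
| maternal read coverage | 676× | reported mean coverage |
| physical molecule coverage | 300× | ~1 ng Chromium input (~150 genome equivalents per haplotype); unreported, chosen once |
| molecules per gem | 10 | typical Chromium partitioning; unreported, chosen once |
| observation error | 0.1% | post-filter base-call error scale |
| plasma depth | 200× per SNP | the depth recommended for RHDO at ~1000 SNPs |
| fetal fractions | 4.10–9.25% | the nine printed per-draw concentrations |
| fetus sex | male only | cohort design |

`dmd_cohort()` encodes the five-family design: three large deletions,
one duplication, one splice point mutation; nine plasma draws at the
printed fetal fractions; the wild-type haplotype transmitted in family
1 and the mutant in the others; and a single fetal recombination event
in family 5 (one crossover, placed mid-region — the study reports the
event but not its coordinate — with the mutant haplotype transmitted at
the mutation locus, matching the confirmed fetal genotype).

Modelling choices worth knowing:

* **Deletion carriers.** Mutant-haplotype molecules are placed on the
  excised genome and mapped back to reference coordinates, so they
  span the deletion junction: they emit no observations inside the
  deleted interval but carry both flanks under one barcode — exactly
  the evidence the deletion linker consumes. Het SNPs are still placed
  uniformly, including inside the deletion, where only the wild-type
  haplotype is observed (in real data such sites are hemizygous; see
  the RHDO section for how they are kept out of the dosage).
* **Duplication carriers.** SNPs inside the duplicated interval are
  observed at doubled rate on the mutant haplotype, reproducing the
  2:1 allele imbalance; plasma fractions there follow the copy-aware
  mixture.
* **Gems mix haplotypes.** A barcode pools 10 molecules that may come
  from either haplotype. Distant SNP pairs co-observed in one gem are
  therefore linked by molecules of random phase — a realistic noise
  floor that the phasing thresholds must (and do) reject.
* **One seed, documented fan-out.** Every dataset derives all its
  randomness from one integer via `stage_seed()` (a string-hash of the
  stage name), so any stage can be re-simulated independently.

What the generator does **not** emulate: base-level sequences and
alignment (observations are allele calls at known het sites), PCR
duplicates and GC bias, capture-efficiency variation along the target,
mapping artefacts in repeats, maternal mosaicism, and female fetuses.
A green test therefore establishes the *statistical* correctness of
the algorithms under the stated read model, not robustness to
alignment pathology.

## Phasing

1. `build_barcode_matrix()` tallies per-barcode allele counts per SNP;
   barcodes seeing fewer than two distinct SNPs carry no linkage
   information and are dropped.
2. `build_phase_graph()` takes each barcode's majority allele per SNP
   (ties discarded — no guessing) and lets every pair of called SNPs
   within a barcode vote *cis* (same allele class) or *trans*.
3. `call_phase_blocks()` keeps an edge iff the winning orientation has
   at least `min_support = 2` votes **and** at least `min_ratio = 0.75`
   of the votes. Connected components become phase blocks. The support
   threshold means no single chimeric gem can create an edge; the
   ratio threshold is what rejects the mixed-haplotype links between
   distant SNPs, whose votes split near 50/50.
4. Relative phases: blocks of ≤ 12 SNPs are solved exactly by
   enumerating all $2^{k-1}$ assignments and maximising vote
   agreement; larger blocks are phased by traversing the
   maximum-support spanning tree (ties broken toward lower SNP
   indices for determinism). Kept edges that contradict the final
   assignment are counted as conflicts; a block with conflicts in
   more than 5% of its non-tree edges is flagged low-confidence.
   The exact small-block solve exists because a greedy tree is not
   always the global maximum-agreement phasing when edges conflict;
   at sizes where exhaustive search is trivial there is no reason to
   accept the heuristic's occasional suboptimum.
5. `anchor_hapA()` orients blocks against the mutation:
   mutation-supporting barcodes (mutant-allele reads for a point
   mutation; junction-spanning or divergent-allele gems for an SV, see
   below) vote on each block's strand, blocks without direct evidence
   are chained through shared barcodes (a spanning tree over the block
   graph rooted at the mutation node), and unreachable blocks stay
   unanchored and are excluded from the HapA/HapB vectors and all
   downstream dosage — exclusion is the conservative choice.

At the emulated regime the 850 SNPs resolve into a single anchored
block and phasing concordance against simulated truth is 100%; the
acceptance criterion only demands > 90%.

## SV-to-haplotype linkage

**Deletions** (`link_deletion()`): gems with observations *inside* the
deleted interval must carry the wild-type haplotype there; gems whose
observations bracket the interval — at least one observation within
`flank_bp = 1.5 ×` the mean molecule length on each side — with none
inside behave like molecules spanning the deletion junction and support
the mutant haplotype. Because this package consumes allele
observations rather than raw bases, the study's re-alignment of mutant
reads to a customised deletion reference is realised as its functional
equivalent: a cross-gap phase-consistency check (each spanning gem's 5′
and 3′ flank alleles must agree on one haplotype; inconsistent gems are
discarded as chimeric). A further flank check verifies that the het
SNPs immediately 5′ and 3′ of the deletion phase to the same
haplotype. Note that some bracketing gems are genuinely wild-type (two
flanking molecules that happen to stop short of the interval); the
consistency filter removes about half of those and the rest vote at
random, which is why the linkage is decided by majority rather than
unanimity.

**Duplications** (`link_duplication()`): pooled allele fractions at
SNPs inside the interval are expected near $2/3$ vs $1/3$; SNPs outside
the band `[af_low, af_high] = [0.4, 0.6]` are *divergent*, their
overrepresented allele identifies the duplicated haplotype, and the
majority vote across divergent SNPs sets the linkage (a split below
75% is flagged). The band is a declared choice — the source describes
only "particularly divergent" — and is exposed as an argument. Its
calibration is molecule-aware: allele fractions fluctuate at molecule
granularity, not read granularity, so the <1% per-SNP false-positive
property holds at the full physical coverage (~300×) and should not be
expected at heavily scaled-down molecule counts.

## RHDO analysis (`rhdo()`)

`rhdo()` is the model-style entry point: plasma counts + anchored
haplotypes in, a classed result out (`print`, `summary`, `coef`,
`plot` methods).

1. **Fraction series.** Per-SNP HapA depth $a_i$, HapB depth $b_i$,
   $F_i = a_i/(a_i+b_i)$, ordered by position. SNPs inside a known
   deletion or duplication interval are excluded up front: in the
   carrier such sites are hemizygous or copy-imbalanced, i.e. not
   informative heterozygous sites, and for a large deletion their
   $F \approx 0$ (or 1) values are numerous enough to shield
   themselves from a single-pass outlier screen (they inflate the
   screen's own standard deviation). The SV coordinates are a pipeline
   input, so the exclusion is deterministic rather than statistical.
2. **Outlier screen** (`remove_outliers()`): a single-pass Shewhart
   individuals chart — points more than `n_sigma = 3` standard
   deviations from the retained-set mean are masked. This is what
   removes residual aberrant fractions from duplicated or repetitive
   sequence. A constant series (sd 0) masks nothing.
3. **Changepoint detection** (`detect_changepoints()`): change-in-mean
   segmentation by PELT under a normal cost with a modified-BIC
   penalty, implemented in this package. In $-2\log L$ units each
   segment costs its standardised residual sum of squares plus
   $\log(\text{segment length})$ and each changepoint adds
   $2\log n$ (the Zhang–Siegmund modified BIC, constants absorbed).
   The noise variance is estimated from mean squared successive
   differences divided by two, which is robust to the mean shifts
   being sought. Minimum segment length is 10 SNPs to suppress
   spurious short segments. Two numerical details matter: candidates
   younger than `min_seg` must stay in PELT's candidate set until they
   become eligible, and the pruning constant must be the *negative*
   slack $K = \log(4/n)$ — the log-length term is subadditive, so a
   positive $K$ over-prunes and silently degrades segmentations. Both
   are pinned by a test obligation: exact agreement with an
   exhaustive $O(n^2)$ optimal-partitioning dynamic program on every
   tested series up to $n = 200$.
4. **Recombination adjustment** (`adjust_recombination()`): a detected
   breakpoint is accepted as a fetal crossover only if the flanking
   segment means lie on opposite sides of 0.5 **and** a two-sample
   z-test on the segments' pooled counts rejects equality at
   `alpha = 0.01`; anything else is drift and ignored. Fractions
   beyond each confirmed breakpoint are reflected
   ($F \to 1-F$, i.e. $a$ and $b$ swapped), reconstructing a series
   that tracks a single transmitted haplotype. The unreflected
   reference segment is the one containing the pathogenic mutation:
   the clinical question — did the fetus inherit the mutant allele? —
   is decided at the mutation locus, so with a crossover between the
   region start and the mutation, anchoring at the first segment would
   invert the call. Reflection by genomic position (not retained
   index) keeps masked SNPs consistent, and the operation is
   idempotent: a reflected series has no opposite-side segments left
   to confirm.
5. **Call** (`call_fetal_genotype()`): pooled counts $A = \sum a_i$,
   $B = \sum b_i$ over retained SNPs, two-sided exact binomial test
   against 0.5 at `alpha = 0.01`; significant and above 0.5 →
   `mutant_inherited`, below → `wildtype_inherited`, otherwise
   `inconclusive`. The explicit inconclusive outcome is an addition —
   the source applies the 0.5 rule directly — so that low fetal
   fraction degrades to "no call" rather than to a coin flip. One
   consequence of using an exact test at $\alpha = 0.01$: under the
   null its rejection rate is 0.96%, so the empirical inconclusive
   rate over a finite seed batch fluctuates around 99.04% and a
   "≥ 99% of 1000 seeds" check is a near-coin-flip at the boundary;
   the package controls the error *in expectation*, which is the
   meaningful guarantee.

Each plasma draw is analysed independently (the emulated study
analysed its two draws per pregnancy separately), ordered by genomic
position.

## A worked example

```{r example, eval = FALSE}
library(hapdose)

cohort <- dmd_cohort()           # the five-family stated world
ds <- simulate_family(cohort[[5]], seed = 1)   # family with the crossover

pair <- phase_linked_reads(ds$reads, ds$config$mutation)
link <- link_deletion(ds$reads, ds$config$mutation, pair)
fit <- rhdo(ds$plasma[[1]], pair)

summary(fit)
plot(fit)         # per-SNP HapA fractions, mean line, breakpoint arrow
```

`run_pipeline(dmd_cohort(), seed = 1)` executes the same stages for
all five families and nine draws; `report_table()` flattens the result
for inspection, and `scripts/acceptance.R` recomputes the headline
quantities (families called correctly, minimum phasing concordance,
fetal-fraction recovery at the lowest and highest concentrations) from
scratch.

## Known limitations

* Observation-level model: no raw reads, so alignment- and
  capture-induced artefacts are out of scope; the outlier screen
  stands in for their downstream effect.
* Only male fetuses: female-fetus dosage (two fetal X's) needs a
  different mixture and is not modelled.
* The deletion linker needs het SNPs within 1.5 molecule lengths of
  both deletion flanks; a deletion at the extreme edge of the target
  would not be linkable.
* Phasing across a region with no informative SNPs for much longer
  than a molecule length will split blocks; unanchored blocks are
  dropped from dosage rather than rescued.
* The fetal-fraction estimator assumes the X-dosage model above; it is
  not a substitute for an autosomal fetal-fraction assay.
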