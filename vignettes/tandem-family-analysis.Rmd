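---
title: "Copy-number genotyping and molecular population genetics of tandem multigene families"
author: "tandemCNV"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy-number genotyping and molecular population genetics of tandem multigene families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Recently formed tandem multigene families — several near-identical gene
copies arranged head-to-tail at one locus — are among the hardest pieces
of a genome to characterize. Short reads cannot be assigned to individual
copies, assemblies routinely collapse or duplicate repeats, and qPCR
primers rarely distinguish a young paralog from its parental gene.
`tandemCNV` implements the analysis toolkit such a locus demands, modeled
on a family that arose as a chimera of two neighboring parental genes
(dynein-related, between a *short wing*-like upstream gene and an
annexin-like downstream gene in *Drosophila melanogaster*), with a repeat
unit of roughly 7.6 kb, copy numbers varying between individuals and
populations, paratype (protein-variant) diversity concentrated in the two
most-3' exons, and rampant gene conversion homogenizing the rest of the
repeat.

Everything the pipelines consume can be generated in-package with known
ground truth, so every module is testable offline; real FASTA/FASTQ/depth
tables and Ct exports drop into the same functions.

## The synthetic region generator

`tandemRegionSpec()` + `buildRegion()` emit a region laid out as

    [flank] [5' parent] [copy 1] ... [copy n] [3' parent] [flank]

with exact truth coordinates for every feature.

* **Parents.** Each parental gene is a unique *anchor section* (the part
  of the gene that never entered the chimeric repeat; `locateRegion()`
  searches for these) plus a repeat-homologous section. Jointly the two
  homologous sections cover the full repeat unit, so on a collapsed
  single-repeat reference the parents capture reads like approximately
  one extra copy — the reason for the genotyper's "−1" correction.
  Parental divergence from the repeat is planted as one substitution
  every 200 nt (0.5%): dense enough that any window of ≥ 201 nt
  (including the 252-nt exon-1 motif) differs from the repeat and cannot
  be mis-annotated as a copy, sparse enough that 100-nt parental reads
  still map onto the repeat.
* **Copies.** Each copy carries a four-exon transcription unit
  (252 + 750 + 750 + 750 nt of coding sequence) with an intact ORF built
  from random sense codons. A paratype label plants a block of six
  consecutive amino-acid substitutions in the two most-3' exons; the
  block position is keyed to the label itself, so regions built from the
  same seed give copies of one paratype identical blocks in every strain
  and joint classification is meaningful. Six codon substitutions
  comfortably exceed the ≥ 5-residue diagnostic threshold.
* **Gene conversion and TEs.** Conversion events overwrite the
  recipient's tract with the donor's current sequence; TE insertions
  shift all downstream truth coordinates and are recorded at emitted
  positions.
* **Flanks.** The `flankLength` parameter stands in for the chromosomal
  background. For annotation work a few kb suffice; for read-depth work
  it must be chromosome-scale (see below).

Randomness always flows from the single integer seed in the spec; no
global RNG state is consumed. Internally, user seeds are passed through a
splitmix64 scramble before seeding the compiled generators, and the
packaged simulation batteries draw per-simulation seeds from one master
stream — consecutive raw `set.seed()` values can produce noticeably
correlated datasets, which matters when estimating error rates from
hundreds of simulations.

What the generator does *not* emulate: paired-end inserts, indel
sequencing errors, GC-dependent coverage bias, segmental duplications
elsewhere in the genome, and assembly errors. Passing tests therefore
demonstrate correctness of the estimators under idealized uniform
coverage, not robustness to every artifact of real libraries.

## Read-depth copy-number genotyping

The estimator follows the collapsed-reference strategy:

1. `buildSyntheticReferences()` emits, per annotated copy, a contig in
   which the tandem array is replaced by exactly that copy and both
   parental genes are excised.
2. `computeDepth()` places reads by exact 31-mer seeding plus
   mismatch-tolerant extension; a read tied between several best
   placements is assigned uniformly at random among them (seeded).
   Discarding multi-mappers would systematically undercount collapsed
   copies, which is why random assignment is the default and only
   behavior.
3. Per-base depth is averaged in 100-nt bins and normalized by the
   reference-wide mean (`DepthProfile`); `callTarget()` reads the raw
   copy-number estimate off the target bins and sizes the called gain as
   the span of ≥ 1.5× runs intersecting the target. An estimate is
   *reliable* iff that call size lies in 7.2–8.0 kb, the plausible
   repeat-unit size range.
4. `aggregateCn()` averages the reliable raw estimates (ANRD), requires
   at least 4 reliable references, rounds half away from zero, and
   subtracts 1 for the parental read capture.

Two numerical choices deserve explanation:

* **Background scale.** Because bins are normalized by the
  reference-wide mean, the repeat itself inflates the denominator: with
  unique background $U$ and repeat length $L$, a planted copy number $n$
  reads out as $(n+1)(U+L)/(U+(n+1)L)$. On a real chromosome
  ($U$ in the tens of Mb) the bias is negligible; at desk scale it is
  not. The recovery study (`cnRecoveryStudy()`) therefore uses
  $U = 5$ Mb (2.5 Mb per side), where the worst-case bias at 12 copies
  is ≈ 0.23 copies — safely inside the rounding margin. This is the
  package's choice of a realistic chromosomal background, stated here so
  nobody mistakes megabase flanks for an arbitrary constant.
* **Boundary-bin trimming.** Only fully contained reads place on the
  reference, and reads spanning the strain's copy–copy junctions have no
  counterpart on a single-repeat contig, so depth ramps over one read
  length at both target ends. `callTarget()` excludes one boundary bin
  per side (exactly the ramp at the default 100-nt bins and reads) from
  the raw mean; `trimBins = 0` restores the plain mean. The call-size
  filter always sees all bins.

The recovery study plants 2–12 copies at 25× coverage with 100-nt reads
(three read sets per copy number) and demands the corrected call equal
truth; the suite also checks that references built from two different
strains give concordant ANRD, and that ANRD is monotone in planted copy
number.

## qPCR copy numbers and expression

Because no primer pair is specific to the family, copy number comes from
two assays: one specific to the parental gene (`sw`), one shared by the
parent and all copies. `relativeQuantity()` implements
efficiency-corrected relative quantification
($E_t^{\Delta Ct_t} / E_r^{\Delta Ct_r}$, replicate-mean Cts, calibrator
ratio ≡ 1), `cnFromAmplicons()` converts ratios to absolute counts via
the calibrator's known counts (a reference female pool: 2 `sw` copies, 14
shared), subtracts, divides by the X dose (1 for male pools, 2 for
female pools — exposed rather than guessed, since pooled whole-body
samples leave it implicit), and rounds to the nearest integer. Family
counts in $[-0.5, 0)$ truncate to zero with a warning; anything lower is
a QC error. The paired simulator `simulateCt()` uses
$Ct = Ct_0 - \log q / \log E + \mathcal{N}(0, \sigma)$ and is exactly
invertible at $\sigma = 0$.

A caution the noisy-recovery simulations make quantitative: the shared
amplicon measures up to $2 + 2c$ copies, so a Ct error $\delta$ inflates
the family count by roughly $(2+2c)\ln 2\,\delta$. With 0.15-cycle well
noise and triplicates, the per-X copy number carries a standard error of
about $0.12\,(1+c)$ copies — exact integer recovery is essentially
certain at 0–1 copies and a coin flip by 6. Integer-exact qPCR
genotyping at high copy number needs either more replication or tighter
chemistry; the package reports the raw and rounded values so users can
judge.

Expression uses the same machinery against a reference gene (`clot`)
with a male calibrator at fold change 1, per-replicate ratios (each
biological replicate is one point in downstream plots/regression),
`regressCnExpression()` for log2-fold-change-on-CN regression and
`anovaTukey()` (Tukey–Kramer for unequal n) for group contrasts.

## V_ST and population statistics

`vst()` computes $V_{ST} = (V_T - V_S)/V_T$ with $V_T$ the pooled sample
variance and $V_S$ the size-weighted mean within-population variance;
all variances use the $n-1$ denominator (the source formulation does not
state a denominator; $n-1$ is used consistently so the choice cancels
where it can). `vstNull()` builds the Monte Carlo null by permuting
population labels (the exchangeability null; a with-replacement
bootstrap is available by flag since the original "bootstrap resampling"
wording is ambiguous) and reports
$p = (\#\{V_{ST}^{perm} \ge V_{ST}^{obs}\} + 1)/(n+1)$, which can never
be 0. For cohorts of ≤ 8 individuals the Monte Carlo p is checked
against exhaustive enumeration in the test suite. Note that with
point-mass populations, relabelings reproducing the observed partition
tie the maximum, so the p-value of a perfectly differentiated cohort is
the frequency of such relabelings, not $1/(n+1)$.

`syntheticGdlCn()` ships a synthetic stand-in for a 70-line,
five-population diversity panel (sizes 11/12/19/16/12, copy numbers
4–10, seven distinct alleles, Beijing shifted low); it exists so the
differentiation pipeline can be exercised end-to-end at the real panel's
shape. Its per-individual values are simulated — statistics computed
from it characterize the machinery, not the published panel.

Nonparametric group comparisons default to pairwise Mann–Whitney with
Holm adjustment, a documented approximation to the named Steel–Dwass
procedure; the studentized-range Steel–Dwass variant is available with
`method = "steel-dwass"`. Sperm-competition P2 values are transformed
with $\arcsin\sqrt{P2}$ (radians by default, degrees by flag) before
group comparison.

## Gene-conversion tract detection

Candidate tracts are maximal runs of consecutive polymorphic columns
over which a sequence pair agrees ("zero mismatches"), after removing
gap-containing columns (mirroring complete-deletion distance handling)
and monomorphic columns. Significance permutes the *order* of
polymorphic columns — destroying runs while preserving every pair's
agreement fraction — and applies a max-statistic familywise correction:
the adjusted p of a fragment is the share of permutations in which the
maximum run across **all** pairs reaches its score. This is exact under
the permutation null and avoids guessing the original software's
analytic correction. Inputs with ≤ 7 polymorphic columns are enumerated
exhaustively. The minimum reportable score is 2 polymorphic sites.

One structural caveat: a pair that agrees at *every* polymorphic column
(complete homogenization) is invariant under column permutation, so its
whole-length fragment has p = 1 by construction. The test detects tracts
against residual divergence of a pair, not identity — the standard
behavior of run-based conversion tests.

`buildComposite()` assembles the parental fragments homologous to the
repeat into one gap-padded pseudo-taxon so parent-to-copy exchange is
detectable in the same framework; `summarizeEvents()` produces per-copy
event counts, group contribution fractions, and a positional histogram
(Circos-style link export).

## Motif-anchored transcript evidence

`countLibrary()` counts RNA-seq reads supporting expression of a
pseudogene-like element: reads failing a mean-Phred ≤ 20 filter (the
whole-read reading of a "Q ≤ 20" rule; a per-base variant is a flag) or
carrying adapters are discarded; survivors are locally aligned (both
strands) against a 130-nt query with a 34-nt core motif
(`ATAGGTCAGTATATACATATTTAACTGTTCCGTT` — the packaged default embeds this
core in synthetic flanks, so real-data work should supply the genuine
130-nt context). A read counts iff the alignment spans > 70 nt of the
query, the entire core is aligned without mismatch or gap, and each
extension (upstream/downstream of the core, judged separately) contains
at most one single-nucleotide mismatch or indel. Scoring is fixed at
match +1, mismatch −1, first gap base −2, each further −1. Verdicts are
validated against an exhaustive dynamic-programming aligner on short
reads in the test suite.

## Problem sizes used by the packaged studies

Chosen once as realistic desk-scale renderings of the study conditions:
read-depth recovery at 2–12 planted copies × 3 read sets, 25× coverage,
100-nt reads, 2.5 Mb flanks; qPCR recovery over 200 simulated plates of
13 genotypes; V_ST calibration over 500 null cohorts of 70 individuals
with 1,000 permutations each (10,000 permutations for single analyses);
gene-conversion power and error over 200 simulated 8-sequence alignments
(2.5 kb, ~10% pairwise divergence, 500-nt planted tracts, 2,000
permutations); paratype recovery over seven strains carrying 13 planted
paratypes.

## Known limitations

* No GC-bias correction in depth profiles (synthetic references share
  composition with their source; real data may need it).
* The depth mapper is substitution-only (no indel alignment) and
  single-end.
* qPCR efficiencies are supplied, not fitted from standard curves.
* Gene-conversion polarity (donor vs recipient) is not inferred.
* The motif filter reports one optimal local alignment per strand;
  co-optimal alignments that differ in extension placement are resolved
  toward the aligner's choice.

## A short tour

```{r tour}
library(tandemCNV)

spec <- tandemRegionSpec(nCopies = 6, paratypes = c("a", "b", "c", "a", "d", "e"),
                         flankLength = 1500, seed = 11)
region <- buildRegion(spec)
copyTable(region)

# annotate it back from scratch
anchors <- parentAnchors(region)
hits <- findCopies(regionSequence(region), exon1Motif(region))
proteins <- vapply(seq_along(hits), function(i) {
  s <- substr(as.character(regionSequence(region)),
              BiocGenerics::start(hits)[i], BiocGenerics::end(hits)[i])
  callOrf(s, spec@exonLayout)$protein
}, character(1))
classifyParatypes(proteins)$labels

# population differentiation with a Monte Carlo null
panel <- syntheticGdlCn(seed = 1)
vstNull(panel$cn, panel$population, n = 10000, seed = 1)
```
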