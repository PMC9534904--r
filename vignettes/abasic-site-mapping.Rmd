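---
title: "Mapping abasic sites at single-nucleotide resolution: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping abasic sites at single-nucleotide resolution: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apsitemap)
```

## The measurement model

An abasic (AP) site is a genomic position whose base has been lost. The
assay this package analyses detects them through their 3'OH chemistry:
pre-existing 3'OH termini are blocked with a dideoxy nucleotide, an AP
endonuclease (APE1 or Endo IV) then cleaves the backbone 5' of each AP
site, and the newly exposed 3'OH on the damaged strand is polyA-tailed,
extended with an oligo-dT primer, polyC-tailed and PCR-amplified. After
paired-end sequencing, the original tails appear as sequence tags: read 1
begins with the literal `AGTTGCGGAT` followed by a G-run, read 2 with a
T-run. Because APE1 cuts 5' of the AP site, the lesion sits one base 3' of
the tail-bearing terminus *on the damaged strand*; in read coordinates
that is one base past the 5' end of read 2 along the strand opposite the
read:

* read 2 on "+" with first sequenced base at position $p$ → site
  $(p - 1, \text{"-"})$;
* read 2 on "−" with 5' end at $p$ → site $(p + 1, \text{"+"})$.

Single-strand-break (SSB) profiling uses the same chemistry without the
endonuclease shift, so the SSB mode sets the offset to 0; on identical
input the two modes differ by exactly one base along the site strand
(tested as an invariant).

All internal coordinates are 0-based half-open. SAM positions are
converted once on input, BED is written 0-based, and nothing else ever
converts — this removes any ambiguity from the one-base shift logic.

## Filters and their parameters

The calling pipeline applies, in order:

1. **Tag structure** — read 1 must start with `AGTTGCGGAT` plus a
   *maximal* G-run of 9–11; read 2 with a maximal T-run of 11–13; both
   prefixes are trimmed. The tag grammar anchors the run after the
   literal `...GAT`: the amplification primer carries G₁₀ followed by a
   non-G base and T₁₂–₁₃ followed by a non-T base, so a run outside those
   bounds cannot come from an intact primer, and a longer run marks a
   boundary the trimmer cannot place. "Maximal" is the only reading under
   which trimming is well defined.
2. **Alignment** — externally produced SAM is accepted; for synthetic
   genomes the packaged exact-match aligner stands in (unique hits MAPQ
   60, multi-mappers MAPQ 0, proper-pair flags 99/147 or 83/163).
3. **Deduplication** — pairs sharing both mates' (chromosome, leftmost
   position, strand) collapse to the highest-summed-MAPQ pair, ties
   broken by read name. This is the standard coordinate-keyed
   (Picard-style) definition; it runs *before* the MAPQ/flag filter,
   matching the published order of operations.
4. **Genomic filter** — read-2 MAPQ strictly greater than 20, SAM flag
   147 or 163, and a first sequenced base aligned as a match (no leading
   soft-clip or insertion, base equal to the reference). The first-base
   rule is evaluated from the CIGAR plus a direct reference comparison.
   Spike-in alignments use their own published variant: MAPQ ≥ 20
   (inclusive), mates uniquely mapped to opposite strands of the same
   spike, distance < 500 bp, first base matched; spikes skip
   deduplication and the polyA filter.
5. **Genomic polyA filter** — the 20 reference bases immediately 5' of
   read 2's first aligned base, read in read orientation on the read's
   alignment strand, must not exceed 40% thymine (strict). This removes
   reads primed in endogenous polyA rather than in the added tail; the
   orientation is the only one consistent with that mechanism. Windows
   truncated by a chromosome end are rescaled to the available length
   rather than dropped — a read with 10 informative upstream bases still
   carries usable evidence.
6. **Assignment** — the coordinate shift above, aggregation of reads
   into per-position depths, and bounds checking.

Every threshold (window 20, fraction 0.40, MAPQ 20, flags, tag-run
ranges, hotspot depth 2, 100 permutations) is a named, defaulted argument
whose default is the published operating point.

## Statistics

**Abundance.** APF (and ASF for SSB libraries) is the number of read
pairs representing sites divided by the number of tag-structure-passing
read pairs; the denominator is taken before deduplication, closest to
"read pairs starting with the expected sequences". APL integrates a
fragment-analyzer electropherogram by trapezoid over 180–1000 bp relative
to 1–1000 bp; the instrument exports a sampled curve, so piecewise-linear
integration with boundary interpolation is the natural quadrature (tested
against a 0.01-bp grid to 1e-4).

**Hotspots.** A sample-level hotspot is a stranded position with depth
≥ 2 in one sample; identity includes strand throughout, since the two DNA
strands carry independent lesions (pooling them would conflate the two
strands' chemistry). Sharing across samples therefore also requires
strand agreement. Group-specific hotspots require depth ≥ 2 in at least
two samples of the group and depth ≤ 1 in every sample outside it,
exactly as stated. Two null models accompany the catalog: uniform
read-matched placement in non-repeat space (both strands), and a
label-permutation null in which per-sample hotspot sets stay fixed and
only group labels move; the empirical p uses the +1 correction,
$(1 + \#\{null \ge obs\}) / (n_{perm} + 1)$, so 100 permutations can
never report p = 0.

**Enrichment.** Three odds-ratio procedures, all observed/expected:

1. *Pairwise overlap* (replica reproducibility, APE1 vs Endo IV):
   expected = |A| divided by the stranded genome size, observed =
   |A ∩ B| / |B|, computed on the full genome including repeats. Since
   site identity is stranded, the position space is 2 × genome length;
   the published description does not fix single- vs double-stranded
   counting, and this choice is the one consistent with stranded site
   identity (it only rescales this mode).
2. *Repeat classes*: read-weighted — sites with the same coordinates
   count separately; expected = merged class length / genome length.
3. *Genomic elements and variants*: repeat-masked and
   coordinate-collapsed — sites in repeats are removed and duplicates
   count once; expected fractions use non-repeat lengths; significance
   from the exact two-sided binomial test (`stats::binom.test`), which
   needs no variant choice and is exactly reproducible.

Sites overlapping two element classes count in both: each class is an
independent comparison. Template/nontemplate ratios call a site on the
strand opposite a gene's annotation strand "template"; expression strata
split genes at TPM ≤ 1, 1 < TPM ≤ 10, TPM > 10, with per-strand density
defined as distinct sites per element bp (the published figures do not
print a density definition; per-bp is scale-free across strata).
TpC-context variant enrichment keeps heterozygous SNPs whose allele reads
C with a 5' T *on its own strand* — a minus-strand variant uses the
reverse-complement context, the orientation in which cytidine deaminases
act. Technical bias against an unblocked control is the squared Pearson
correlation of depths over the sample's positions (0 where the control
lacks a call). Mitochondrial strand asymmetry reports read-weighted
heavy (−) and light (+) strand fractions outside an excluded window
(default 15,650–15,900, the D-loop hotspot region) and their fold.

## The simulator: what it emulates, and what it does not

`sim_genome()` builds random chromosomes with configurable GC, a merged
repeat mask covering a target fraction, non-overlapping three-exon genes,
TSS ± 1 kb flanks, promoter/enhancer-like element classes and a TPM table
spanning the three strata. `plant_sites()` draws stranded positions with
per-nucleotide weights (default A 0.39, G 0.31, C 0.15, T 0.15 — the
purine bias reported for mammalian AP sites), hotspot positions with a
depth range, an optional template-strand weighting inside expressed
genes, and per-class enrichment multipliers. A requested multiplier *m*
is converted to the raw weight $m(W - W_e)/(W - mW_e)$ so that the
*measured* odds ratio recovers *m* after renormalisation — the multiplier
is a target odds ratio, not a raw weight.

`simulate_reads()` emits, per molecule, read 2 as a sampled T-run plus
the reverse complement of the damaged strand starting at the terminus,
and read 1 as the tag plus genomic sequence placed randomly within a
fixed 400 bp fragment (read 1's genomic portion is analytically inert —
it exists so deduplication sees distinct molecules — hence a fixed
fragment model rather than a fragmentation-size model). Unblocked
background reads start at random fragment ends at a default rate of 1.5%
(the reported backgrounds are 1–2%), and PCR duplicates are exact
re-emissions at a flat rate.

Two generator choices deserve emphasis because they encode a real
information-theoretic limit of the chemistry:

* A lesion whose damaged-strand 5' neighbour is adenine yields a read
  whose first genomic base is thymine; the trimmer must absorb it into
  the T-run and the call shifts by one. No algorithm can avoid this —
  it is the ±1-nt blur seen in spike-in profiles. The genomic planter
  therefore draws only *callable* positions (neighbour not absorbing,
  upstream window below the polyA threshold), so that ground truth is
  exactly recoverable and every discrepancy flags a pipeline defect
  rather than a modelling artifact. What passing tests then show is that
  the pipeline is exact *on callable sites*; they deliberately do not
  quantify the blur on ambiguous contexts.
* Default spike sequences are generated without AA, AT or TT
  dinucleotides and without lesions in the 20 bases nearest the
  read-side end, so every planted thymine lesion is single-base
  localisable and unblocked termini (modelled as uniformly ragged over
  the 3 bases before each strand's 3' terminus) always land inside the
  published 4-base background window. This mirrors how one designs
  spike-in controls: ambiguous contexts are avoided at design time.

The simulator does not model sequencing errors, base qualities, indels,
non-uniform PCR bias, chimeras or aligner heuristics; real libraries will
show losses and blurs the synthetic tests cannot exhibit. Conclusions
about real data should lean on the spike-in QC, not on the simulator.

## Numerical and degenerate-input conventions

Zero denominators (APF with no tag pairs, background with no spike
reads, strand fold with no light-strand reads, r² with a constant
vector) return NA rather than raising. Depth aggregation requires depth
≥ 1 and unique stranded positions. The spike hotspot operator uses
strict inequalities on both the threshold and the neighbours, so
plateaus produce no hotspot. Weighted sampling without replacement uses
exponential races (deterministic under the seed, linear in candidates).
Genes without a TPM fall into the nonexpressed stratum with a warning.

## Problem sizes

The test-suite fixtures use 2 × 50 kb genomes with 1,500–2,000 read
pairs; parameter-recovery checks use 2 × 100 kb with 10,000 reads; the
spike analyses use three 300–500 bp spikes with up to 50,000 read pairs;
the permutation analyses use 12 samples in 4 groups with 100
permutations. These sizes keep every run in the reads-much-smaller-than-
position-space regime that genome-scale data occupies — at a desk-scale
genome, inflating read counts makes uniform random placement collide by
chance and would blur the real-versus-random hotspot contrast that the
method relies on.

## Known limitations

* The exact aligner accepts only perfect matches; it is a stand-in for a
  production aligner on synthetic genomes, not a general-purpose tool.
* Lesions in tag-absorbing or polyA-adjacent contexts are invisible to
  the method (and excluded from simulation ground truth); genome-wide
  lesion totals are therefore lower bounds.
* The negative-spike spontaneous depurination rate is not published; the
  default (0.1 × the positive uracil rate, which itself defaults to
  1/126 per thymine from the 1:125 dUTP:dTTP ratio) reproduces the
  qualitative positive/negative contrast without asserting an unprinted
  number.
* No multiple-testing correction is applied across enrichment classes;
  p-values are reported raw, matching the published analysis scope.
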