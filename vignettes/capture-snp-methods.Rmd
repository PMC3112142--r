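---
title: "Methods: targeted-capture SNP calling and tumor-normal comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: targeted-capture SNP calling and tumor-normal comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(captureSNP)
```

## The analysis model

`captureSNP` models the classic targeted-enrichment resequencing design:
exonic regions of a gene panel are tiled with 50-mer capture probes,
genomic DNA from matched tumor and blood-leukocyte samples is enriched by
hybridization, and 50 bp paired-end reads are sequenced to several hundred
fold depth over the panel. The pipeline stages, each an exported function,
are:

1. **Read QC** (`filter_ambiguous`): a pair is removed when either mate has
   three or more ambiguous (`N`) base calls. The whole pair is dropped
   because all downstream logic is pair-based; the two surviving mates each
   carry at most two `N`.
2. **Mapping** (`map_reads`): ungapped placement on both strands with a
   Hamming budget of 3 mismatches; an `N` mismatches every reference base.
   A read is kept only when a single placement attains the minimal distance;
   a tie at the minimum makes it a discarded multi-mapper. A stricter mode
   (any second placement within budget) is available via `strict = TRUE`.
3. **Pair acceptance** (`accept_pairs`): opposite strands, inward FR
   orientation, and an outer fragment length — leftmost read start to
   rightmost mate end inclusive — within [100, 500] bp, bounds inclusive.
4. **Coverage** (`compute_depth`, `summarize_coverage`, `enrichment_fold`):
   per-target-base unique-read depth; mean fold defined as read bases over
   target size (the definition that reproduces the fold figure of the
   motivating experiment scale: 3.1e6 reads × 50 bp / 504 kb → 308); the
   observed mean of per-base depths is exported alongside. Enrichment fold
   is the on-target read fraction over the target's genome fraction.
5. **Pileup and calling** (`build_pileup`, `call_genotypes`): per-position
   allele counts split by alignment strand; genotype from the top two
   alleles with a minor-fraction threshold (below).
6. **Depth tiers** (`confidence_filter`): depth < 10 removed, depth > 50
   high confidence, 10–50 inclusive low confidence. The wording of the
   source thresholds ("higher than 50", "smaller than 10") is read
   literally, so both boundaries are strict.
7. **Tumor-normal comparison** (`compare_tumor_normal`): differences of
   unordered allele pairs at sites with depth > 50 in both tissues.
8. **Set statistics and annotation** (`pairwise_overlap`, `venn_counts`,
   `annotate_known`, `gene_summary`, `encode_haplotype`,
   `cohort_genotype_freq`).

## Calibrating the genotype caller

The caller is a threshold reconstruction, not a probabilistic model: the
commercial caller used in the motivating study is a black box, but its
printed strand-split counts and genotype calls constrain the decision
boundary. Among the fourteen published tumor/leukocyte rows, the smallest
minor-allele fraction called heterozygous is 0.254 and the largest called
homozygous is 0.172, so any threshold in the open interval (0.172, 0.254)
reproduces all fourteen calls. The default `het_min_fraction = 0.20` sits
near the middle of that window and is exposed as a parameter; the test
suite pins the window so a threshold change that breaks the reproduction
fails loudly.

Two further choices follow from the same table. There is **no
strand-balance filter**: one published heterozygous call has all of its
minor-allele support on a single strand, so one-strand support must be
admissible. And calls are **invariant under swapping forward and reverse
counts** (a tested property), which also makes the unstated strand order of
`fwd;rev` entries irrelevant. Two published rows have printed coverages one
read larger than the sum of their printed counts; ingestion recomputes
depth from the counts and flags the discrepancy rather than guessing the
missing base. Columns whose third-ranked allele also clears the
heterozygosity threshold are called from the top two alleles with a
warning; deep data did not produce such columns.

A normal-het/tumor-hom difference is deliberately labelled `loh_or_hom`,
never "somatic mutation": read counts cannot separate loss of
heterozygosity from homozygosity or hemizygosity without copy-number
information.

## The synthetic-data generator

The simulator emulates the capture experiment with known ground truth so
that recovery can be measured exactly. Its defaults are fixed once:

| parameter | default | rationale |
|---|---|---|
| read length | 50 bp | geometry of the emulated platform |
| fragment length | uniform 100–500 bp | the accepted outer-fragment window |
| reference / targets | 500 kb, 24 genes × 8 exons, 10% target fraction | a panel-sized footprint that keeps simulation tractable |
| probe tiling | 50-mers, step 11, ≥ 20 probes/exon, alternating strand | the emulated array design; small exons are tiled more densely |
| snp_density | 2 / kb target | of the order of human heterozygosity, enriched for an exonic panel |
| het_fraction | 0.65 | roughly two heterozygous sites per homozygous-alternate site |
| loh_fraction | 0.30 | glioblastomas lose chromosomal material frequently; the retained allele is uniform, so some events revert to homozygous reference |
| error_rate | 0.005 | early short-read per-base substitution scale |
| n_artifact_rate | 0.01 | reads corrupted with three `N` calls, exercising QC |
| off_target_fraction | 0.10 | fragments drawn strictly outside targets |
| decoy_duplications | 2 | target segments copied elsewhere, creating multi-mappers |

Fragments are anchored on target bases (except the off-target share, which
is rejection-sampled to be disjoint from targets), assigned one of the two
haplotypes uniformly, and read from both ends in FR orientation. All
randomness flows from one seeded stream per stage with a documented draw
order, so a configuration is byte-reproducible; per-stage child seeds are
derived from the master seed and stay within 32-bit integer range.

What the simulator does **not** model: indels and structural variants, copy
number, GC and mappability bias, base-quality decay along the read,
duplicate reads, chimeric fragments. Passing recovery tests therefore show
the pipeline's thresholds and bookkeeping are correct under ideal
substitution-only noise; they do not certify performance on real
libraries, where alignment artifacts and coverage bias dominate.

## Mapping: seed-accelerated, exhaustively equivalent

The mapper guarantees exact equivalence with a brute-force Hamming scan of
every offset on both strands. A read is split into `max_mismatch + 1`
non-overlapping chunks; any placement within budget must contain at least
one exact chunk (pigeonhole), and all exact chunk matches are enumerated
through a 12-mer index of the reference. Reads shorter than 48 bp (chunks
shorter than the index k-mer) fall back to a full scan in compiled code.
The equivalence is property-tested against an independent R oracle on
randomized references.

## Numerical and convention choices

* Coordinates: pileups and variants are 1-based (VCF convention); intervals
  are 0-based half-open (BED); alignments carry 0-based leftmost positions.
* Rounding is half away from zero at the precision of the published
  tables: fold values to integers, percentages to one decimal (overlap,
  gene summary) or whole percent (cohort frequencies, target coverage).
* Overlap percentages use the union of the two sets as denominator — the
  only denominator consistent with all six published comparisons.
* Variant identity is the allele-aware key `(chrom, pos, alt)` with the
  better-supported alternate first; known/novel annotation matches on that
  key by default, with position-only matching as an option, since the
  matching granularity of public catalogues varies.
* Genotypes are unordered allele pairs; no phasing is attempted anywhere.
  Haplotype encoding consequently emits `unphased` as soon as any site of
  the definition is heterozygous.
* Degenerate inputs: zero-depth pileup columns are no-calls (an error if
  passed to the caller), an empty accepted-alignment set yields an all-zero
  depth track and a header-only VCF, and an empty target list yields an
  empty probe design.

## Benchmark problem sizes

The recovery benchmarks simulate a 300 kb reference with 15 genes × 6 exons
(about 45 kb of targets), 12 planted variants per target kilobase (~540
sites), and 80,000 read pairs per sample — a median planted-site depth
above 100×, so essentially all sites sit in the high-confidence tier. Unit
tests use a 60 kb / 2,000-pair configuration. These sizes are the package's
benchmark design: large enough for stable rates (binomial 99% intervals are
used wherever a rate is asserted), small enough to rebuild from scratch in
every run.

## Known limitations

* The caller is a calibrated threshold reconstruction; it reports no
  genotype likelihoods and no quality scores.
* Indels are out of scope end to end (simulation, mapping, calling).
* Multi-mapper handling resolves ties by discarding; no rescue by pairing
  information is attempted.
* The tumor-normal comparison is per-site and descriptive; it performs no
  statistical test and no segmentation of contiguous LOH tracts.
* `read_sam` ingests external alignments but trusts their mapping-quality
  and flag conventions (MAPQ 0 or secondary/supplementary → multi-mapper).
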