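---
title: "Methods and design of isoatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of isoatlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`isoatlas` augments a reference gene annotation with transcript models
assembled from long-read sequencing across developmental stages and
validates the novel models by orthogonal evidence. This vignette
explains the models and procedures, the tunable parameters, what the
synthetic-data generator does and does not emulate, and the numerical
and design choices made where conventions were open.

## Coordinate model

All coordinates inside the package are 0-based half-open; GTF (1-based
closed) converts at the I/O boundary with `start_internal = start_gtf −
1`, `end_internal = end_gtf`, an exact bijection. Transcripts must be
stranded (`+`/`−`): strand determines the TSS (5′ end), splice-motif
orientation and the 5′/3′ assignment of alternative-splicing types, so
unstranded models are rejected at parse time rather than silently
mis-analysed. The TSS of a `+` transcript is its first exon start; of a
`−` transcript, its last exon end − 1.

## Transcript classification

A query transcript receives the first matching class code in priority
order `=` > `c` > `j` > `e` > other > `u`:

* `=`: identical ordered intron chain with some same-strand reference
  transcript; terminal exon ends are free. Mono-exon transcripts have
  no chain, so equality is defined as ≥ 50% reciprocal span overlap
  with a mono-exon reference — a common convention where the choice is
  otherwise tool-defined; the threshold is the `mono_reciprocal`
  argument.
* `c`: the query chain is a *contiguous* sub-chain of a reference chain
  and the query span lies inside the reference span (mono-exon: the
  query lies inside one reference exon).
* `j`: at least one shared splice junction with a same-strand
  reference; this captures both novel junctions and novel combinations
  of known junctions.
* `e`: exonic overlap plus ≥ `min_intron_overlap` (default 10) bases
  extending into a reference intron without splicing there — a retained
  or mis-bounded fragment.
* other: same-strand exonic overlap not qualifying above
  (unclassified), opposite-strand exonic overlap (antisense), or full
  containment in a reference intron (intronic). These are excluded from
  the annotated/novel sets downstream.
* `u`: no reference overlap on either strand — a potentially novel
  gene.

The best reference is the transcript triggering the rule; ties break by
shared-junction count, then exonic-overlap bases, then lexicographic id,
making the result deterministic. `{=, c}` is the annotated set,
`{j, e, u}` the novel set.

Merging collapses multi-exon transcripts with identical (chrom, strand,
chain) to one model carrying the extreme observed 5′/3′ ends, and
mono-exon transcripts by same-strand overlap into their union span;
loci (`XLOC_…` gene ids) are same-strand span-overlap clusters. Merging
is idempotent.

The saturation analysis permutes the stage order (default 100
repetitions), merges cumulatively, and counts merged transcripts with
novel codes at each step; the confidence band is the empirical
percentile interval (0.5%/99.5% for the default 99% level) — the
interval construction was an open choice and the empirical percentile
is the least parametric. Because the count after a step depends only on
the *set* of stages merged so far, the implementation memoises counts
per subset; results are identical to the naive loop.

## Biotype, ORFs, homology, tiers

Novel transcripts are classified from a consumed coding-potential score
in [0, 1]: protein coding above the 0.44 cutoff, lncRNA at or below it
with spliced length > 200 bp, else otherwise. "Spliced length" (sum of
exon lengths) is used for the 200-bp rule since the scoring model
consumes the spliced sequence. Scores are inputs, not computed — the
contribution here is the classification rule, not the scoring model.

`find_orfs()` scans the three forward frames of the sense-strand spliced
sequence for ATG-initiated, stop-terminated ORFs of ≥ 300 bp (the stop
codon counts toward the length). Reverse frames are not scanned because
transcripts are sense-stranded by construction. Whether 3′-incomplete
ORFs should count is ambiguous; they are excluded by default and
available via `allow_incomplete = TRUE`. Homology calls are significant
per source iff log10(e-value) < −5, strictly; classes are both /
blast_only / pfam_only / none. Expression tiers: not detected (TPM ≤ 1),
expressed (1 < TPM ≤ 10), high (TPM > 10).

## Conservation

Conservation is computed over the spliced exonic sequence (concatenated
exons), since the transcript is the unit of interest; control regions
are unspliced intergenic intervals of matching total length. The
intergenic space is the complement of annotated transcript spans — in
the pipeline, of the *augmented* annotation, so that the novel
transcripts being scored never contaminate their own controls. One
control per transcript is placed by weighting every feasible start
position across all gaps equally, which realises the same uniform
placement a rejection sampler targets but deterministically and without
a retry bound; an error is raised only when no gap can host the length.

Cutoffs are calibrated as the 95th percentile (linear-interpolation
empirical quantile, R type 7 — stated so results are exactly
reproducible) of: all per-base phyloP-style values pooled over controls
(base cutoff), then the per-control conserved-base fractions and
maximal 200-bp window means computed with that base cutoff. Pooling
bases (rather than per-region maxima) for the base-level percentile was
an open reading and is the implemented one. Regions shorter than the
window use their whole-region mean. Applying the cutoffs back to the
controls flags ≈ 5% per criterion by construction, which the tests
check within binomial bounds.

`rank_sum_test()` enumerates all group assignments with mid-rank ties
when the pooled size is ≤ 16 (two-sided p = twice the smaller tail of
the U statistic, capped at 1) and otherwise uses the normal
approximation with tie and continuity correction — matching the exact
null distribution where enumeration is feasible and the standard
large-sample form elsewhere.

## TSS validation

Annotated TSS intervals are ±300 bp around each reference transcript's
TSS (per transcript, not per gene; same strand required). Novel-gene
TSSs are their own group; novel-isoform TSSs inside an annotated
interval are classic, the rest novel; exact matches serve as the
annotated comparison group.

Promoter metaprofiles cover ±4 kb in 161 bins of 100 bp at 50-bp steps.
A naive tiling of 8 kb yields 159 interior bins; to honour the stated
161, bins start at `tss − 4050` so the 81st bin is centred on the TSS.
The geometry is configurable. Bins are ordered 5′→3′ (minus-strand
profiles reversed); bases beyond chromosome ends contribute the track
default (0), mirroring the treatment of uncovered bases as zeros when
averaging over a fixed denominator. A TSS is high-confidence iff the
union of the supplied peak sets intersects its ±500-bp window; CAGE
support intersects the union of nonzero-signal intervals with the same
window.

## Alternative splicing

Seven local event types are enumerated from pairwise isoform
comparison within a gene: SE (an exon with both flanking junctions in
one isoform, removed by the single spanning junction in another), A5/A3
(two introns sharing exactly one boundary whose alternative-boundary
exons overlap; the 5′/3′ side is strand-aware, and the inclusion form
is the shorter intron, i.e. the longer exonic form), RI (an intron of
one isoform fully exonic in another with exactly matching outer exon
boundaries; retention is the inclusion form), MX (two consecutive
intron pairs sharing outer boundaries whose middle exons are disjoint;
the 5′-proximal exon is the inclusion form), AF/AL (non-overlapping
alternative terminal exons with distinct TSS/TES sharing their inner
junction boundary; the distal side is the inclusion form). Requiring
exon overlap for A5/A3 and non-overlap plus terminal position for
AF/AL makes the types mutually exclusive — the hand-built seven-gene
fixture yields exactly one event per type with zero cross-type calls.
Event identity is (type, chrom, strand, coordinate tuple); duplicates
collapse, and inclusion/exclusion isoform sets are collected over all
isoforms of the gene. Merged-annotation events are recomputed on the
merged transcript set rather than unioned per stage.

PSI is Σ TPM(inclusion) / (Σ TPM(inclusion) + Σ TPM(exclusion)),
undefined (NA) when the denominator is zero; it is invariant under
uniform TPM scaling. Differential splicing compares mean replicate PSI
between conditions (ΔPSI) with a two-sided label-permutation p-value on
the difference of means. All label arrangements are enumerated exactly
when their number is at most 5000 — which covers the 5-vs-5 design
(252 arrangements) used for calibration — and Monte-Carlo sampling with
an add-one estimator is used beyond that; enumeration wherever feasible
gives exact, deterministic p-values at negligible cost. With only two
replicates per condition the smallest attainable two-sided exact p is
1/3, so no event can reach p < 0.05: differential-splicing analyses
need ≥ 5 replicates per condition, and the recovery tests simulate
five. Classes: up (ΔPSI > 0, p < 0.05), down (ΔPSI < 0, p < 0.05),
none; events with no defined PSI in a condition are skipped with an NA
class.

Junction motifs are the first and last two intron bases read on the
sense strand (reverse-complemented for minus-strand transcripts);
GT..AG is canonical. A junction is high-confidence when ≥ 10 short
reads support it in at least one sample; junctions absent from the
support table count as unsupported.

## Expression dynamics

ZGA: a feature is a ZGA transcript/gene when its oocyte value is ≤ 1,
its 1-cell and 2-cell values exceed 1, and the 2-cell value is more
than twice the 1-cell value. "Expressed" is read as value > 1,
symmetric with the ≤ 1 off rule. Replicates are averaged per stage
before the clauses are applied — per-replicate thresholding was the
alternative reading; averaging is less sensitive to single-replicate
noise. Splicing-factor coupling uses plain Pearson correlation between
per-stage factor expression and per-stage AS-event totals (≥ 3 paired
stages; zero-variance vectors yield NA). Row z-scores are (x − mean)/sd
with zero rows for zero-sd features. The quantification-change flag
compares per-stage mapped-read counts under two annotation references;
the change measure δ was left undefined by convention, so both a ratio
form max(a+1, b+1)/min(a+1, b+1) (default; the +1 guards empty counts)
and an absolute-difference form are provided, flagging transcripts with
δ > 5 in at least one stage.

## The synthetic-data generator

The generator emulates, on a three-chromosome 900-kb toy genome, the
features the analyses consume: two dozen multi-isoform genes (5–8 exons
of 120–360 bp, introns 400–1500 bp, 1–3 isoforms built as single-exon
skips of a skeleton), a candidate pool containing planted members of
all five categories (trimmed exact copies; interior-exon contained
models; double-skip, retained-intron, shifted-donor and
alternative-first-exon novel isoforms; mono- and multi-exon novel genes
in dedicated intergenic slots; antisense and intronic "other" models),
seven stage sets realising the category mixture 60/10/20/7/3 exactly by
largest-remainder apportionment with a 0.7 share fraction between
consecutive stages, splice-site motifs written into the genome per
distinct junction (canonical with probability 0.97, otherwise GC..AG or
AT..AC subject to shared-site consistency; a junction forced canonical
by a shared site is recorded as canonical in the truth), bimodal
H3K4me3 bumps with peaks at marked TSSs, CAGE runs at a marked subset,
genome-wide conservation background (phyloP-style N(0, 0.3); phastCons-
style ≈ 0.1) with elevation (N(1.5, 0.2); ≈ 0.9) over the exons of
planted conserved candidates, log-normal TPM noise (σ_log = 0.15)
around planted stage means, and a junction support table giving every
junction ≥ 10 reads in one sample unless planted unsupported (5%).

Planted expression patterns keep wide margins around the ZGA
thresholds (off ≈ 0.05, on ≥ 3, ZGA profile 0.05/8/40), so threshold
recovery is exact by construction rather than luck. Differential-
splicing genes express only their inclusion/exclusion pair (other
isoforms of the gene drop to ≈ 0) so the planted PSI of 0.25 shifting
by ±0.4 at the 1-cell→2-cell boundary is not diluted by unrelated
isoforms entering the event's isoform sets. Conserved labels are
planted only on non-coding novel-gene candidates: novel genes occupy
disjoint intergenic slots, so elevated conservation signal never bleeds
into the exons of other scored transcripts — planting it on novel
isoforms would contaminate same-gene negatives and turn specificity
into a property of gene structure rather than of the method. High-
confidence-TSS and CAGE truth flags are *realised* after track
construction: any TSS within ±500 bp of an emitted peak or nonzero CAGE
run is flagged, so incidental neighbours are part of the truth and
recovery can be exact. Two replicates per stage mirror the two sample
batches of the emulated study design; differential-splicing
calibrations use a five-replicate configuration.

Everything is deterministic under (seed, config); each generation stage
draws from `seed + fixed offset`. What the generator does **not**
emulate: read-level noise (no FASTQ, sequencing error, or polyA-capture
bias), fragmentary or mis-assembled transcript models, genes sharing
loci or overlapping on the same strand, expression-dependent assembly
dropout, and realistic conservation autocorrelation beyond 100-bp
blocks. Passing the recovery tests therefore demonstrates correctness
of the analysis logic under clean inputs, not robustness to upstream
assembly artefacts.

## Problem sizes and runtime

The test-suite and acceptance runs use the default conditions: 24 genes
(50 reference isoforms) on 3 × 300 kb, 60 transcripts per stage across
7 stages (118 distinct candidates present), ~200 distinct junctions,
100-repetition saturation, 2000 null plus 300 shifted events for the
differential-splicing calibration at 5 replicates, and one control
region per scored non-coding novel transcript. These sizes were chosen
so every planted feature class is represented with enough members for
binomial checks while a full suite run stays in the low minutes on one
CPU.

## Known limitations

* Mono-exon classification conventions (the 50% reciprocal rule, the
  containment-in-exon rule) are defensible but not canonical; borderline
  fragments may classify differently than under other tools.
* The permutation test is coarse at low replicate counts by
  construction; with two replicates it cannot reach significance.
* AS event membership is junction-pattern based and may include
  isoforms that carry the defining junctions embedded in a larger
  structure.
* Conservation calibration assumes enough intergenic space and enough
  controls for a stable 95th percentile; with very few scored
  transcripts the cutoffs inherit their sampling noise.
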