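---
title: "Methods: isoform annotation from long-read amplicons with isoamp"
author: "isoamp maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isoform annotation from long-read amplicons with isoamp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Long-range RT-PCR of one gene followed by nanopore sequencing yields
full-length cDNA reads that each span an entire transcript, so a single
read carries a complete exon chain. This solves the isoform-deconvolution
problem that defeats short reads, but introduces two new ones: nanopore
errors are indel-dominant and concentrate damage precisely where exon
boundaries must be read precisely, and a single locus can express dozens
of isoforms differing by a handful of nucleotides. `isoamp` implements an
annotation-and-quantification pipeline for this assay: it discovers
unannotated exons, repairs splice-junction breakpoints against a
data-derived catalogue of canonical junctions, collapses reads into a
unique isoform set at two resolutions (exon level and splice-site level),
quantifies isoforms with multi-compatibility down-weighting and TMM
normalisation, and predicts each isoform's coding impact.

# The metagene

All exon-level analysis happens against a *metagene*: the concatenation of
every distinct annotated exon of the locus, in transcription order
(minus-strand genes are reverse complemented exon-wise). Reads align to
the metagene without intron gaps; a skipped exon appears as a target gap,
a novel exon as a read insertion. Internally all coordinates are 0-based
half-open; GTF import/export converts to and from 1-based inclusive.
Annotated exons with overlapping-but-different boundaries are kept as
distinct exon records and concatenated as distinct units: the union of
distinct intervals is the most conservative reading of "concatenation of
all exons", and each read's alignment disambiguates which variant it
uses. After novel exons are accepted they are spliced into the metagene in
transcription order and every read is realigned against the augmented
metagene (a faster `"carriers"` mode realigns only reads with a mined
junction insertion and coordinate-lifts the rest, at the cost of missing
novel-exon copies whose insertion escaped mining).

# The built-in spliced aligner

Production users can supply alignments from any spliced aligner (SAM/BAM,
BLAT PSL, LAST MAF are ingested losslessly). For self-contained operation
the package ships a banded Gotoh aligner (C++ via Rcpp) with a two-piece
target-gap cost:

* match +2, mismatch −4;
* read insertions: affine, open 6, extend 3;
* short target deletions (sequencing errors): affine, open 6, extend 3,
  reported as CIGAR `D`;
* long target gaps (skipped exons): open 18, extend 0.2, reported as `N`.

The two-piece gap makes skipping an absent 9-nt exon (cost ≈ 19.8) cheaper
than forcing random sequence through it (expected score ≈ −22), while a
1-nt error deletion costs 9 — less than two mismatches — so small errors do
not masquerade as skips. The alignment is semi-global (the read aligned end
to end, free target overhangs) inside a parallelogram band whose width is
`|target − read| + 2 × band_slack` (default slack 150 nt, which must exceed
the longest expected novel-exon insertion). Tie-breaking in the traceback
is fixed (diagonal, then read-gap, then short, then long target gap), so
output is deterministic. Because gap placement inside short sequence
repeats is an arbitrary tie-break, target-gap runs are normalised after
alignment: each gap slides within its sequence-equivalent range so its
endpoints land on exon boundaries where possible (leftmost otherwise) —
without this a whole-exon skip can systematically straddle a boundary by
one base and corrupt downstream junction analysis. The aligner is
intended for single-locus
references of a few kilobases; genome-scale alignment is out of scope.

# Novel exon discovery

Reads are first filtered: mean read q-score ≥ 9 where qualities are
available, uniquely best alignment to the target gene (score ties with any
other target discard the read), and at least 50% of the read aligned.
Insertions are then mined from the CIGARs: all insertion runs of ≥ 3 nt
whose target position lies within ±6 nt of the same exon–exon boundary are
pooled into one event (long novel-exon insertions are routinely fragmented
by spurious micro-matches; runs separated by micro-matches of up to 10
target nt are chained), and an event is kept when the pooled length
reaches 9 nt. Each event's inserted sequence is locally aligned against
the intron between its flanking exons and placed when identity and insert
coverage both reach 80%. Placements are snapped to the nearest canonical
intronic flanks (`AG` immediately upstream, `GT` immediately downstream,
within ±6 nt), merged when intervals overlap reciprocally by ≥ 50% (the
merged interval is the support-weighted modal boundary pair), and accepted
when (a) the candidate is ≥ 6 nt from every existing exon, (b) it was seen
in ≥ 2 individuals or ≥ 2 tissues, and (c) every contributing library has
≥ 5 supporting reads. If two accepted candidates still overlap — truncated
insert spans occasionally survive as sub-intervals — only the
better-supported one is kept.

# Splice-site-level analysis

Exon-level chains are insensitive to variation of a few codons inside an
exon, so a second analysis works on junction chains in genome space.
Metagene alignments are projected to the genome (introns become `N` gaps;
for minus-strand genes the record is emitted genome-forward).

**Catalogue.** A junction enters the catalogue when a read maps with zero
mismatches and zero read-side indels for 8 nt on both sides of the gap and
the intron is GT–AG on the transcribed strand (GC–AG/AT–AC can be enabled).
Two details matter at nanopore error rates:

* *Gap merging.* Target-side deletions flush against an intron are merged
  into the gap — in a genome alignment a deletion touching an intron is
  indistinguishable from a slightly longer intron, so the merged gap is
  the only well-defined breakpoint pair. Aligned islands shorter than 8 nt
  strictly between gap ops are treated as alignment noise and absorbed
  (no real exon is that small; accepted novel microexons are ≥ 9 nt).
* *Noise pruning.* Because merged gaps admit target-side deletions, a
  sequencing deletion flush to a real intron can manufacture a "perfect"
  junction shifted by the deletion length whenever the shifted intron
  happens to end on a canonical motif. Per-read this is genuinely
  indistinguishable from a small splice variant; the catalogue therefore
  applies two statistical screens. First, site resolution: a novel
  donor/acceptor within 2 nt of a better-supported site of the same side
  is collapsed away — sub-codon breakpoint resolution is not achievable at
  percent-level indel rates, and real variants of biological interest in
  this assay differ by at least one codon (3 nt), which the 2 nt radius
  keeps distinct. Second, an error-echo rule: a novel junction
  sharing one endpoint with a junction ≥ 20× better supported, with its
  other endpoint within 15 nt, is dropped; genuine shift variants at a few
  percent of their parent junction's abundance pass this screen, while
  echoes at the per-base error rate do not (a variant below ~5% of its
  parent is at the edge of detectability under this rule, a consequence
  of percent-level deletion rates rather than a tunable choice). A global floor of 3 perfect
  reads applies. All screens spare annotated junctions and are
  configurable.

**Correction.** Every read gap's endpoints snap to the nearest catalogued
donor/acceptor within 15 nt (ties: higher support, then the upstream
site). The 15 nt default mirrors the observed scale of small splice-site
differences in this assay class. Gaps with no site in range keep raw
breakpoints and are flagged. Reads already on catalogued sites are
unchanged. Identical corrected junction chains collapse to junction-level
transcript models, filtered at ≥ 24 reads; per-site support is reported
with a ≥ 10 read flag; each junction model is annotated as identical to,
a small-scale (≤ 15 nt) variant of, or distinct from the exon-level
models.

# Exon-level isoform calling

A read's chain contains every exon whose length is covered ≥ 50% by
aligned blocks. Chains observed with complete ends (first and last
metagene exon present) found models; identical chains collapse. "Longest
possible variants" is formalised as end-truncation absorption: an
incomplete chain that is a contiguous sub-chain of exactly one model adds
its support to that model; internal splicing differences never merge. An
incomplete chain contained in several models is held aside as ambiguous
(its reads enter quantification down-weighted); full-length amplicons
make truncations artefactual, so truncated chains never found models.
Models supported by one read are dropped; the filtered set requires ≥ 24
reads across ≥ 2 libraries, the high-confidence set ≥ 100 reads. These
thresholds count raw reads before down-weighting, and libraries sequenced
in several runs are kept as separate run-tagged libraries by default.
Models whose chain equals an annotation chain keep the annotation id;
novel models are named `<gene> n<k>` by descending support (ties:
lexicographic chain order), so naming is deterministic.

# Quantification

A read is compatible with a model if its chain is identical (complete
reads) or a contiguous sub-chain (incomplete reads). A read compatible
with k models contributes 1/k to each, so raw column sums equal assigned
reads exactly. Between-library normalisation uses the published trimmed
mean of M-values procedure (reference library = upper-quartile/total ratio
closest to the mean; per-transcript log-ratios M and average abundances A
over transcripts nonzero in both libraries; 30% trim on M, 5% on A;
precision-weighted mean; factors rescaled to geometric mean 1) via
`edgeR::calcNormFactors`; the test suite verifies the factors against an
independent direct-formula implementation to 1e-8. Normalised values are
`count / (library size × factor)`. Sequencing-depth differences between
libraries can additionally be removed by downsampling every library to
the smallest depth (seeded, without replacement) and re-quantifying. The
log10 transform uses pseudocount 1 (counts are integers or simple
fractions; zeros stay zero). Exported tables include per-library
proportions; a proportion × 1e6 column is available where a TPM-like
scale is wanted — length normalisation is deliberately omitted because
all models are near-full-length amplicons of one gene.

# Coding impact

Each model's CDS is spliced between the annotated genomic CDS anchors;
models missing an anchor exon are reported as `incomplete_ends`. The frame
is maintained iff the length difference to the reference CDS is a multiple
of 3; a premature stop is an in-frame stop strictly before the final 3
codons (NMD is not modelled); `putative_coding` requires both. Indel
events come from a global alignment against the reference CDS and are
reported in 1-based reference protein coordinates (a 12-nt deletion is a
4-aa event); where the flanking sequence makes the gap placement
ambiguous the alignment picks one equivalent placement, so coordinates
are exact up to that intrinsic ambiguity. Events are labelled with any
user-supplied protein regions (a synthetic example table for a
voltage-gated calcium-channel alpha-1 subunit ships in `extdata`; region
calls do not alter the coding classification, they only flag events for
inspection).

# The simulator

`sim_config()` defaults define the study conditions used throughout the
tests: a plus-strand gene of 12 annotated exons (60–250 nt, the per-exon
scale of a large channel gene; half the internal exons frame-neutral),
introns of 300–800 nt, a stop-free CDS spanning the whole amplicon; 3
planted intronic novel exons (9–120 nt, ≥ 20 nt from annotated exons,
with AG/GT flanks); junction-shift deletions of 9/12/15 nt (the
3/4/5-amino-acid microdeletion case, acceptor-side, with AG engineered at
the shifted boundary) plus one 4-nt frame-shifting deletion; 10 isoforms
(reference, the three microdeletions, the frameshift, three novel-exon
inclusions, one in-frame and one frame-shifting skip); 6 libraries = 3
individuals × 2 tissues at 3000 reads; per-base error rates sub 0.03 /
ins 0.03 / del 0.04 (≈ 10% total, deletion-biased as in nanopore data)
plus, per junction per read, a 0.15 chance of one extra 1–6 nt indel
within ±10 nt of the junction; and a cerebellum-style isoform switch (the
top novel isoform near-equal to the reference in cerebellum, 5:1
elsewhere). Reads are drawn multinomially so column sums equal library
depths exactly; per-read q-scores are Phred-consistent with the realised
error count. Intended-coding isoforms are guaranteed premature-stop-free
by redrawing the locus, so coding truth is exact by construction.

The generator emulates the features the pipeline must survive —
full-length chains, indel-dominant noise concentrated at junctions,
sub-exon splice variants, library structure — and deliberately not
others: no PCR chimeras, no basecaller-specific error profiles, no
RNA-degradation length bias, no barcode misassignment. Passing the
simulation-based checks therefore demonstrates the pipeline logic, not
performance on any particular chemistry.

Quantification recovery is evaluated against truth aggregated to
exon-level-distinct chains, because isoforms differing only by sub-exon
microdeletions are indistinguishable at exon level by construction (they
are separated by the splice-site-level analysis).

Breakpoint repair is evaluated on a variant of the configuration with no
sub-exon shift isoforms (`microdeletion_lengths` and
`frameshift_deletion_lengths` empty) and elevated junction jitter. This
isolates the property being tested — repair of junction-adjacent noise
against a complete catalogue. When genuine shift variants sit within the
error kernel of an annotated junction (the 4-15 nt microdeletions of the
default configuration), a read whose gap edge has been displaced by
errors is intrinsically ambiguous between the two junctions, and no
nearest-site rule can assign every read correctly; the pipeline's
junction-level *models* still recover such variants because the
population of error-free reads supports them directly.

# Problem sizes and runtime

The default evaluation (6 × 3000 reads over a ~2 kb metagene) runs the
full pipeline in a few minutes on one CPU; the built-in aligner takes
~5 ms per read at this scale. Unit tests use the same generator at depths
of 150–400 reads per library. These sizes were chosen so that the whole
evaluation is routinely re-runnable on a laptop while keeping the
binomial support counts (≥ 5 reads per library, ≥ 24 per transcript) far
from their thresholds for the planted truth.

# Known limitations

* The built-in aligner is not a general spliced aligner: its band assumes
  the read is a near-subsequence of the metagene, and it has no splice
  motif model (junction placement inside repeats is resolved by the
  breakpoint-correction stage instead).
* Splice shifts of 1–2 nt are below the catalogue's site resolution by
  design; they are irrecoverable at percent-level indel rates.
* The coding classifier reports frame and stop status only; it does not
  model NMD or translate region knowledge into the coding call.
* Single-locus by design: multi-gene metagenes, novel first/last exons
  and genome-wide discovery are out of scope (the assay anchors both
  amplicon ends in annotated terminal exons).
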