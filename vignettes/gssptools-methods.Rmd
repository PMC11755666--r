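---
title: "Methods: proteogenomic event calling from GSSP evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proteogenomic event calling from GSSP evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its methods: the statistical
model behind each stage, the thresholds and why they default where they
do, what the synthetic data does and does not emulate, and the numerical
conventions a maintainer needs to know.

## The problem

A standard database search only identifies peptides that the gene
annotation predicts. Searching the same spectra against a six-frame
translation of the genome recovers peptides from unannotated coding
sequence; peptides absent from the known proteome but placeable at a
unique genomic location — genome search-specific peptides, GSSPs — then
become evidence for four classes of events: novel protein-coding regions,
gene-model revisions, unannotated splice junctions, and single amino acid
variants (SAAVs). The pipeline's job is to make each inferential step in
that chain explicit, parameterised, and testable.

## Search-space construction

`six_frame_translate()` splits every frame at stop codons (and at codons
containing `N`, which are treated as untranslatable breaks, never
wildcards) into stop-to-stop segments. Within a segment it emits the ORF
starting at the first in-frame start codon from {ATG, GTG, TTG} — the
start set reflecting the start-codon usage observed for
proteogenomically recovered plant genes, with alternative starts
translated as initiator methionine — or, when no start exists, the whole
segment as a `fragment` entry. Fragments are retained deliberately:
peptides from ORFs with non-canonical starts must stay findable, and the
distinct label keeps them out of start-codon statistics.

Default `min_orf_len` is 20 codons. Novel proteins recovered this way
are often short (sORFs under 100 codons are a recognised class), so the
floor must be low; 20 keeps nearly all genuinely translatable products
while bounding the database size, which grows quickly as the floor drops.

"Three-frame translation" is implemented as translation of assembled
transcripts in their three forward frames (`three_frame_translate()`):
transcripts are already stranded, and this is the only reading of the
term under which the transcript assembly feeds the search space.

Decoys are sequence reversals, one per target, prefixed `rev_` — the most
common convention, chosen because reversal preserves length and
composition exactly.

## Class-specific FDR

False positives do not distribute evenly between known-proteome matches
and six-frame matches: the novel search space is orders of magnitude
larger, so at any global threshold the novel identifications carry most
of the error. `class_specific_fdr()` therefore ranks each class
separately; the raw estimate at score $s$ is
$\widehat{\mathrm{FDR}}(s) = d(s)/t(s)$ (decoys and targets at or above
$s$), and the q-value is its cumulative minimum from the bottom of the
ranking. The plain $d/t$ estimator is the default with the conservative
$(d+1)/t$ variant behind a flag; ties rank decoys above targets.

Filtering is at **peptide level** by default (best score per peptide,
per class), with a PSM-level mode. The choice is deliberate: event
evidence is counted in distinct peptides, so the error estimate should
live on the same unit.

`empirical_fdr()` closes the loop on simulated data: given true
correctness labels, it measures the realised fraction of incorrect
accepted identifications — the quantity the estimate is supposed to
bound. The test suite asserts, over repeated simulations with decoy and
incorrect-target scores i.i.d., that the mean realised FDR stays within
Monte-Carlo error of the 1% target.

## Genomic anchoring

Peptides matching an annotated protein as a contiguous substring are
"known"; I and L are interchangeable throughout (isobaric in MS/MS —
no spectrum can tell them apart, so no mapping step may distinguish
them). Orphans are matched into the coordinate-bearing ORF entries and
their protein offsets converted to genomic blocks; placements identical
after coordinate collapse (overlapping frames emitting the same product)
count once, and only peptides with exactly one placement are unique
GSSPs — multi-placed peptides are retained for reporting but never count
as evidence.

Spliced placement (`find_splice_mapping()`) runs only for peptides with
no contiguous placement. The peptide is split into a donor part and an
acceptor part with at least 9 nt (three residues) of genomic block on
each side — short blocks would place essentially anywhere — and all
three intron phases are searched: a codon may straddle the junction, in
which case it must reassemble from the two block ends to the observed
residue. Introns must be GT..AG (GC..AG available via `donors`), no
longer than `max_intron` (default 10,000 bp, generous for a compact
plant genome). Every placement the pipeline emits is re-translated from
the genome and compared with the peptide — a standing assertion, not
just a test.

## Event classification

Unique GSSP placements cluster into loci at a 1,000 bp gap (the
`locus_gap` default separates neighbouring features in genomes of
ordinary gene density while tolerating the within-gene spread of
peptides from one product).

* **Novel genes** need a locus with zero same-strand overlap with any
  annotated gene span and ≥ 2 distinct unique peptides
  (`min_gssps_per_novel`): one peptide is one spectrum-level inference;
  two independent peptides make a locus a reproducible observation.
  Overlap is judged against gene spans, not exons, so intronic orphans
  are not mistaken for intergenic novelty; antisense-only overlap is a
  novel call flagged `antisense`.
* **Revisions** partially overlap exactly one same-strand gene (neither
  fully inside its annotated CDS — such placements are
  annotation-consistent and discarded — nor fully outside the span).
  Sub-typing into 5'/3' extensions and intronic/internal calls is this
  package's taxonomy, added because the downstream curation action
  differs. Loci overlapping several genes are reported separately as
  ambiguous rather than forced into a call.
* **AS junctions** are junction placements whose intron coordinates are
  absent from the annotated intron set, grouped by exact
  (donor_end, acceptor_start). Junction coordinates are stored on the
  forward genomic axis regardless of strand (donor_end = last exonic
  base before the intron interval), which makes exact matching
  strand-free and unambiguous.
* **SAAVs**: orphans of ≥ 10 residues (shorter mismatched peptides match
  too promiscuously) with ≤ 2 substitutions against the best-matching
  annotated protein window. Each mismatch is traced through the gene
  model to its genomic codon; candidate alternative codons are exactly
  the single-base edits encoding the observed residue. With nucleotide
  evidence covering the site the supported codon is selected; without
  it the candidate set is reported and **no codon is guessed**.
  Mismatches needing more than one base change are flagged
  `multi_nucleotide` and kept out of the default report; a second pass
  of `call_saavs()` against called novel-ORF proteins covers variants on
  novel proteins.

Tissue presence is the set of tissues contributing at least one accepted
supporting PSM; tissue-specific means exactly one.

## Quantitation and integration

Features must be detected in ≥ 2 of 3 replicates of a tissue to be
quantifiable, and in both tissues of a comparison to be tested — missing
values are never imputed. Tests are Welch t-tests on log2 intensities by
default (replicate variances are rarely equal; the classical
pooled-variance test is a flag), with BH q-values reported alongside.
The differential gate is |FC| ≥ 1.5 **and** raw p ≤ 0.05 — the gate uses
raw p because that is the stated decision rule being reproduced, with a
strict-q mode for users who want FDR-gated calls. Ratios are oriented
second-named tissue over first, in log2.

`correlate_omics()` reports Pearson r for all shared features, for
cor-DEGs-DEPs (differential in both layers), and for the same- and
opposite-trend splits *within* the cor-DEGs-DEPs subset — the nesting
matches how those panels are conventionally drawn. Subsets under 3
features yield `NA` with a warning rather than a meaningless r.

The delta-mass module is a deliberately simplified open-modification
annotator: it bins precursor mass deltas against a table, it does not
re-score spectra or localise sites. Deltas above 250 Da are rejected
(the cap of the blind search it emulates); within 0.01 Da of zero is
unmodified; otherwise the nearest table entry within `ptm_tolerance`
(default 0.01 Da, high-resolution instruments) matches, with all entries
in tolerance listed as ambiguous. The 18-entry default table carries
monoisotopic masses from the public Unimod registry and ships as a
user-replaceable TSV (`inst/extdata/modifications.tsv`).

## The synthetic data: what it emulates, what it does not

`simulate_dataset()` builds the full study in miniature, with defaults
chosen once as the evaluation conditions: a 100 kb single-chromosome
genome; 50 two-exon genes on both strands; 10 strictly intergenic novel
ORFs (≥ ~1 kb of spacer isolates every feature, making "no overlap"
unambiguous and keeping distinct loci from merging at the clustering
gap); 15 SAAV sites; 8 unannotated in-frame GT..AG exon-skipping
isoforms; 5 genes with in-frame 5' extensions; five tissue labels
mirroring a five-organ floral design, with each event assigned a random
non-empty tissue subset and each gene present everywhere.

Construction guarantees detectability rather than hoping for it: novel
ORFs are regenerated until they yield ≥ 2 fully-tryptic peptides of ≥ 7
residues unique to their locus; AS skip regions are engineered so
junction-spanning tryptic peptides exist with ≥ 4 residues on each side
(shorter overhangs are excluded from the PSM input, as peptides with
one- or two-residue overhangs would be spurious near-matches of the
annotated protein); variant peptides are single-edit, non-synonymous by
construction, with K/R/P excluded at the edit so tryptic boundaries
survive. The genome always carries the *reference* allele — the variant
exists only in the PSM data, exactly as in a real search.

PSM scores are two Gaussians: correct identifications N(35, 5),
incorrect identifications and decoys N(10, 5), one PSM per (peptide,
tissue, replicate) with three replicates. The 5-standard-deviation
separation encodes the working assumption that correct identifications
from a calibrated engine score far above chance matches; under a 1%
FDR threshold this makes the loss of genuinely correct peptides
negligible, which is the regime in which exact recovery of every
injected event is a meaningful expectation. (The FDR-control
simulations deliberately use a much harder 3-standard-deviation
separation — error control must hold even when scores overlap.)
Incorrect target PSMs carry freshly generated random tryptic-like
sequences disjoint from every true peptide: a wrong spectrum match
points at a sequence that is not actually present, so error control and
event precision can both be measured honestly.

Not emulated: spectra themselves (m/z peaks, retention time, charge),
protein inference, intensity-dependent detectability, homology between
genes, multi-transcript gene models, and sequencing errors. Passing
tests therefore demonstrate the correctness of the decision chain on
data satisfying its assumptions — not robustness to the full mess of
real MS data.

## Numerical conventions and edge cases

* Coordinates are 1-based inclusive on the forward strand throughout,
  the GenomicRanges convention; BED12 output converts to 0-based
  half-open at the writer. ORF intervals include the trailing stop codon
  when present.
* Reverse-strand features are always stored on the forward axis; codon
  order for minus-strand genes descends genomically, and evidence bases
  are complemented at exactly one boundary (`infer_saav_codon()`),
  which the minus-strand tests pin down.
* Score ties in FDR ranking resolve decoys-first (conservative). A
  class with no decoys gets q = 0 everywhere plus an explicit
  "unestimable" warning rather than silent acceptance.
* Zero variance with equal means in a t-test yields p = 1 by convention;
  features failing quantifiability are never tested.
* Determinism: every stochastic step derives from the configuration
  seed; identical configurations produce byte-identical FASTA/GFF3/
  JSON/TSV outputs, asserted by checksum in the tests. The generator
  restores the caller's RNG state.
* Evaluation conventions: novel loci match truth at reciprocal overlap
  ≥ 90%; junctions and SAAV positions/codons match exactly; zero calls
  of a kind score precision 1 with a warning (no evidence is not
  counter-evidence).

## Problem sizes

The shipped tests run the full pipeline on 100 kb genomes with ~34,000
simulated PSMs (the default study conditions) and verify the six-frame
and digestion primitives against brute-force enumeration on 100 random
2 kb sequences and 100 random proteins respectively; the FDR-control
simulation uses 20 seeds of 20,000 PSMs each. These sizes exercise every
code path at meaningful multiplicity while keeping a complete test run
around a minute on a laptop.

## Known limitations

* SAAV search scans annotated proteins only (plus called novel proteins
  in a second pass); a variant in a protein absent from both sets is
  invisible.
* Splice mapping considers exactly two blocks; peptides spanning two
  junctions (three exons) are not placed.
* The revision caller names one gene; overlaps of two or more genes are
  surfaced as ambiguous rather than resolved.
* Peptide-level FDR treats the best score per peptide as one
  observation; no attempt is made at posterior error probabilities or
  protein-level FDR.
* The delta-mass annotator cannot distinguish isobaric modifications
  beyond listing them as ambiguous, and does not localise sites.
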