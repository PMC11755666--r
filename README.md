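# gssptools

Proteogenomic event calling from genome search-specific peptides (GSSPs),
for researchers who search shotgun MS/MS data against translated genome
databases to find what the gene annotation missed: unannotated
protein-coding regions, wrong gene boundaries, unreported splice isoforms
and coding single-nucleotide variants — and who want the whole decision
chain (database construction, error control, genomic anchoring, event
classification) reproducible and testable on data with known ground truth.

## What it does

Starting from a genome (FASTA), its annotation (GFF3), the known proteome
and a table of peptide-spectrum matches (PSMs), the pipeline:

1. **Builds the search space** — six-frame translation of the genome into
   stop-to-stop ORFs anchored at the first ATG/GTG/TTG (plus "fragment"
   entries for segments without a canonical start), optional three-frame
   translation of assembled transcripts, concatenated with the known
   proteome and reversed decoys. Every ORF identifier carries its genomic
   coordinates (`g6|chr1|+|0|1201-1530|ATG`).
2. **Controls errors class-specifically** — targets are ranked per class
   (known vs novel peptides) and the q-value at score *s* is the
   cumulative minimum of the raw estimate FDR(s) = #decoys ≥ s / #targets
   ≥ s. The novel class, searched against the vastly larger six-frame
   space, gets its own estimate so its error rate cannot hide behind the
   well-behaved known class. Default threshold: q ≤ 0.01.
3. **Separates known from orphan peptides** (substring of any annotated
   protein, I/L-equivalent) and **anchors orphans to the genome**:
   contiguous placements via the coordinate-bearing ORFs, then spliced
   two-block placements across GT..AG introns (all three intron phases; a
   codon straddling the junction must reassemble to the observed residue).
   Uniquely placed peptides are GSSPs, the evidence unit for every call.
4. **Classifies events** — clusters of ≥ 2 unique GSSPs with no
   same-strand gene overlap become novel protein-coding regions; clusters
   partially overlapping exactly one gene become gene-model revisions
   (5'/3' extension or intronic); junction placements absent from the
   annotated intron set become alternative-splicing calls; orphans of
   ≥ 10 residues matching an annotated protein with ≤ 2 substitutions are
   traced through the gene model to their reference codon, and every codon
   encoding the observed residue one base change away is enumerated
   (nucleotide evidence selects among them — never guessed). Events are
   tagged with the tissues whose accepted PSMs support them.
5. **Integrates quantitation** — the detected-in-≥2-of-3-replicates
   filter, per-feature t-tests on log2 intensities with |FC| ≥ 1.5 and
   p ≤ 0.05 gates (BH q-values reported), and Pearson correlation of
   protein vs transcript ratios for all shared features, the
   cor-DEGs-DEPs subset and its same/opposite-trend splits. A delta-mass
   module bins precursor mass shifts (cap 250 Da) against a configurable
   18-entry modification table.

A first-class synthetic-data generator (`simulate_dataset()`) builds an
annotated ~100 kb genome with injected events of every class, in-silico
tryptic peptides and target/decoy PSM score distributions with a known
fraction of incorrect identifications, so that recovery and error control
are measurable against truth (`evaluate_against_truth()`).

## Worked example

```r
library(gssptools)

cfg <- synth_config(genome_length = 40000, n_genes = 15, n_novel_orfs = 3,
                    n_saavs = 4, n_as_isoforms = 3, n_revisions = 2, seed = 7)
b   <- simulate_dataset(cfg)
run <- run_pipeline(b$genome, b$annotation, b$known_proteome, b$psms,
                    transcript_evidence = b$transcript_evidence)
str(run$manifest$counts)
#> $ psms_in            : int 9426
#> $ psms_accepted      : int 4713
#> $ peptides_accepted  : int 347
#> $ peptides_known     : int 279
#> $ peptides_orphan    : int 68
#> $ gssp_placements    : int 46
#> $ gssp_unique        : int 46
#> $ peptides_unplaced  : int 22
#> $ junction_placements: int 15
#> $ events             : List of 3 (as_junction 3, novel_gene 3, revision 2)
#> $ saavs              : int 4
```

Of 9,426 simulated PSMs (half decoys), 4,713 targets survive 1% FDR;
347 distinct peptides split into 279 known and 68 orphans. 46 orphans
place contiguously and uniquely, 15 place across an unannotated junction,
and 22 place nowhere exactly — the SAAV candidates. Comparing the calls
with the injected truth:

```r
evaluate_against_truth(run$events, run$saavs, b$truth)
#>          kind n_truth n_calls n_matched_calls precision recall
#> 1  novel_gene       3       3               3         1      1
#> 2 as_junction       3       3               3         1      1
#> 3        saav       4       4               4         1      1
#> 4    revision       2       2               2         1      1
```

Every injected event is recovered exactly — novel loci by reciprocal
overlap ≥ 90%, junctions by exact donor/acceptor coordinates, SAAVs by
exact reference/alternative codon. One recovered SAAV:

```r
run$saavs[1, c("peptide", "gene_id", "ref_codon", "selected_alt_codon",
               "ref_aa", "alt_aa", "genomic_position")]
#>      peptide gene_id ref_codon selected_alt_codon ref_aa alt_aa genomic_position
#> 1 MFFWVAYLLR gene_03       GGC                GTC      G      V             4053
```

The peptide differs from the annotated protein of `gene_03` at one
residue (Gly → Val); the reference codon read from the gene model is GGC,
and the transcript-level variant evidence selects GTC among the
single-edit valine codons, placing a G→T substitution at genomic position
4053. The textbook case — glutamic acid GAA observed as aspartic acid —
resolves the same way:

```r
saav_candidate_codons("GAA", "D", evidence_base = list(position = 3, base = "C"))
#> $candidates: "GAC" "GAT"   $selected: "GAC"
#> $substitution: ref_base "A", alt_base "C", codon_position 3
```

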