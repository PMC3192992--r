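---
title: "Reference-cascade annotation of de novo transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-cascade annotation of de novo transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txcascade)
```

## The problem

De novo transcriptome surveys of species without a sequenced genome produce
tens of thousands of contigs and singleton reads that carry no annotation.
txcascade assigns homology to such sequences by searching them against an
ordered series of reference databases — the mitochondrial genome of the
species, known non-coding RNAs, annotated coding transcripts of related
species, EST cluster representatives, genomic sequence, and finally the
annotated sequences of co-analysed species — removing each sequence from
the stream at the first round where it finds a convincing match.  Assigned
sequences are then condensed into reference-anchored majority-consensus
"gene" sequences, screened for microsatellites and heterozygous sites, and
(at the amino-acid level) assembled into partitioned supermatrices for
phylogenomic inference.

Everything runs on ordinary tibbles: reads, hits, assignments, marker
tables and ortholog tables are data frames, so each stage chains with the
pipe and integrates with dplyr/ggplot2 workflows.  Fitted-object-like
results (`cascade_result`, `consensus_record`, `supermatrix`) provide
`tidy()`, `glance()` and `autoplot()` methods.

## The cascade and its parameters

Each round couples a search parameterisation to an acceptance filter:

| round   | mode       | word | match/mismatch or matrix | gaps | filter |
|---------|------------|------|--------------------------|------|--------|
| mtDNA   | nucleotide | 11   | +2 / −1                  | 5/1  | ≥ 50 bp, ≥ 50% id |
| ncRNA   | nucleotide | 11   | +2 / −1                  | 5/1  | ≥ 50 bp, ≥ 50% id |
| coding  | translated | 3    | BLOSUM45                 | 11/1 | ≥ 30 aa, ≥ 50% id |
| unigene | nucleotide | 9    | +2 / −1                  | 5/1  | ≥ 50 bp, ≥ 50% id |
| genomic | nucleotide | 9    | +2 / −1                  | 5/1  | ≥ 50 bp, ≥ 50% id |
| cross-species | nucleotide | 9 | +2 / −1               | 5/1  | ≥ 50 bp, ≥ 50% id |

The e-value ceiling is 10 in every round.  The filters are deliberately
non-strict at the boundary: a 50 bp / 50%-identity hit survives, because the
rejection rule is phrased strictly ("shorter than", "below").  When a query
hits several database entries, the best hit minimises e-value, then
maximises alignment length, then percent identity; any remaining tie goes to
the first hit in the deterministic hit-table order, so reruns are
reproducible.

### The built-in search engine

The engine is a classic seed-and-extend design.  Exact words (11-mers for
nucleotide rounds, 3-mer residues across all 6×6 frame pairs for the
translated round) seed candidate query/subject pairs; a pair is extended
only when it carries two non-overlapping word hits on a single alignment
diagonal.  This *two-hit* gate matters with the permissive scoring above:
a match/mismatch ratio of +2/−1 with gap costs 5/1 sits in a regime where a
single chance 11-mer seed can grow, by stitching, into alignments that pass
a 50 bp / 50% filter.  Requiring a second same-diagonal hit suppresses
those chance seeds while leaving genuine homologs (which share many words)
untouched.

Extension is an affine-gap local (Smith–Waterman/Gotoh) alignment computed
in compiled code; a gap of length *k* costs `gap_open + k·gap_extend`.  In
translated mode stop codons score −1000, so an extension can never cross a
stop.  E-values use the ungapped Karlin–Altschul formula with λ solved
exactly for the configured scoring scheme (uniform base composition for
nucleotides, Robinson–Robinson residue frequencies for proteins) and a
fixed K = 0.1.  These statistics rank and threshold consistently, but they
are *not* numerically comparable with the gapped statistics of external
search engines; precomputed tabular hit files from such engines can be
loaded through `parse_blast_tabular()` instead.  The engine reports the
single best alignment per query/subject pair (per query frame in translated
mode); secondary HSPs are not retained because no downstream stage consumes
them.

Soft-masking follows the usual convention: `mask_low_complexity()`
lowercases DUST-style low-complexity windows (triplet-composition score
above 2 in 64 bp windows), lowercase positions never seed, but extensions
may run through them.

## Read preprocessing

Raw pyrosequencing-style reads carry amplification adaptors (by default the
25-mer CAP oligo and its reverse complement) and polyA tails.
`remove_adaptors()` excises every full-length adaptor occurrence within 2
mismatches (no indels) in either orientation, plus truncated occurrences of
at least 10 bp overhanging a read end.  A terminal occurrence trims the
read; an internal one splits it in two, qualities travelling with each
part; fragments under 30 bp are discarded (they could never pass the 50 bp
hit filter).  The accounting identity
`reads_out = reads_in − discarded + splits` is checked by the tests on
every run.

Two parameter choices are our own, since only the steps themselves are
standard: "near-exact" is interpreted as ≤ 2 mismatches over the full
adaptor (configurable), and polyA trimming removes a terminal A-run (or
leading T-run) of ≥ 10 bases with ≤ 10% impurity.  One consequence of the
run definition worth knowing: if the biological sequence itself ends in A
adjacent to a polyA tail, that terminal A is part of the run and is
trimmed — no trimmer can distinguish it from the tail.  Quality trimming is
a 3′ sliding window (10 bp, mean Phred ≥ 20): the read is shortened until
its trailing window passes, which can leave a few low-quality bases at the
boundary window — the guarantee is about the trailing window mean, not
about individual bases.

## Consensus building

A reference matched by exactly one query is a *one-to-one* consensus: the
query passes through verbatim, renamed after the reference.  With several
members, the built-in aligner is *reference-anchored*: each member is
oriented (`best_orientation()`, ties to forward) or translated in its
best-hit frame, pairwise-aligned to the reference, and projected into the
reference's coordinate frame; insertions relative to the reference are kept
as member-only columns.  The reference defines coordinates but never
votes: the consensus at each column is the majority over member residues,
`-` where no member reaches, and ties resolve to the IUPAC ambiguity code
(protein-mode residue ties become `X`, emitted as `NNN` after
back-translation).  In protein mode members are back-translated to their
source codons *before* the majority call, so the consensus is always
nucleotide; the reference's reading frame is taken from its longest ORF
(frame +1 for a clean CDS), and because translated alignments never cross a
stop codon, the reference's stop codon itself is never part of the anchored
block.

Gap percentages are reported for three regions of the alignment — by
default the 5′ 30%, middle 40% and 3′ 30% of columns, boundaries rounded
half-up — a compact diagnostic of whether a consensus is missing its ends
or its middle.

Multi-member consensuses in which at least two members disagree at ≥ 10% of
their shared columns are flagged `discordant` (joined paralog fragments
look like this) but are not rejected; the flag is surfaced by `glance()`.

Mitochondrial reads take a different route: `reference_guided_assembly()`
places each member on the organelle genome by best local alignment in
either orientation, majority-calls a consensus per reference position,
reports per-feature coverage against the GFF3 annotation, and returns the
full per-position allele pileup for variant calling.

## Marker discovery

`find_ssrs()` implements the conventional microsatellite thresholds:
mononucleotide motifs at ≥ 10 repeats, di- through hexanucleotide motifs at
≥ 5.  We read the usual "more than 10 / more than 5" phrasing as these
inclusive MISA-convention bounds, which is how the tool that phrase
describes actually behaves; a strict reading is available via
`ssr_thresholds(strict = TRUE)`.  A repeat whose unit is itself periodic
(e.g. `ATAT`) reports under the shortest unit; motifs are classed by
`canonical_motif()` (minimum over rotations and reverse complement, so
`GT`/`TG`/`CA`/`AC` are all class `AC`).  Perfect loci separated by
*strictly fewer than* 50 bp merge into compound loci — 49 bp merges, 50
does not, and the tests pin both sides of the boundary.

`call_variants()` applies the minor-allele depth rule: a pileup column is a
variant when ≥ 2 alleles are observed, and *high-confidence* when the
second-most-frequent allele has depth ≥ 3 (hence informative depth ≥ 6) —
the cutoff that separates genuine heterozygous sites from sequencing error
in single-individual data.  Gap alleles make the site an indel; an indel
adjacent to a run of ≥ 3 identical bases is flagged `in_homopolymer`
(pyrosequencing's characteristic error mode, low-confidence regardless of
depth).  The run length 3 is our choice; the flag's source material never
defines one.  Note that a deletion inside a homopolymer run has no unique
position: the aligner places it deterministically, but anywhere within the
run is equivalent, and the tests treat it so.

`classify_substitutions()` walks a sample/reference alignment, splits
substitutions into transitions and transversions, and assigns codon
positions inside CDS features from the feature frame and strand, the usual
sanity check that organelle variants are dominated by transitions and spare
second codon positions.

## Phylogenomic supermatrices

`ortholog_table()` holds gene × taxon amino-acid sequences in long form.
Genes are aligned by the anchored aligner (longest sequence anchors, global
pairwise projection), hybrids are built, genes are concatenated in
lexicographic order with all-gap blocks for absent taxa, and partitions
(1-based inclusive column ranges) always tile the matrix.

A *hybrid taxon* fills its row gene-by-gene from a priority-ordered group
of closely related species: for each gene, the whole-gene sequence of the
highest-priority member that has one.  We deliberately select whole-gene
sequences, never within-gene mosaics of two species; every hybrid cell is
therefore byte-identical to one member's cell and the provenance table
names it.

`trim_columns()` offers the two standard gap-trimming modes:
`remove_all_gapped` deletes every column containing a gap;
`max_drop` scores each column by its fraction of non-gap residues, sorts
the distinct scores descending, cuts at the largest drop between
consecutive scores, and deletes columns strictly below the cut.  Ties in
the drop location resolve toward retaining more columns.  Missing data is
written as `-` (consistently with the gap-trimming rules); the PHYLIP
writer can remap it to `?`.  Tree inference itself is out of scope: the
package exports relaxed PHYLIP plus a partition file for external ML
programs.

## The synthetic corpus

`sim_config()` fixes the study conditions for all closure tests: 20 genes
of 600–1500 bp, 5% truth-to-reference divergence, 100–300 bp fragments at 5
fragments per gene, 0.5% read error — a deliberately small emulation of a
shallow single-run transcriptome survey against ~5%-divergent reference
species.  Reference homologs are diverged codon-aware (no in-frame stops),
as real coding orthologs are.  Generators for planted SSRs, exact-depth
variant pileups, and an annotated mitochondrial genome emit machine-readable
truth tables so that every closure test (generate → run → compare to truth)
runs offline in seconds.

What the generator does *not* emulate — indel sequencing errors,
expression-level coverage bias, chimeric reads, real flowgram noise,
paralogous gene families — bounds what green tests mean: they demonstrate
the pipeline's rules are implemented exactly and recover planted truth
under the stated conditions, not that the pipeline is robust to every
artefact of real data.

Problem sizes in the test-suite and acceptance script (100 fragments / 20
genes for cascade recovery, 200 pairs for the aligner oracle, a 6-gene
corpus for the end-to-end determinism check) were chosen as the smallest
sets that still exercise every rule; all complete in a few minutes on one
CPU.

## Numerical and design choices

* Coordinates are 0-based half-open nowhere and 1-based inclusive
  everywhere at file boundaries (tabular hits, GFF3, partitions); internal
  projections convert once.
* `N` is an unknown base and never a gap; `-` is a gap everywhere.
* Gap cost is `open + k·extend` (open 5/extend 1 nucleotide, 11/1
  translated), matching the convention of the tabular formats consumed.
* Majority ties: IUPAC codes (nucleotide) / `X` (protein); a tie between a
  gap and a base resolves to the base.
* Best-hit and hit-table order are fully deterministic; the pipeline
  manifest hash is the reproducibility witness, and a rerun on identical
  inputs is byte-identical.
* The `run_pipeline()` config is a declarative list (or YAML file);
  unknown keys are rejected up front, and database paths are validated
  before any compute.

## Known limitations

* E-values are internally consistent but not BLAST-comparable; use the
  tabular adapter when fidelity to an external engine matters.
* The translated round reports one alignment per query/subject/frame; HSP
  chaining across subjects is not implemented.
* The reference-anchored aligner is not a general progressive MSA; with
  highly divergent members a profile aligner (pluggable via aligned FASTA)
  will do better.
* Species-level assignment percentages of real surveys depend on the real
  reference databases and read sets, which the synthetic corpus does not
  model; no such figures are claimed.
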