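---
title: "Spidroin discovery, gene-model reconstruction and silk composition"
author: "spidroinr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spidroin discovery, gene-model reconstruction and silk composition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spidroinr)
```

## The problem

Spider silk proteins (spidroins) share a tri-partite architecture: a long,
low-complexity tandem-repeat domain flanked by conserved, nonrepetitive
N- and C-terminal domains of roughly 100-150 residues. The repeat domain
carries the mechanical properties of the fiber and is written in a small
motif vocabulary — poly-alanine runs `(A)n`, glycine-alanine dyad arrays
`(GA)n`, `GGX`, `GPGXX` and `XQQ` — while the terminal domains are the only
parts conserved enough for homology search. This combination makes
spidroins notoriously hard to annotate: standard gene predictors fragment
the repeat arrays, assemblies collapse them, and single-base errors inside
a repeat silently frameshift half a gene.

`spidroinr` implements the resulting annotation workflow as a tested
pipeline: find candidates in a proteome by terminal-domain homology,
validate the tri-partite architecture, rebuild full-length gene models
directly on the genome from N/C anchors with frameshift-aware repair,
classify and group the catalog along chromosomes, and profile gland
expression and dragline-silk composition. A seeded synthetic-genome
generator with a ground-truth table makes every stage testable without any
external download.

## The synthetic study system

`make_bundle(config, seed)` is a pure function of its configuration and
seed. The default configuration mirrors the catalog structure reported for
golden orb-weavers:

* 13 spidroin genes arranged as three chromosomal groups — `MaSp1a-c` plus
  `MaSp2e` on `chr4`, `MaSp2a-d` on `chr7`, and `MiSp-a-e` on `chr6` — with
  both strands represented;
* 50 decoy genes (uniform-random proteins carrying a contiguous
  collagen-like GXY block, rejection-sampled so that no segment shares more
  than 40% identity with any reference terminal domain over half its
  length) interleaved among the spidroins;
* two corrupted loci: one single-nucleotide deletion placed in the central
  80% of a repeat array (`MaSp1b`), and one C-terminal truncation
  (`MaSp2c`);
* a 27-sample expression matrix covering the seven gland types, with the
  major ampullate (Ma) gland split into its Tail, Sac and Duct segments.

Repeat arrays are generated by drawing **one master unit per gene** from a
family-specific motif grammar and tandem-copying it with a small
per-residue substitution rate (`unit_noise = 0.02`). Drawing every unit
independently would look superficially similar but would destroy the
self-alignment periodicity that both real spidroin arrays (which are
homogenised by concerted evolution) and the detector rely on. Terminal
domains come from a synthetic reference library — one random
globular-composition domain per (type, terminus), generated once from a
fixed seed and shipped as a FASTA fixture — and are mutated at
`substitution_rate = 0.05` per gene, emulating cross-species divergence
from the reference.

Genes are single-exon CDSs (reverse-translated with uniform synonymous
codon usage plus a stop codon) separated by random intergenic flanks of
0.8-2 kb. This is the one place the generator is deliberately simpler than
a real genome: introns, UTRs and repetitive intergenic DNA would add no
behaviour that any stage of this pipeline tests. Passing tests therefore
demonstrate correctness of the method's logic, not robustness to
spliced-gene annotation, assembly collapse, or sequencing error — real
data adds all three.

Baseline expression is log-normal (`meanlog = 1`, `sdlog = 1`, FPKM
scale); each spidroin is multiplied by `fold = 1000` in its cognate gland
samples. Major-ampullate spidroins are cognate to Tail and Sac — the
synthesis and storage segments — but not the Duct, which only spins the
fiber. With only 63 genes in the bundle the Duct's silk load is bounded
below by the spidroins' share of the gene count (~13%), so the Tail/Duct
contrast is structural (about 7-8 fold) rather than the two orders of
magnitude seen with a full transcriptome; the tests assert the structural
bound, not the real-data magnitude.

## Homology search

`align_local()` computes optimal Smith-Waterman local alignments under
BLOSUM62 with affine gaps (open 11, extend 1; a gap of length L costs
`11 + L`). The engine is `Biostrings::pairwiseAlignment`; the test suite
verifies it cell-for-cell against an independent three-state dynamic
program on exhaustive short pairs and hundreds of random longer pairs.
E-values use the Karlin-Altschul form `E = K m n exp(-lambda S)` with the
canonical gapped-BLOSUM62 constants `lambda = 0.267`, `K = 0.041`, and
`n` equal to the summed reference length — fixed published constants make
E-values reproducible without an empirical calibration stage. The
discovery cutoff is `E < 1e-10`; `1e-5` is the conventional setting for
cross-species ortholog search. `collapse_nonredundant()` reduces hits to
one best hit per query gene (smallest E, then largest bit score, then
lexicographic reference id); per-gene best-hit is this package's declared
reading of "nonredundant", since locus-level deduplication would require
coordinates that a proteome search does not have.

Stops (`*`) are accepted and scored via the matrix's stop column so that
six-frame translations can be searched directly; any character outside
the amino-acid alphabet plus B/Z/X/`*` is an error naming the character.

## Repeat detection and motif grammar

`periodicity()` computes the lag profile
`m(l) = #\{i : s[i] = s[i+l]\} / (L - l)`; a tandem array of unit length
`u` drives `m(u)` and its multiples toward 1. `find_repeat_region()` takes
the unit length as the *smallest* lag within 5% of the profile maximum
(preferring the fundamental period over its harmonics, which are recorded
in the result), screens for the maximal run of positions whose windowed
(window `2u`) shifted-match fraction reaches `theta = 0.5`, and then
refines the boundaries: each boundary seeds on a run of at least four
consecutive exact self-matches (a random coincidence of that length has
probability ~20^-4 per position) and extends through adjacent matches.
On noiseless arrays this recovers the true span to within a residue or
two, and the unit length exactly for units of 5-100 residues; both facts
are asserted in the acceptance suite. A single unit is not an array: the
region must span at least two units or nothing is reported.

`count_motifs()` counts the five motif classes independently of one
another, each as maximal non-overlapping matches scanned left to right:
`(A)n` requires runs of at least 4 alanines (the canonical poly-alanine
block; counted as runs and as total residues), `(GA)n` at least 2 dyads,
and `GGX`/`GPGXX`/`XQQ` are fixed-width with `X` any residue. Cross-class
overlaps are allowed because no precedence rule exists in the literature;
independent counting is order-free and directly checkable against a
character-walk oracle, which the tests do exactly on 1000 random strings.
These are declared defaults, not reconstructions of any particular
legacy script. Motif `coverage` — the fraction of sequence under at least
one motif — doubles as the objective for frameshift repair below.

## Gene-model reconstruction and frameshift repair

`anchor_search()` aligns every reference terminal domain against all six
translation frames of every chromosome; because one frame can harbour
several genes, each hit is masked and the frame re-searched until the
E-value cutoff fails. Hits become codon-aligned genomic anchors.
`pair_anchors()` pairs each N anchor with the nearest downstream C anchor
(in transcription orientation) on the same chromosome and strand within
`max_span = 50` kb — generous for single-locus spidroin genes — with one
guard: no other N anchor may lie between the pair, so the lone N anchor of
a C-truncated gene cannot capture the next gene's C terminus. Unpaired
anchors become partial loci flagged with their missing terminus; a locus
missing its C anchor is extended downstream and translated to the first
stop, emulating ORF extension from a lone anchor.

`repair_frameshifts()` is the stage where the repeat grammar pays off.
An internal stop proves a frame break *somewhere upstream*, but silk
repeat codons (GGN, GCN, CCN, CAR...) are thymine-poor, so a frameshifted
repeat can run dozens of codons before producing a stop — repairing at the
stop would leave everything between the true indel and the stop as
garbage. The breakpoint is therefore searched: every codon-aligned
position within `back_search = 400` codons upstream of the stop is tried
with both single-nucleotide shifts (`-1` deletes the base at the
breakpoint, `+1` duplicates it), scoring each candidate by the motif
coverage of a `lookahead = 60`-codon window upstream in the current frame
plus the window downstream in the shifted frame. That objective peaks at
the true breakpoint: placing the edit too late leaves wrongly-framed
garbage in the upstream window, too early puts it in the downstream
window. A candidate must clear the stop, and the winning candidate must
reach `min_coverage = 0.3` downstream coverage — a frameshift inside a
terminal domain fails that bar (terminal domains carry no repeat grammar)
and flags the locus unresolved rather than silently "repairing" it. At
most `max_edits = 3` edits are applied, each logged with position, shift
and score, and serialized into the emitted GFF3 attributes. On the default
bundle this restores single-deletion genes to ~99% identity with the
pre-corruption protein, with the edit landing inside the truth repeat
span.

Internally all coordinates are 1-based closed (the R/Bioconductor
convention); GFF3 export is 1-based closed with gene/mRNA/CDS features and
`ID=`/`Parent=` attributes, and round-trips through `rtracklayer`.

## Classification, grouping, and catalogs

`assign_type()` replaces a phylogenetic classification with a
deterministic bit-score vote: the type with the largest summed bit score
over a gene's hits wins, with ties broken by the strongest single hit,
then by C-terminus evidence (the C-terminal domain is the more reliably
conserved anchor), then lexicographically. A tree over terminal domains
would be neither deterministic nor unit-testable against ground truth;
the vote recovers the generator's truth types for >95% of uncorrupted
genes. `detect_groups()` clusters spidroin genes per chromosome by single
linkage with a gap threshold of `max_gap = 1` Mb and reports clusters of
at least `min_size = 3`, labelled by majority superfamily with mixed
membership allowed (a MaSp1 group may contain a MaSp2 gene). The 1 Mb /
size-3 defaults are declared, since published group figures come without a
clustering rule; grouping is invariant under whole-chromosome translation
and only refines as `max_gap` decreases.

The bundled reference catalog (28 genes, 26 full-length: 9 MaSp, 5 MiSp,
2 FlSp, 1 TuSp, 2 AgSp, 1 AcSp, 1 PySp, 5 other) treats the published
per-type list as the full-length breakdown and carries the remaining two
genes as partial entries of type "other"; the two totals are otherwise
irreconcilable from the printed numbers alone.

## Expression and composition analytics

`fpkm()` is the textbook `counts * 1e9 / (length * library_size)`.
Tissue restriction uses the tau index,
`tau = sum(1 - x_i / x_max) / (N - 1)` over tissue means — 0 for uniform,
1 for single-tissue expression — with `tau >= 0.8` as the declared
"gland-specific" threshold for reporting. `silk_load()` is the fraction
of a segment's total FPKM contributed by the silk genes; over any
partition of the genes the loads sum to 1. `segment_specific_genes()`
requires mean FPKM of at least 1 in the focal segment and at least 4-fold
over every other segment; both values are declared defaults for a screen
whose published form is not specified in detail. The
annotation-integration filter keeps a gene model iff repeat proportion
< 0.5, protein length > 50 aa, FPKM > 0.1 in at least 10 samples, and
transcript support (Iso-seq identity > 95%) or homolog support
(E < 1e-5 and identity > 50%); inequalities are strict except the
support-sample count, boundary values drop, and each dropped gene carries
the first failing reason in the fixed order repeat, length, expression,
evidence. The homolog-support E-value direction is implemented as "<"
(the conventional direction) — sources sometimes print it inverted.

`tryptic_digest()` cleaves after K or R except before P with zero missed
cleavages, so the peptides tile the protein exactly. iBAQ divides each
protein's summed intensity by its count of theoretically observable
peptides, windowed at 7-30 residues — 7 matching the conventional minimal
search peptide length, 30 a standard upper bound; the window is a declared
convention, as iBAQ implementations do not publish theirs. Shares are
percentages of total iBAQ and sum to 100 by construction. The bundled
dragline proteome and metabolite tables are synthetic stand-ins (ids and
intensities constructed, not measured) that reproduce the published
*structure* — 28 proteins with 10 spidroins and top-5 iBAQ shares of
37.7/12.2/11.9/10.4/7.2% (79.4% cumulative), and 180 metabolites with 109
classified into ten categories — with the unitemized remainder spread
over the minor records.

## Problem sizes and numerical choices

The default bundle is ~160 kb of genome across three chromosomes, 63
genes, and a 63 x 27 expression matrix; generation takes seconds and the
full pipeline (search, assembly, repair, grouping) about half a minute.
These sizes were chosen so the whole test suite and the acceptance script
re-run the pipeline from scratch in minutes while leaving every
recovery statistic far from its floor: discovery precision/recall and
reconstruction accuracy are 1.0 at typical seeds, against acceptance
bounds of 0.9.

All randomness flows through explicit seeds (`make_bundle` restores the
caller's RNG state afterwards), and identical (config, seed) gives
byte-identical bundles; writers emit expression values with 17 significant
digits so the write/read round trip is exact. Degenerate inputs error
early and by name: empty reference databases, invalid residues or bases,
overlapping chromosome plans, zero transcript lengths, all-zero
intensities.

## Known limitations

* Full dynamic programming, no heuristic seeding: desk-scale genomes only.
* Single-exon gene models; spliced spidroins (rare but real) are out of
  scope, as are Iso-seq spliced alignment and browser curation.
* The repair search assumes the repeat grammar downstream of a break; a
  frameshift in a terminal domain is flagged, not fixed.
* Type assignment is homology voting, not phylogenetics; it cannot place
  a genuinely novel spidroin family except as "other".
* The synthetic expression design has no library-size variation, batch
  structure or dispersion trend — it tests bookkeeping, not inference.
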