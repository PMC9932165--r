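# spidroinr

Spider silk proteins (spidroins) are among the hardest genes in any genome
to annotate: a conserved ~100–150-residue N- and C-terminal domain flank a
huge, low-complexity tandem-repeat array written in a small motif
vocabulary — poly-alanine `(A)n`, `(GA)n` dyad arrays, `GGX`, `GPGXX`,
`XQQ`. Gene predictors fragment the arrays, and a single-base indel
silently frameshifts half a gene. `spidroinr` implements the full
annotation and silk-composition workflow for people studying silk-gland
biology:

* **discovery** — Smith–Waterman search of a proteome against a
  terminal-domain reference library, with Karlin–Altschul E-values
  (`E = K·m·n·e^(−λS)`, λ = 0.267, K = 0.041, BLOSUM62, gaps 11/1) and an
  `E < 1e−10` cutoff, collapsed to one best hit per gene;
* **architecture** — tandem-repeat detection by self-alignment
  periodicity (`m(ℓ) = #{i : s[i] = s[i+ℓ]}/(L−ℓ)`), silk motif counting,
  and the tri-partite call (full-length ⟺ N-domain + repeat array +
  C-domain);
* **gene-model reconstruction** — six-frame translated anchor search on
  the genome, greedy N/C anchor pairing, and frameshift repair that
  *searches* for the breakpoint by maximizing silk-motif coverage around
  each candidate single-nucleotide shift;
* **catalog** — type assignment by bit-score vote, per-type tallies,
  single-linkage chromosomal grouping (gap ≤ 1 Mb, size ≥ 3);
* **expression** — FPKM, τ tissue specificity
  (`τ = Σ(1 − x_i/x_max)/(N−1)`), silk transcriptional load per gland
  segment, segment-specific gene screens, annotation-integration filter;
* **silk composition** — tryptic digestion, iBAQ quantification
  (intensity / theoretical 7–30-aa peptides) with shares, top-k cumulative
  abundance, proteome and metabolite tallies;
* **synthetic data** — a seeded generator producing genome + GFF3 +
  proteome + expression + ground truth with the statistical structure the
  analysis assumes (motif-grammar repeats, partial and
  frameshift-corrupted loci, low-complexity decoys, cognate-gland
  expression), so the whole pipeline is testable offline.

## Worked example

The numbered scripts under `analysis/` run the whole study on a synthetic
bundle (seed 42) and write their tables under `results/`:

```sh
Rscript analysis/01_simulate_bundle.R
Rscript analysis/02_discover_spidroins.R
Rscript analysis/03_assemble_gene_models.R
Rscript analysis/04_classify_and_group.R
Rscript analysis/05_expression_profiles.R
Rscript analysis/06_silk_composition.R
```

Selected output actually printed by those scripts:

```
silk_bundle: 3 chromosome(s) (160,272 nt), 13 spidroins, 50 decoys, seed 42
24 hits below E=1e-10; 13 distinct genes
candidates with spidroin architecture: 13 (recall 1.00, precision 1.00 vs truth)
completeness matches truth for 13/13 loci; repaired loci: MaSp1b

chromosomal groups (single linkage, gap <= 1 Mb, size >= 3):
  group chromosome label size start   end                            members
1     1       chr4  MaSp    4  1430 51698        MaSp1a,MaSp1b,MaSp1c,MaSp2e
2     2       chr6  MiSp    5 18027 45572 MiSp-a,MiSp-b,MiSp-e,MiSp-c,MiSp-d
3     3       chr7  MaSp    4  4565 47119        MaSp2b,MaSp2d,MaSp2c,MaSp2a

dragline silk transcriptional load: Tail 99.2%, Sac 99.4%, Duct 13.0%
top-5 cumulative share: 79.4% of total iBAQ
proteome: 28 proteins (10 spidroins, 18 nonspidroin)
metabolome: 180 metabolites, 109 classified into 10 categories
```

Reading the numbers: all 13 simulated spidroins are discovered from the
proteome with no decoy false positives; the genome-level reconstruction
reproduces every gene with the correct completeness, including the
frameshift-corrupted `MaSp1b` (repaired to ~99% identity, the single edit
landing inside the true repeat span) and the C-truncated `MaSp2c`
(correctly reported partial, not "repaired"); the three configured
chromosome groups come back with their exact sizes and labels; and the
dragline-silk worked-example tables reproduce the published catalog
structure (28 proteins, 10 spidroins, top five components at 79.4% of
total iBAQ).

## Documentation

The methods vignette (`vignettes/spidroin-discovery.Rmd`) explains the
models and their assumptions, every tunable threshold with its default and
rationale, what the synthetic generator does and does not emulate, and the
package's design decisions and limitations.
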