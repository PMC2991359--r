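---
title: "Comparative genomics of a small bacterial clade: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative genomics of a small bacterial clade: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cladecompare)
```

`cladecompare` implements the desk-scale comparative analyses with which a
newly sequenced bacterial genome is usually characterised against a handful
of relatives: genome summary statistics and windowed composition signatures,
protein best-hit filtering and reciprocal-best-hit (RBH) orthology,
pan-genome partitioning, gene-order synteny, an insertion-sequence (IS)
census, and circular-atlas track export. Its motivating use case is a
food-associated *Arthrobacter* chromosome compared with three environmental
relatives — a genome with a strikingly expanded mobilome, a reduced
carbohydrate-catabolism repertoire, and iron-acquisition islands with offset
G+C — but every stage is generic.

This vignette records the methods, their assumptions, the parameters that
matter, and the design decisions that were genuinely open.

## The data model

A genome is a `genome_annotation`: an ordered list of `replicon` objects
(sequence plus a *declared* topology — circular and linear molecules behave
differently in windowed statistics and upstream scans, and topology is never
guessed from sequence) and a feature table in 1-based inclusive coordinates,
the GenBank/EMBL convention. The single place another convention appears is
the atlas track writer, which emits the 0-based half-open dialect that track
pipelines expect; that converter is the sole authority for the translation.

Features carry the annotation columns the comparative stages need:
`is_transposase` (transposases are excluded from orthology, pan-genome and
synteny, since IS-borne genes recombine independently of the backbone),
`is_pseudo`, semicolon-separated COG category letters, domain-family IDs
(e.g. `PF00356` to count LacI-family regulators), and the protein sequence,
translated from coordinates with the bacterial genetic code (table 11) when
absent. Internal stop codons in a non-pseudo CDS warn rather than fail:
real annotation exchange files contain them.

## Composition signatures

`windowed_gc()` and `gc_skew()` tile each replicon with fixed windows
(default 10 kb, the usual atlas resolution). G+C ignores `N` in both
numerator and denominator; an all-`N` window is `NA`. Skew is
$(G-C)/(G+C)$, with the convention that a window without any G or C scores
0 rather than propagating an undefined value. On circular replicons the
final window wraps the origin so that every window holds exactly
`window_bp` bases; on linear replicons the final window is simply shorter,
which keeps the length-weighted mean of window values identical to the
whole-replicon value.

`region_gc()` measures the span between two loci — the standard check for
horizontally acquired islands, whose base composition is offset from the
genome background. `upstream_motif_scan()` searches the coding-strand
upstream region of every CDS for an IUPAC motif (both orientations, optional
mismatches; matching is delegated to `Biostrings`). Positions follow the
convention that the base immediately 5′ of the start codon is −1 and a hit
is reported at its 5′-most base; this is the convention under which
published iron-box positions (−32 and similar) reproduce, and the package
fixes it explicitly because operator-site literature rarely states it.

## Similarity and orthology

`align_proteins()` is a desk-scale all-vs-all local aligner:
Smith–Waterman via `Biostrings::pairwiseAlignment` with BLOSUM62 and affine
gaps (open 11, extend 1), reported in the common 12(+2)-column tabular hit
format. E-values use the Karlin–Altschul formula
$E = K m n e^{-\lambda S}$ with the ungapped BLOSUM62 constants
($K = 0.041$, $\lambda = 0.267$) and search space $mn$ = query length ×
total subject length. Using ungapped constants for gapped scores is a
deliberate, documented approximation: it is monotone in the score, accurate
enough to impose a 10⁻³ significance cutoff on toy-scale sets, and it keeps
the aligner dependency-free. Externally computed hit tables
(`read_hit_table()`) remain authoritative for real genomes.

`filter_best_hits()` applies the classical retention rule — e-value
strictly below 10⁻³ and alignment overlap strictly above 80% — and keeps
one best hit per query. The overlap denominator is the query length by
default; the literature rarely says query vs subject vs shorter, so a
`"shorter"` basis is available as a switch. Ties are broken by e-value,
then bitscore, then lexicographic subject id, making the map deterministic
under input permutation. Orthologs are reciprocal best hits
(`reciprocal_best_hits()`), which yields a partial matching (injective both
ways) per genome pair.

`pan_partition()` assigns every non-transposase focal gene a presence
pattern over the other genomes — present in genome X iff the gene occurs in
the focal–X ortholog map — and derives Venn-cell labels (`core`,
`specific`, or the subset of sharing genomes). Membership is deliberately
per-pair: orthology is defined pairwise, pattern counting reproduces a Venn
diagram directly, and no transitivity across genomes is assumed. A strict
`clique` mode is provided for sensitivity analysis; it additionally demands
that the partner genes in every pair of pattern genomes be orthologs of one
another, and demotes non-transitive patterns to `specific`. COG profiles
weight a gene carrying $k$ categories $1/k$ per category so proportions over
annotated genes sum to one; unannotated genes are reported separately.

## Gene-order synteny

`align_gene_trains()` detects conserved gene trains between two gene orders
by local dynamic programming over gene indices. A column aligning genes
$(a, b)$ scores `match` (+2) when the pair is orthologous, `mismatch` (+1)
when it is homologous-but-not-orthologous (a best hit in either direction
under the same thresholds, without reciprocity), and is *forbidden*
otherwise — unrelated genes must be gapped (−1 each), never aligned. The
alignment runs against the second order as given and reversed (orientation
`inverted`); blocks are extracted greedily by descending score with the
aligned genes of each extracted block masked, so no gene is matched twice.
Blocks with fewer than 3 ortholog columns or score below 4 are discarded.

Two design points deserve a note:

* **Scoring and thresholds are package choices.** The approach — DP over
  gene orders with gaps and homology-level mismatches — is standard, but no
  published parameterisation exists for it; +2/+1/−1 with a 3-match minimum
  was chosen so that a three-ortholog train with one gap is still reported,
  and everything is config-exposed.
* **Strand awareness (default on).** A same-orientation column also
  requires the two genes to lie on the same strand; an inverted column
  requires opposite strands. A physical inversion flips both order and
  strand, so this is the gene-level signature of a true inversion — and it
  is what prevents a long flanking collinear block from profitably
  "stealing" a single interior gene out of a reversed segment (crossing a
  reversed run of length $L$ with one stolen match scores $4-2L$, always
  better than $-2L$ without the strand rule). With strand awareness the
  planted inversions of the synthetic clade are recovered with exactly the
  planted gene set. The flag can be disabled for strand-free data, and the
  test suite checks the DP against an independent collinear-chain
  enumeration in both modes.
* **Masking masks aligned genes only.** Genes a chain jumps over as gaps
  are not "in" that block; masking them would let a collinear block that
  crosses an inversion consume the inverted genes and suppress the inverted
  block entirely.

Circular chromosomes are linearised at the origin; `wrap_b = TRUE` doubles
the second order to catch origin-spanning blocks. `dotplot_export()` emits
the classic dot-plot records (gene midpoints, red for strand-concordant
pairs, blue otherwise).

## Mobilome

IS copies are ingested as annotation (`read_is_table()`) together with a
catalog of reference lengths per IS. `classify_completeness()` calls a copy
complete when it reaches 90% of its reference length (boundary inclusive);
the threshold is a package invention — curated databases judge completeness
case by case, and ingested labels always override the computation.
`is_census()` tallies copies by family and completeness and reports the
fraction of each replicon covered by the *union* of IS intervals
(overlapping or split copies are not double-counted; the denominator is the
single replicon's length). `is_cluster_scan()` slides a 200-kb window at
10-kb steps and merges windows holding ≥ 10 copy starts into maximal
regions — defaults chosen to flag hotspots of the density reported for
IS-expanded chromosomes, and config-exposed. `nested_is_detect()` reports
"russian-doll" insertions: a complete element lying strictly between two
fragments that share a parent label, with the fragments' facing ends within
10 bp of the element's ends — the arithmetic signature left when a later
insertion splits an earlier copy.

## The synthetic clade generator

Real accession-based inputs are optional everywhere; the test bed is
`generate_clade()`, which emits a clade with known ground truth in exactly
the formats the readers consume.

The model: ancestral proteins are sampled i.i.d. over the 20 amino acids
(gamma-distributed lengths, mean 150, sd 30 residues; leading methionine
fixed); descendants mutate independently along a **star phylogeny** at a
per-site substitution probability per branch (default 0.02) — pairwise
orthology needs no tree structure, and a star keeps recall analysis simple.
CDSs are back-translated with a genome-specific synonymous codon bias
calibrated (by solving a one-parameter weight $w^{gc(codon)}$) so the
expected coding G+C hits the genome target (default 60 mol%); intergenic
spacers (geometric, mean 100 bp — arbitrary and config-exposed) are sampled
at the same rate. Each genome is one circular replicon.

Defaults describe the study conditions the package is exercised under: four
genomes, 50 core families, 10 strain-specific genes per genome, one 5-gene
subset shared by genomes 1–3, one planted inversion (4–8 genes) in genome
2, an IS expansion in the focal genome (12 insertion events vs 3
elsewhere, 3 synthetic IS families, 20% truncation and 20% nesting
probability), and one ~10-kb island at +10 G+C points in the focal genome.

Three generator details exist to make the planted truth *cleanly*
recoverable, and are worth stating:

* **Inversions are planted on runs that are near-contiguous in both
  genomes** (shared-gene runs whose focal-side span exceeds the run length
  by at most 2). A run interrupted focal-side by the island or a crowd of
  strain-specific genes would be a compound rearrangement, not an
  inversion, and no method could return "exactly the planted genes".
  Inverted runs flip both order and strand.
* **Islands are offset in amino-acid composition, not just codon usage.**
  Synonymous choice alone cannot push coding G+C past ~66%, so a +10-point
  island over a 60% background also shifts amino-acid composition toward
  GC-rich codons' residues (the GARP shift real high-G+C genes show). The
  island's internal spacers receive an exactly compensating G/C
  composition, so the island span meets target + offset by construction
  rather than within ~0.5 points of binomial noise. Consequently the
  genome-level G+C target describes the *background*; an island of a tenth
  of a desk-scale genome visibly raises the whole-genome mean, exactly as
  intended.
* **Fragmented IS copies arise mechanistically**: a nesting insertion
  splits an earlier complete copy into two fragments sharing a parent
  label, so the nested-insertion detector has realistic positives. Emitted
  IS tables carry `unset` completeness — classification is the pipeline's
  job, and the census is compared against the generator's own bookkeeping.

`score_recovery()` computes precision/recall for ortholog maps (empty
inference: precision 1, recall 0 by convention), exact-cell agreement for
partitions, exact-gene-set recovery flags for planted inversions, and count
agreement for the census.

What passing these tests does *not* show: the generator has no indels
within proteins, no codon-level selection, no rearrangements beyond clean
inversions, no paralogous families, and genomes of tens of kilobases. Exact
RBH recovery at zero mutation demonstrates the machinery, not performance
on diverged real proteomes; the 5%-substitution recall check (≥ 0.95) is
the only stress applied.

## Numerical and reporting conventions

* Percentages in reports are printed to one decimal, rounded half away
  from zero, always computed from unrounded values; a zero denominator
  prints `NA`.
* Best-hit and block extraction tie-breaks are total orders (documented
  above), so every pipeline output is byte-identical under a fixed seed.
* The problem sizes used throughout the test suite and the acceptance
  script — the default clade above, 500 random ≤ 8-gene orders for the
  DP-vs-chain-enumeration equivalence, 100 random protein pairs for the
  significance check — were chosen as the smallest sizes at which each
  property is meaningfully exercised.

## Pipeline and known limitations

`run_pipeline()` drives the stages (`simulate`, `summarize`, `orthologs`,
`pangenome`, `synteny`, `mobilome`, `scan-motif`, `atlas`, `score`) from a
YAML config with the thresholds above as defaults; a thin Rscript wrapper
(`inst/cli/cladecompare.R`) maps validation and usage errors to exit codes
1 and 2.

Limitations: the GenBank reader handles the flat-file subset bacterial
annotation exchange needs (single-interval locations, `complement()`, the
common qualifiers) and is not a general parser; the built-in aligner is not
a BLAST replacement and its e-values are approximate; pan-genome cells
depend on the orthology thresholds and on pattern-vs-clique mode, and
published Venn counts for real genome sets are not asserted to reproduce;
Fig-style synteny output is qualitative — the original tools' block
parameters are unpublished.
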