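---
title: "Pan-genome construction and curation with panmatrix: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pan-genome construction and curation with panmatrix: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panmatrix)
```

This vignette documents the models, parameters and design decisions behind
`panmatrix`, in the spirit of a methods section: what is computed, under
which assumptions, and where the genuinely open choices were made.

## The SuperGenome coordinate system

A multiple whole-genome alignment in XMFA format consists of blocks; each
block aligns intervals of a subset of the genomes, possibly
reverse-complemented, with gap characters padding the columns. The
SuperGenome concatenates the columns of all blocks *in file order* into a
single axis `1..total_length` and stores, per genome, two maps:

* **forward**: genome position → signed column. The sign is negative when
  the genome's block entry is on the reverse strand, i.e. the genome is
  reverse-complemented at that column; within such an entry, genome
  positions descend as columns ascend.
* **backward**: column → genome position, `NA` where the genome has a gap
  or is absent from the block.

Assumptions: coordinates are 1-based inclusive (the Mauve convention); an
entry with coordinates `0-0` marks a genome absent from a block; per
genome, the intervals covered by different blocks must be disjoint
(violations raise an error rather than silently overwriting the map).
Positions covered by no block are *unaligned* and map to `NA`. The maps
are stored densely per genome, so queries are O(1); for bacterial genomes
(a few Mb) this costs a few integer vectors per genome.

Block order is a genuinely open choice: when an aligner reports
rearranged locally-collinear blocks there is no canonical linear order.
We use file order, which makes the axis reproducible from the input file
alone; reordering, if ever needed, amounts to permuting blocks before
`build_supergenome()`.

## From annotations to pan genes

Gene annotations (GFF3, one file per genome; `gene` records by default)
are lifted through the forward map. Three decisions matter:

* **Strand**: records without a strand are rejected (with a warning),
  because strand orients the presence glyph. The lifted strand is the
  annotation strand, flipped when the carrying block aligns the genome in
  reverse — so an inversion annotated on the minus strand inside a
  forward-aligned block keeps its minus strand in the matrix, while a
  whole region aligned in reverse does not artificially flip its genes.
* **Multi-block genes** are lifted to the interval of the block containing
  the majority of their aligned bases. A pan gene holds a single
  SuperGenome interval ("one gene, one cell"); splitting genes across
  intervals would break that invariant. Genes with no aligned base at all
  are dropped with a warning.
* Ambiguity characters other than A/C/G/T are treated as `N` and never
  count as matches in similarity computations.

**Overlap grouping.** Two lifted genes are connected when their intervals
share at least `min_overlap` columns (default **1**: any shared column is
evidence of common alignment; the similarity stage, not the overlap
stage, is responsible for separating false joins). Candidate ortholog
groups are the connected components of this graph, computed with
interval-overlap queries (IRanges) and graph components (igraph). Note
that overlap is therefore transitive within a component, and abutting
intervals (no shared column) do not connect.

**Pairwise identity.** Sequence similarity is nucleotide global-alignment
identity: Needleman–Wunsch with match +1, mismatch −1, linear gap −2
(Biostrings), identity = identical A/C/G/T columns divided by alignment
length. This is symmetric and lies in [0, 1]. The metric and its
threshold are configuration keys (`identity_threshold`, default **0.5**)
— half of the alignment columns matching is a deliberately permissive
cut-off, meant to keep diverged and truncated orthologs together while
excluding unrelated overlapping features.

**Component resolution.** Within a component, groups are merged by greedy
average-linkage agglomeration: starting from singletons, repeatedly merge
the pair of groups with the highest average inter-group identity, allowed
only when their genome sets are disjoint (the pan gene constraint: at
most one gene per genome) and the average is at least the threshold. Ties
are broken deterministically by the smaller merged SuperGenome start,
then the smaller genome roster index. Whether merges should be scored by
average, minimum or single linkage is not dictated by the construction;
average linkage is this package's declared default because it is robust
to a single diverged pair and easy to validate: on components of ≤ 8
genes the greedy result is compared in the test suite against exhaustive
enumeration of all genome-feasible set partitions under the score
Σ within-group pairs (identity − threshold). On components whose
similarities are bimodal — ortholog copies well above the threshold,
unrelated genes well below, which is what alignment-derived components
look like — the greedy result ties the enumerated optimum.

Pan genes are ordered ascendingly by (super start, super stop) and receive
identifiers `PG000001`, `PG000002`, … in that order; the consensus
description is the most frequent member description, ties resolved
lexicographically.

## The matrix model and curation algebra

The matrix is an ordered list of pan genes over a fixed genome roster.
Classification is purely by member count: *n* members = core, 1 = orphan,
otherwise dispensable; the three counts always sum to the number of pan
genes.

**Aggregation** merges two or more *complementary* rows — rows whose
member genome sets are pairwise disjoint. Strand differences never block
a merge, since orthologs change strand through inversions. The merged row:

* takes a fresh identifier `AGN<serial>` with display label
  `AGN<serial> (k)`, where `k` counts the original pan genes folded in
  (nested aggregates contribute their own constituent counts). Serials
  are session-monotonic integers — the label alone does not have to be
  unique, but replayable histories need unique identifiers;
* sits at the row of the constituent with the smallest super start,
  preserving the positional ordering (row rank is the fallback for
  matrices loaded without coordinates);
* keeps its constituents in memory, so **deaggregation** restores them
  exactly (identifiers, row positions, memberships).

**Undo** restores the state before the last event from an internal
snapshot stack. The history is an *append-only* audit log: undo appends a
compensating event rather than truncating, so an exported history is a
faithful record and `replay_history()` on the originally loaded matrix
reproduces the current state, including AGN serial assignment.
Consequences worth noting: undo information lives only in the session
(files store the curated state, not the undo stack), and a matrix
round-tripped through `write_panmap()`/`read_panmap()` keeps AGN
identifiers but not their constituent lists.

**Candidate detection** quantifies the disrupted-pan-gene pattern: two
rows within `window` row ranks of each other (default **2** — "direct or
very close neighbourhood" is not a number, so it is a parameter), passing
the complementarity test, with matching annotation (equal non-empty
TIGRFAM families, case-insensitively equal consensus descriptions, or
either). Candidates are emitted as pairs only — chains are handled by
repeated application, which keeps each step validated — ranked by row
distance then combined size, both deterministic. The number of core genes
directly flanking a pair is reported as context (conserved regions make
disruption more likely) but never used as a filter, since a ranking
beyond the declared key would be invented.

## File formats

Two tab-separated pan-map dialects are supported. The *generic* dialect is
a header of genome names plus one identifier column; cells hold
`gene_id` or `gene_id:-` (strand suffix optional, `+` assumed). The
*pangee* dialect adds coordinates and descriptions: `pan_id`,
`super_start`, `super_stop`, `consensus_description`, then a
`gene_id`/`strand`/`description` triplet per genome. The exact column
layout of this richer dialect is this package's own declaration — it
houses every field the model carries; it is not a claim about any other
tool's file layout. Writers emit UTF-8, tab-separated, unquoted rows and
never reorder rows or columns; saving uses the dialect the matrix was
loaded from unless overridden. TIGRFAM assignment tables are
`gene_id`/`tigrfam_id`/`description`; one family is kept per gene (first
wins) — multi-domain assignment is out of scope.

## Rendering

Present genes draw as isosceles-triangle glyphs, apex up for the forward
strand and down for the reverse; absences stay blank. Colour schemes:
uniform presence colour; strand (forward/reverse colours, which makes a
genome annotated with an inconsistent strand convention stand out as a
uniform column); or TIGRFAM, using 20 colours with hues `i/20`,
`i = 0..19`, at fixed saturation 0.65 and brightness 0.85 (only hue
equidistance is inherent to the scheme; saturation and brightness are
overridable parameters). Families map to colours via a stable 32-bit
string hash modulo 20 — with hundreds of families repetitions are
unavoidable, and a hash keeps the assignment reproducible across
sessions, which session-order assignment would not. The group-size column
is black by default or classification-coloured: blue core, red orphan,
and dispensable sizes on a linear red→blue RGB gradient from size 2 to
size *n* − 1. Aggregated rows are highlighted in the row-header margin.

The renderer produces a resolution-independent element list; the SVG
serialiser is purpose-built so that identical matrix and configuration
yield byte-identical output (fixed number formatting, no timestamps),
which makes figures diffable. PDF and the bitmap formats (PNG, JPEG,
TIFF) draw the same element list through R's graphics devices at one
pixel per document unit.

## Synthetic data: what it emulates, and what it does not

`make_toy_dataset()` writes toy genomes as concatenations of gene loci
separated by conserved spacers, together with their *true* alignment
(the generator knows the homology, so no aligner runs), GFF3 annotations,
TIGRFAM tables and the ground-truth matrix. Core loci appear in every
genome with up to 5% random substitutions per copy (keeping copies far
above the 0.5 identity threshold, as ortholog copies of one species are);
orphans are genome-private loci; dispensable loci go to random proper
subsets. Inversions reverse-complement one genome's copy in place and
annotate it on the minus strand. Truncations emulate a frameshift: an
extra adenine inserted into a homopolymer, the annotation shortened to a
premature stop (~45% of the locus), and the copy emitted as a private
alignment block — producing exactly the disrupted pattern (orphan next to
complementary group, same annotation) that curation is meant to catch.
An optional block-split perturbation cuts shared blocks at random
columns, emulating aligner fragmentation; coordinates and grouping are
invariant to it by construction of the majority-block lift.

What the generator does **not** emulate: realistic sequence evolution
(no phylogeny, no rate heterogeneity, no indels within aligned blocks of
the toy set — random gap placement is exercised by the separate
`make_random_alignment()` generator), misassemblies, or aligner error
beyond block splitting. Passing the recovery tests therefore shows the
machinery is correct on data whose alignment is right; it does not show
robustness to a wrong alignment, which is precisely the situation the
interactive curation features exist for.

`make_synthetic_matrix()` skips sequences entirely and builds a matrix of
an exact core/orphan/dispensable composition; the `saureus_like` preset
uses a 32-genome composition (1846/3848/2953) typical of a large
staphylococcal strain collection. Dispensable group sizes are uniform on
[2, n−1].

## Numerical and degenerate-input choices

* All generator functions take an integer seed and are byte-deterministic
  for a fixed seed.
* `sample()`'s scalar-first-argument behaviour is avoided throughout with
  an explicit vector-resampling helper.
* Deterministic tie-breaks everywhere a choice could depend on iteration
  order: component order by (min super start, roster index), merge ties
  by (average identity, merged super start, roster index), candidate
  ranking by (row distance, combined size, row index).
* Degenerate inputs: empty matrices summarise to zeros, render to an
  empty canvas with headers, and write header-only files; empty TIGRFAM
  tables are valid; an empty alignment-block list is an error.
* Matrices loaded from the generic dialect have no coordinates
  (`NA` super positions); aggregation placement then falls back to row
  rank.

## Validation scale

The shipped test suite and the acceptance script validate at sizes chosen
to make exhaustive oracles feasible: coordinate round trips on 50 random
gapped alignments (2–5 genomes, blocks up to 150 columns, reverse strands
and unaligned tails included) against an independent column-scan oracle;
grouping on 200 random planted components of up to 8 genes against
exhaustive partition enumeration; end-to-end truth recovery on toy sets
of 3–5 genomes with 6–8 core loci; curation recall on every planted
disruption; aggregation algebra on 100 random matrices with random event
sequences followed by full undo and byte-level file comparison.

## Known limitations

* One TIGRFAM family per gene; multi-domain proteins lose information.
* Genes lifted across blocks keep only their majority-block interval;
  orthologs whose majority blocks differ can fail to overlap and then
  appear as complementary rows — detectable by curation, not prevented.
* The greedy resolution is validated against the exhaustive optimum only
  for the bimodal similarity structure described above; adversarial
  similarity matrices near the threshold can make greedy and optimum
  diverge.
* Protein-level similarity, paralog family reconstruction beyond the
  one-gene-per-genome constraint, and pan-genomes of non-gene features
  are out of scope, as are running the aligner or the HMM scans
  themselves — their outputs are this package's inputs.
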