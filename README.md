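# panmatrix

Pan-genome construction, curation and visualisation from multiple
whole-genome alignments.

## The problem

The pan-genome of a bacterial species is the union of all genes found in
any strain. Given a set of annotated genomes, the central task is to group
the genes into *pan genes* — orthologous gene groups with at most one
member per genome — and to classify each group as **core** (present in all
*n* strains), **orphan** (present in exactly one) or **dispensable**
(present in a proper subset of size ≥ 2). Reciprocal-BLAST approaches
ignore gene neighbourhood and risk clustering paralogs; `panmatrix`
instead works from a multiple whole-genome alignment, which encodes
synteny directly.

The alignment (XMFA, as produced by progressiveMauve) is turned into a
**SuperGenome**: the alignment columns of all blocks, concatenated in file
order, form a single shared coordinate axis with a bidirectional map to
every genome's own coordinates. A position *p* of genome *g* maps to a
signed column *to_super(g, p)* (negative when *g* is reverse-complemented
at that column), and every column maps back through *to_genome*, so that
*to_genome(to_super(p)) = p* wherever *p* is aligned.

Pan genes are then built in three steps:

1. **Lift-over** — each gene's start/stop is transferred into SuperGenome
   columns (genes spanning several blocks take the interval of the block
   holding the majority of their aligned bases).
2. **Overlap grouping** — genes whose lifted intervals share at least
   `min_overlap` columns (default 1) are connected; connected components
   are candidate ortholog groups.
3. **Identity refinement** — within a component, groups are merged
   greedily by highest average pairwise identity (Needleman–Wunsch global
   alignment, match +1 / mismatch −1 / gap −2; identity = matching
   columns / alignment length), subject to the pan gene constraint that no
   genome contributes two genes and the average identity is at least
   `identity_threshold` (default 0.5).

The resulting pan genes are ordered ascendingly by their appearance on the
SuperGenome axis and form a presence–absence matrix (rows = pan genes,
columns = genomes) that supports curation: complementary groups — sharing
no genome — can be **aggregated** into one `AGN` row (and deaggregated, or
undone, with a replayable history), and likely *disrupted* pan genes
(close rows, complementary membership, same TIGRFAM family or consensus
description) are detected automatically as aggregation candidates. The
matrix renders as a glyph matrix — one up/down arrow per present gene,
oriented by strand — exportable to SVG, PDF, PNG, JPEG and TIFF.

## Worked example

Everything below runs offline: the synthetic-data generator builds toy
genomes with known ground truth, including a planted truncation — an
extra adenine in a homopolymer shifts the reading frame, so one genome's
copy is annotated short and falls out of the shared alignment block.

```r
library(panmatrix)

dir <- file.path(tempdir(), "toy")
res <- make_toy_dataset(dir, seed = 42, n_genomes = 3, n_core = 5,
                        n_orphan_per_genome = 1, n_dispensable = 2,
                        truncation_rate = 0.4)

sg <- build_supergenome(parse_xmfa(res$xmfa), res$genome_lengths)
sg
#> SuperGenome: 3 genomes, 2746 alignment columns, 23 blocks

anns <- lapply(names(res$gff), function(g) read_gff(res$gff[[g]], g))
pan <- build_pangenome(sg, anns, sequences = res$sequences)
pan <- attach_tigrfam(pan, read_tigrfam(res$tigrfam))
summary(pan)
#> genomes:     3
#> pan genes:   12
#> core:        3
#> orphan:      5
#> dispensable: 4
```

Two of the five core loci were disrupted by the planted truncations: each
shows up as an orphan next to a complementary 2-of-3 group. The candidate
detector finds exactly those pairs:

```r
find_candidates(pan, window = 2, require = "either")
#>   pan_id_i pan_id_j              reason combined_size ...
#> 1 PG000002 PG000003 tigrfam+description             3
#> 2 PG000011 PG000012 tigrfam+description             3

pan2 <- aggregate(pan, c("PG000002", "PG000003"))
pan_label(pan2$pangenes[["AGN1"]])
#> [1] "AGN1 (2)"
summary(pan2)
#> genomes:     3
#> pan genes:   11
#> core:        4      # the re-joined locus is core again
#> orphan:      4
#> dispensable: 3
```

Aggregations are validated (groups sharing a genome are rejected),
reversible (`deaggregate`, `undo`) and logged (`export_history`,
`replay_history`). `write_panmap` saves the curated matrix in the dialect
it was loaded from; `render_matrix` + `export_image` draw it:

```r
export_image(render_matrix(pan2, render_config(colour_scheme = "tigrfam")),
             "pan.svg")
```

A shell interface wrapping the same functions is installed as
`exec/panmatrix` (subcommands `simulate`, `build`, `stats`, `candidates`,
`aggregate`, `batch`, `render`).

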