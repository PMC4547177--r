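# Pan gene construction: lift gene annotations onto the SuperGenome axis,
# group genes whose lifted intervals overlap, refine groups with pairwise
# nucleotide identity under the one-gene-per-genome constraint, and order
# the resulting pan genes along the SuperGenome.

#' Lift gene annotations into SuperGenome coordinates
#'
#' Transfers each gene's start/stop into the shared alignment coordinate
#' system. A gene whose aligned bases fall into several blocks is lifted to
#' the interval of the block containing the majority of its aligned bases
#' (one gene, one interval). Genes with no aligned base are dropped with a
#' warning. The lifted strand is the annotation strand, flipped when the
#' carrying block aligns the genome in reverse orientation.
#'
#' @param sg A [build_supergenome()] object.
#' @param annotations Annotation data frame (see [read_gff()]) or a list of
#'   such data frames, covering genomes in the roster.
#' @return A data frame of lifted genes with the annotation columns plus
#'   `super_start`, `super_stop` and `lifted_strand`.
#' @export
lift_annotations <- function(sg, annotations) {
  if (is.list(annotations) && !is.data.frame(annotations)) {
    annotations <- do.call(rbind, annotations)
  }
  bad <- setdiff(unique(annotations$genome_id), sg$roster)
  if (length(bad)) {
    stop("Annotations refer to genomes outside the roster: ",
         paste(bad, collapse = ", "))
  }
  block_starts <- sg$block_offsets + 1L
  n <- nrow(annotations)
  super_start <- super_stop <- integer(n)
  lifted_strand <- character(n)
  keep <- logical(n)
  dropped <- character(0)

  for (i in seq_len(n)) {
    g <- annotations$genome_id[i]
    pos <- annotations$start[i]:annotations$end[i]
    mapped <- sg$forward[[g]][pos]
    aligned <- mapped[!is.na(mapped)]
    if (length(aligned) == 0L) {
      dropped <- c(dropped, annotations$gene_id[i])
      next
    }
    cols <- abs(aligned)
    blk <- findInterval(cols, block_starts)
    major <- as.integer(names(which.max(table(blk))))
    in_major <- cols[blk == major]
    super_start[i] <- min(in_major)
    super_stop[i] <- max(in_major)
    reverse_block <- aligned[blk == major][1] < 0L
    ann_strand <- annotations$strand[i]
    lifted_strand[i] <- if (reverse_block) {
      if (ann_strand == "+") "-" else "+"
    } else ann_strand
    keep[i] <- TRUE
  }
  if (length(dropped)) {
    warning(length(dropped), " gene(s) with no aligned base dropped: ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "")
  }
  out <- annotations[keep, , drop = FALSE]
  out$super_start <- super_start[keep]
  out$super_stop <- super_stop[keep]
  out$lifted_strand <- lifted_strand[keep]
  rownames(out) <- NULL
  out
}

#' Group lifted genes into overlap components
#'
#' Two genes are connected when their SuperGenome intervals share at least
#' `min_overlap` columns; components are the connected components of that
#' graph, so overlap is transitive within a component. Components are
#' ordered by (smallest super start, genome roster index) for determinism.
#'
#' @param lifted Data frame from [lift_annotations()].
#' @param min_overlap Minimum number of shared columns (default 1).
#' @param roster Genome roster used for deterministic tie-breaking; defaults
#'   to order of appearance in `lifted`.
#' @return A list of integer vectors indexing rows of `lifted`, each sorted
#'   by (super_start, roster index).
#' @export
overlap_components <- function(lifted, min_overlap = 1L, roster = NULL) {
  if (min_overlap < 1L) stop("min_overlap must be >= 1")
  if (nrow(lifted) == 0L) return(list())
  if (is.null(roster)) roster <- unique(lifted$genome_id)
  ir <- IRanges::IRanges(start = lifted$super_start, end = lifted$super_stop)
  hits <- IRanges::findOverlaps(ir, minoverlap = min_overlap,
                                drop.self = TRUE, drop.redundant = TRUE)
  g <- igraph::make_empty_graph(n = nrow(lifted), directed = FALSE)
  if (length(hits)) {
    g <- igraph::add_edges(g, rbind(S4Vectors::queryHits(hits),
                                    S4Vectors::subjectHits(hits)))
  }
  memb <- igraph::components(g)$membership
  ridx <- match(lifted$genome_id, roster)
  comps <- split(seq_len(nrow(lifted)), memb)
  comps <- lapply(comps, function(ix)
    ix[order(lifted$super_start[ix], ridx[ix])])
  keys <- vapply(comps, function(ix)
    min(lifted$super_start[ix]) * 1e6 + min(ridx[ix]), numeric(1))
  unname(comps[order(keys)])
}

# Substitution matrix over A,C,G,T,N: +1 for an identical A/C/G/T pair,
# -1 otherwise (N never matches, so ambiguity cannot inflate identity).
.NUC_MATRIX <- local({
  bases <- c("A", "C", "G", "T", "N")
  m <- matrix(-1, 5, 5, dimnames = list(bases, bases))
  diag(m) <- 1
  m["N", "N"] <- -1
  m
})

# Map any ambiguity character other than A/C/G/T to N, uppercase.
.sanitize_nuc <- function(x) {
  x <- toupper(x)
  gsub("[^ACGT]", "N", x)
}

#' Global-alignment nucleotide identity
#'
#' Aligns two sequences globally (Needleman-Wunsch; match +1, mismatch -1,
#' linear gap -2) and returns the fraction of alignment columns that are
#' identical A/C/G/T pairs. Ambiguity characters are treated as `N` and
#' never match. The measure is symmetric.
#'
#' @param seq_a,seq_b Non-empty nucleotide strings.
#' @return Identity fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(seq_a, seq_b) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) {
    stop("pairwise_identity requires two non-empty sequences")
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(.sanitize_nuc(seq_a)),
    Biostrings::DNAString(.sanitize_nuc(seq_b)),
    substitutionMatrix = .NUC_MATRIX,
    gapOpening = 0, gapExtension = 2, type = "global")
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  sum(pa == sa & pa != "-" & pa != "N") / length(pa)
}

# Extract a gene's nucleotide sequence from its genome (reverse-complemented
# for annotation strand "-").
.gene_sequence <- function(sequences, genome_id, start, end, strand) {
  s <- sequences[[genome_id]]
  if (is.null(s)) stop("No sequence provided for genome ", genome_id)
  sub <- substring(s, start, end)
  if (strand == "-") {
    sub <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(.sanitize_nuc(sub))))
  }
  sub
}

#' Resolve an overlap component into pan genes
#'
#' Greedy average-linkage agglomeration under the pan gene constraints:
#' starting from singletons, repeatedly merge the pair of groups with the
#' highest average inter-group identity, allowed only when their genome sets
#' are disjoint and that average is at least `threshold`. Ties are broken by
#' the smaller merged super start, then the smaller genome roster index.
#'
#' @param component Data frame of lifted genes (rows of one overlap
#'   component).
#' @param similarity Symmetric numeric matrix of pairwise identities for the
#'   component's genes (defaults to all 1, i.e. overlap alone decides).
#' @param threshold Minimum average identity allowing a merge.
#' @param roster Genome roster for tie-breaking.
#' @return A list of integer vectors (groups of row indices into
#'   `component`); their union is the whole component.
#' @export
resolve_component <- function(component, similarity = NULL, threshold = 0.5,
                              roster = NULL) {
  k <- nrow(component)
  if (is.null(roster)) roster <- unique(component$genome_id)
  if (is.null(similarity)) similarity <- matrix(1, k, k)
  if (!isTRUE(all.equal(dim(similarity), c(k, k)))) {
    stop("similarity must be a ", k, "x", k, " matrix")
  }
  ridx <- match(component$genome_id, roster)
  groups <- as.list(seq_len(k))

  repeat {
    n_g <- length(groups)
    if (n_g < 2L) break
    best <- NULL
    for (a in seq_len(n_g - 1L)) for (b in (a + 1L):n_g) {
      ga <- groups[[a]]; gb <- groups[[b]]
      if (length(intersect(component$genome_id[ga],
                           component$genome_id[gb]))) next
      avg <- mean(similarity[ga, gb])
      if (avg < threshold) next
      key <- c(-avg,
               min(component$super_start[c(ga, gb)]),
               min(ridx[c(ga, gb)]), a, b)
      if (is.null(best) || .lex_less(key, best$key)) {
        best <- list(a = a, b = b, key = key)
      }
    }
    if (is.null(best)) break
    groups[[best$a]] <- c(groups[[best$a]], groups[[best$b]])
    groups[[best$b]] <- NULL
  }
  groups <- lapply(groups, function(ix)
    ix[order(component$super_start[ix], ridx[ix])])
  keys <- vapply(groups, function(ix)
    min(component$super_start[ix]) * 1e6 + min(ridx[ix]), numeric(1))
  unname(groups[order(keys)])
}

.lex_less <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

#' Build a pan-genome matrix from an alignment and annotations
#'
#' Runs the full construction: lift annotations onto the SuperGenome,
#' connect genes whose lifted intervals overlap, refine every component by
#' pairwise nucleotide identity under the one-gene-per-genome rule, and
#' order the resulting pan genes ascendingly by their appearance on the
#' SuperGenome axis. Identifiers `PG000001`, `PG000002`, ... are assigned in
#' that order. Each pan gene's consensus description is the most frequent
#' member description (ties broken lexicographically).
#'
#' @param sg A `SuperGenome`.
#' @param annotations Per-genome annotations (data frame or list of data
#'   frames).
#' @param sequences Optional named character vector/list of genome sequences;
#'   when given, pairwise identities refine the overlap grouping, otherwise
#'   overlap alone decides.
#' @param min_overlap Minimum shared columns connecting two genes.
#' @param identity_threshold Minimum average identity allowing a merge.
#' @return A `PanGenomeMatrix` whose roster is the SuperGenome roster.
#' @export
build_pangenome <- function(sg, annotations, sequences = NULL,
                            min_overlap = 1L, identity_threshold = 0.5) {
  lifted <- lift_annotations(sg, annotations)
  comps <- overlap_components(lifted, min_overlap = min_overlap,
                              roster = sg$roster)
  groups <- list()
  for (comp_ix in comps) {
    comp <- lifted[comp_ix, , drop = FALSE]
    sim <- NULL
    if (!is.null(sequences) && nrow(comp) > 1L) {
      seqs <- vapply(seq_len(nrow(comp)), function(i)
        .gene_sequence(sequences, comp$genome_id[i], comp$start[i],
                       comp$end[i], comp$strand[i]), "")
      sim <- diag(nrow(comp))
      for (a in seq_len(nrow(comp) - 1L)) for (b in (a + 1L):nrow(comp)) {
        sim[a, b] <- sim[b, a] <- pairwise_identity(seqs[a], seqs[b])
      }
    }
    res <- resolve_component(comp, similarity = sim,
                             threshold = identity_threshold,
                             roster = sg$roster)
    groups <- c(groups, lapply(res, function(ix) comp_ix[ix]))
  }

  starts <- vapply(groups, function(ix) min(lifted$super_start[ix]), 0L)
  stops <- vapply(groups, function(ix) max(lifted$super_stop[ix]), 0L)
  ord <- order(starts, stops)
  pgs <- vector("list", length(groups))
  for (r in seq_along(ord)) {
    ix <- groups[[ord[r]]]
    rows <- lifted[ix, , drop = FALSE]
    rows <- rows[order(match(rows$genome_id, sg$roster)), , drop = FALSE]
    members <- stats::setNames(lapply(seq_len(nrow(rows)), function(i) list(
      gene_id = rows$gene_id[i],
      strand = rows$lifted_strand[i],
      description = rows$description[i],
      tigrfam_id = NA_character_)), rows$genome_id)
    pgs[[r]] <- new_pangene(
      pan_id = sprintf("PG%06d", r),
      members = members,
      super_start = starts[ord[r]],
      super_stop = stops[ord[r]],
      consensus_description = .consensus(rows$description))
  }
  new_pan_matrix(sg$roster, pgs, dialect = "pangee")
}
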