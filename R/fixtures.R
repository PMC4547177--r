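# Deterministic synthetic data: toy genome sets with shared, strain-specific
# and dispensable genes (plus inversions and truncation-disrupted loci),
# their true alignment as XMFA, GFF3 annotations, TIGRFAM tables and the
# ground-truth pan-genome matrix; random gapped alignments for coordinate
# property tests; and direct synthesis of pan-genome matrices of a given
# core/orphan/dispensable composition.

.DESC_VOCAB <- c(
  "GMP synthase", "DNA gyrase subunit A", "elongation factor Tu",
  "cell division protein FtsZ", "ABC transporter ATP-binding protein",
  "30S ribosomal protein S4", "DNA polymerase III subunit alpha",
  "phosphoglycerate kinase", "penicillin-binding protein 2",
  "transcription termination factor Rho")

# sample() treats a length-1 numeric first argument as 1:x; this picks
# uniformly from the given vector regardless of its length
.resample <- function(x, size = 1L) x[sample.int(length(x), size)]

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n_mut <- round(length(chars) * rate)
  if (n_mut == 0L) return(seq)
  at <- sample(length(chars), n_mut)
  for (i in at) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  }
  paste(chars, collapse = "")
}

.revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Write alignment blocks as an XMFA file
#'
#' @param blocks Blocks in the structure produced by [parse_xmfa()] (with or
#'   without the roster attribute).
#' @param path Output path.
#' @param wrap Sequence line width.
#' @return `path`, invisibly.
#' @export
write_xmfa <- function(blocks, path, wrap = 80L) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (b in blocks) {
    for (e in b$entries) {
      writeLines(sprintf("> %s:%d-%d %s", e$genome_id, e$start, e$end,
                         e$strand), con)
      s <- e$seq
      starts <- seq(1L, nchar(s), by = wrap)
      writeLines(substring(s, starts, pmin(starts + wrap - 1L, nchar(s))),
                 con)
    }
    writeLines("=", con)
  }
  invisible(path)
}

.write_gff3 <- function(ann, genome_id, genome_length, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf("##sequence-region %s 1 %d", genome_id, genome_length),
             con)
  for (i in seq_len(nrow(ann))) {
    writeLines(paste(
      genome_id, "panmatrix", "gene", ann$start[i], ann$end[i], ".",
      ann$strand[i], ".",
      sprintf("ID=%s;product=%s", ann$gene_id[i], ann$description[i]),
      sep = "\t"), con)
  }
  invisible(path)
}

.write_fasta <- function(seq, name, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste0(">", name), con)
  starts <- seq(1L, nchar(seq), by = 70L)
  writeLines(substring(seq, starts, pmin(starts + 69L, nchar(seq))), con)
  invisible(path)
}

#' Generate a toy genome data set with known pan-genome truth
#'
#' Builds `n_genomes` toy genomes sharing `n_core` gene loci (each copy
#' carrying up to `mutation_rate` random substitutions), `n_orphan_per_genome`
#' strain-specific genes per genome, and `n_dispensable` genes present in a
#' random proper subset of genomes. Loci are separated by conserved spacer
#' segments. With probability `inversion_rate` a core locus is annotated on
#' the reverse strand in one genome (an inversion event). With probability
#' `truncation_rate` a core locus is disrupted in one genome: an extra
#' adenine inserted into a homopolymer shifts the reading frame, the
#' annotated gene is truncated to a premature stop, and the copy falls out
#' of the shared alignment block -- so the truth matrix contains the typical
#' disrupted pattern of an orphan next to its complementary group. With
#' probability `block_split_rate` a shared block is additionally split at a
#' random internal column, emulating fragmentation of heuristic aligners.
#'
#' Everything the pipeline consumes is written under `out_dir`: per-genome
#' FASTA and GFF3, the XMFA alignment of the constructed sequences (blocks
#' in locus order, which defines the SuperGenome axis), and a TIGRFAM
#' assignment table. The returned object also carries the inputs in memory
#' plus the ground-truth `PanGenomeMatrix` and the planted disrupted pairs.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed; identical seeds give byte-identical outputs.
#' @param n_genomes Number of genomes (at least 2).
#' @param n_core Number of core loci.
#' @param n_orphan_per_genome Strain-specific genes per genome.
#' @param n_dispensable Genes present in a random proper subset (needs at
#'   least 3 genomes).
#' @param inversion_rate Per-core-locus probability of a one-genome
#'   inversion.
#' @param truncation_rate Per-core-locus probability of a one-genome
#'   truncation disruption.
#' @param mutation_rate Per-base substitution rate of core/dispensable
#'   copies (at most 0.05).
#' @param block_split_rate Per-shared-block probability of an extra split.
#' @return A list with `dir`, file paths (`xmfa`, `fasta`, `gff`,
#'   `tigrfam`), in-memory `sequences`, `annotations`, `tigrfam_table`,
#'   `genome_lengths`, the `truth` matrix and `disrupted_pairs`.
#' @export
make_toy_dataset <- function(out_dir, seed = 1L, n_genomes = 3L,
                             n_core = 5L, n_orphan_per_genome = 1L,
                             n_dispensable = 0L, inversion_rate = 0,
                             truncation_rate = 0, mutation_rate = 0.02,
                             block_split_rate = 0) {
  if (n_genomes < 2L) stop("n_genomes must be at least 2")
  if (n_core < 0L || n_orphan_per_genome < 0L || n_dispensable < 0L) {
    stop("Locus counts must be non-negative")
  }
  if (n_dispensable > 0L && n_genomes < 3L) {
    stop("Dispensable genes need at least 3 genomes")
  }
  if (mutation_rate < 0 || mutation_rate > 0.05) {
    stop("mutation_rate must be in [0, 0.05]")
  }
  if (n_core + n_orphan_per_genome + n_dispensable == 0L) {
    stop("At least one locus is required")
  }
  set.seed(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  genomes <- sprintf("G%02d", seq_len(n_genomes))

  # locus table: one row per gene locus, shuffled into a fixed backbone order
  loci <- data.frame(kind = c(rep("core", n_core),
                              rep("orphan", n_genomes * n_orphan_per_genome),
                              rep("dispensable", n_dispensable)),
                     stringsAsFactors = FALSE)
  loci$owner <- NA_character_
  if (n_orphan_per_genome > 0L) {
    loci$owner[loci$kind == "orphan"] <-
      rep(genomes, each = n_orphan_per_genome)
  }
  loci <- loci[sample(nrow(loci)), , drop = FALSE]
  rownames(loci) <- NULL
  n_loci <- nrow(loci)
  loci$length <- sample(seq(120L, 240L, by = 3L), n_loci, replace = TRUE)
  loci$description <- sprintf("%s %d",
                              .DESC_VOCAB[(seq_len(n_loci) - 1L) %%
                                            length(.DESC_VOCAB) + 1L],
                              seq_len(n_loci))
  loci$tigrfam <- sprintf("TIGR%05d", 100L + seq_len(n_loci))
  loci$present <- lapply(seq_len(n_loci), function(i) {
    switch(loci$kind[i],
           core = genomes,
           orphan = loci$owner[i],
           dispensable = sort(sample(genomes,
                                     .resample(2:(n_genomes - 1L)))))
  })
  loci$base_seq <- vapply(loci$length, .random_dna, "")
  loci$inverted_in <- NA_character_
  loci$truncated_in <- NA_character_
  is_core <- loci$kind == "core"
  if (inversion_rate > 0 && any(is_core)) {
    pick <- is_core & stats::runif(n_loci) < inversion_rate
    loci$inverted_in[pick] <- vapply(which(pick), function(i)
      .resample(loci$present[[i]]), "")
  }
  if (truncation_rate > 0 && any(is_core)) {
    pick <- is_core & is.na(loci$inverted_in) &
      stats::runif(n_loci) < truncation_rate
    loci$truncated_in[pick] <- vapply(which(pick), function(i)
      .resample(loci$present[[i]]), "")
  }

  cursor <- stats::setNames(rep(1L, n_genomes), genomes)   # next free bp
  seqs <- stats::setNames(rep("", n_genomes), genomes)
  ann <- list()          # per-gene annotation rows
  gene_no <- stats::setNames(rep(0L, n_genomes), genomes)
  blocks <- list()
  col_offset <- 0L
  truth_rows <- list()   # list of (members, super_start, super_stop, desc)
  tigr_rows <- list()
  disrupted <- list()

  emit_block <- function(entries) {
    blocks[[length(blocks) + 1L]] <<- list(index = length(blocks) + 1L,
                                           entries = entries)
    width <- nchar(entries[[1]]$seq)
    col_offset <<- col_offset + width
    width
  }
  add_segment <- function(genome, segment) {
    start <- cursor[[genome]]
    end <- start + nchar(segment) - 1L
    seqs[[genome]] <<- paste0(seqs[[genome]], segment)
    cursor[[genome]] <<- end + 1L
    c(start, end)
  }
  next_gene_id <- function(genome) {
    gene_no[[genome]] <<- gene_no[[genome]] + 1L
    sprintf("%s_%04d", genome, gene_no[[genome]])
  }
  spacer <- function() {
    sp <- .random_dna(sample(30:60, 1))
    entries <- lapply(genomes, function(g) {
      se <- add_segment(g, sp)
      list(genome_id = g, start = se[1], end = se[2], strand = "+", seq = sp)
    })
    emit_block(entries)
  }

  spacer()
  for (i in seq_len(n_loci)) {
    present <- loci$present[[i]]
    victim <- loci$truncated_in[i]
    shared <- if (is.na(victim)) present else setdiff(present, victim)
    copies <- stats::setNames(lapply(shared, function(g)
      .mutate_seq(loci$base_seq[i], mutation_rate)), shared)

    entries <- list()
    members <- list()
    for (g in genomes) {
      if (!(g %in% shared)) next
      copy <- copies[[g]]
      inverted <- identical(loci$inverted_in[i], g)
      segment <- if (inverted) .revcomp(copy) else copy
      se <- add_segment(g, segment)
      gid <- next_gene_id(g)
      strand <- if (inverted) "-" else "+"
      ann[[length(ann) + 1L]] <- data.frame(
        genome_id = g, gene_id = gid, start = se[1], end = se[2],
        strand = strand, description = loci$description[i],
        stringsAsFactors = FALSE)
      members[[g]] <- list(gene_id = gid, strand = strand,
                           description = loci$description[i],
                           tigrfam_id = NA_character_)
      tigr_rows[[length(tigr_rows) + 1L]] <-
        c(gid, loci$tigrfam[i], paste(loci$description[i], "family"))
      # block shows the genome's forward-strand sequence; an inverted copy
      # stays in forward orientation (mismatching columns, same locus)
      entries[[length(entries) + 1L]] <- list(
        genome_id = g, start = se[1], end = se[2], strand = "+",
        seq = segment)
    }
    start_col <- col_offset + 1L
    width <- emit_block(entries)
    truth_rows[[length(truth_rows) + 1L]] <- list(
      members = members, super_start = start_col,
      super_stop = col_offset, description = loci$description[i])

    if (!is.na(victim)) {
      # disrupted copy: extra adenine in a homopolymer shifts the frame;
      # the annotated ORF stops early and the copy is unaligned to the rest
      copy <- .mutate_seq(loci$base_seq[i], mutation_rate)
      at <- regexpr("AA", copy, fixed = TRUE)
      at <- if (at > 0) at + 1L else 10L
      seg <- paste0(substring(copy, 1L, at), "A",
                    substring(copy, at + 1L, nchar(copy)))
      trunc_len <- max(30L, 3L * (floor(0.45 * nchar(seg)) %/% 3L))
      se <- add_segment(victim, seg)
      gid <- next_gene_id(victim)
      ann[[length(ann) + 1L]] <- data.frame(
        genome_id = victim, gene_id = gid, start = se[1],
        end = se[1] + trunc_len - 1L, strand = "+",
        description = loci$description[i], stringsAsFactors = FALSE)
      tigr_rows[[length(tigr_rows) + 1L]] <-
        c(gid, loci$tigrfam[i], paste(loci$description[i], "family"))
      orphan_start <- col_offset + 1L
      emit_block(list(list(genome_id = victim, start = se[1], end = se[2],
                           strand = "+", seq = seg)))
      truth_rows[[length(truth_rows) + 1L]] <- list(
        members = stats::setNames(list(list(
          gene_id = gid, strand = "+",
          description = loci$description[i],
          tigrfam_id = NA_character_)), victim),
        super_start = orphan_start,
        super_stop = orphan_start + trunc_len - 1L,
        description = loci$description[i])
      disrupted[[length(disrupted) + 1L]] <- c(length(truth_rows) - 1L,
                                               length(truth_rows))
    }
    spacer()
  }

  # optional perturbation: cut shared blocks at a random internal column
  if (block_split_rate > 0) {
    blocks <- .split_blocks(blocks, block_split_rate)
  }

  genome_lengths <- cursor - 1L
  attr(blocks, "roster") <- genomes

  paths <- list(
    xmfa = file.path(out_dir, "alignment.xmfa"),
    tigrfam = file.path(out_dir, "tigrfam.tsv"),
    fasta = stats::setNames(file.path(out_dir, paste0(genomes, ".fasta")),
                            genomes),
    gff = stats::setNames(file.path(out_dir, paste0(genomes, ".gff3")),
                          genomes))
  write_xmfa(blocks, paths$xmfa)
  annotations <- do.call(rbind, ann)
  for (g in genomes) {
    .write_fasta(seqs[[g]], g, paths$fasta[[g]])
    .write_gff3(annotations[annotations$genome_id == g, , drop = FALSE],
                g, genome_lengths[[g]], paths$gff[[g]])
  }
  tig <- do.call(rbind, tigr_rows)
  con <- file(paths$tigrfam, open = "wb")
  writeLines(c("gene_id\ttigrfam_id\tdescription",
               apply(tig, 1, paste, collapse = "\t")), con)
  close(con)
  tigrfam_table <- data.frame(gene_id = tig[, 1], tigrfam_id = tig[, 2],
                              description = tig[, 3],
                              stringsAsFactors = FALSE)

  # ground truth matrix, ordered by SuperGenome start like build_pangenome
  ord <- order(vapply(truth_rows, `[[`, 0L, "super_start"))
  truth_pgs <- lapply(seq_along(ord), function(r) {
    tr <- truth_rows[[ord[r]]]
    mem <- tr$members[order(match(names(tr$members), genomes))]
    new_pangene(sprintf("PG%06d", r), mem,
                super_start = tr$super_start, super_stop = tr$super_stop,
                consensus_description = tr$description)
  })
  truth <- new_pan_matrix(genomes, truth_pgs, dialect = "pangee")
  disrupted_pairs <- if (length(disrupted)) {
    data.frame(
      pan_id_i = vapply(disrupted, function(d)
        sprintf("PG%06d", match(d[1], ord)), ""),
      pan_id_j = vapply(disrupted, function(d)
        sprintf("PG%06d", match(d[2], ord)), ""),
      stringsAsFactors = FALSE)
  } else {
    data.frame(pan_id_i = character(0), pan_id_j = character(0),
               stringsAsFactors = FALSE)
  }

  list(dir = out_dir, xmfa = paths$xmfa, fasta = paths$fasta,
       gff = paths$gff, tigrfam = paths$tigrfam,
       sequences = seqs, annotations = annotations,
       tigrfam_table = tigrfam_table, genome_lengths = genome_lengths,
       blocks = blocks, truth = truth, disrupted_pairs = disrupted_pairs)
}

# Cut the ends of shared blocks: each multi-entry gapless block is split at
# a random internal column with the given probability.
.split_blocks <- function(blocks, rate) {
  out <- list()
  for (b in blocks) {
    width <- if (length(b$entries)) nchar(b$entries[[1]]$seq) else 0L
    if (length(b$entries) > 1L && width > 2L && stats::runif(1) < rate) {
      cut <- .resample(2:(width - 1L))
      left <- lapply(b$entries, function(e) {
        list(genome_id = e$genome_id, start = e$start,
             end = e$start + cut - 1L, strand = e$strand,
             seq = substring(e$seq, 1L, cut))
      })
      right <- lapply(b$entries, function(e) {
        list(genome_id = e$genome_id, start = e$start + cut, end = e$end,
             strand = e$strand, seq = substring(e$seq, cut + 1L))
      })
      out[[length(out) + 1L]] <- list(index = length(out) + 1L,
                                      entries = left)
      out[[length(out) + 1L]] <- list(index = length(out) + 1L,
                                      entries = right)
    } else {
      b$index <- length(out) + 1L
      out[[length(out) + 1L]] <- b
    }
  }
  attr(out, "roster") <- attr(blocks, "roster")
  out
}

#' Generate a random gapped alignment for property testing
#'
#' Produces alignment blocks with random genome subsets, random gap
#' placement, reverse-strand entries and unaligned leftover tails --
#' exercising the full coordinate machinery rather than biological realism.
#'
#' @param seed Integer seed.
#' @param n_genomes Number of genomes (2-5 is typical).
#' @param n_blocks Number of alignment blocks.
#' @param max_block Maximum block width in columns.
#' @return A list with `blocks` (roster attached), `genome_lengths` and the
#'   per-position expected forward map `truth_forward` computed by a direct
#'   column scan.
#' @export
make_random_alignment <- function(seed = 1L, n_genomes = 3L, n_blocks = 6L,
                                  max_block = 120L) {
  set.seed(seed)
  genomes <- sprintf("G%02d", seq_len(n_genomes))
  cursor <- stats::setNames(rep(1L, n_genomes), genomes)
  blocks <- list()
  col_offset <- 0L
  truth_forward <- stats::setNames(
    lapply(genomes, function(g) integer(0)), genomes)

  for (bi in seq_len(n_blocks)) {
    width <- sample(20:max_block, 1)
    members <- sample(genomes, sample(1:n_genomes, 1))
    entries <- list()
    for (g in members) {
      n_res <- sample(seq_len(width), 1)
      res_cols <- sort(sample(width, n_res))
      chars <- rep("-", width)
      chars[res_cols] <- sample(c("A", "C", "G", "T"), n_res, replace = TRUE)
      strand <- sample(c("+", "-"), 1)
      start <- cursor[[g]] + sample(0:3, 1)      # small unaligned gap
      end <- start + n_res - 1L
      cursor[[g]] <- end + 1L
      entries[[length(entries) + 1L]] <- list(
        genome_id = g, start = start, end = end, strand = strand,
        seq = paste(chars, collapse = ""))
      # independent truth: walk the columns
      fwd <- truth_forward[[g]]
      length(fwd) <- end
      pos_seq <- if (strand == "+") start:end else end:start
      for (k in seq_len(n_res)) {
        fwd[pos_seq[k]] <- (col_offset + res_cols[k]) *
          (if (strand == "+") 1L else -1L)
      }
      truth_forward[[g]] <- fwd
    }
    blocks[[bi]] <- list(index = bi, entries = entries)
    col_offset <- col_offset + width
  }
  genome_lengths <- cursor - 1L + sample(0:5, n_genomes, replace = TRUE)
  for (g in genomes) {
    fwd <- truth_forward[[g]]
    length(fwd) <- genome_lengths[[g]]
    truth_forward[[g]] <- fwd
  }
  attr(blocks, "roster") <- genomes
  list(blocks = blocks, genome_lengths = genome_lengths,
       truth_forward = truth_forward)
}

#' Synthesise a pan-genome matrix of a given composition
#'
#' Directly builds a `PanGenomeMatrix` with exactly the requested number of
#' core, orphan and dispensable pan genes over `n_genomes` genomes, with
#' dispensable group sizes drawn uniformly from `[2, n_genomes - 1]`. The
#' preset `"saureus_like"` reproduces the composition of a 32-genome
#' staphylococcal study (1846 core, 3848 orphan, 2953 dispensable).
#'
#' @param n_genomes,n_core,n_orphan,n_dispensable Composition counts.
#' @param seed Integer seed.
#' @param preset Optional preset name overriding the counts
#'   (`"saureus_like"`).
#' @return A `PanGenomeMatrix`.
#' @export
make_synthetic_matrix <- function(n_genomes = 3L, n_core = 2L,
                                  n_orphan = 1L, n_dispensable = 1L,
                                  seed = 1L, preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, "saureus_like")
    n_genomes <- 32L; n_core <- 1846L
    n_orphan <- 3848L; n_dispensable <- 2953L
  }
  if (n_genomes < 2L) stop("n_genomes must be at least 2")
  if (n_core < 0L || n_orphan < 0L || n_dispensable < 0L) {
    stop("Category counts must be non-negative")
  }
  if (n_dispensable > 0L && n_genomes < 3L) {
    stop("Dispensable pan genes need at least 3 genomes")
  }
  set.seed(seed)
  genomes <- sprintf("G%02d", seq_len(n_genomes))
  kinds <- sample(c(rep("core", n_core), rep("orphan", n_orphan),
                    rep("dispensable", n_dispensable)))
  gene_no <- stats::setNames(rep(0L, n_genomes), genomes)
  pgs <- vector("list", length(kinds))
  pos <- 1L
  for (i in seq_along(kinds)) {
    present <- switch(kinds[i],
                      core = genomes,
                      orphan = sample(genomes, 1),
                      dispensable = sort(sample(
                        genomes, .resample(2:(n_genomes - 1L)))))
    width <- sample(300:1500, 1)
    desc <- sprintf("%s %d",
                    .DESC_VOCAB[(i - 1L) %% length(.DESC_VOCAB) + 1L], i)
    members <- stats::setNames(lapply(present, function(g) {
      gene_no[[g]] <<- gene_no[[g]] + 1L
      list(gene_id = sprintf("%s_%05d", g, gene_no[[g]]),
           strand = sample(c("+", "-"), 1),
           description = desc, tigrfam_id = NA_character_)
    }), present)
    pgs[[i]] <- new_pangene(sprintf("PG%06d", i), members,
                            super_start = pos, super_stop = pos + width - 1L,
                            consensus_description = desc)
    pos <- pos + width + sample(20:200, 1)
  }
  new_pan_matrix(genomes, pgs, dialect = "pangee")
}
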