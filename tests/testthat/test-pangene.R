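# Annotation lift-over, overlap components, identity refinement and the
# full pan-genome build.

simple_sg <- function(lines) {
  f <- tempfile(fileext = ".xmfa")
  writeLines(lines, f)
  build_supergenome(parse_xmfa(f))
}

test_that("identity alignments lift genes verbatim", {
  sg <- simple_sg(c(
    sprintf("> A:1-30 +"), strrep("ACGTA", 6),
    sprintf("> B:1-30 +"), strrep("ACGTA", 6), "="))
  ann <- data.frame(genome_id = "A", gene_id = "g1", start = 10L, end = 20L,
                    strand = "+", description = "d",
                    stringsAsFactors = FALSE)
  lifted <- lift_annotations(sg, ann)
  expect_equal(lifted$super_start, 10L)
  expect_equal(lifted$super_stop, 20L)
  expect_equal(lifted$lifted_strand, "+")
})

test_that("genes on reverse-mapped blocks flip strand and swap endpoints", {
  sg <- simple_sg(c(
    "> A:1-10 +", "ACGTACGTAC", "> B:11-20 +", "ACGTACGTAC", "=",
    "> A:11-20 +", "ACGTACGTAC", "> B:1-10 -", "GTACGTACGT", "="))
  ann <- data.frame(genome_id = "B", gene_id = "g1", start = 3L, end = 8L,
                    strand = "+", description = "d",
                    stringsAsFactors = FALSE)
  lifted <- lift_annotations(sg, ann)
  # column-scan oracle: B pos 10..1 occupy columns 11..20, so 3..8 -> 13..18
  expect_equal(lifted$super_start, 13L)
  expect_equal(lifted$super_stop, 18L)
  expect_equal(lifted$lifted_strand, "-")
})

test_that("genes with no aligned base are dropped with a warning", {
  sg <- simple_sg(c("> A:1-10 +", "ACGTACGTAC", "="))
  sg$genome_lengths[["A"]] <- 30L
  sg$forward[["A"]] <- c(sg$forward[["A"]], rep(NA_integer_, 20L))
  ann <- data.frame(genome_id = "A", gene_id = c("in", "out"),
                    start = c(2L, 15L), end = c(9L, 25L),
                    strand = "+", description = "d",
                    stringsAsFactors = FALSE)
  expect_warning(lifted <- lift_annotations(sg, ann), "no aligned base")
  expect_equal(lifted$gene_id, "in")
})

test_that("multi-block genes are lifted to their majority block", {
  sg <- simple_sg(c("> A:1-10 +", "ACGTACGTAC", "=",
                    "> A:11-14 +", "ACGT", "="))
  ann <- data.frame(genome_id = "A", gene_id = "g1", start = 5L, end = 13L,
                    strand = "+", description = "d",
                    stringsAsFactors = FALSE)
  lifted <- lift_annotations(sg, ann)
  expect_equal(c(lifted$super_start, lifted$super_stop), c(5L, 10L))
})

test_that("overlap components follow transitive overlap with a hard boundary", {
  lifted <- data.frame(
    genome_id = c("A", "B", "C"), gene_id = c("a", "b", "c"),
    super_start = c(100L, 150L, 300L), super_stop = c(200L, 250L, 400L),
    stringsAsFactors = FALSE)
  comps <- overlap_components(lifted)
  expect_equal(comps, list(c(1L, 2L), 3L))

  abutting <- data.frame(
    genome_id = c("A", "B"), gene_id = c("a", "b"),
    super_start = c(1L, 11L), super_stop = c(10L, 20L),
    stringsAsFactors = FALSE)
  expect_length(overlap_components(abutting), 2L)

  chain <- data.frame(
    genome_id = c("A", "B", "C"), gene_id = c("a", "b", "c"),
    super_start = c(1L, 8L, 16L), super_stop = c(10L, 18L, 26L),
    stringsAsFactors = FALSE)
  expect_length(overlap_components(chain), 1L)
  expect_error(overlap_components(chain, min_overlap = 0L), "min_overlap")
})

test_that("overlap components agree with a brute-force pairwise check", {
  for (seed in 1:8) {
    set.seed(seed)
    k <- sample(4:12, 1)
    starts <- sample(1:500, k)
    lifted <- data.frame(
      genome_id = sample(sprintf("G%02d", 1:4), k, replace = TRUE),
      gene_id = sprintf("g%02d", 1:k),
      super_start = starts,
      super_stop = starts + sample(20:120, k, replace = TRUE),
      stringsAsFactors = FALSE)
    min_ov <- sample(1:10, 1)
    comps <- overlap_components(lifted, min_overlap = min_ov)
    # brute force union-find over pairwise overlaps
    parent <- seq_len(k)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    for (a in 1:(k - 1)) for (b in (a + 1):k) {
      ov <- min(lifted$super_stop[a], lifted$super_stop[b]) -
        max(lifted$super_start[a], lifted$super_start[b]) + 1L
      if (ov >= min_ov) parent[find(a)] <- find(b)
    }
    expected <- unname(split(seq_len(k),
                             vapply(seq_len(k), find, integer(1))))
    got <- lapply(comps, sort)
    expect_setequal(lapply(expected, sort), got)
    expect_equal(sum(lengths(comps)), k)
  }
})

test_that("pairwise identity matches an independent DP oracle", {
  expect_equal(pairwise_identity("ACGT", "ACGT"), 1.0)
  expect_equal(pairwise_identity("AAAA", "TTTT"), 0.0)
  # oracle alignment: ACGTACGT / ACG-ACGT -> 7 matches over 8 columns
  expect_equal(nw_identity_oracle("ACGTACGT", "ACGACGT"), 0.875)
  expect_equal(pairwise_identity("ACGTACGT", "ACGACGT"), 0.875)
  expect_error(pairwise_identity("", "ACGT"), "non-empty")

  set.seed(202)
  for (i in 1:25) {
    n <- sample(20:60, 1)
    a <- paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
    # mutated/indel copy, as orthologous gene copies look
    chars <- strsplit(a, "")[[1]]
    mut <- sample(n, ceiling(n * 0.1))
    for (j in mut) chars[j] <- sample(c("A", "C", "G", "T"), 1)
    if (runif(1) < 0.5) chars <- chars[-sample(n, sample(1:3, 1))]
    b <- paste(chars, collapse = "")
    expect_equal(pairwise_identity(a, b), nw_identity_oracle(a, b),
                 info = paste("case", i))
    expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
  }
})

test_that("ambiguity characters never count as matches", {
  expect_equal(pairwise_identity("ANNNA", "ANNNA"), 2 / 5)
  expect_equal(pairwise_identity("ARYSA", "ARYSA"), 2 / 5)
})

test_that("resolve_component merges conflict-free groups and separates paralogs", {
  comp <- data.frame(
    genome_id = c("G1", "G2", "G3"), gene_id = c("a", "b", "c"),
    super_start = c(100L, 105L, 110L), super_stop = c(200L, 205L, 210L),
    stringsAsFactors = FALSE)
  sim <- matrix(0.9, 3, 3); diag(sim) <- 1
  expect_equal(resolve_component(comp, sim, 0.5), list(1:3))

  # two same-genome paralogs, each similar to a different partner
  comp2 <- data.frame(
    genome_id = c("G1", "G1", "G2", "G3"),
    gene_id = c("a1", "a2", "b", "c"),
    super_start = c(100L, 120L, 101L, 121L),
    super_stop = c(200L, 220L, 201L, 221L),
    stringsAsFactors = FALSE)
  sim2 <- diag(4)
  sim2[1, 3] <- sim2[3, 1] <- 0.95
  sim2[2, 4] <- sim2[4, 2] <- 0.92
  sim2[1, 2] <- sim2[2, 1] <- 0.9   # paralogs similar but same genome
  groups <- resolve_component(comp2, sim2, 0.5)
  expect_length(groups, 2L)
  expect_setequal(lapply(groups, sort), list(c(1L, 3L), c(2L, 4L)))
})

test_that("resolve_component ties the exhaustive partition oracle on planted components", {
  for (seed in 1:30) {
    pc <- make_planted_component(seed)
    groups <- resolve_component(pc$component, pc$sim, 0.5,
                                roster = pc$roster)
    expect_equal(sort(unlist(groups)), seq_len(nrow(pc$component)))
    for (ix in groups) {
      expect_false(anyDuplicated(pc$component$genome_id[ix]) > 0)
    }
    expect_equal(
      grouping_score(groups, pc$sim, 0.5),
      partition_oracle_score(pc$component$genome_id, pc$sim, 0.5),
      tolerance = 1e-12)
  }
})

test_that("build_pangenome recovers core and orphan structure with conservation", {
  res <- make_toy_dataset(tempfile(), seed = 21, n_genomes = 3, n_core = 5,
                          n_orphan_per_genome = 1)
  sg <- build_supergenome(parse_xmfa(res$xmfa), res$genome_lengths)
  anns <- lapply(names(res$gff), function(g) read_gff(res$gff[[g]], g))
  m <- build_pangenome(sg, anns, sequences = res$sequences)
  s <- summary(m)
  expect_equal(s$n_pan_genes, 8L)
  expect_equal(s$n_core, 5L)
  expect_equal(s$n_orphan, 3L)
  expect_equal(total_genes(m), nrow(res$annotations))
  starts <- vapply(m$pangenes, `[[`, 0L, "super_start")
  expect_true(all(diff(starts) >= 0))
  expect_true(all(grepl("^PG\\d{6}$", names(m$pangenes))))
})

test_that("an inverted ortholog stays in its group with a minus strand", {
  res <- make_toy_dataset(tempfile(), seed = 33, n_genomes = 3, n_core = 4,
                          n_orphan_per_genome = 0, inversion_rate = 1)
  sg <- build_supergenome(parse_xmfa(res$xmfa), res$genome_lengths)
  anns <- lapply(names(res$gff), function(g) read_gff(res$gff[[g]], g))
  m <- build_pangenome(sg, anns, sequences = res$sequences)
  expect_true(same_matrix_state(m, res$truth))
  strands <- unlist(lapply(m$pangenes, function(pg)
    vapply(pg$members, `[[`, "", "strand")))
  expect_true(any(strands == "-"))
  expect_equal(summary(m)$n_core, 4L)
})

test_that("a copy truncated to 60% still joins its ortholog group", {
  res <- make_toy_dataset(tempfile(), seed = 8, n_genomes = 3, n_core = 3,
                          n_orphan_per_genome = 0)
  # truncate one annotated copy to 60% of its length
  ann <- res$annotations
  i <- which(ann$genome_id == "G01")[1]
  ann$end[i] <- ann$start[i] +
    as.integer(0.6 * (ann$end[i] - ann$start[i] + 1L)) - 1L
  sg <- build_supergenome(parse_xmfa(res$xmfa), res$genome_lengths)
  m <- build_pangenome(sg, ann, sequences = res$sequences)
  expect_equal(summary(m)$n_pan_genes, 3L)
  expect_equal(summary(m)$n_core, 3L)
})
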