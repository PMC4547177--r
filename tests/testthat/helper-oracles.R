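# Independent oracles and small fixture builders used across the suite.
# These deliberately re-derive expected values by brute force, separately
# from the package's own code paths.

# --- Needleman-Wunsch identity oracle -------------------------------------
# Plain quadratic DP with explicit traceback (diagonal preferred, then up,
# then left); match +1, mismatch -1, linear gap -2; identity is
# matches / alignment length.
nw_identity_oracle <- function(a, b) {
  A <- strsplit(toupper(a), "")[[1]]
  B <- strsplit(toupper(b), "")[[1]]
  A[!(A %in% c("A", "C", "G", "T"))] <- "N"
  B[!(B %in% c("A", "C", "G", "T"))] <- "N"
  n <- length(A); m <- length(B)
  H <- matrix(0, n + 1, m + 1)
  H[, 1] <- -2 * (0:n)
  H[1, ] <- -2 * (0:m)
  s <- function(x, y) if (x == y && x != "N") 1 else -1
  for (i in 1:n) for (j in 1:m) {
    H[i + 1, j + 1] <- max(H[i, j] + s(A[i], B[j]),
                           H[i, j + 1] - 2,
                           H[i + 1, j] - 2)
  }
  i <- n; j <- m; matches <- 0L; len <- 0L
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 && H[i + 1, j + 1] == H[i, j] + s(A[i], B[j])) {
      if (A[i] == B[j] && A[i] != "N") matches <- matches + 1L
      i <- i - 1L; j <- j - 1L
    } else if (i > 0 && H[i + 1, j + 1] == H[i, j + 1] - 2) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
    len <- len + 1L
  }
  matches / len
}

# --- partition enumeration oracle -----------------------------------------
# Exhaustively enumerates all set partitions whose blocks never repeat a
# genome, scoring each as the sum over within-block pairs of
# (similarity - threshold); returns the maximum score.
partition_oracle_score <- function(genomes, sim, threshold) {
  n <- length(genomes)
  env <- new.env()
  env$best <- -Inf
  env$blocks <- list()
  block_score <- function(ix) {
    if (length(ix) < 2L) return(0)
    tot <- 0
    for (a in seq_len(length(ix) - 1L)) for (b in (a + 1L):length(ix)) {
      tot <- tot + sim[ix[a], ix[b]] - threshold
    }
    tot
  }
  recurse <- function(i) {
    if (i > n) {
      sc <- sum(vapply(env$blocks, block_score, numeric(1)))
      if (sc > env$best) env$best <- sc
      return()
    }
    for (j in seq_along(env$blocks)) {
      blk <- env$blocks[[j]]
      if (!(genomes[i] %in% genomes[blk])) {
        env$blocks[[j]] <- c(blk, i)
        recurse(i + 1L)
        env$blocks[[j]] <- blk
      }
    }
    env$blocks[[length(env$blocks) + 1L]] <- i
    recurse(i + 1L)
    env$blocks[[length(env$blocks)]] <- NULL
  }
  recurse(1L)
  env$best
}

# score of a concrete grouping under the same objective
grouping_score <- function(groups, sim, threshold) {
  tot <- 0
  for (ix in groups) {
    if (length(ix) < 2L) next
    for (a in seq_len(length(ix) - 1L)) for (b in (a + 1L):length(ix)) {
      tot <- tot + sim[ix[a], ix[b]] - threshold
    }
  }
  tot
}

# --- column-scan oracle for SuperGenome coordinates -----------------------
# Walks every block's characters directly and builds the expected signed
# forward map per genome, independently of build_supergenome's vectorised
# construction.
scan_forward_oracle <- function(blocks, genome_lengths) {
  roster <- names(genome_lengths)
  fwd <- lapply(genome_lengths, function(n) rep(NA_integer_, n))
  col <- 0L
  for (b in blocks) {
    width <- if (length(b$entries)) nchar(b$entries[[1]]$seq) else 0L
    for (e in b$entries) {
      chars <- strsplit(e$seq, "")[[1]]
      p <- if (e$strand == "+") e$start else e$end
      step <- if (e$strand == "+") 1L else -1L
      for (k in seq_len(width)) {
        if (chars[k] != "-") {
          fwd[[e$genome_id]][p] <- (col + k) * step
          p <- p + step
        }
      }
    }
    col <- col + width
  }
  fwd
}

# --- planted overlap components for grouping tests ------------------------
# Gene similarities in real components are bimodal: ortholog copies sit far
# above the identity threshold, unrelated overlapping genes far below.
make_planted_component <- function(seed, max_genes = 8L, n_genomes = 4L) {
  set.seed(seed)
  k <- sample(2:max_genes, 1)
  genome_pool <- sprintf("G%02d", seq_len(n_genomes))
  truth <- integer(k)
  genome_of <- character(k)
  grp <- 0L
  i <- 1L
  while (i <= k) {
    grp <- grp + 1L
    size <- min(sample(1:n_genomes, 1), k - i + 1L)
    gs <- sample(genome_pool, size)
    truth[i:(i + size - 1L)] <- grp
    genome_of[i:(i + size - 1L)] <- gs
    i <- i + size
  }
  sim <- matrix(0, k, k)
  for (a in seq_len(k)) for (b in seq_len(k)) {
    if (a == b) {
      sim[a, b] <- 1
    } else if (truth[a] == truth[b]) {
      sim[a, b] <- sim[b, a] <- stats::runif(1, 0.75, 1.0)
    } else {
      sim[a, b] <- sim[b, a] <- stats::runif(1, 0.05, 0.40)
    }
  }
  starts <- sort(sample(1000:2000, k))
  component <- data.frame(
    genome_id = genome_of,
    gene_id = sprintf("gene%02d", seq_len(k)),
    super_start = starts,
    super_stop = starts + sample(100:200, k, replace = TRUE),
    stringsAsFactors = FALSE)
  list(component = component, sim = sim, truth = truth,
       roster = genome_pool)
}

# --- tiny hand-built matrices ---------------------------------------------
pg_stub <- function(id, genomes, pos, strand = "+", desc = "protein X",
                    tigrfam = NA_character_) {
  members <- stats::setNames(lapply(genomes, function(g) list(
    gene_id = paste0(g, "_", id), strand = strand, description = desc,
    tigrfam_id = tigrfam)), genomes)
  new_pangene(id, members, super_start = pos, super_stop = pos + 50L,
              consensus_description = desc, tigrfam_id = tigrfam)
}

# random valid event sequence applied to a matrix; returns the final matrix
# and the number of events applied
apply_random_events <- function(m, n_events, seed) {
  set.seed(seed)
  applied <- 0L
  for (e in seq_len(n_events)) {
    ids <- names(m$pangenes)
    agns <- ids[vapply(m$pangenes, function(pg)
      !is.null(pg$constituents) && length(pg$constituents) > 0, TRUE)]
    move <- sample(c("aggregate", "deaggregate", "undo"), 1,
                   prob = c(0.6, 0.2, 0.2))
    if (move == "deaggregate" && length(agns)) {
      m <- deaggregate(m, sample(agns, 1))
      applied <- applied + 1L
    } else if (move == "undo" && length(m$undo_stack)) {
      m <- undo(m)
      applied <- applied + 1L
    } else if (length(ids) >= 2L) {
      # try a few random pairs/triples for a feasible aggregation
      for (try in 1:10) {
        pick <- sample(ids, min(sample(2:3, 1), length(ids)))
        if (isTRUE(can_aggregate(m, pick))) {
          m <- aggregate(m, pick)
          applied <- applied + 1L
          break
        }
      }
    }
  }
  list(matrix = m, applied = applied)
}

# total number of gene cells in a matrix
total_genes <- function(m) {
  sum(vapply(m$pangenes, function(pg) length(pg$members), integer(1)))
}
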