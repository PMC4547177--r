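# SuperGenome: a shared coordinate axis over a blockwise multiple genome
# alignment, with bidirectional maps between alignment columns and each
# genome's own 1-based coordinates.

#' Parse an XMFA multiple genome alignment
#'
#' Reads a blockwise multiple alignment in the XMFA dialect written by
#' progressiveMauve: entries start with `> seqId:start-end strand [comment]`,
#' gapped sequence lines follow, and blocks are terminated by a line starting
#' with `=`. An entry with coordinates `0-0` marks a genome absent from the
#' block and is dropped.
#'
#' @param path Path to an XMFA file.
#' @return A list of alignment blocks in file order. Each block is a list with
#'   `index` (ordinal) and `entries`, a list of entries with fields
#'   `genome_id`, `start`, `end` (1-based inclusive), `strand` (`"+"`/`"-"`)
#'   and `seq` (gapped sequence). The genome roster, in order of first
#'   appearance, is attached as attribute `"roster"`.
#' @export
parse_xmfa <- function(path) {
  if (!file.exists(path)) {
    stop("XMFA file not found: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  blocks <- list()
  roster <- character(0)
  entries <- list()
  cur <- NULL        # entry under construction
  cur_seq <- character(0)

  flush_entry <- function() {
    if (is.null(cur)) return()
    cur$seq <<- paste(cur_seq, collapse = "")
    entries[[length(entries) + 1L]] <<- cur
    cur <<- NULL
    cur_seq <<- character(0)
  }
  flush_block <- function() {
    flush_entry()
    if (length(entries) == 0L) return()
    blk <- .validate_block(entries, length(blocks) + 1L)
    for (e in blk$entries) {
      if (!(e$genome_id %in% roster)) roster <<- c(roster, e$genome_id)
    }
    blocks[[length(blocks) + 1L]] <<- blk
    entries <<- list()
  }

  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (startsWith(line, "#") || (grepl("^\\s*$", line) && is.null(cur))) next
    if (startsWith(line, "=")) {
      flush_block()
    } else if (startsWith(line, ">")) {
      flush_entry()
      m <- regmatches(line, regexec(
        "^>\\s*([^:[:space:]]+):(\\d+)-(\\d+)\\s+([+-])(\\s+.*)?$", line))[[1]]
      if (length(m) == 0L) {
        stop("Malformed XMFA header at line ", i, ": ", line)
      }
      cur <- list(genome_id = m[[2]],
                  start = as.integer(m[[3]]),
                  end = as.integer(m[[4]]),
                  strand = m[[5]])
    } else if (!is.null(cur)) {
      cur_seq <- c(cur_seq, gsub("\\s", "", line))
    } else {
      stop("Unexpected sequence data outside an entry at line ", i)
    }
  }
  flush_block()
  attr(blocks, "roster") <- roster
  blocks
}

# Validate one parsed block: drop 0-0 absence entries, check equal gapped
# lengths, non-gap count vs coordinates, and per-block genome uniqueness.
.validate_block <- function(entries, index) {
  keep <- list()
  for (e in entries) {
    if (e$start == 0L && e$end == 0L) next   # Mauve convention: absent
    keep[[length(keep) + 1L]] <- e
  }
  if (length(keep) == 0L) return(list(index = index, entries = list()))
  lens <- vapply(keep, function(e) nchar(e$seq), integer(1))
  if (length(unique(lens)) != 1L) {
    stop("Block ", index, ": gapped sequences have unequal lengths (",
         paste(lens, collapse = ", "), ")")
  }
  ids <- vapply(keep, `[[`, "", "genome_id")
  if (anyDuplicated(ids)) {
    stop("Block ", index, ": genome ", ids[duplicated(ids)][1],
         " appears more than once")
  }
  for (e in keep) {
    n_res <- nchar(gsub("-", "", e$seq))
    if (n_res != e$end - e$start + 1L) {
      stop("Block ", index, ", genome ", e$genome_id, ": ", n_res,
           " residues but coordinates span ", e$end - e$start + 1L)
    }
  }
  list(index = index, entries = keep)
}

#' Build a SuperGenome coordinate system from alignment blocks
#'
#' Concatenates alignment blocks in file order into a single column axis
#' (columns `1..total_length`) and records, for every genome, the
#' bidirectional map between genome positions and alignment columns. Mapped
#' super positions are signed: negative means the genome is reverse-
#' complemented at that column. Genome positions covered by no block map to
#' `NA` (unaligned); columns where a genome has a gap map back to `NA`.
#'
#' @param blocks Alignment blocks as returned by [parse_xmfa()].
#' @param genome_lengths Optional named integer vector of genome lengths;
#'   defaults to the largest aligned end per genome.
#' @return An object of class `SuperGenome` with fields `roster`,
#'   `genome_lengths`, `total_length`, `forward` (per-genome signed column or
#'   `NA` for each genome position), `backward` (per-genome genome position or
#'   `NA` for each column), and per-block column offsets.
#' @export
build_supergenome <- function(blocks, genome_lengths = NULL) {
  if (length(blocks) == 0L) stop("No alignment blocks given")
  roster <- attr(blocks, "roster")
  if (is.null(roster)) {
    roster <- unique(unlist(lapply(blocks, function(b)
      vapply(b$entries, `[[`, "", "genome_id"))))
  }
  block_lengths <- vapply(blocks, function(b) {
    if (length(b$entries) == 0L) 0L else nchar(b$entries[[1]]$seq)
  }, integer(1))
  offsets <- c(0L, cumsum(block_lengths))
  total <- offsets[length(offsets)]

  max_end <- stats::setNames(integer(length(roster)), roster)
  for (b in blocks) for (e in b$entries) {
    max_end[e$genome_id] <- max(max_end[e$genome_id], e$end)
  }
  if (is.null(genome_lengths)) {
    genome_lengths <- max_end
  } else {
    genome_lengths <- genome_lengths[roster]
    if (anyNA(genome_lengths) || any(genome_lengths < max_end)) {
      stop("genome_lengths must cover every genome's aligned extent")
    }
  }

  forward <- lapply(genome_lengths, function(n) rep(NA_integer_, n))
  backward <- stats::setNames(
    lapply(roster, function(g) rep(NA_integer_, total)), roster)

  for (bi in seq_along(blocks)) {
    b <- blocks[[bi]]
    for (e in b$entries) {
      chars <- strsplit(e$seq, "", fixed = TRUE)[[1]]
      cols <- offsets[bi] + which(chars != "-")
      pos <- if (e$strand == "+") e$start:e$end else e$end:e$start
      g <- e$genome_id
      if (any(!is.na(forward[[g]][pos]))) {
        stop("Genome ", g, ": interval ", e$start, "-", e$end,
             " overlaps a previously aligned interval")
      }
      forward[[g]][pos] <- if (e$strand == "+") cols else -cols
      backward[[g]][cols] <- pos
    }
  }

  structure(list(
    roster = roster,
    genome_lengths = genome_lengths,
    total_length = total,
    forward = forward,
    backward = backward,
    block_offsets = offsets[-length(offsets)],
    block_lengths = block_lengths
  ), class = "SuperGenome")
}

#' @export
print.SuperGenome <- function(x, ...) {
  cat("SuperGenome:", length(x$roster), "genomes,",
      x$total_length, "alignment columns,",
      length(x$block_lengths), "blocks\n")
  invisible(x)
}

.check_genome <- function(sg, genome_id) {
  if (!(genome_id %in% sg$roster)) {
    stop("Unknown genome '", genome_id, "'; roster: ",
         paste(sg$roster, collapse = ", "))
  }
}

#' Map genome positions to SuperGenome columns
#'
#' @param sg A `SuperGenome`.
#' @param genome_id Genome identifier (must be in the roster).
#' @param position Integer vector of 1-based genome positions.
#' @return Signed integer vector of alignment columns; negative when the
#'   genome is reverse-complemented at that column, `NA` where the position is
#'   unaligned.
#' @export
to_super <- function(sg, genome_id, position) {
  .check_genome(sg, genome_id)
  n <- sg$genome_lengths[[genome_id]]
  if (any(position < 1L | position > n)) {
    stop("Position out of range 1..", n, " for genome ", genome_id)
  }
  sg$forward[[genome_id]][position]
}

#' Map SuperGenome columns to genome positions
#'
#' @param sg A `SuperGenome`.
#' @param genome_id Genome identifier (must be in the roster).
#' @param super_position Integer vector of 1-based alignment columns
#'   (unsigned).
#' @return Integer vector of genome positions; `NA` where the genome has a
#'   gap or is absent from the block.
#' @export
to_genome <- function(sg, genome_id, super_position) {
  .check_genome(sg, genome_id)
  if (any(super_position < 1L | super_position > sg$total_length)) {
    stop("Super position out of range 1..", sg$total_length)
  }
  sg$backward[[genome_id]][super_position]
}
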