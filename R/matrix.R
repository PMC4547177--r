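# The pan-genome matrix: an ordered list of pan genes over a fixed genome
# roster, with classification, summary statistics, aggregation curation,
# undo and a replayable interaction history.

#' Construct a pan gene (ortholog group)
#'
#' A pan gene holds at least one and at most `n` member genes, never two from
#' the same genome. Members are keyed by genome.
#'
#' @param pan_id Unique identifier (`PG...` for computed groups, `AGN...` for
#'   aggregated ones).
#' @param members Named list, one entry per member genome, each a list with
#'   `gene_id`, `strand` (`"+"`/`"-"`), `description` and optional
#'   `tigrfam_id`.
#' @param super_start,super_stop 1-based SuperGenome columns (may be `NA` for
#'   matrices loaded from files without coordinates).
#' @param consensus_description Consensus of the member descriptions.
#' @param tigrfam_id Optional consensus TIGRFAM accession.
#' @param aggregated_from Character vector of constituent pan gene ids
#'   (empty unless this row was created by aggregation).
#' @return An object of class `PanGene`.
#' @export
new_pangene <- function(pan_id, members, super_start = NA_integer_,
                        super_stop = NA_integer_,
                        consensus_description = "",
                        tigrfam_id = NA_character_,
                        aggregated_from = character(0)) {
  if (length(members) < 1L) stop("A pan gene must contain at least one gene")
  if (is.null(names(members)) || anyDuplicated(names(members))) {
    stop("Pan gene ", pan_id,
         ": members must be uniquely keyed by genome (one gene per genome)")
  }
  if (!is.na(super_start) && !is.na(super_stop) && super_start > super_stop) {
    stop("Pan gene ", pan_id, ": super_start > super_stop")
  }
  members <- lapply(members, function(mm) {
    if (is.null(mm$gene_id) || is.null(mm$strand)) {
      stop("Pan gene ", pan_id, ": every member needs gene_id and strand")
    }
    list(gene_id = mm$gene_id, strand = mm$strand,
         description = mm$description %||% "",
         tigrfam_id = mm$tigrfam_id %||% NA_character_)
  })
  structure(list(
    pan_id = pan_id,
    members = members,
    super_start = as.integer(super_start),
    super_stop = as.integer(super_stop),
    consensus_description = consensus_description,
    tigrfam_id = tigrfam_id,
    aggregated_from = aggregated_from,
    constituents = NULL,     # full constituent PanGenes while loaded
    orig_rows = NULL         # their row indices at aggregation time
  ), class = "PanGene")
}

#' Construct a pan-genome matrix
#'
#' @param roster Ordered character vector of genome identifiers; fixed for the
#'   lifetime of the matrix.
#' @param pangenes List of [new_pangene()] objects in row order.
#' @param dialect Source file dialect tag, `"pangee"` or `"generic"`.
#' @return An object of class `PanGenomeMatrix`.
#' @export
new_pan_matrix <- function(roster, pangenes = list(), dialect = "pangee") {
  ids <- vapply(pangenes, `[[`, "", "pan_id")
  if (anyDuplicated(ids)) {
    stop("Duplicate pan gene identifier: ", ids[duplicated(ids)][1])
  }
  for (pg in pangenes) {
    bad <- setdiff(names(pg$members), roster)
    if (length(bad)) {
      stop("Pan gene ", pg$pan_id, " has members outside the roster: ",
           paste(bad, collapse = ", "))
    }
  }
  names(pangenes) <- ids
  structure(list(
    roster = roster,
    pangenes = pangenes,
    dialect = dialect,
    history = .empty_history(),
    undo_stack = list(),
    agn_serial = 0L
  ), class = "PanGenomeMatrix")
}

.empty_history <- function() {
  data.frame(timestamp = character(0), kind = character(0),
             pan_ids = character(0), result = character(0),
             stringsAsFactors = FALSE)
}

.log_event <- function(m, kind, pan_ids, result) {
  m$history <- rbind(m$history, data.frame(
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3"),
    kind = kind, pan_ids = paste(pan_ids, collapse = ","),
    result = result, stringsAsFactors = FALSE))
  m
}

#' @export
print.PanGenomeMatrix <- function(x, ...) {
  s <- summary(x)
  cat("PanGenomeMatrix:", s$n_pan_genes, "pan genes x", s$n_genomes,
      "genomes (", s$n_core, "core,", s$n_orphan, "orphan,",
      s$n_dispensable, "dispensable )\n")
  invisible(x)
}

#' @export
print.PanGene <- function(x, ...) {
  cat(x$pan_id, ": ", length(x$members), " member(s) [",
      paste(names(x$members), collapse = ", "), "]\n", sep = "")
  invisible(x)
}

#' Classify a pan gene as core, orphan or dispensable
#'
#' Core genes are present in all `n` genomes, orphans in exactly one, and
#' dispensable genes in a proper subset of size at least two.
#'
#' @param pg A `PanGene`.
#' @param n Number of genomes in the roster.
#' @return One of `"core"`, `"orphan"`, `"dispensable"`.
#' @export
classify <- function(pg, n) {
  k <- length(pg$members)
  if (k < 1L || k > n) {
    stop("Pan gene ", pg$pan_id, " has ", k, " members outside [1, ", n, "]")
  }
  if (k == n) "core" else if (k == 1L) "orphan" else "dispensable"
}

#' Summary statistics of a pan-genome matrix
#'
#' @param object A `PanGenomeMatrix`.
#' @param ... Ignored.
#' @return A `SummaryStats` list with `n_genomes`, `n_pan_genes`, `n_core`,
#'   `n_orphan`, `n_dispensable`.
#' @export
summary.PanGenomeMatrix <- function(object, ...) {
  n <- length(object$roster)
  cls <- vapply(object$pangenes, classify, "", n = n)
  structure(list(
    n_genomes = n,
    n_pan_genes = length(cls),
    n_core = sum(cls == "core"),
    n_orphan = sum(cls == "orphan"),
    n_dispensable = sum(cls == "dispensable")
  ), class = "SummaryStats")
}

#' @export
print.SummaryStats <- function(x, ...) {
  cat("genomes:     ", x$n_genomes, "\n",
      "pan genes:   ", x$n_pan_genes, "\n",
      "core:        ", x$n_core, "\n",
      "orphan:      ", x$n_orphan, "\n",
      "dispensable: ", x$n_dispensable, "\n", sep = "")
  invisible(x)
}

.pg_index <- function(m, pan_id) {
  i <- match(pan_id, names(m$pangenes))
  if (is.na(i)) stop("Unknown pan gene id: ", pan_id)
  i
}

#' Test whether pan genes can be aggregated
#'
#' Aggregation requires complementarity: the member genome sets of the
#' selected pan genes must be pairwise disjoint. Strand differences never
#' block aggregation, since orthologs can change strand through inversions.
#'
#' @param m A `PanGenomeMatrix`.
#' @param pan_ids Two or more pan gene identifiers.
#' @return `TRUE` or `FALSE`, with attribute `"reason"` naming the first
#'   genome shared between two groups when `FALSE`.
#' @export
can_aggregate <- function(m, pan_ids) {
  if (length(pan_ids) < 2L) stop("Aggregation needs at least two pan genes")
  if (anyDuplicated(pan_ids)) stop("Duplicate pan gene ids in selection")
  idx <- vapply(pan_ids, .pg_index, 0L, m = m)
  seen <- character(0)
  for (i in idx) {
    gs <- names(m$pangenes[[i]]$members)
    shared <- intersect(seen, gs)
    if (length(shared)) {
      res <- FALSE
      attr(res, "reason") <- paste0(
        "genome ", shared[1], " has a gene in more than one selected group")
      return(res)
    }
    seen <- c(seen, gs)
  }
  res <- TRUE
  attr(res, "reason") <- "complementary"
  res
}

# Number of original (leaf) pan genes folded into pg.
.n_leaves <- function(pg) {
  if (is.null(pg$constituents) || length(pg$constituents) == 0L) return(1L)
  sum(vapply(pg$constituents, .n_leaves, integer(1)))
}

# Most frequent value; ties broken lexicographically.
.consensus <- function(values) {
  values <- values[!is.na(values) & values != ""]
  if (length(values) == 0L) return("")
  tab <- table(values)
  names(tab)[order(-tab, names(tab))][1]
}

.snapshot <- function(m) list(pangenes = m$pangenes, agn_serial = m$agn_serial)

#' Aggregate complementary pan genes
#'
#' Merges the selected pan genes into one group carrying a fresh `AGN`
#' identifier and a display label `AGN<serial> (k)`, where `k` counts the
#' original pan genes folded in (nested aggregates contribute their own
#' constituent counts). The merged row replaces the constituent with the
#' smallest SuperGenome start, preserving the positional ordering; the other
#' constituent rows are removed. The event is appended to the interaction
#' history and can be reversed with [deaggregate()] or [undo()].
#'
#' @param x A `PanGenomeMatrix`.
#' @param pan_ids Two or more complementary pan gene identifiers.
#' @param ... Ignored.
#' @return The modified matrix, with the new id in attribute `"new_pan_id"`.
#' @export
aggregate.PanGenomeMatrix <- function(x, pan_ids, ...) {
  ok <- can_aggregate(x, pan_ids)
  if (!ok) {
    stop("Aggregation is not feasible: ", attr(ok, "reason"))
  }
  idx <- vapply(pan_ids, .pg_index, 0L, m = x)
  parts <- x$pangenes[idx]

  x$undo_stack[[length(x$undo_stack) + 1L]] <- .snapshot(x)
  x$agn_serial <- x$agn_serial + 1L
  agn_id <- paste0("AGN", x$agn_serial)

  members <- list()
  for (pg in parts) members <- c(members, pg$members)
  members <- members[order(match(names(members), x$roster))]

  starts <- vapply(parts, `[[`, NA_integer_, "super_start")
  stops <- vapply(parts, `[[`, NA_integer_, "super_stop")
  k <- sum(vapply(parts, .n_leaves, integer(1)))

  merged <- new_pangene(
    pan_id = agn_id,
    members = members,
    super_start = if (all(is.na(starts))) NA_integer_ else min(starts, na.rm = TRUE),
    super_stop = if (all(is.na(stops))) NA_integer_ else max(stops, na.rm = TRUE),
    consensus_description = .consensus(
      vapply(members, function(mm) mm$description %||% "", "")),
    tigrfam_id = {
      tf <- .consensus(vapply(members, function(mm)
        mm$tigrfam_id %||% NA_character_, ""))
      if (tf == "") NA_character_ else tf
    },
    aggregated_from = unname(vapply(parts, `[[`, "", "pan_id")))
  merged$constituents <- unname(parts)
  merged$orig_rows <- unname(idx)
  attr(merged, "label") <- sprintf("%s (%d)", agn_id, k)

  # place at the row of the constituent with the smallest super_start
  # (row rank as fallback when coordinates are absent)
  anchor <- if (all(is.na(starts))) min(idx) else idx[which.min(starts)]
  x$pangenes[[anchor]] <- merged
  names(x$pangenes)[anchor] <- agn_id
  drop <- setdiff(idx, anchor)
  if (length(drop)) x$pangenes <- x$pangenes[-drop]

  x <- .log_event(x, "aggregate", pan_ids, agn_id)
  attr(x, "new_pan_id") <- agn_id
  x
}

#' Display label of a pan gene
#'
#' For aggregated rows this is `AGN<serial> (k)` with `k` the number of
#' original pan genes folded in; otherwise the plain identifier.
#' @param pg A `PanGene`.
#' @return A character label.
#' @export
pan_label <- function(pg) {
  lbl <- attr(pg, "label")
  if (is.null(lbl)) pg$pan_id else lbl
}

#' Deaggregate an aggregated pan gene
#'
#' Restores the constituent pan genes exactly as they were before the
#' aggregation (identifiers, row positions, memberships), removes the `AGN`
#' row, and logs the event.
#'
#' @param m A `PanGenomeMatrix`.
#' @param agn_id Identifier of an aggregated pan gene.
#' @return The modified matrix.
#' @export
deaggregate <- function(m, agn_id) {
  i <- .pg_index(m, agn_id)
  pg <- m$pangenes[[i]]
  if (is.null(pg$constituents) || length(pg$constituents) == 0L) {
    stop("Pan gene ", agn_id, " is not an aggregated group")
  }
  m$undo_stack[[length(m$undo_stack) + 1L]] <- .snapshot(m)

  remaining <- m$pangenes[-i]
  ord <- order(pg$orig_rows)
  for (j in ord) {
    at <- min(pg$orig_rows[j], length(remaining) + 1L)
    remaining <- append(remaining, stats::setNames(
      list(pg$constituents[[j]]), pg$constituents[[j]]$pan_id), after = at - 1L)
  }
  m$pangenes <- remaining
  m <- .log_event(m, "deaggregate", agn_id,
                  paste(vapply(pg$constituents, `[[`, "", "pan_id"),
                        collapse = ","))
  m
}

#' Undo the last interaction
#'
#' Reverses the most recent aggregation or deaggregation. The history is an
#' append-only audit log: undo appends a compensating `undo` event rather
#' than truncating it.
#'
#' @param m A `PanGenomeMatrix`.
#' @return The matrix as it was before the last event.
#' @export
undo <- function(m) {
  if (length(m$undo_stack) == 0L) stop("Nothing to undo")
  snap <- m$undo_stack[[length(m$undo_stack)]]
  m$undo_stack[[length(m$undo_stack)]] <- NULL
  m$pangenes <- snap$pangenes
  m$agn_serial <- snap$agn_serial
  .log_event(m, "undo", character(0), "")
}

#' Export the interaction history
#'
#' Writes the append-only event log as a tab-separated file with columns
#' `timestamp`, `kind`, `pan_ids`, `result`. The log can be replayed on the
#' originally loaded matrix with [replay_history()].
#'
#' @param m A `PanGenomeMatrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_history <- function(m, path) {
  utils::write.table(m$history, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Replay an interaction history
#'
#' Applies a sequence of `aggregate`/`deaggregate`/`undo` events (as recorded
#' in the history of a matrix, or read back from [export_history()] output)
#' to a matrix in its loaded state.
#'
#' @param m A `PanGenomeMatrix` in the state the history started from.
#' @param history A history data frame (`m$history` of another matrix) or the
#'   path to an exported history TSV.
#' @return The matrix after all events.
#' @export
replay_history <- function(m, history) {
  if (is.character(history)) {
    history <- utils::read.delim(history, colClasses = "character")
  }
  for (r in seq_len(nrow(history))) {
    kind <- history$kind[r]
    if (kind == "aggregate") {
      m <- aggregate(m, strsplit(history$pan_ids[r], ",", fixed = TRUE)[[1]])
    } else if (kind == "deaggregate") {
      m <- deaggregate(m, history$pan_ids[r])
    } else if (kind == "undo") {
      m <- undo(m)
    } else {
      stop("Unknown event kind in history: ", kind)
    }
  }
  m
}

# Canonical state for equality checks: row order, ids and full pan gene
# content, ignoring history/undo bookkeeping.
.canonical_state <- function(m) {
  list(roster = m$roster, dialect = m$dialect,
       pangenes = lapply(m$pangenes, function(pg) {
         attr(pg, "label") <- NULL
         pg
       }))
}

#' Test two matrices for equal curated state
#'
#' Compares roster, row order and every pan gene (identifier, members,
#' coordinates, descriptions), ignoring history and undo bookkeeping.
#' @param a,b `PanGenomeMatrix` objects.
#' @return `TRUE` or `FALSE`.
#' @export
same_matrix_state <- function(a, b) {
  identical(.canonical_state(a), .canonical_state(b))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
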