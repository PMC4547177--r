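# Curation support: detect pan genes that look like one group disrupted by
# alignment or annotation error (close rows, complementary genome sets,
# matching functional annotation), and search the matrix.

#' Find aggregation candidates
#'
#' A disrupted pan gene typically shows up as two rows in direct or very
#' close neighbourhood on the SuperGenome axis whose genome sets are
#' complementary and whose functional annotation agrees. This scans all row
#' pairs within `window` ranks of each other, keeps those that pass
#' [can_aggregate()] and the annotation requirement, and ranks them by row
#' distance (ascending), then combined member count (descending). The number
#' of core genes directly flanking the pair is reported as an informational
#' score, not used as a filter.
#'
#' @param m A `PanGenomeMatrix`.
#' @param window Maximum row-rank distance between candidate rows
#'   (default 2).
#' @param require Annotation evidence required: `"tigrfam"` (equal non-empty
#'   consensus TIGRFAM), `"description"` (case-insensitive equal non-empty
#'   consensus descriptions) or `"either"`.
#' @return A data frame with columns `rank_i`, `rank_j`, `pan_id_i`,
#'   `pan_id_j`, `reason`, `combined_size`, `flanking_core_count`.
#' @export
find_candidates <- function(m, window = 2L,
                            require = c("either", "tigrfam", "description")) {
  require <- match.arg(require)
  if (window < 1L) stop("window must be >= 1")
  n_rows <- length(m$pangenes)
  n <- length(m$roster)
  out <- data.frame(rank_i = integer(0), rank_j = integer(0),
                    pan_id_i = character(0), pan_id_j = character(0),
                    reason = character(0), combined_size = integer(0),
                    flanking_core_count = integer(0),
                    stringsAsFactors = FALSE)
  if (n_rows < 2L) return(out)
  cls <- vapply(m$pangenes, classify, "", n = n)
  for (i in seq_len(n_rows - 1L)) {
    for (j in (i + 1L):min(n_rows, i + window)) {
      a <- m$pangenes[[i]]; b <- m$pangenes[[j]]
      tf_match <- !is.na(a$tigrfam_id) && !is.na(b$tigrfam_id) &&
        a$tigrfam_id == b$tigrfam_id
      de_match <- nzchar(a$consensus_description) &&
        nzchar(b$consensus_description) &&
        tolower(a$consensus_description) == tolower(b$consensus_description)
      hit <- switch(require,
                    tigrfam = tf_match,
                    description = de_match,
                    either = tf_match || de_match)
      if (!hit) next
      if (!isTRUE(can_aggregate(m, c(a$pan_id, b$pan_id)))) next
      flank <- sum(c(if (i > 1L) cls[i - 1L] == "core" else FALSE,
                     if (j < n_rows) cls[j + 1L] == "core" else FALSE))
      out <- rbind(out, data.frame(
        rank_i = i, rank_j = j, pan_id_i = a$pan_id, pan_id_j = b$pan_id,
        reason = if (tf_match && de_match) "tigrfam+description"
                 else if (tf_match) "tigrfam" else "description",
        combined_size = length(a$members) + length(b$members),
        flanking_core_count = flank, stringsAsFactors = FALSE))
    }
  }
  out <- out[order(out$rank_j - out$rank_i, -out$combined_size, out$rank_i), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a candidate report
#'
#' @param candidates Data frame from [find_candidates()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(candidates, path) {
  utils::write.table(candidates, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Search a pan-genome matrix
#'
#' Case-insensitive substring search over selected fields, letting the user
#' find genes, pan genes, aggregated groups or pan genes of specific
#' function. Matches are ordered by row rank.
#'
#' @param m A `PanGenomeMatrix`.
#' @param query Non-empty search string.
#' @param fields Fields to search: any of `"gene_id"`, `"pan_id"`,
#'   `"description"`, `"tigrfam_id"`.
#' @return A data frame with columns `rank`, `pan_id`, `genome_id` (`NA` for
#'   row-level matches), `field` and `value`.
#' @export
search_pangenome <- function(m, query,
                             fields = c("gene_id", "pan_id", "description",
                                        "tigrfam_id")) {
  if (!nzchar(query)) stop("Search query must be non-empty")
  fields <- match.arg(fields, several.ok = TRUE)
  q <- tolower(query)
  hit <- function(x) !is.na(x) && grepl(q, tolower(x), fixed = TRUE)
  res <- list()
  add <- function(rank, pan_id, genome_id, field, value) {
    res[[length(res) + 1L]] <<- data.frame(
      rank = rank, pan_id = pan_id, genome_id = genome_id,
      field = field, value = value, stringsAsFactors = FALSE)
  }
  for (r in seq_along(m$pangenes)) {
    pg <- m$pangenes[[r]]
    if ("pan_id" %in% fields && hit(pg$pan_id)) {
      add(r, pg$pan_id, NA_character_, "pan_id", pg$pan_id)
    }
    if ("description" %in% fields && hit(pg$consensus_description)) {
      add(r, pg$pan_id, NA_character_, "description",
          pg$consensus_description)
    }
    if ("tigrfam_id" %in% fields && hit(pg$tigrfam_id)) {
      add(r, pg$pan_id, NA_character_, "tigrfam_id", pg$tigrfam_id)
    }
    if ("gene_id" %in% fields) {
      for (g in names(pg$members)) {
        if (hit(pg$members[[g]]$gene_id)) {
          add(r, pg$pan_id, g, "gene_id", pg$members[[g]]$gene_id)
        }
      }
    }
  }
  if (length(res) == 0L) {
    return(data.frame(rank = integer(0), pan_id = character(0),
                      genome_id = character(0), field = character(0),
                      value = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  out <- out[order(out$rank), , drop = FALSE]
  rownames(out) <- NULL
  out
}
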