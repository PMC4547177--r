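# Readers and writers for the tabular formats the tool touches: GFF3 gene
# annotations, the two pan-genome map dialects, and TIGRFAM assignment
# tables. All writers emit UTF-8, tab-separated, unquoted rows.

#' Read gene annotations from a GFF3 file
#'
#' Selects records of one feature type and returns them as a plain
#' annotation table. Records without an `ID` attribute, or with strand `"."`
#' (strand is required to orient the presence glyphs), are skipped with a
#' warning.
#'
#' @param path Path to a GFF3 file for a single genome.
#' @param genome_id Genome identifier to stamp on every annotation.
#' @param feature_type GFF3 type to keep, usually `"gene"` or `"CDS"`.
#' @return A data frame with columns `genome_id`, `gene_id`, `start`, `end`
#'   (1-based inclusive), `strand` and `description`, in file order.
#' @export
read_gff <- function(path, genome_id, feature_type = "gene") {
  gr <- rtracklayer::import.gff3(path)
  gr <- gr[as.character(gr$type) == feature_type]
  if (length(gr) == 0L) {
    return(data.frame(genome_id = character(0), gene_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), description = character(0),
                      stringsAsFactors = FALSE))
  }
  ids <- as.character(gr$ID)
  strands <- as.character(BiocGenerics::strand(gr))
  desc <- rep("", length(gr))
  for (col in c("product", "description", "Name")) {
    if (col %in% names(S4Vectors::mcols(gr))) {
      v <- as.character(S4Vectors::mcols(gr)[[col]])
      desc <- ifelse(desc == "" & !is.na(v), v, desc)
    }
  }
  keep <- rep(TRUE, length(gr))
  if (anyNA(ids)) {
    warning(sum(is.na(ids)), " record(s) without ID attribute skipped in ",
            basename(path))
    keep <- keep & !is.na(ids)
  }
  if (any(strands == "*")) {
    warning(sum(strands == "*" & keep),
            " record(s) without strand skipped in ", basename(path))
    keep <- keep & strands != "*"
  }
  ann <- data.frame(
    genome_id = genome_id,
    gene_id = ids[keep],
    start = BiocGenerics::start(gr)[keep],
    end = BiocGenerics::end(gr)[keep],
    strand = strands[keep],
    description = desc[keep],
    stringsAsFactors = FALSE)
  if (anyDuplicated(ann$gene_id)) {
    stop("Duplicate gene ID within genome ", genome_id, ": ",
         ann$gene_id[duplicated(ann$gene_id)][1])
  }
  rownames(ann) <- NULL
  ann
}

.read_tsv_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines[!grepl("^\\s*$", lines)]
}

#' Read a pan-genome map file
#'
#' Two dialects are supported. The `"pangee"` dialect has columns `pan_id`,
#' `super_start`, `super_stop`, `consensus_description`, followed by a
#' `gene_id`/`strand`/`description` column triplet per genome (empty triplet
#' = gene absent). The `"generic"` dialect has a `pan_id` column followed by
#' one column per genome whose cells are empty or hold `gene_id` or
#' `gene_id:-` tokens (strand suffix optional, `+` by default).
#'
#' @param path Path to a tab-delimited pan-genome map.
#' @param dialect `"pangee"` or `"generic"`.
#' @return A [new_pan_matrix()] object; genome roster in header order, pan
#'   genes in row order.
#' @export
read_panmap <- function(path, dialect = c("pangee", "generic")) {
  dialect <- match.arg(dialect)
  lines <- .read_tsv_lines(path)
  if (length(lines) == 0L) stop("Empty pan-genome map: ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  rows <- lapply(lines[-1], function(l) strsplit(l, "\t", fixed = TRUE)[[1]])

  if (dialect == "generic") {
    roster <- header[-1]
    make_pg <- function(cells, pan_id) {
      members <- list()
      for (j in seq_along(roster)) {
        tok <- if (j + 1L <= length(cells)) cells[j + 1L] else ""
        if (tok == "") next
        if (grepl("[ ,;]", tok)) {
          stop("Pan gene ", pan_id, ", genome ", roster[j],
               ": cell holds more than one gene (a pan gene cannot contain ",
               "two or more genes from the same genome)")
        }
        strand <- "+"
        if (grepl(":[+-]$", tok)) {
          strand <- substring(tok, nchar(tok))
          tok <- substring(tok, 1L, nchar(tok) - 2L)
        }
        members[[roster[j]]] <- list(gene_id = tok, strand = strand,
                                     description = "",
                                     tigrfam_id = NA_character_)
      }
      new_pangene(pan_id, members)
    }
    pgs <- lapply(rows, function(cells) make_pg(cells, cells[1]))
  } else {
    if (length(header) < 4L || (length(header) - 4L) %% 3L != 0L) {
      stop("Malformed pangee header: expected pan_id, super_start, ",
           "super_stop, consensus_description + 3 columns per genome")
    }
    n_gen <- (length(header) - 4L) %/% 3L
    roster <- vapply(seq_len(n_gen), function(j) {
      sub("\\.gene_id$", "", header[4L + 3L * (j - 1L) + 1L])
    }, "")
    make_pg <- function(cells) {
      cells <- c(cells, rep("", length(header) - length(cells)))
      members <- list()
      for (j in seq_len(n_gen)) {
        base <- 4L + 3L * (j - 1L)
        gid <- cells[base + 1L]
        if (gid == "") next
        members[[roster[j]]] <- list(
          gene_id = gid,
          strand = cells[base + 2L],
          description = cells[base + 3L],
          tigrfam_id = NA_character_)
      }
      new_pangene(
        cells[1], members,
        super_start = if (cells[2] == "") NA_integer_ else as.integer(cells[2]),
        super_stop = if (cells[3] == "") NA_integer_ else as.integer(cells[3]),
        consensus_description = cells[4])
    }
    pgs <- lapply(rows, make_pg)
  }

  ids <- vapply(pgs, `[[`, "", "pan_id")
  if (anyDuplicated(ids)) {
    stop("Duplicate pan gene identifier in ", path, ": ",
         ids[duplicated(ids)][1])
  }
  new_pan_matrix(roster, pgs, dialect = dialect)
}

#' Write a pan-genome map file
#'
#' The output dialect defaults to the one the matrix was loaded from, so that
#' a modified matrix is saved in the same format as the chosen input format.
#' Reading the file back reproduces identifiers, row order, memberships and
#' strands; aggregated rows keep their `AGN` identifiers.
#'
#' @param m A `PanGenomeMatrix`.
#' @param path Output path.
#' @param dialect `"pangee"` or `"generic"`; default: the matrix's source
#'   dialect.
#' @return `path`, invisibly.
#' @export
write_panmap <- function(m, path, dialect = NULL) {
  dialect <- dialect %||% m$dialect
  dialect <- match.arg(dialect, c("pangee", "generic"))
  na2empty <- function(x) ifelse(is.na(x), "", as.character(x))
  if (dialect == "generic") {
    header <- paste(c("pan_id", m$roster), collapse = "\t")
    body <- vapply(m$pangenes, function(pg) {
      cells <- vapply(m$roster, function(g) {
        mm <- pg$members[[g]]
        if (is.null(mm)) return("")
        if (mm$strand == "-") paste0(mm$gene_id, ":-") else mm$gene_id
      }, "")
      paste(c(pg$pan_id, cells), collapse = "\t")
    }, "")
  } else {
    header <- paste(c("pan_id", "super_start", "super_stop",
                      "consensus_description",
                      unlist(lapply(m$roster, function(g)
                        paste0(g, c(".gene_id", ".strand", ".description"))))),
                    collapse = "\t")
    body <- vapply(m$pangenes, function(pg) {
      cells <- unlist(lapply(m$roster, function(g) {
        mm <- pg$members[[g]]
        if (is.null(mm)) c("", "", "")
        else c(mm$gene_id, mm$strand, mm$description)
      }))
      paste(c(pg$pan_id, na2empty(pg$super_start), na2empty(pg$super_stop),
              pg$consensus_description, cells), collapse = "\t")
    }, "")
  }
  con <- file(path, open = "wb", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(header, unname(body)), con, sep = "\n")
  invisible(path)
}

#' Read a TIGRFAM assignment table
#'
#' Expects a tab-delimited file with columns `gene_id`, `tigrfam_id` and an
#' optional family description. Genes absent from the file simply carry no
#' assignment; duplicated gene rows keep the first assignment (one family
#' per gene), with a warning.
#'
#' @param path Path to the assignment table. A header row starting with
#'   `gene_id` is tolerated and skipped.
#' @return A data frame with columns `gene_id`, `tigrfam_id`, `description`.
#' @export
read_tigrfam <- function(path) {
  lines <- .read_tsv_lines(path)
  if (length(lines) && startsWith(lines[1], "gene_id")) lines <- lines[-1]
  if (length(lines) == 0L) {
    return(data.frame(gene_id = character(0), tigrfam_id = character(0),
                      description = character(0), stringsAsFactors = FALSE))
  }
  parts <- lapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1]])
  df <- data.frame(
    gene_id = vapply(parts, `[`, "", 1),
    tigrfam_id = vapply(parts, function(p)
      if (length(p) >= 2L) p[2] else "", ""),
    description = vapply(parts, function(p)
      if (length(p) >= 3L) p[3] else "", ""),
    stringsAsFactors = FALSE)
  if (anyDuplicated(df$gene_id)) {
    warning("Duplicate gene_id rows in ", basename(path),
            "; keeping the first assignment per gene")
    df <- df[!duplicated(df$gene_id), , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Attach TIGRFAM assignments to a pan-genome matrix
#'
#' Stamps the per-gene `tigrfam_id` on every member and sets each pan gene's
#' consensus family (most frequent member family, ties broken
#' lexicographically). Assignments for gene ids not present in the matrix are
#' counted and reported via a message.
#'
#' @param m A `PanGenomeMatrix`.
#' @param assignments Data frame from [read_tigrfam()].
#' @return The annotated matrix.
#' @export
attach_tigrfam <- function(m, assignments) {
  lut <- stats::setNames(assignments$tigrfam_id, assignments$gene_id)
  used <- character(0)
  m$pangenes <- lapply(m$pangenes, function(pg) {
    fams <- character(0)
    for (g in names(pg$members)) {
      gid <- pg$members[[g]]$gene_id
      if (!is.na(lut[gid])) {
        pg$members[[g]]$tigrfam_id <- unname(lut[gid])
        fams <- c(fams, unname(lut[gid]))
        used <<- c(used, gid)
      }
    }
    tf <- .consensus(fams)
    pg$tigrfam_id <- if (tf == "") NA_character_ else tf
    pg
  })
  unused <- setdiff(assignments$gene_id, used)
  if (length(unused)) {
    message(length(unused),
            " TIGRFAM assignment(s) refer to genes not in the matrix")
  }
  m
}
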