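# Static rendering of the pan-genome matrix: strand-oriented arrow glyphs,
# presence/strand/TIGRFAM colour schemes, a group-size column, an overview
# thumbnail, and export to SVG, PDF and bitmap formats. The SVG writer is
# a purpose-built serialiser so that identical input yields identical bytes.

.PRESENCE_COLOUR <- "#4575B4"   # default colour of a present gene
.FORWARD_COLOUR <- "#1B7837"    # strand scheme: forward
.REVERSE_COLOUR <- "#762A83"    # strand scheme: reverse
.CORE_COLOUR <- "#0000FF"       # group-size column: core = blue
.ORPHAN_COLOUR <- "#FF0000"     # group-size column: orphan = red
.AGN_HIGHLIGHT <- "#FFF2B2"     # background of aggregated row headers

#' The 20-colour TIGRFAM palette
#'
#' Twenty colours with hues chosen equidistantly from the HSB spectrum
#' (hue i/20 for i = 0..19) at fixed saturation and brightness.
#'
#' @param saturation,brightness HSB saturation and brightness components.
#' @return Character vector of 20 distinct hex colours.
#' @export
tigrfam_palette <- function(saturation = 0.65, brightness = 0.85) {
  grDevices::hsv(h = (0:19) / 20, s = saturation, v = brightness)
}

# Stable 32-bit string hash (djb2 variant); independent of R's internals so
# colour assignment is reproducible across sessions and platforms.
.stable_hash <- function(s) {
  h <- 5381
  for (code in utf8ToInt(s)) h <- (h * 33 + code) %% 2147483647
  h
}

#' Colour for a TIGRFAM accession
#'
#' Maps an accession to one of the 20 palette colours via a stable string
#' hash, so the same family always receives the same colour (repetitions
#' across families are accepted). Genes without an assignment get the
#' default presence colour.
#'
#' @param tigrfam_id Accession string or `NA`.
#' @param palette Colour vector from [tigrfam_palette()].
#' @return A single hex colour.
#' @export
colour_for <- function(tigrfam_id, palette = tigrfam_palette()) {
  if (is.null(tigrfam_id) || is.na(tigrfam_id) || !nzchar(tigrfam_id)) {
    return(.PRESENCE_COLOUR)
  }
  palette[(.stable_hash(tigrfam_id) %% length(palette)) + 1L]
}

#' Rendering configuration
#'
#' @param cell_size Cell edge length in pixels (minimum 4).
#' @param colour_scheme `"presence"` (uniform), `"strand"` (forward/reverse
#'   colours) or `"tigrfam"` (per-gene family colours).
#' @param group_size_scheme `"uniform_black"` or `"core_orphan"` (blue core,
#'   red orphan, red-to-blue gradient over dispensable sizes).
#' @param region Integer pair of pan gene ranks to draw (default: all rows).
#' @param show_headers Draw row/column headers.
#' @param saturation,brightness TIGRFAM palette components.
#' @return A `RenderConfig` list.
#' @export
render_config <- function(cell_size = 14,
                          colour_scheme = c("presence", "strand", "tigrfam"),
                          group_size_scheme = c("uniform_black",
                                                "core_orphan"),
                          region = NULL, show_headers = TRUE,
                          saturation = 0.65, brightness = 0.85) {
  if (cell_size < 4) stop("cell_size must be at least 4 px")
  structure(list(
    cell_size = cell_size,
    colour_scheme = match.arg(colour_scheme),
    group_size_scheme = match.arg(group_size_scheme),
    region = region,
    show_headers = isTRUE(show_headers),
    saturation = saturation,
    brightness = brightness
  ), class = "RenderConfig")
}

# Red (size 2) to blue (size n-1) linear RGB gradient for dispensable sizes.
.dispensable_colour <- function(size, n) {
  if (n <= 3L) return(.ORPHAN_COLOUR)
  t <- (size - 2) / ((n - 1) - 2)
  rgb <- (1 - t) * grDevices::col2rgb(.ORPHAN_COLOUR) +
    t * grDevices::col2rgb(.CORE_COLOUR)
  grDevices::rgb(rgb[1], rgb[2], rgb[3], maxColorValue = 255)
}

.fmt_num <- function(x) {
  # fixed, locale-independent numeric formatting for byte-stable SVG
  sub("\\.?0+$", "", sprintf("%.2f", x))
}

#' Render the pan-genome matrix as a glyph document
#'
#' Builds a resolution-independent document: one arrow glyph per present
#' gene (pointing up on the forward strand, down on the reverse strand),
#' blanks for absences, pan gene identifiers as row headers (aggregated rows
#' highlighted), genome names as column headers, and an optional group-size
#' column coloured by classification. The document is a pure function of the
#' matrix and configuration.
#'
#' @param m A `PanGenomeMatrix`.
#' @param config A [render_config()].
#' @return A `pan_render` document (element list plus pixel dimensions),
#'   ready for [export_image()].
#' @export
render_matrix <- function(m, config = render_config()) {
  cs <- config$cell_size
  n_col <- length(m$roster)
  region <- config$region %||% c(1L, length(m$pangenes))
  if (length(m$pangenes) == 0L) {
    region <- c(1L, 0L)
  } else if (region[1] < 1L || region[2] > length(m$pangenes) ||
             region[1] > region[2]) {
    stop("region must lie within 1..", length(m$pangenes))
  }
  rows <- if (region[2] >= region[1]) region[1]:region[2] else integer(0)
  left <- if (config$show_headers) 90 else 0
  top <- if (config$show_headers) 30 else 0
  gs_gap <- 6
  width <- left + n_col * cs + gs_gap + cs + 2
  height <- top + length(rows) * cs + 2
  n <- length(m$roster)
  palette <- tigrfam_palette(config$saturation, config$brightness)

  el <- list()
  push <- function(e) el[[length(el) + 1L]] <<- e

  if (config$show_headers) {
    for (j in seq_len(n_col)) {
      push(list(type = "text", x = left + (j - 0.5) * cs, y = top - 6,
                text = m$roster[j], anchor = "middle", size = min(cs, 11),
                colour = "#000000", class = "col-header"))
    }
  }
  for (r in seq_along(rows)) {
    pg <- m$pangenes[[rows[r]]]
    y0 <- top + (r - 1) * cs
    is_agn <- !is.null(pg$constituents) || startsWith(pg$pan_id, "AGN")
    if (config$show_headers) {
      if (is_agn) {
        push(list(type = "rect", x = 0, y = y0, w = left - 4, h = cs,
                  fill = .AGN_HIGHLIGHT, stroke = "none",
                  class = "row-highlight"))
      }
      push(list(type = "text", x = left - 6, y = y0 + cs * 0.72,
                text = pan_label(pg), anchor = "end", size = min(cs, 11),
                colour = if (is_agn) "#B35806" else "#000000",
                class = "row-header"))
    }
    for (j in seq_len(n_col)) {
      mm <- pg$members[[m$roster[j]]]
      if (is.null(mm)) next
      x0 <- left + (j - 1) * cs
      fill <- switch(config$colour_scheme,
        presence = .PRESENCE_COLOUR,
        strand = if (mm$strand == "-") .REVERSE_COLOUR else .FORWARD_COLOUR,
        tigrfam = colour_for(mm$tigrfam_id, palette))
      pad <- max(1, cs * 0.12)
      xs <- c(x0 + cs / 2, x0 + cs - pad, x0 + pad)
      ys <- if (mm$strand == "-") {
        c(y0 + cs - pad, y0 + pad, y0 + pad)     # points downwards
      } else {
        c(y0 + pad, y0 + cs - pad, y0 + cs - pad) # points upwards
      }
      push(list(type = "glyph", xs = xs, ys = ys, fill = fill,
                strand = mm$strand, gene_id = mm$gene_id,
                class = "gene-glyph"))
    }
    # group-size column
    gx <- left + n_col * cs + gs_gap
    size <- length(pg$members)
    gcol <- if (config$group_size_scheme == "uniform_black") {
      "#000000"
    } else {
      switch(classify(pg, n),
             core = .CORE_COLOUR,
             orphan = .ORPHAN_COLOUR,
             dispensable = .dispensable_colour(size, n))
    }
    bh <- max(1, cs * size / max(n, 1L))
    push(list(type = "rect", x = gx, y = y0 + cs - bh, w = cs, h = bh,
              fill = gcol, stroke = "none", class = "group-size"))
  }
  structure(list(width = width, height = height, elements = el,
                 config = config, n_rows = length(rows), n_cols = n_col),
            class = "pan_render")
}

#' @export
print.pan_render <- function(x, ...) {
  cat("pan_render document:", x$n_rows, "rows x", x$n_cols, "genomes,",
      length(x$elements), "elements,", x$width, "x", x$height, "px\n")
  invisible(x)
}

#' Render the overview thumbnail
#'
#' A miniature of the whole matrix (one shaded column stripe per pan gene,
#' darker for fuller groups) with a red outlined rectangle marking the part
#' of the matrix loaded in the current view.
#'
#' @param m A `PanGenomeMatrix`.
#' @param view_region Integer pair of pan gene ranks currently in view.
#' @param width,height Thumbnail size in pixels.
#' @return A `pan_render` document.
#' @export
render_overview <- function(m, view_region = NULL, width = 240, height = 80) {
  n_rows <- length(m$pangenes)
  el <- list()
  el[[1]] <- list(type = "rect", x = 0, y = 0, w = width, h = height,
                  fill = "#FFFFFF", stroke = "#888888", class = "frame")
  if (n_rows > 0L) {
    n <- length(m$roster)
    # coarse density stripes: at most one per horizontal pixel
    step <- max(1L, ceiling(n_rows / width))
    starts <- seq(1L, n_rows, by = step)
    for (s in starts) {
      ix <- s:min(n_rows, s + step - 1L)
      fill_frac <- mean(vapply(m$pangenes[ix], function(pg)
        length(pg$members) / n, numeric(1)))
      shade <- grDevices::gray(1 - 0.8 * fill_frac)
      x0 <- (s - 1L) / n_rows * width
      x1 <- (max(ix)) / n_rows * width
      el[[length(el) + 1L]] <- list(type = "rect", x = x0, y = 1,
                                    w = x1 - x0, h = height - 2,
                                    fill = shade, stroke = "none",
                                    class = "density")
    }
    view_region <- view_region %||% c(1L, n_rows)
    vx <- (view_region[1] - 1L) / n_rows * width
    vw <- (view_region[2] - view_region[1] + 1L) / n_rows * width
    el[[length(el) + 1L]] <- list(type = "rect", x = vx, y = 0, w = vw,
                                  h = height, fill = "none",
                                  stroke = "#FF0000", class = "view-rect")
  }
  structure(list(width = width, height = height, elements = el,
                 config = NULL, n_rows = n_rows,
                 n_cols = length(m$roster)),
            class = "pan_render")
}

.svg_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

.doc_to_svg <- function(doc) {
  out <- c(sprintf(
    paste0('<svg xmlns="http://www.w3.org/2000/svg" width="%s" height="%s" ',
           'viewBox="0 0 %s %s" version="1.1">'),
    .fmt_num(doc$width), .fmt_num(doc$height),
    .fmt_num(doc$width), .fmt_num(doc$height)))
  for (e in doc$elements) {
    out <- c(out, switch(e$type,
      rect = sprintf(
        '<rect class="%s" x="%s" y="%s" width="%s" height="%s" fill="%s" stroke="%s"/>',
        e$class, .fmt_num(e$x), .fmt_num(e$y), .fmt_num(e$w), .fmt_num(e$h),
        e$fill, e$stroke),
      glyph = sprintf(
        '<polygon class="%s" points="%s" fill="%s"/>',
        e$class,
        paste(paste(.fmt_num(e$xs), .fmt_num(e$ys), sep = ","),
              collapse = " "),
        e$fill),
      text = sprintf(
        '<text class="%s" x="%s" y="%s" text-anchor="%s" font-size="%s" font-family="sans-serif" fill="%s">%s</text>',
        e$class, .fmt_num(e$x), .fmt_num(e$y), e$anchor, .fmt_num(e$size),
        e$colour, .svg_escape(e$text)),
      stop("Unknown element type: ", e$type)))
  }
  c(out, "</svg>")
}

.draw_on_device <- function(doc) {
  graphics::par(mar = c(0, 0, 0, 0), xaxs = "i", yaxs = "i")
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, doc$width), ylim = c(doc$height, 0))
  for (e in doc$elements) {
    if (e$type == "rect") {
      graphics::rect(e$x, e$y + e$h, e$x + e$w, e$y,
                     col = if (e$fill == "none") NA else e$fill,
                     border = if (e$stroke == "none") NA else e$stroke)
    } else if (e$type == "glyph") {
      graphics::polygon(e$xs, e$ys, col = e$fill, border = NA)
    } else if (e$type == "text") {
      adj <- switch(e$anchor, middle = 0.5, end = 1, 0)
      graphics::text(e$x, e$y, labels = e$text, adj = c(adj, 0),
                     cex = e$size / 12, col = e$colour)
    }
  }
}

#' Export a rendered document to an image file
#'
#' Vector formats: SVG (byte-reproducible for fixed input and
#' configuration) and PDF. Bitmap formats: PNG, JPEG and TIFF, rasterised at
#' one pixel per document unit.
#'
#' @param doc A `pan_render` document.
#' @param path Output path.
#' @param format One of `"svg"`, `"pdf"`, `"png"`, `"jpeg"`, `"tiff"`
#'   (case-insensitive; default: from the file extension, with `jpg`
#'   accepted for JPEG).
#' @return `path`, invisibly.
#' @export
export_image <- function(doc, path, format = NULL) {
  if (is.null(format)) {
    format <- tolower(tools::file_ext(path))
    if (format == "jpg") format <- "jpeg"
  }
  format <- tolower(format)
  if (!(format %in% c("svg", "pdf", "png", "jpeg", "tiff"))) {
    stop("Unsupported image format: ", format,
         " (supported: SVG, PDF, PNG, JPEG, TIFF)")
  }
  if (format == "svg") {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(.doc_to_svg(doc), con, sep = "\n")
    return(invisible(path))
  }
  if (format == "pdf") {
    grDevices::pdf(path, width = doc$width / 72, height = doc$height / 72)
  } else {
    dev <- switch(format, png = grDevices::png, jpeg = grDevices::jpeg,
                  tiff = grDevices::tiff)
    dev(path, width = doc$width, height = doc$height)
  }
  on.exit(grDevices::dev.off())
  .draw_on_device(doc)
  invisible(path)
}
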