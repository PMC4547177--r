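# Palette, colour assignment, glyph-matrix rendering and image export.

glyph_count <- function(doc) {
  sum(vapply(doc$elements, function(e) e$type == "glyph", logical(1)))
}

test_that("the TIGRFAM palette has 20 equidistant distinct hues", {
  pal <- tigrfam_palette()
  expect_length(pal, 20L)
  expect_equal(anyDuplicated(pal), 0L)
  expect_identical(pal, grDevices::hsv(h = (0:19) / 20, s = 0.65,
                                       v = 0.85))
  # hues recovered from the 8-bit hex colours are equidistant up to
  # quantisation
  hues <- grDevices::rgb2hsv(grDevices::col2rgb(pal))["h", ]
  expect_equal(hues[1], 0)
  expect_equal(hues[11], 0.5)
  expect_equal(diff(hues), rep(1 / 20, 19), tolerance = 0.05)
})

test_that("colour assignment is stable, defaults for unassigned, repeats by pigeonhole", {
  pal <- tigrfam_palette()
  expect_equal(colour_for("TIGR00123", pal), colour_for("TIGR00123", pal))
  expect_equal(colour_for(NA_character_, pal), colour_for(NA, pal))
  expect_false(colour_for(NA_character_, pal) %in% pal)
  cols <- vapply(sprintf("TIGR%05d", 1:21), colour_for, "", palette = pal)
  expect_gt(anyDuplicated(cols), 0L)
  expect_true(all(cols %in% pal))
})

test_that("one glyph per present gene, oriented by strand", {
  m <- new_pan_matrix(c("G1", "G2", "G3"), list(
    pg_stub("P1", c("G1", "G2", "G3"), 100L),
    pg_stub("P2", c("G1", "G3"), 200L),
    pg_stub("P3", "G2", 300L, strand = "-"),
    pg_stub("P4", "G1", 400L)))
  doc <- render_matrix(m, render_config(cell_size = 10))
  expect_equal(glyph_count(doc), 7L)
  down <- Filter(function(e) e$type == "glyph" && e$strand == "-",
                 doc$elements)
  expect_length(down, 1L)
  # a down glyph has its apex (single y) below its base pair of ys
  expect_gt(down[[1]]$ys[1], down[[1]]$ys[2])
})

test_that("glyph count equals present-gene count on random matrices", {
  for (seed in c(4, 9, 23)) {
    m <- make_synthetic_matrix(n_genomes = 3 + seed %% 4, n_core = 3,
                               n_orphan = 3, n_dispensable = 2, seed = seed)
    doc <- render_matrix(m)
    expect_equal(glyph_count(doc), total_genes(m))
  }
})

test_that("rendering is pure: identical input gives identical SVG bytes", {
  m <- make_synthetic_matrix(n_genomes = 4, n_core = 2, n_orphan = 2,
                             n_dispensable = 1, seed = 6)
  cfg <- render_config(cell_size = 12, colour_scheme = "tigrfam")
  f1 <- tempfile(fileext = ".svg"); f2 <- tempfile(fileext = ".svg")
  export_image(render_matrix(m, cfg), f1)
  export_image(render_matrix(m, cfg), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("the SVG export is valid XML with the expected structure", {
  skip_if_not_installed("xml2")
  m <- new_pan_matrix(c("G1", "G2"), list(
    pg_stub("P1", "G1", 100L), pg_stub("P2", "G2", 200L)))
  a <- aggregate(m, c("P2", "P1"))   # exercise the AGN highlight
  f <- tempfile(fileext = ".svg")
  export_image(render_matrix(a), f)
  doc <- xml2::read_xml(f)
  expect_equal(xml2::xml_name(doc), "svg")
  polys <- xml2::xml_find_all(doc, "//*[local-name()='polygon']")
  expect_length(polys, 2L)
  texts <- xml2::xml_text(xml2::xml_find_all(
    doc, "//*[local-name()='text']"))
  expect_true(any(grepl("AGN1 \\(2\\)", texts)))
})

test_that("strand colouring makes an inconsistently annotated genome stand out", {
  # one genome annotated all-reverse while the others are all-forward
  pgs <- lapply(1:4, function(i) {
    members <- stats::setNames(lapply(c("G1", "G2", "G3"), function(g) list(
      gene_id = paste0(g, "_", i),
      strand = if (g == "G2") "-" else "+",
      description = "")), c("G1", "G2", "G3"))
    new_pangene(paste0("P", i), members, super_start = i * 100L,
                super_stop = i * 100L + 50L)
  })
  m <- new_pan_matrix(c("G1", "G2", "G3"), pgs)
  doc <- render_matrix(m, render_config(colour_scheme = "strand",
                                        show_headers = FALSE))
  glyphs <- Filter(function(e) e$type == "glyph", doc$elements)
  fills <- vapply(glyphs, `[[`, "", "fill")
  strands <- vapply(glyphs, `[[`, "", "strand")
  expect_length(unique(fills[strands == "-"]), 1L)
  expect_length(unique(fills[strands == "+"]), 1L)
  expect_false(unique(fills[strands == "-"]) %in% fills[strands == "+"])
})

test_that("bitmap export dimensions equal the document geometry", {
  skip_if_not_installed("png")
  m <- new_pan_matrix(c("G1", "G2"), list(pg_stub("P1", c("G1", "G2"),
                                                  100L)))
  cfg <- render_config(cell_size = 10)
  doc <- render_matrix(m, cfg)
  # headers (90 left, 30 top) + 2 cells + gap + size column + border
  expect_equal(doc$width, 90 + 2 * 10 + 6 + 10 + 2)
  expect_equal(doc$height, 30 + 1 * 10 + 2)
  f <- tempfile(fileext = ".png")
  export_image(doc, f)
  img <- png::readPNG(f)
  expect_equal(dim(img)[1:2], c(doc$height, doc$width))
})

test_that("PDF export writes a file and unsupported formats error", {
  m <- new_pan_matrix("G1", list(pg_stub("P1", "G1", 100L)))
  doc <- render_matrix(m)
  f <- tempfile(fileext = ".pdf")
  export_image(doc, f)
  expect_gt(file.size(f), 0)
  expect_error(export_image(doc, tempfile(fileext = ".bmp")),
               "Unsupported image format")
})

test_that("the overview thumbnail marks the viewed region proportionally", {
  m <- make_synthetic_matrix(n_genomes = 3, n_core = 4, n_orphan = 4,
                             n_dispensable = 2, seed = 3)
  full <- render_overview(m, c(1L, 10L), width = 200, height = 60)
  rect <- Filter(function(e) identical(e$class, "view-rect"),
                 full$elements)[[1]]
  expect_equal(rect$x, 0)
  expect_equal(rect$w, 200)

  half <- render_overview(m, c(1L, 5L), width = 200, height = 60)
  rect <- Filter(function(e) identical(e$class, "view-rect"),
                 half$elements)[[1]]
  expect_equal(rect$w, 100)

  blank <- render_overview(new_pan_matrix("G1", list()))
  expect_length(Filter(function(e) identical(e$class, "view-rect"),
                       blank$elements), 0L)
})

test_that("region selection bounds are validated and cell size has a floor", {
  m <- make_synthetic_matrix(n_genomes = 3, n_core = 2, n_orphan = 1,
                             n_dispensable = 1, seed = 2)
  doc <- render_matrix(m, render_config(region = c(2L, 3L)))
  present <- sum(vapply(m$pangenes[2:3], function(pg) length(pg$members),
                        integer(1)))
  expect_equal(glyph_count(doc), present)
  expect_error(render_matrix(m, render_config(region = c(0L, 2L))), "region")
  expect_error(render_matrix(m, render_config(region = c(2L, 99L))),
               "region")
  expect_error(render_config(cell_size = 3), "cell_size")
})
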