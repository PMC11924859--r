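test_that("detections scale per axis from image pixels to page points", {
  d <- tibble::tibble(label = "table", score = 0.9, page = 0L,
                      img_w = 100, img_h = 100,
                      x0 = 10, y0 = 10, x1 = 20, y1 = 20)
  expect_equal(unlist(scale_to_page(d, 100, 100)[c("x0", "y0", "x1", "y1")]),
               c(x0 = 10, y0 = 10, x1 = 20, y1 = 20))
  expect_equal(unlist(scale_to_page(d, 200, 200)[c("x0", "y0", "x1", "y1")]),
               c(x0 = 20, y0 = 20, x1 = 40, y1 = 40))
  d2 <- dplyr::mutate(d, img_h = 200)
  expect_equal(unlist(scale_to_page(d2, 200, 200)[c("x0", "y0", "x1", "y1")]),
               c(x0 = 20, y0 = 10, x1 = 40, y1 = 20))
  d3 <- dplyr::mutate(d, img_w = 0)
  expect_error(scale_to_page(d3, 100, 100), "positive")
})

test_that("column count is the lower median of cells per detected row", {
  expect_equal(estimate_column_count(c(3, 3, 3)), 3)
  expect_equal(estimate_column_count(c(3, 4, 3, 4)), 3)
  expect_equal(estimate_column_count(5), 5)
  expect_error(estimate_column_count(integer(0)), "no rows")
})

test_that("column ranges use min/max with pad and last-column expansion", {
  cells <- tibble::tibble(x0 = c(10, 12, 100, 105),
                          x1 = c(50, 48, 140, 138),
                          y0 = 0, y1 = 10)
  rng <- estimate_column_ranges(cells, 2, avg_char_width = 5, pad = 1)
  expect_equal(rng$lo[1], 9)
  expect_equal(rng$hi[1], 51)
  expect_equal(rng$hi[2], 141 + 2 * 5)  # last column + two char widths

  single <- estimate_column_ranges(cells[1:2, ], 1, avg_char_width = 5, pad = 1)
  expect_equal(unlist(single), c(lo = 9, hi = 51 + 10), ignore_attr = TRUE)

  # overlapping estimates are resolved at the midpoint
  over <- tibble::tibble(x0 = c(0, 30), x1 = c(40, 80), y0 = 0, y1 = 10)
  rng2 <- estimate_column_ranges(over, 2, avg_char_width = 1, pad = 1)
  expect_lte(rng2$hi[1], rng2$lo[2])
})

test_that("text lines group by top-y and split at wide gaps", {
  mk_chars <- function(glyphs, x0s, y0 = 100, w = 5, h = 8) {
    tibble::tibble(glyph = glyphs, x0 = x0s, y0 = y0,
                   x1 = x0s + w, y1 = y0 + h)
  }
  p <- page_record(0L, chars = mk_chars(c("a", "b"), c(0, 6)))
  lines <- build_text_lines(p)
  expect_equal(nrow(lines), 1)
  expect_equal(lines$text, "ab")

  # superscript: the raised "2" of H2O has a different top y
  ch <- dplyr::bind_rows(mk_chars(c("H", "O"), c(0, 12)),
                         mk_chars("2", 6, y0 = 95))
  p2 <- page_record(0L, chars = ch)
  lines2 <- build_text_lines(p2)
  expect_equal(length(unique(lines2$band)), 2)

  # two words separated by ten character widths split into segments
  p3 <- page_record(0L, chars = mk_chars(c("a", "b"), c(0, 60)))
  lines3 <- build_text_lines(p3)
  expect_equal(nrow(lines3), 2)
  expect_identical(build_text_lines(page_record(0L))$text, character(0))
})

test_that("word spaces are re-inserted from glyph gaps", {
  lay <- layout_spec()
  ch <- keytables:::cell_glyphs("anti GFP body", 100, 50, lay)
  p <- page_record(0L, chars = ch)
  expect_equal(build_text_lines(p)$text, "anti GFP body")
})

test_that("assembly places wrapped continuation rows with empty cells", {
  f <- overflow_fixture(seed = 31, n_rows = 6, long_cells = 1)
  raw <- reconstruct_table(f$detections, f$pages, mode = "col")
  overseg <- logical_table(f$sim$oversegmented$cells)
  expect_true(tables_equal(raw, overseg))
  # over-segmentation persists without the language model
  expect_gte(nrow(raw$cells), nrow(f$gold$cells))
  cont <- raw$cells[rowSums(raw$cells == "") > 0, , drop = FALSE]
  expect_gt(nrow(cont), 0)
})

test_that("mode row with exact boxes reproduces the over-segmented grid", {
  f <- overflow_fixture(seed = 32, n_rows = 6, long_cells = 1)
  rec <- reconstruct_table(f$detections, f$pages, mode = "row")
  expect_true(tables_equal(rec, logical_table(f$sim$oversegmented$cells)))
})

test_that("rule 1 absorbs superscript lines; unrelated rows stay", {
  f <- noiseless_fixture(seed = 33, n_rows = 5, superscripts = 2)
  rec <- reconstruct_table(f$detections, f$pages, mode = "col")
  expect_true(tables_equal(rec, logical_table(f$gold$cells)))

  # without canonicalization the superscript lines survive as rows
  raw <- reconstruct_table(f$detections, f$pages, mode = "col",
                           canonicalize = FALSE)
  expect_gt(nrow(raw$cells), nrow(f$gold$cells))
})

test_that("rule 2 merges a vertically overlapping continuation row", {
  # build segment geometry directly: a full row and, 60% overlapping it
  # vertically, a row with two empty cells (e.g. a lowered annotation)
  lines <- tibble::tibble(
    band = c(1L, 1L, 1L, 2L),
    y_top = c(0, 0, 0, 4), y0 = c(0, 0, 0, 4), y1 = c(10, 10, 10, 14),
    x0 = c(0, 50, 100, 0), x1 = c(40, 90, 140, 30),
    text = c("name", "source", "id", "extra"),
    page = 0L, chars = vector("list", 4))
  ranges <- tibble::tibble(lo = c(-1, 49, 99), hi = c(41, 91, 141))
  grid <- assemble_grid(lines, ranges)
  expect_equal(dim(grid$table), c(2L, 3L))
  merged <- heuristic_row_merge(grid, tsr_row_boxes = NULL)
  expect_equal(dim(merged), c(1L, 3L))
  expect_equal(merged$cells[1, 1], "name extra")

  # zero vertical overlap: rule 2 does not fire
  lines2 <- dplyr::mutate(lines, y_top = c(0, 0, 0, 12),
                          y0 = c(0, 0, 0, 12), y1 = c(10, 10, 10, 22))
  grid2 <- assemble_grid(lines2, ranges)
  expect_equal(dim(heuristic_row_merge(grid2, NULL)), c(2L, 3L))
})

test_that("heuristic row merge is idempotent", {
  f <- noiseless_fixture(seed = 34, n_rows = 6, superscripts = 2)
  p <- f$pages[[1]]
  d <- scale_to_page(f$detections, p$page_width, p$page_height)
  cellb <- d[d$label == "table_cell", ]
  rowb <- d[d$label == "table_row", ]
  lines <- build_text_lines(p)
  rng <- estimate_column_ranges(cellb, 3, 4)
  grid <- assemble_grid(lines, rng)
  once <- heuristic_row_merge(grid, tibble::tibble(lo = rowb$y0, hi = rowb$y1))
  # re-running on the merged result (rebuilt grid state) changes nothing
  expect_true(tables_equal(
    once,
    heuristic_row_merge(list(table = once, row_geom = grid$row_geom,
                             segments = grid$segments),
                        tibble::tibble(lo = rowb$y0, hi = rowb$y1))))
})

test_that("reconstruction conserves the glyph multiset inside the table", {
  for (s in c(41, 42)) {
    f <- overflow_fixture(seed = s, n_rows = 7, long_cells = 1)
    rec <- reconstruct_table(f$detections, f$pages, mode = "col")
    glyphs_in <- sort(unlist(lapply(f$pages, function(p) p$chars$glyph)))
    glyphs_out <- sort(strsplit(gsub(" ", "", paste(rec$cells, collapse = "")),
                                "")[[1]])
    expect_identical(glyphs_out, glyphs_in)
  }
})

test_that("cell x-centers are monotone across columns in every row", {
  f <- noiseless_fixture(seed = 43, n_rows = 6)
  p <- f$pages[[1]]
  d <- scale_to_page(f$detections, p$page_width, p$page_height)
  cellb <- d[d$label == "table_cell", ]
  rng <- estimate_column_ranges(cellb, 3, 4)
  lines <- build_text_lines(p)
  grid <- assemble_grid(lines, rng)
  segs <- grid$segments
  for (r in unique(segs$.row)) {
    rs <- segs[segs$.row == r, ]
    rs <- rs[order(rs$.col), ]
    expect_true(!is.unsorted((rs$x0 + rs$x1) / 2))
  }
})

test_that("missing table detections raise an error", {
  f <- noiseless_fixture(seed = 44, n_rows = 4)
  d <- f$detections[f$detections$label != "table", ]
  expect_error(reconstruct_table(d, f$pages), "no table detection")
})

test_that("jittered row boxes hurt row mode more than column mode", {
  diffs <- numeric(0)
  for (s in 1:12) {
    f <- noiseless_fixture(seed = 200 + s, n_rows = 7, jitter_sd = 2.5)
    col_g <- grits(f$gold, reconstruct_table(f$detections, f$pages, "col"))$grits
    row_g <- grits(f$gold, reconstruct_table(f$detections, f$pages, "row"))$grits
    diffs <- c(diffs, col_g - row_g)
  }
  expect_gte(mean(diffs), 0)
})
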