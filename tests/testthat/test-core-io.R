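test_that("charboxes JSONL round-trips both dialects and preserves glyphs", {
  chars <- tibble::tibble(glyph = c("A", "b", "µ"),
                          x0 = c(10, 16, 22), y0 = c(100, 100, 97.6),
                          x1 = c(15, 21, 27), y1 = c(110, 110, 107.6))
  pg <- page_record(0L, 612, 792, chars)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_charboxes(list(pg), path)
  back <- read_charboxes(path)
  expect_length(back, 1)
  expect_equal(back[[1]]$chars$glyph, chars$glyph)
  expect_equal(back[[1]]$chars$x0, chars$x0)

  # per-character dialect
  path2 <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c('{"page":1,"c":"A","x0":1,"y0":2,"x1":3,"y1":4}',
               '{"page":0,"c":"b","x0":5,"y0":6,"x1":7,"y1":8}'), path2)
  pages <- read_charboxes(path2)
  expect_equal(vapply(pages, `[[`, integer(1), "page_index"), c(0L, 1L))
  expect_equal(pages[[2]]$chars$glyph, "A")
})

test_that("charboxes reader rejects malformed and invalid records by line", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c('{"page":0,"c":"A","x0":1,"y0":2,"x1":3,"y1":4}', "{oops"), path)
  expect_error(read_charboxes(path), "line 2")
  writeLines('{"page":0,"c":"A","x0":9,"y0":2,"x1":3,"y1":4}', path)
  expect_error(read_charboxes(path), "x0 < x1")
  file.create(path2 <- withr::local_tempfile(fileext = ".jsonl"))
  expect_identical(read_charboxes(path2), list())
})

test_that("bottom-left-origin extractors can be ingested with flip_y", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines('{"page":0,"w":100,"h":200,"chars":[{"c":"A","x0":1,"y0":20,"x1":3,"y1":30}]}',
             path)
  pg <- read_charboxes(path, flip_y = TRUE)[[1]]
  expect_equal(pg$chars$y0, 170)
  expect_equal(pg$chars$y1, 180)
})

test_that("detection reader validates labels, scores and bounds", {
  path <- withr::local_tempfile(fileext = ".json")
  rec <- function(label, score = 0.9, x1 = 20) {
    sprintf('{"label":"%s","score":%g,"page":0,"img_w":100,"img_h":100,"x0":10,"y0":10,"x1":%g,"y1":20}',
            label, score, x1)
  }
  writeLines(sprintf("[%s]", rec("table_column")), path)
  d <- read_detections(path)
  expect_equal(nrow(d), 1)
  expect_equal(d$label, "table_column")

  writeLines(sprintf("[%s]", rec("figure")), path)
  expect_error(read_detections(path), "table_row")  # error lists allowed labels
  writeLines(sprintf("[%s]", rec("table", score = 1.2)), path)
  expect_error(read_detections(path), "score")
  writeLines(sprintf("[%s]", rec("table", x1 = 150)), path)
  expect_error(read_detections(path), "image bounds")
})

test_that("table writers and readers are exact inverses", {
  fly <- "Pry[+t7.2]=hsFLP12, y[1] w[*]; Pw[+mW.hs]=GawBap[md544]"
  tables <- list(
    logical_table(matrix(c("a,b", "c", "x\ny", "z"), 2, 2)),
    logical_table(matrix(fly, 1, 1)),
    logical_table(matrix(character(), 0, 0)),
    generate_resource_table(4, seed = 1))
  for (fmt in c("json", "csv", "html")) {
    for (t in tables) {
      path <- withr::local_tempfile(fileext = paste0(".", fmt))
      write_table(t, path, fmt)
      back <- read_table(path, fmt)
      expect_true(tables_equal(logical_table(t$cells), back),
                  label = sprintf("%s round trip", fmt))
    }
  }
  expect_error(write_table(tables[[1]], tempfile(), "parquet"))
})

test_that("random special-character tables survive every format", {
  set.seed(42)
  for (k in 1:15) {
    t <- random_special_table()
    for (fmt in c("json", "csv", "html")) {
      path <- withr::local_tempfile(fileext = paste0(".", fmt))
      write_table(t, path, fmt)
      expect_true(tables_equal(logical_table(t$cells), read_table(path, fmt)),
                  label = sprintf("format %s, draw %d", fmt, k))
    }
  }
})

test_that("JSON format preserves header rows and spans", {
  t <- logical_table(matrix(c("h", "h", "a", "a"), 2, 2, byrow = TRUE),
                     n_header_rows = 1L,
                     spans = tibble::tibble(row_start = 1L, row_end = 2L,
                                            col_start = 0L, col_end = 2L))
  path <- withr::local_tempfile(fileext = ".json")
  write_table(t, path, "json")
  back <- read_table(path, "json")
  expect_true(tables_equal(t, back, check_meta = TRUE))
})

test_that("logical_table enforces its invariants", {
  expect_error(logical_table(list(c("a", "b"), c("c"))), "unequal")
  expect_error(logical_table(matrix("a", 1, 1), n_header_rows = 2), "between 0 and R")
  expect_error(
    logical_table(matrix("a", 2, 2),
                  spans = tibble::tibble(row_start = c(0L, 0L), row_end = c(2L, 1L),
                                         col_start = c(0L, 0L), col_end = c(1L, 1L))),
    "overlap")
  expect_error(bbox(5, 0, 1, 1), "x0 < x1")
})

test_that("JATS tables parse with headers, spans and errors", {
  jats <- '<article><body><table-wrap id="T1"><table>
    <thead><tr><th>Name</th><th colspan="2">Details</th></tr></thead>
    <tbody><tr><td>a</td><td>b</td><td>c</td></tr>
           <tr><td>d</td><td>e</td><td>f</td></tr></tbody>
  </table></table-wrap></body></article>'
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(jats, path)
  tabs <- read_jats_tables(path)
  expect_length(tabs, 1)
  t <- tabs[[1]]
  expect_equal(dim(t), c(3L, 3L))
  expect_equal(t$n_header_rows, 1L)
  expect_equal(t$cells[1, ], c("Name", "Details", "Details"))
  expect_equal(nrow(t$spans), 1)
  expect_equal(t$spans$col_end - t$spans$col_start, 2L)

  writeLines("<article><body><p>no tables</p></body></article>", path)
  expect_identical(read_jats_tables(path), list())

  bad <- '<article><table-wrap id="T9"><table>
    <tr><td>a</td><td>b</td></tr><tr><td>only-one</td></tr>
  </table></table-wrap></article>'
  writeLines(bad, path)
  expect_error(read_jats_tables(path), "T9")

  writeLines("<article><unclosed>", path)
  expect_error(read_jats_tables(path), "parse")
})

test_that("rowspan expansion keeps the grid rectangular", {
  jats <- '<article><table-wrap id="T2"><table>
    <tr><td rowspan="2">tall</td><td>b</td></tr>
    <tr><td>d</td></tr>
  </table></table-wrap></article>'
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(jats, path)
  t <- read_jats_tables(path)[[1]]
  # hand expansion: the tall cell covers (1,1) and (2,1)
  expect_equal(t$cells, matrix(c("tall", "tall", "b", "d"), 2, 2))
  expect_equal(t$spans$row_end - t$spans$row_start, 2L)
})
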