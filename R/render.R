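#' Monospace page layout for the synthetic renderer
#'
#' All units are page points (1/72 inch), top-left origin. Glyphs are
#' `0.85 * char_width` wide on a fixed advance of `char_width`, and
#' `0.8 * line_height` tall; superscript markers are raised by
#' `0.4 * line_height`, enough to fall outside the text-line grouping
#' tolerance and produce the spurious lines the canonicalization rules
#' target. Detection boxes are emitted in image pixels at `img_scale`
#' pixels per point, optionally perturbed by Gaussian jitter of standard
#' deviation `jitter_sd` (points).
#'
#' @param char_width monospace advance (pt).
#' @param line_height baseline-to-baseline distance (pt).
#' @param column_gap horizontal gap between columns (pt).
#' @param page_width,page_height page size (pt).
#' @param max_lines_per_page lines before a page break.
#' @param jitter_sd detection-box jitter (pt, 0 = exact boxes).
#' @param margin_x,margin_y top-left text origin (pt).
#' @param img_scale detection image pixels per point.
#' @return a `layout_spec` list.
#' @export
layout_spec <- function(char_width = 6, line_height = 12, column_gap = 18,
                        page_width = 612, page_height = 792,
                        max_lines_per_page = 50, jitter_sd = 0,
                        margin_x = 54, margin_y = 54, img_scale = 2) {
  vals <- list(char_width = char_width, line_height = line_height,
               column_gap = column_gap, page_width = page_width,
               page_height = page_height,
               max_lines_per_page = as.integer(max_lines_per_page),
               jitter_sd = jitter_sd, margin_x = margin_x,
               margin_y = margin_y, img_scale = img_scale)
  pos <- c("char_width", "line_height", "column_gap", "page_width",
           "page_height", "max_lines_per_page", "img_scale")
  if (any(vapply(vals[pos], function(v) v <= 0, logical(1)))) {
    abort("layout_spec: all dimensions must be positive")
  }
  if (jitter_sd < 0) abort("layout_spec: `jitter_sd` must be >= 0")
  structure(vals, class = "layout_spec")
}

glyph_w_frac <- 0.85  # glyph width as a fraction of the monospace advance
glyph_h_frac <- 0.80  # glyph height as a fraction of the line height
sup_raise_frac <- 0.4 # superscript raise as a fraction of the line height

# Character boxes for one cell string at a column origin; spaces advance
# the pen but emit no glyph. `sup_from` marks the 1-based character
# position from which glyphs are superscripted (raised), NA for none.
cell_glyphs <- function(text, x_origin, y_top, layout, sup_from = NA) {
  n <- nchar(text)
  if (n == 0) return(empty_chars())
  ch <- strsplit(text, "")[[1]]
  pos <- seq_len(n)
  keep <- ch != " "
  if (!any(keep)) return(empty_chars())
  ch <- ch[keep]; pos <- pos[keep]
  raised <- !is.na(sup_from) & pos >= sup_from
  cw <- layout$char_width; lh <- layout$line_height
  y0 <- ifelse(raised, y_top - sup_raise_frac * lh, y_top)
  tibble(glyph = ch,
         x0 = x_origin + (pos - 1) * cw,
         y0 = y0,
         x1 = x_origin + (pos - 1) * cw + glyph_w_frac * cw,
         y1 = y0 + glyph_h_frac * lh)
}

#' Render a logical table to character boxes and detection fixtures
#'
#' Monospace layout: column j starts at a fixed x offset, each physical
#' row occupies one text line, and the page breaks after
#' `max_lines_per_page` lines. Rows listed in `attr(table,
#' "superscripts")` have their final space-separated token raised above
#' the baseline. The emitted detections mimic table detection / table
#' structure recognition output: per page one `table` box, one
#' `table_column` box per column, one `table_row` box per physical row
#' and one `table_cell` box per non-empty cell, all in image pixel
#' coordinates (`img_scale` px/pt), optionally jittered.
#'
#' @param table a [logical_table()] (possibly over-segmented).
#' @param layout a [layout_spec()].
#' @param seed RNG seed for the jitter (unused when `jitter_sd = 0`).
#' @param rules also emit horizontal/vertical graphics rule lines around
#'   the grid (used by the page-classifier's structural indicators).
#' @return list with `pages` (list of [page_record()]), `detections`
#'   (tibble) and `gold` (the input table).
#' @export
render_table <- function(table, layout = layout_spec(), seed = 1L,
                         rules = FALSE) {
  assert_logical_table(table)
  cells <- table$cells
  R <- nrow(cells); C <- ncol(cells)
  if (R == 0 || C == 0) abort("render_table: empty table")
  col_chars <- pmax(1L, apply(nchar(cells, type = "chars"), 2, max))
  cw <- layout$char_width
  xs <- layout$margin_x + c(0, cumsum(col_chars * cw + layout$column_gap))[seq_len(C)]
  right_edge <- xs[C] + col_chars[C] * cw
  if (right_edge > layout$page_width - layout$margin_x / 2) {
    abort("render_table: table wider than the page at this char_width")
  }
  sup <- attr(table, "superscripts")
  sup_from_for <- function(i, j) {
    if (is.null(sup) || !any(sup$row == i & sup$col == j)) return(NA)
    txt <- cells[i, j]
    sp <- gregexpr(" ", txt, fixed = TRUE)[[1]]
    if (sp[1] == -1) return(NA)
    max(sp) + 1L
  }
  lh <- layout$line_height
  mlp <- layout$max_lines_per_page
  row_page <- (seq_len(R) - 1L) %/% mlp
  row_line <- (seq_len(R) - 1L) %% mlp
  row_ytop <- layout$margin_y + row_line * lh
  chars_by_page <- list()
  cell_boxes <- list()
  for (i in seq_len(R)) {
    for (j in seq_len(C)) {
      g <- if (nzchar(cells[i, j])) {
        cell_glyphs(cells[i, j], xs[j], row_ytop[i], layout,
                    sup_from = sup_from_for(i, j))
      } else empty_chars()
      pg <- as.character(row_page[i])
      if (nrow(g) > 0) {
        chars_by_page[[pg]] <- c(chars_by_page[[pg]] %||% list(), list(g))
        box <- c(min(g$x0), min(g$y0), max(g$x1), max(g$y1))
      } else {
        # structure recognition derives cells as row x column grid
        # intersections, so empty grid positions still yield a box
        box <- c(xs[j], row_ytop[i],
                 xs[j] + col_chars[j] * cw, row_ytop[i] + glyph_h_frac * lh)
      }
      cell_boxes[[length(cell_boxes) + 1]] <-
        tibble(page = row_page[i], row = i, col = j, empty = nrow(g) == 0,
               x0 = box[1], y0 = box[2], x1 = box[3], y1 = box[4])
    }
  }
  cb <- dplyr::bind_rows(cell_boxes)
  if (all(cb$empty)) abort("render_table: table has no non-empty cells")
  dets <- list()
  graphics_by_page <- list()
  for (pg in sort(unique(cb$page))) {
    pcb <- cb[cb$page == pg, ]
    tx0 <- min(pcb$x0) - 2; ty0 <- min(pcb$y0) - 2
    tx1 <- max(pcb$x1) + 2; ty1 <- max(pcb$y1) + 2
    dets[[length(dets) + 1]] <- tibble(label = "table", score = 0.99, page = pg,
                                       x0 = tx0, y0 = ty0, x1 = tx1, y1 = ty1)
    for (j in seq_len(C)) {
      jc <- pcb[pcb$col == j, ]
      if (nrow(jc) == 0) next
      dets[[length(dets) + 1]] <- tibble(label = "table_column", score = 0.95,
                                         page = pg, x0 = min(jc$x0) - 0.5,
                                         y0 = ty0, x1 = max(jc$x1) + 0.5, y1 = ty1)
    }
    for (i in sort(unique(pcb$row))) {
      rc <- pcb[pcb$row == i, ]
      dets[[length(dets) + 1]] <- tibble(label = "table_row", score = 0.9,
                                         page = pg, x0 = tx0,
                                         y0 = min(rc$y0) - 0.5,
                                         x1 = tx1, y1 = max(rc$y1) + 0.5)
    }
    dets[[length(dets) + 1]] <- dplyr::mutate(pcb[c("page", "x0", "y0", "x1", "y1")],
                                              label = "table_cell", score = 0.85)
    if (rules) {
      hy <- c(ty0, row_ytop[unique(pcb$row)] + glyph_h_frac * lh + 1, ty1)
      graphics_by_page[[as.character(pg)]] <- dplyr::bind_rows(
        tibble(orientation = "h", x0 = tx0, y0 = hy, x1 = tx1, y1 = hy),
        tibble(orientation = "v", x0 = c(tx0, tx1), y0 = ty0,
               x1 = c(tx0, tx1), y1 = ty1))
    }
  }
  det <- dplyr::bind_rows(dets)
  sc <- layout$img_scale
  det <- dplyr::mutate(det,
                       img_w = layout$page_width * sc,
                       img_h = layout$page_height * sc,
                       dplyr::across(c("x0", "y0", "x1", "y1"), ~ .x * sc))
  if (layout$jitter_sd > 0) {
    det <- withr::with_seed(seed, {
      n <- nrow(det)
      jit <- function(v) v + rnorm(n, 0, layout$jitter_sd * sc)
      det$x0 <- jit(det$x0); det$y0 <- jit(det$y0)
      det$x1 <- jit(det$x1); det$y1 <- jit(det$y1)
      det
    })
    det <- dplyr::mutate(det,
      x0 = pmax(0, pmin(x0, img_w - 1)), y0 = pmax(0, pmin(y0, img_h - 1)),
      x1 = pmax(x0 + 0.5, pmin(x1, img_w)), y1 = pmax(y0 + 0.5, pmin(y1, img_h)))
  }
  det <- det[c("label", "score", "page", "img_w", "img_h", "x0", "y0", "x1", "y1")]
  det$page <- as.integer(det$page)
  pages <- lapply(sort(unique(cb$page)), function(pg) {
    chars <- dplyr::bind_rows(chars_by_page[[as.character(pg)]])
    chars <- chars[order(chars$y0, chars$x0), ]
    page_record(pg, layout$page_width, layout$page_height, chars,
                graphics_by_page[[as.character(pg)]] %||% empty_graphics())
  })
  list(pages = pages, detections = det, gold = table)
}

#' Render a prose page (negative material for the page classifier)
#'
#' @param n_lines number of text lines.
#' @param seed RNG seed.
#' @param layout a [layout_spec()].
#' @param page_index page number of the emitted record.
#' @return a [page_record()].
#' @export
render_prose_page <- function(n_lines = 20, seed = 1L,
                              layout = layout_spec(), page_index = 0L) {
  withr::with_seed(seed, {
    chars <- dplyr::bind_rows(lapply(seq_len(n_lines), function(i) {
      txt <- prose_line(sample(7:12, 1))
      cell_glyphs(txt, layout$margin_x,
                  layout$margin_y + (i - 1) * layout$line_height, layout)
    }))
    page_record(page_index, layout$page_width, layout$page_height, chars)
  })
}

#' Canonical synthetic fixtures
#'
#' `noiseless_fixture()` renders a clean, non-overflowing resource table;
#' `overflow_fixture()` renders the over-segmented form of a table passed
#' through [simulate_overflow()], together with the overflow metadata and
#' cell crops for the OCR pipeline. Over-segmented tables are wide
#' (the resource column alone can exceed 60 characters), so the fixtures
#' use a 5 pt monospace advance (about an 8 pt font).
#'
#' @param seed RNG seed.
#' @param n_rows body rows.
#' @param superscripts rows with a raised footnote marker.
#' @param long_cells overflow-forcing cells (overflow fixture).
#' @param jitter_sd detection-box jitter in points.
#' @param layout a [layout_spec()].
#' @return list with `pages`, `detections`, `gold` (and for the overflow
#'   fixture `sim`, the [simulate_overflow()] result, and `crops`).
#' @export
noiseless_fixture <- function(seed = 1L, n_rows = 6L, superscripts = 0L,
                              jitter_sd = 0,
                              layout = layout_spec(char_width = 5,
                                                   jitter_sd = jitter_sd)) {
  tbl <- generate_resource_table(n_rows, seed = seed,
                                 superscripts = superscripts)
  r <- render_table(tbl, layout, seed = seed)
  r$crops <- render_cell_crops(tbl)
  r
}

#' @rdname noiseless_fixture
#' @export
overflow_fixture <- function(seed = 1L, n_rows = 8L, long_cells = 1L,
                             jitter_sd = 0,
                             layout = layout_spec(char_width = 5,
                                                  jitter_sd = jitter_sd)) {
  tbl <- generate_resource_table(n_rows, seed = seed, long_cells = long_cells)
  sim <- simulate_overflow(tbl, overflow_config(seed = seed))
  r <- render_table(sim$oversegmented, layout, seed = seed)
  r$gold <- tbl
  r$sim <- sim
  r$crops <- render_cell_crops(sim$oversegmented)
  r
}
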