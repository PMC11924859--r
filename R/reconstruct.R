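#' Scale detection boxes from image pixels to page points
#'
#' Table detection runs on page images; box coordinates are divided by
#' the image size and multiplied by the page size, per axis.
#'
#' @param detections detection tibble (see [read_detections()]).
#' @param page_width,page_height page size in points.
#' @return the tibble with `x0`, `y0`, `x1`, `y1` in page points.
#' @export
scale_to_page <- function(detections, page_width, page_height) {
  if (any(detections$img_w <= 0 | detections$img_h <= 0)) {
    abort("scale_to_page: image dimensions must be positive")
  }
  dplyr::mutate(detections,
                x0 = .data$x0 * page_width / .data$img_w,
                x1 = .data$x1 * page_width / .data$img_w,
                y0 = .data$y0 * page_height / .data$img_h,
                y1 = .data$y1 * page_height / .data$img_h)
}

# Assign each cell detection to the table_row detection with maximal
# vertical overlap; returns the row index (or NA).
assign_to_rows <- function(cells, rows) {
  vapply(seq_len(nrow(cells)), function(i) {
    ov <- interval_overlap(cells$y0[i], cells$y1[i], rows$y0, rows$y1)
    if (all(ov <= 0)) NA_integer_ else which.max(ov)
  }, integer(1))
}

#' Estimate the number of table columns
#'
#' The effective column count is the median number of cell detections in
#' a structure-recognition row; for an even number of rows the lower
#' median is used (conservative: never invents a column).
#'
#' @param row_cell_counts integer vector, cells per detected row.
#' @return integer column count.
#' @export
estimate_column_count <- function(row_cell_counts) {
  row_cell_counts <- row_cell_counts[!is.na(row_cell_counts)]
  if (length(row_cell_counts) == 0) abort("estimate_column_count: no rows")
  s <- sort(row_cell_counts)
  s[floor((length(s) + 1) / 2)]
}

# Cluster cell boxes into C ordered column groups. Columns are regions
# of x-interval coverage separated by gaps, so connected components of
# the overlap graph (interval sweep) are the primary grouping; when
# jittered boxes bridge a gap (too few components) the widest internal
# x-center gap is split, and spurious gaps (too many components) are
# merged at the narrowest separation.
cluster_columns <- function(x0, x1, C) {
  n <- length(x0)
  ord <- order(x0, x1)
  comp <- integer(n)
  comp[ord[1]] <- 1L
  hi <- x1[ord[1]]
  for (k in seq_len(n)[-1]) {
    i <- ord[k]
    if (x0[i] > hi) comp[i] <- comp[ord[k - 1]] + 1L
    else comp[i] <- comp[ord[k - 1]]
    hi <- max(hi, x1[i])
  }
  n_comp <- max(comp)
  while (n_comp > C) {  # merge the two components with the smallest gap
    lo_c <- vapply(seq_len(n_comp), function(g) min(x0[comp == g]), 1)
    hi_c <- vapply(seq_len(n_comp), function(g) max(x1[comp == g]), 1)
    gaps <- lo_c[-1] - hi_c[-n_comp]
    j <- which.min(gaps)
    comp[comp > j] <- comp[comp > j] - 1L
    n_comp <- n_comp - 1L
  }
  while (n_comp < C) {  # split the widest internal center gap
    centers <- (x0 + x1) / 2
    best <- NULL
    for (g in seq_len(n_comp)) {
      idx <- which(comp == g)
      if (length(idx) < 2) next
      cs <- sort(centers[idx])
      gaps <- diff(cs)
      if (length(gaps) == 0 || max(gaps) <= 0) next
      k <- which.max(gaps)
      if (is.null(best) || gaps[k] > best$gap) {
        best <- list(gap = gaps[k], g = g, cut = (cs[k] + cs[k + 1]) / 2)
      }
    }
    if (is.null(best)) break
    comp[comp > best$g] <- comp[comp > best$g] + 1L
    comp[comp == best$g & centers > best$cut] <- best$g + 1L
    n_comp <- n_comp + 1L
  }
  comp
}

#' Estimate column x-ranges from cell detections
#'
#' Cells are clustered into `C` columns by their x-centers; column j's
#' range is the min x0 to max x1 of its cells, padded by `pad` on both
#' sides ("about 1 pixel" of slack against boundary alignment errors).
#' The last column is additionally expanded right by two average
#' character widths, compensating for clipped trailing characters.
#' Overlapping ranges are resolved at the interval midpoints so that the
#' ranges always partition.
#'
#' @param cell_boxes tibble of cell detections in page points.
#' @param C number of columns.
#' @param avg_char_width mean glyph width over the table region (pt).
#' @param pad boundary slack (pt).
#' @return tibble with one row per column: `lo`, `hi`.
#' @export
estimate_column_ranges <- function(cell_boxes, C, avg_char_width, pad = 1) {
  if (C < 1) abort("estimate_column_ranges: C must be >= 1")
  grp <- cluster_columns(cell_boxes$x0, cell_boxes$x1, C)
  rng <- dplyr::summarise(
    dplyr::group_by(dplyr::mutate(cell_boxes, .col = grp), .data$.col),
    lo = min(.data$x0) - pad, hi = max(.data$x1) + pad, .groups = "drop")
  rng <- dplyr::arrange(rng, .data$lo)[c("lo", "hi")]
  rng$hi[nrow(rng)] <- rng$hi[nrow(rng)] + 2 * avg_char_width
  if (nrow(rng) > 1) {
    for (j in seq_len(nrow(rng) - 1)) {
      if (rng$hi[j] > rng$lo[j + 1]) {
        mid <- (rng$hi[j] + rng$lo[j + 1]) / 2
        rng$hi[j] <- mid
        rng$lo[j + 1] <- mid
      }
    }
  }
  rng
}

#' Group character boxes into text lines
#'
#' Characters are grouped by top-y coordinate (within `y_tolerance`,
#' default a quarter of the estimated line height) and, within a group,
#' split into segments wherever the horizontal gap between consecutive
#' glyphs exceeds `gap_factor` average character widths. Word spaces
#' (gaps wider than about half a character) are re-inserted as single
#' space characters in the segment text. Superscripts and subscripts
#' have different top-y values than their baseline and therefore come
#' out as separate (spurious) lines, handled later by canonicalization.
#'
#' @param page a [page_record()].
#' @param y_tolerance top-y grouping tolerance (pt); default
#'   `0.25 * estimated line height`.
#' @param gap_factor segment-splitting gap threshold, in average
#'   character widths.
#' @return tibble with one row per line segment: `band` (y-group id),
#'   `y_top`, `y0`, `y1`, `x0`, `x1`, `text`, `page`, and `chars` (the
#'   member glyph boxes, a list column).
#' @export
build_text_lines <- function(page, y_tolerance = NULL, gap_factor = 1.5) {
  ch <- page$chars
  if (nrow(ch) == 0) {
    return(tibble(band = integer(), y_top = double(), y0 = double(),
                  y1 = double(), x0 = double(), x1 = double(),
                  text = character(), page = integer(), chars = list()))
  }
  aw <- mean(ch$x1 - ch$x0)
  line_h <- 1.25 * median(ch$y1 - ch$y0)
  tol <- y_tolerance %||% (0.25 * line_h)
  ch <- ch[order(ch$y0, ch$x0), ]
  band <- integer(nrow(ch))
  band_start <- ch$y0[1]
  b <- 1L
  for (i in seq_len(nrow(ch))) {
    if (ch$y0[i] - band_start > tol) {
      b <- b + 1L
      band_start <- ch$y0[i]
    }
    band[i] <- b
  }
  segs <- list()
  for (bb in unique(band)) {
    g <- ch[band == bb, ]
    g <- g[order(g$x0), ]
    cut <- which(g$x0[-1] - g$x1[-nrow(g)] > gap_factor * aw)
    seg_id <- findInterval(seq_len(nrow(g)), cut + 1L) + 1L
    for (s in unique(seg_id)) {
      gs <- g[seg_id == s, ]
      # re-insert single spaces at word gaps
      if (nrow(gs) > 1) {
        gapped <- c(FALSE, gs$x0[-1] - gs$x1[-nrow(gs)] > 0.5 * aw)
        txt <- paste0(ifelse(gapped, paste0(" ", gs$glyph), gs$glyph),
                      collapse = "")
      } else {
        txt <- gs$glyph
      }
      segs[[length(segs) + 1]] <-
        tibble(band = bb, y_top = min(gs$y0), y0 = min(gs$y0), y1 = max(gs$y1),
               x0 = min(gs$x0), x1 = max(gs$x1), text = txt,
               page = page$page_index, chars = list(gs))
    }
  }
  out <- dplyr::bind_rows(segs)
  dplyr::arrange(out, .data$y_top, .data$x0)
}

#' Assemble the raw cell grid from text lines and column ranges
#'
#' Each line segment goes to the column whose x-range contains its
#' center (segments outside every range go to the nearest range). In
#' mode `"col"` each text-line band becomes one physical row; in mode
#' `"row"` segments are binned into the supplied structure-recognition
#' row y-ranges by maximal vertical overlap (zero-overlap segments go to
#' the nearest range). Cell text is the concatenation of the cell's
#' segments left-to-right, single-spaced; cells without segments are
#' empty strings.
#'
#' @param lines segment tibble from [build_text_lines()] (possibly
#'   several pages' worth, already clipped to the table box).
#' @param col_ranges tibble `lo`/`hi` from [estimate_column_ranges()].
#' @param row_ranges optional tibble `lo`/`hi` of row y-ranges (mode
#'   `"row"`); `NULL` for mode `"col"`.
#' @return list with `table` (the raw [logical_table()]), `row_geom`
#'   (tibble `y0`, `y1`, `has_segments`) and `segments` (the input
#'   segments annotated with `.row`/`.col`).
#' @export
assemble_grid <- function(lines, col_ranges, row_ranges = NULL) {
  C <- nrow(col_ranges)
  if (nrow(lines) == 0) {
    return(list(table = logical_table(matrix(character(), 0, C)),
                row_geom = tibble(y0 = double(), y1 = double()),
                segments = lines))
  }
  centers <- (lines$x0 + lines$x1) / 2
  col_of <- vapply(centers, function(cx) {
    inside <- which(cx >= col_ranges$lo & cx <= col_ranges$hi)
    if (length(inside) > 0) return(inside[1])
    # nearest range, flagged
    d <- pmax(col_ranges$lo - cx, cx - col_ranges$hi)
    which.min(d)
  }, integer(1))
  if (is.null(row_ranges)) {
    key <- paste(lines$page, lines$band)
    row_of <- match(key, unique(key[order(lines$page, lines$y_top)]))
  } else {
    row_of <- vapply(seq_len(nrow(lines)), function(i) {
      ov <- interval_overlap(lines$y0[i], lines$y1[i], row_ranges$lo, row_ranges$hi)
      if (any(ov > 0)) return(which.max(ov))
      mid <- (lines$y0[i] + lines$y1[i]) / 2
      d <- pmax(row_ranges$lo - mid, mid - row_ranges$hi)
      which.min(d)
    }, integer(1))
  }
  R <- max(row_of)
  cells <- matrix("", R, C)
  for (r in seq_len(R)) {
    for (j in seq_len(C)) {
      idx <- which(row_of == r & col_of == j)
      if (length(idx) == 0) next
      idx <- idx[order(lines$x0[idx])]
      cells[r, j] <- paste(lines$text[idx], collapse = " ")
    }
  }
  present <- tabulate(row_of, nbins = R) > 0
  row_geom <- tibble(
    y0 = vapply(seq_len(R), function(r) if (present[r]) min(lines$y0[row_of == r]) else NA_real_, 1),
    y1 = vapply(seq_len(R), function(r) if (present[r]) max(lines$y1[row_of == r]) else NA_real_, 1))
  segments <- dplyr::mutate(lines, .row = row_of, .col = col_of)
  list(table = logical_table(cells), row_geom = row_geom, segments = segments)
}

# Rebuild cell text of merged physical rows from their segments: sorted
# by x then y, so a raised superscript (same row band, larger x) lands
# after its base text and a wrapped continuation (same x, larger y)
# lands after its first line.
rebuild_cells <- function(segments, C, group_of) {
  R <- max(group_of)
  cells <- matrix("", R, C)
  for (r in seq_len(R)) {
    for (j in seq_len(C)) {
      idx <- which(group_of[segments$.row] == r & segments$.col == j)
      if (length(idx) == 0) next
      idx <- idx[order(segments$x0[idx], segments$y0[idx])]
      cells[r, j] <- paste(segments$text[idx], collapse = " ")
    }
  }
  cells
}

#' Heuristic row-merge canonicalization
#'
#' Two rules, applied top-down until neither fires, with overlap
#' fractions normalized by the smaller of the two intervals:
#'
#' * Rule 1: a physical row whose vertical extent overlaps the closest
#'   structure-recognition row rectangle by 70% or more is merged into
#'   the physical row anchored by that rectangle (absorbs superscript
#'   and subscript lines).
#' * Rule 2: a physical row with at least one empty cell, whose closest
#'   row above has no empty cells and whose vertical text range overlaps
#'   that row's by 50% or more, is merged upward.
#'
#' Merged cell text is rebuilt from the member segments ordered left to
#' right (ties top to bottom), joined with single spaces; empty cells
#' absorb content unchanged.
#'
#' @param grid result of [assemble_grid()].
#' @param tsr_row_boxes tibble `lo`/`hi` of structure-recognition row
#'   y-ranges in page points (may be empty: Rule 1 is then inactive).
#' @param rule1_overlap,rule2_overlap overlap thresholds.
#' @return a [logical_table()].
#' @export
heuristic_row_merge <- function(grid, tsr_row_boxes = NULL,
                                rule1_overlap = 0.70, rule2_overlap = 0.50) {
  segments <- grid$segments
  geom <- grid$row_geom
  C <- ncol(grid$table$cells)
  R <- nrow(geom)
  if (R == 0) return(grid$table)
  group_of <- seq_len(R)  # physical row -> merged group id (contiguous)
  repeat {
    cells <- rebuild_cells(segments, C, group_of)
    groups <- sort(unique(group_of))
    gy0 <- vapply(groups, function(g) suppressWarnings(min(geom$y0[group_of == g], na.rm = TRUE)), 1)
    gy1 <- vapply(groups, function(g) suppressWarnings(max(geom$y1[group_of == g], na.rm = TRUE)), 1)
    fired <- FALSE
    for (gi in seq_along(groups)) {
      g <- groups[gi]
      if (!is.finite(gy0[gi])) next
      h_g <- gy1[gi] - gy0[gi]
      # Rule 1: merge into the row anchored by the closest TSR rectangle
      if (!is.null(tsr_row_boxes) && nrow(tsr_row_boxes) > 0) {
        ov <- interval_overlap(gy0[gi], gy1[gi], tsr_row_boxes$lo, tsr_row_boxes$hi)
        k <- which.max(ov)
        denom <- min(h_g, tsr_row_boxes$hi[k] - tsr_row_boxes$lo[k])
        if (denom > 0 && ov[k] / denom >= rule1_overlap) {
          anchor_ov <- interval_overlap(gy0, gy1, tsr_row_boxes$lo[k], tsr_row_boxes$hi[k])
          anchor <- which.max(anchor_ov)
          if (anchor != gi) {
            group_of[group_of == g] <- groups[anchor]
            fired <- TRUE
            break
          }
        }
      }
      # Rule 2: continuation row with empty cells under a complete row
      if (gi > 1) {
        row_cells <- cells[gi, ]
        above <- cells[gi - 1, ]
        if (any(!nzchar(row_cells)) && all(nzchar(above))) {
          ov <- interval_overlap(gy0[gi], gy1[gi], gy0[gi - 1], gy1[gi - 1])
          denom <- min(h_g, gy1[gi - 1] - gy0[gi - 1])
          if (denom > 0 && ov / denom >= rule2_overlap) {
            group_of[group_of == g] <- groups[gi - 1]
            fired <- TRUE
            break
          }
        }
      }
    }
    if (!fired) break
    group_of <- match(group_of, sort(unique(group_of)))  # renumber contiguously
  }
  logical_table(rebuild_cells(segments, C, match(group_of, sort(unique(group_of)))))
}

#' Reconstruct a table from detections and character boxes
#'
#' Full orchestration of the geometry-based pipelines: scale detections
#' to page coordinates, group cell detections into structure-recognition
#' rows, estimate the column count (median cells per row) and column
#' ranges, build text lines clipped to the table box, assemble the raw
#' grid (mode `"col"`: one physical row per text-line band, followed by
#' heuristic row-merge canonicalization; mode `"row"`: bin lines into
#' the detected row ranges), and concatenate multi-page tables in page
#' order.
#'
#' @param detections detection tibble in image pixel coordinates.
#' @param pages list of [page_record()].
#' @param mode `"col"` (column ranges only) or `"row"` (column and row
#'   ranges).
#' @param pad column-range slack in points.
#' @param canonicalize apply [heuristic_row_merge()] in mode `"col"`.
#' @return a [logical_table()].
#' @export
reconstruct_table <- function(detections, pages, mode = c("col", "row"),
                              pad = 1, canonicalize = TRUE) {
  mode <- match.arg(mode)
  page_idx <- vapply(pages, `[[`, integer(1), "page_index")
  parts <- list()
  any_table <- FALSE
  for (p in pages[order(page_idx)]) {
    det <- detections[detections$page == p$page_index, ]
    if (nrow(det) == 0 || !any(det$label == "table")) next
    any_table <- TRUE
    det <- scale_to_page(det, p$page_width, p$page_height)
    tb <- det[det$label == "table", ][1, ]
    cellb <- det[det$label == "table_cell", ]
    rowb <- det[det$label == "table_row", ]
    rowb <- rowb[order(rowb$y0), ]
    # characters inside the table box (by glyph center)
    ch <- p$chars
    cx <- (ch$x0 + ch$x1) / 2; cy <- (ch$y0 + ch$y1) / 2
    inside <- cx >= tb$x0 & cx <= tb$x1 & cy >= tb$y0 & cy <= tb$y1
    clipped <- p
    clipped$chars <- ch[inside, ]
    if (nrow(clipped$chars) == 0) next
    aw <- mean(clipped$chars$x1 - clipped$chars$x0)
    if (nrow(cellb) > 0 && nrow(rowb) > 0) {
      row_of <- assign_to_rows(cellb, rowb)
      C <- estimate_column_count(tabulate(row_of, nbins = nrow(rowb)))
      col_ranges <- estimate_column_ranges(cellb, C, aw, pad = pad)
    } else {
      colb <- det[det$label == "table_column", ]
      if (nrow(colb) == 0) abort("reconstruct_table: no cell or column detections")
      col_ranges <- tibble(lo = sort(colb$x0) - pad, hi = sort(colb$x1) + pad)
      col_ranges$hi[nrow(col_ranges)] <- col_ranges$hi[nrow(col_ranges)] + 2 * aw
    }
    lines <- build_text_lines(clipped)
    row_ranges <- if (mode == "row") {
      if (nrow(rowb) == 0) abort("reconstruct_table: mode \"row\" needs table_row detections")
      tibble(lo = rowb$y0, hi = rowb$y1)
    }
    grid <- assemble_grid(lines, col_ranges, row_ranges)
    part <- if (mode == "col" && canonicalize) {
      heuristic_row_merge(grid, if (nrow(rowb) > 0) tibble(lo = rowb$y0, hi = rowb$y1))
    } else {
      grid$table
    }
    parts[[length(parts) + 1]] <- part
  }
  if (!any_table) abort("reconstruct_table: no table detection on the given pages")
  parts <- parts[vapply(parts, function(t) nrow(t$cells) > 0, logical(1))]
  C <- max(vapply(parts, function(t) ncol(t$cells), integer(1)))
  cells <- do.call(rbind, lapply(parts, function(t) {
    m <- t$cells
    if (ncol(m) < C) m <- cbind(m, matrix("", nrow(m), C - ncol(m)))
    m
  }))
  logical_table(cells)
}
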