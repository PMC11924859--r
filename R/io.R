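#' Page record: all glyphs and primitive graphics of one PDF page
#'
#' @param page_index 0-based page number.
#' @param page_width,page_height page size in points.
#' @param chars tibble with columns `glyph` (single character), `x0`, `y0`,
#'   `x1`, `y1` (top-left-origin points).
#' @param graphics tibble with columns `orientation` ("h"/"v"), `x0`, `y0`,
#'   `x1`, `y1`; the box may be degenerate in one axis (rule lines).
#' @return an object of class `page_record`.
#' @export
page_record <- function(page_index, page_width = 612, page_height = 792,
                        chars = empty_chars(), graphics = empty_graphics()) {
  chars <- as_tibble(chars)
  graphics <- as_tibble(graphics)
  if (nrow(chars) > 0) {
    bad <- nchar(chars$glyph) != 1L
    if (any(bad)) {
      abort(sprintf("page_record: glyph must be a single character (record %s)",
                    paste(head(which(bad), 5), collapse = ", ")))
    }
    validate_bbox(chars$x0, chars$y0, chars$x1, chars$y1, what = "char bbox")
  }
  if (nrow(graphics) > 0) {
    validate_bbox(graphics$x0, graphics$y0, graphics$x1, graphics$y1,
                  what = "graphics line", degenerate_ok = TRUE)
    bad_o <- !graphics$orientation %in% c("h", "v")
    if (any(bad_o)) abort("page_record: graphics orientation must be \"h\" or \"v\"")
  }
  structure(list(page_index = as.integer(page_index),
                 page_width = page_width, page_height = page_height,
                 chars = chars, graphics = graphics),
            class = "page_record")
}

empty_chars <- function() {
  tibble(glyph = character(), x0 = double(), y0 = double(),
         x1 = double(), y1 = double())
}
empty_graphics <- function() {
  tibble(orientation = character(), x0 = double(), y0 = double(),
         x1 = double(), y1 = double())
}

#' @export
print.page_record <- function(x, ...) {
  cat(sprintf("<page_record %d: %gx%g pt, %d glyphs, %d graphics lines>\n",
              x$page_index, x$page_width, x$page_height,
              nrow(x$chars), nrow(x$graphics)))
  invisible(x)
}

#' Read character bounding boxes (JSONL)
#'
#' One JSON object per line. Two dialects are accepted: per-page objects
#' `{"page":0,"w":612,"h":792,"chars":[{"c":"A","x0":..,"y0":..,"x1":..,"y1":..},...],
#' "lines":[{"o":"h","x0":..,...},...]}`, or per-character objects
#' `{"page":0,"c":"A","x0":..,"y0":..,"x1":..,"y1":..}` (page size then
#' defaults to US letter unless `"w"`/`"h"` are present). Coordinates are
#' top-left-origin points; extractors that emit PDF bottom-left-origin
#' coordinates can be ingested with `flip_y = TRUE`, which maps
#' `y -> page_height - y`.
#'
#' @param path JSONL file path.
#' @param flip_y convert bottom-left-origin y coordinates to top-left.
#' @return list of [page_record()] sorted by `page_index`. Every glyph is
#'   preserved byte-exactly (Unicode, superscripts, subscripts).
#' @export
read_charboxes <- function(path, flip_y = FALSE) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(list())
  objs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    objs[[i]] <- tryCatch(
      jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
      error = function(e) abort(sprintf("read_charboxes: malformed JSON on line %d: %s",
                                        i, conditionMessage(e))))
  }
  per_page <- vapply(objs, function(o) !is.null(o$chars) || !is.null(o$lines),
                     logical(1))
  if (any(per_page) && !all(per_page)) {
    abort("read_charboxes: mixed per-page and per-character dialects")
  }
  parse_char <- function(ch, line_no) {
    if (is.null(ch$c) || is.null(ch$x0)) {
      abort(sprintf("read_charboxes: incomplete character record on line %d", line_no))
    }
    list(glyph = ch$c, x0 = ch$x0, y0 = ch$y0, x1 = ch$x1, y1 = ch$y1)
  }
  if (all(per_page)) {
    pages <- lapply(seq_along(objs), function(i) {
      o <- objs[[i]]
      w <- o$w %||% 612; h <- o$h %||% 792
      chs <- lapply(o$chars %||% list(), parse_char, line_no = i)
      chars <- if (length(chs)) dplyr::bind_rows(lapply(chs, as_tibble)) else empty_chars()
      gls <- o$lines %||% list()
      graphics <- if (length(gls)) {
        dplyr::bind_rows(lapply(gls, function(g) {
          tibble(orientation = g$o, x0 = g$x0, y0 = g$y0, x1 = g$x1, y1 = g$y1)
        }))
      } else empty_graphics()
      if (flip_y && nrow(chars) > 0) {
        tmp <- chars$y0; chars$y0 <- h - chars$y1; chars$y1 <- h - tmp
      }
      if (flip_y && nrow(graphics) > 0) {
        tmp <- graphics$y0; graphics$y0 <- h - graphics$y1; graphics$y1 <- h - tmp
      }
      tryCatch(page_record(o$page %||% 0L, w, h, chars, graphics),
               error = function(e) abort(sprintf("read_charboxes: line %d: %s",
                                                 i, conditionMessage(e))))
    })
  } else {
    recs <- dplyr::bind_rows(lapply(seq_along(objs), function(i) {
      o <- objs[[i]]
      ch <- parse_char(o, i)
      tibble(page = as.integer(o$page %||% 0L), w = o$w %||% 612, h = o$h %||% 792,
             glyph = ch$glyph, x0 = ch$x0, y0 = ch$y0, x1 = ch$x1, y1 = ch$y1,
             .line = i)
    }))
    pages <- lapply(split(recs, recs$page), function(d) {
      chars <- d[c("glyph", "x0", "y0", "x1", "y1")]
      if (flip_y) { tmp <- chars$y0; chars$y0 <- d$h[1] - chars$y1; chars$y1 <- d$h[1] - tmp }
      tryCatch(page_record(d$page[1], d$w[1], d$h[1], chars),
               error = function(e) abort(sprintf("read_charboxes: line %d: %s",
                                                 d$.line[1], conditionMessage(e))))
    })
  }
  unname(pages[order(vapply(pages, `[[`, integer(1), "page_index"))])
}

#' Write character bounding boxes (JSONL, per-page dialect)
#'
#' @param pages list of [page_record()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_charboxes <- function(pages, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (p in pages) {
    chars <- lapply(seq_len(nrow(p$chars)), function(i) {
      r <- p$chars[i, ]
      list(c = r$glyph, x0 = r$x0, y0 = r$y0, x1 = r$x1, y1 = r$y1)
    })
    gl <- lapply(seq_len(nrow(p$graphics)), function(i) {
      r <- p$graphics[i, ]
      list(o = r$orientation, x0 = r$x0, y0 = r$y0, x1 = r$x1, y1 = r$y1)
    })
    obj <- list(page = p$page_index, w = p$page_width, h = p$page_height,
                chars = chars, lines = gl)
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), con,
               useBytes = TRUE)
  }
  invisible(path)
}

detection_labels <- c("table", "table_column", "table_row", "table_cell",
                      "spanning_cell")

#' Read table detection / structure-recognition records (JSON)
#'
#' Expects a JSON array of objects
#' `{"label":..,"score":..,"page":..,"img_w":..,"img_h":..,"x0":..,"y0":..,"x1":..,"y1":..}`
#' with bbox coordinates in source-image pixels.
#'
#' @param path JSON file path.
#' @return tibble with one row per detection, in file order.
#' @export
read_detections <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (length(raw) == 0) return(empty_detections())
  d <- dplyr::bind_rows(lapply(raw, function(o) {
    tibble(label = o$label, score = o$score, page = as.integer(o$page %||% 0L),
           img_w = o$img_w, img_h = o$img_h,
           x0 = o$x0, y0 = o$y0, x1 = o$x1, y1 = o$y1)
  }))
  validate_detections(d)
  d
}

empty_detections <- function() {
  tibble(label = character(), score = double(), page = integer(),
         img_w = double(), img_h = double(),
         x0 = double(), y0 = double(), x1 = double(), y1 = double())
}

validate_detections <- function(d) {
  bad_lab <- !d$label %in% detection_labels
  if (any(bad_lab)) {
    abort(sprintf("unknown detection label(s) %s; allowed: %s",
                  paste(unique(d$label[bad_lab]), collapse = ", "),
                  paste(detection_labels, collapse = ", ")))
  }
  if (any(d$score < 0 | d$score > 1)) {
    abort(sprintf("detection score outside [0, 1] (record %s)",
                  paste(which(d$score < 0 | d$score > 1), collapse = ", ")))
  }
  if (any(d$img_w <= 0 | d$img_h <= 0)) abort("detection image dims must be positive")
  validate_bbox(d$x0, d$y0, d$x1, d$y1, what = "detection bbox")
  out <- d$x0 < 0 | d$y0 < 0 | d$x1 > d$img_w | d$y1 > d$img_h
  if (any(out)) {
    abort(sprintf("detection bbox outside image bounds (record %s)",
                  paste(which(out), collapse = ", ")))
  }
  invisible(d)
}

#' Write detection records (JSON)
#'
#' @param detections tibble as returned by [read_detections()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_detections <- function(detections, path) {
  recs <- lapply(seq_len(nrow(detections)), function(i) as.list(detections[i, ]))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
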