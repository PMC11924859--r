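#' Preprocess a cell-crop image for OCR
#'
#' Grayscale conversion (luminosity average over channels for RGB
#' arrays) followed by contrast enhancement: a linear min-max stretch to
#' the full 0-255 range. Constant images are returned unchanged (the
#' stretch is undefined). Idempotent.
#'
#' @param img numeric matrix (grayscale) or 3-d array (H x W x channels),
#'   intensities in \[0, 255\].
#' @return numeric matrix in \[0, 255\]; non-pixel attributes of the
#'   input are preserved.
#' @export
preprocess_cell_image <- function(img) {
  if (length(img) == 0) abort("preprocess_cell_image: empty image")
  atts <- attributes(img)
  if (length(dim(img)) == 3) {
    img <- apply(img, c(1, 2), mean)
  }
  lo <- min(img); hi <- max(img)
  out <- if (hi > lo) (img - lo) / (hi - lo) * 255 else img
  keep <- setdiff(names(atts), c("dim", "dimnames"))
  for (a in keep) attr(out, a) <- atts[[a]]
  out
}

#' Render cell-crop images for an over-segmented table grid
#'
#' One crop per grid position (empty cells give blank crops). The crop
#' is a crude glyph raster; the cell text is also embedded in the
#' `glyph_text` attribute, which is what the lossless fake engine reads.
#'
#' @param table a [logical_table()] or character matrix.
#' @return list of lists `row`, `col`, `img`.
#' @export
render_cell_crops <- function(table) {
  cells <- if (is_logical_table(table)) table$cells else table
  crops <- list()
  for (i in seq_len(nrow(cells))) {
    for (j in seq_len(ncol(cells))) {
      txt <- cells[i, j]
      n <- max(1L, nchar(txt))
      img <- matrix(255, 8, 4 * n)
      if (nzchar(txt)) {
        codes <- utf8ToInt(txt)
        for (k in seq_along(codes)) {
          # 3-px-wide bar pattern keyed to the low bits of the code point
          bits <- bitwAnd(bitwShiftR(codes[k], 0:7), 1L)
          img[, (k - 1) * 4 + seq_len(3)] <- 255 - 200 * bits
        }
      }
      attr(img, "glyph_text") <- txt
      crops[[length(crops) + 1]] <- list(row = i, col = j, img = img)
    }
  }
  crops
}

#' OCR engines
#'
#' `fake_ocr_engine()` reads the text embedded by the synthetic
#' renderer losslessly; `noisy_ocr_engine(p, seed)` wraps it with a
#' seeded per-character substitution error of probability `p`,
#' emulating point errors of a real engine. A real engine can be
#' supplied as any `function(img) -> character`, configured for a
#' single uniform block of text.
#'
#' @param p per-character substitution probability.
#' @param seed RNG seed of the noise process.
#' @return an OCR engine function.
#' @export
fake_ocr_engine <- function() {
  structure(function(img) {
    txt <- attr(img, "glyph_text")
    if (is.null(txt)) {
      abort("fake OCR engine: image carries no embedded glyph text")
    }
    txt
  }, class = c("ocr_engine", "function"))
}

#' @rdname fake_ocr_engine
#' @export
noisy_ocr_engine <- function(p = 0.01, seed = 1L) {
  base <- fake_ocr_engine()
  env <- new.env()
  env$rng <- seed
  structure(function(img) {
    txt <- base(img)
    if (!nzchar(txt)) return(txt)
    env$rng <- env$rng + 1L
    withr::with_seed(env$rng, {
      ch <- strsplit(txt, "")[[1]]
      flip <- runif(length(ch)) < p
      if (any(flip)) {
        ch[flip] <- sample(c(letters, LETTERS, 0:9), sum(flip), replace = TRUE)
      }
      paste0(ch, collapse = "")
    })
  }, class = c("ocr_engine", "function"))
}

#' Recognize the text of one cell crop
#'
#' Preprocessing ([preprocess_cell_image()]) followed by the injected
#' engine; trailing whitespace is stripped. A missing engine raises a
#' capability error rather than returning silent empty output.
#'
#' @param img cell-crop image.
#' @param engine an OCR engine function.
#' @return recognized text.
#' @export
ocr_cell <- function(img, engine) {
  if (is.null(engine) || !is.function(engine)) {
    abort("ocr_cell: no OCR engine available (inject one, e.g. fake_ocr_engine())")
  }
  sub("\\s+$", "", engine(preprocess_cell_image(img)))
}

#' Reconstruct a table from cell-crop images (OCR pipeline)
#'
#' Assembles the grid from the structure-recognition rows and columns
#' and fills each cell from its crop through the OCR engine. Works on
#' the image modality alone.
#'
#' @param detections detection tibble (used for the grid dimensions:
#'   `table_row` count by `table_column` count; must contain a `table`).
#' @param cell_crops list of `row`/`col`/`img` entries (see
#'   [render_cell_crops()]); one crop per grid position.
#' @param engine OCR engine function.
#' @return a [logical_table()].
#' @export
reconstruct_table_ocr <- function(detections, cell_crops,
                                  engine = fake_ocr_engine()) {
  if (!any(detections$label == "table")) {
    abort("reconstruct_table_ocr: no table detection")
  }
  R <- max(vapply(cell_crops, `[[`, numeric(1), "row"))
  C <- max(vapply(cell_crops, `[[`, numeric(1), "col"))
  cells <- matrix("", R, C)
  seen <- matrix(FALSE, R, C)
  for (crop in cell_crops) {
    cells[crop$row, crop$col] <- ocr_cell(crop$img, engine)
    seen[crop$row, crop$col] <- TRUE
  }
  if (!all(seen)) {
    miss <- which(!seen, arr.ind = TRUE)[1, ]
    abort(sprintf("reconstruct_table_ocr: missing crop for cell (%d, %d)",
                  miss[1], miss[2]))
  }
  logical_table(cells)
}
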