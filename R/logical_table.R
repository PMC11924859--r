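#' Logical table: the R x C grid of cell strings
#'
#' The target of reconstruction and the operand of the GriTS metrics. Cells
#' are plain strings; optional spans record cells covering several grid
#' positions as half-open `[start, end)` ranges of 0-based row/column
#' indices (the anchor grid position holds the content, covered positions
#' repeat it after expansion).
#'
#' @param cells character matrix (R x C), or an object coercible to one
#'   (e.g. a data frame of character columns, or a list of equal-length
#'   character vectors, one per row).
#' @param n_header_rows number of header rows (>= 0).
#' @param spans optional tibble with columns `row_start`, `row_end`,
#'   `col_start`, `col_end` (half-open, 0-based); spans must lie inside the
#'   grid and must not overlap.
#' @return an object of class `logical_table`.
#' @export
logical_table <- function(cells, n_header_rows = 0L, spans = NULL) {
  if (is.data.frame(cells)) {
    cells <- as.matrix(cells)
    storage.mode(cells) <- "character"
  } else if (is.list(cells) && !is.matrix(cells)) {
    if (length(cells) == 0) {
      cells <- matrix(character(), nrow = 0, ncol = 0)
    } else {
      lens <- lengths(cells)
      if (length(unique(lens)) != 1) abort("logical_table: rows have unequal lengths")
      cells <- matrix(as.character(unlist(cells)), nrow = length(cells),
                      byrow = TRUE)
    }
  }
  if (!is.matrix(cells) || !is.character(cells)) {
    abort("logical_table: `cells` must be a character matrix")
  }
  if (anyNA(cells)) abort("logical_table: cells must not be NA (use \"\")")
  n_header_rows <- as.integer(n_header_rows)
  if (is.na(n_header_rows) || n_header_rows < 0 || n_header_rows > nrow(cells)) {
    abort("logical_table: `n_header_rows` must be between 0 and R")
  }
  if (!is.null(spans)) {
    spans <- as_tibble(spans)
    needed <- c("row_start", "row_end", "col_start", "col_end")
    if (!all(needed %in% names(spans))) {
      abort("logical_table: spans need columns row_start/row_end/col_start/col_end")
    }
    spans <- spans[needed]
    if (nrow(spans) > 0) {
      with(spans, {
        if (any(row_start < 0 | col_start < 0 |
                row_end > nrow(cells) | col_end > ncol(cells) |
                row_start >= row_end | col_start >= col_end)) {
          abort("logical_table: span outside grid or empty")
        }
      })
      cover <- matrix(FALSE, nrow(cells), ncol(cells))
      for (k in seq_len(nrow(spans))) {
        ri <- (spans$row_start[k] + 1):spans$row_end[k]
        ci <- (spans$col_start[k] + 1):spans$col_end[k]
        if (any(cover[ri, ci])) abort("logical_table: overlapping spans")
        cover[ri, ci] <- TRUE
      }
    }
  }
  structure(list(cells = cells, n_header_rows = n_header_rows, spans = spans),
            class = "logical_table")
}

#' @export
dim.logical_table <- function(x) dim(x$cells)

#' @export
print.logical_table <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<logical_table: %d x %d, %d header row%s%s>\n", d[1], d[2],
              x$n_header_rows, if (x$n_header_rows == 1) "" else "s",
              if (!is.null(x$spans) && nrow(x$spans) > 0)
                sprintf(", %d spans", nrow(x$spans)) else ""))
  if (d[1] > 0) {
    shown <- x$cells[seq_len(min(d[1], 8L)), , drop = FALSE]
    shown[] <- ifelse(nchar(shown) > 28, paste0(substr(shown, 1, 25), "..."), shown)
    print(as.data.frame(shown, stringsAsFactors = FALSE), right = FALSE)
    if (d[1] > 8) cat(sprintf("... and %d more rows\n", d[1] - 8))
  }
  invisible(x)
}

#' @export
as_tibble.logical_table <- function(x, ...) {
  d <- dim(x)
  if (prod(d) == 0) return(tibble(row = integer(), col = integer(), text = character()))
  tibble(row = rep(seq_len(d[1]), times = d[2]),
         col = rep(seq_len(d[2]), each = d[1]),
         text = as.vector(x$cells))
}

#' @export
as.matrix.logical_table <- function(x, ...) x$cells

#' Exact cell-for-cell equality of two logical tables
#'
#' @param a,b `logical_table` objects.
#' @param check_meta also compare header-row counts and spans.
#' @return logical scalar.
#' @export
tables_equal <- function(a, b, check_meta = FALSE) {
  if (!identical(dim(a), dim(b))) return(FALSE)
  if (!identical(unname(a$cells), unname(b$cells))) return(FALSE)
  if (check_meta) {
    if (!identical(a$n_header_rows, b$n_header_rows)) return(FALSE)
    sa <- a$spans; sb <- b$spans
    norm <- function(s) if (is.null(s) || nrow(s) == 0) NULL else
      as.data.frame(s[order(s$row_start, s$col_start), ])
    if (!identical(norm(sa), norm(sb))) return(FALSE)
  }
  TRUE
}

is_logical_table <- function(x) inherits(x, "logical_table")

assert_logical_table <- function(x, arg = "table") {
  if (!is_logical_table(x)) abort(sprintf("`%s` must be a logical_table", arg))
  invisible(x)
}
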