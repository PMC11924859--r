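#' Bounding-box helpers
#'
#' All geometry in the package uses a single convention: page points
#' (1/72 inch), origin at the top-left corner, y increasing downward.
#' A box is the numeric vector `c(x0, y0, x1, y1)` (or the columns of the
#' same names in a tibble), with `x0 < x1` and `y0 < y1`.
#'
#' @param x0,y0,x1,y1 numeric box coordinates.
#' @param what label used in error messages.
#' @return `bbox()` returns a named numeric vector of length 4.
#' @export
bbox <- function(x0, y0, x1, y1) {
  b <- c(x0 = x0, y0 = y0, x1 = x1, y1 = y1)
  validate_bbox(b["x0"], b["y0"], b["x1"], b["y1"])
  b
}

validate_bbox <- function(x0, y0, x1, y1, what = "bbox", degenerate_ok = FALSE) {
  ok_fin <- is.finite(x0) & is.finite(y0) & is.finite(x1) & is.finite(y1)
  if (!all(ok_fin)) {
    abort(sprintf("%s: non-finite coordinates (record %s)", what,
                  paste(which(!ok_fin), collapse = ", ")))
  }
  tol <- if (degenerate_ok) 0.5 else 0
  bad <- (x1 - x0) < -tol | (y1 - y0) < -tol | (!degenerate_ok & (x1 <= x0 | y1 <= y0))
  if (any(bad)) {
    abort(sprintf("%s: invalid extent, need x0 < x1 and y0 < y1 (record %s)",
                  what, paste(which(bad), collapse = ", ")))
  }
  invisible(TRUE)
}

#' Intersection-over-union of two boxes
#'
#' @param a,b numeric vectors `c(x0, y0, x1, y1)`.
#' @return IoU in \[0, 1\].
#' @export
bbox_iou <- function(a, b) {
  ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  area_a <- (a[3] - a[1]) * (a[4] - a[2])
  area_b <- (b[3] - b[1]) * (b[4] - b[2])
  if (area_a <= 0 || area_b <= 0) abort("bbox_iou: degenerate (zero-area) box")
  inter / (area_a + area_b - inter)
}

# Overlap length of two 1-d intervals [a0,a1], [b0,b1].
interval_overlap <- function(a0, a1, b0, b1) {
  pmax(0, pmin(a1, b1) - pmax(a0, b0))
}
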