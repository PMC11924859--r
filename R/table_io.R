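#' Write / read a logical table
#'
#' JSON is the lossless canonical format (cells, header-row count, spans).
#' CSV (RFC-4180, no header line, cells only) and HTML (`<table>` with
#' `<thead>`/`<tbody>` and `rowspan`/`colspan` attributes) are provided for
#' interchange. `read_table(write_table(t))` reproduces `t` cell-for-cell,
#' including embedded newlines, commas and Unicode.
#'
#' @param table a [logical_table()].
#' @param path file path.
#' @param format one of `"csv"`, `"json"`, `"html"`.
#' @return `write_table()` returns `path` invisibly; `read_table()` returns
#'   a [logical_table()].
#' @export
write_table <- function(table, path, format = c("json", "csv", "html")) {
  assert_logical_table(table)
  format <- match.arg(format)
  switch(format,
    json = write_table_json(table, path),
    csv = write_table_csv(table, path),
    html = write_table_html(table, path))
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path, format = c("json", "csv", "html")) {
  format <- match.arg(format)
  switch(format,
    json = read_table_json(path),
    csv = read_table_csv(path),
    html = read_table_html(path))
}

write_table_json <- function(table, path) {
  d <- dim(table)
  cells <- lapply(seq_len(d[1]), function(i) as.list(table$cells[i, ]))
  obj <- list(n_header_rows = table$n_header_rows, n_cols = d[2], cells = cells)
  if (!is.null(table$spans) && nrow(table$spans) > 0) {
    obj$spans <- lapply(seq_len(nrow(table$spans)),
                        function(k) as.list(table$spans[k, ]))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
}

read_table_json <- function(path) {
  o <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  rows <- lapply(o$cells, function(r) vapply(r, as.character, character(1)))
  ncol <- o$n_cols %||% if (length(rows)) length(rows[[1]]) else 0
  cells <- if (length(rows) == 0) {
    matrix(character(), 0, ncol)
  } else {
    matrix(unlist(rows), nrow = length(rows), byrow = TRUE)
  }
  spans <- if (!is.null(o$spans)) dplyr::bind_rows(lapply(o$spans, as_tibble))
  logical_table(cells, n_header_rows = o$n_header_rows %||% 0L, spans = spans)
}

write_table_csv <- function(table, path) {
  d <- dim(table)
  if (prod(d) == 0) {
    writeLines(character(), path, useBytes = TRUE)
    return(invisible(path))
  }
  df <- as.data.frame(table$cells, stringsAsFactors = FALSE)
  # quote everything so an all-empty row is not read back as a blank line
  readr::write_csv(df, path, col_names = FALSE, quote = "all")
}

read_table_csv <- function(path) {
  if (file.size(path) == 0) {
    return(logical_table(matrix(character(), 0, 0)))
  }
  df <- readr::read_csv(path, col_names = FALSE,
                        col_types = readr::cols(.default = readr::col_character()),
                        na = character(), progress = FALSE,
                        show_col_types = FALSE)
  m <- as.matrix(df)
  dimnames(m) <- NULL
  logical_table(m)
}

span_lookup <- function(table) {
  # matrix of span ids per grid position; 0 = simple cell
  d <- dim(table)
  id <- matrix(0L, d[1], d[2])
  if (!is.null(table$spans) && nrow(table$spans) > 0) {
    for (k in seq_len(nrow(table$spans))) {
      s <- table$spans[k, ]
      id[(s$row_start + 1):s$row_end, (s$col_start + 1):s$col_end] <- k
    }
  }
  id
}

write_table_html <- function(table, path) {
  d <- dim(table)
  esc <- function(s) {
    s <- gsub("&", "&amp;", s, fixed = TRUE)
    s <- gsub("<", "&lt;", s, fixed = TRUE)
    gsub(">", "&gt;", s, fixed = TRUE)
  }
  ids <- span_lookup(table)
  row_html <- function(i, tag) {
    tds <- character(0)
    for (j in seq_len(d[2])) {
      k <- ids[i, j]
      if (k > 0) {
        s <- table$spans[k, ]
        if (i != s$row_start + 1 || j != s$col_start + 1) next  # covered position
        attrs <- ""
        if (s$row_end - s$row_start > 1) attrs <- sprintf('%s rowspan="%d"', attrs, s$row_end - s$row_start)
        if (s$col_end - s$col_start > 1) attrs <- sprintf('%s colspan="%d"', attrs, s$col_end - s$col_start)
        tds <- c(tds, sprintf("<%s%s>%s</%s>", tag, attrs, esc(table$cells[i, j]), tag))
      } else {
        tds <- c(tds, sprintf("<%s>%s</%s>", tag, esc(table$cells[i, j]), tag))
      }
    }
    paste0("<tr>", paste0(tds, collapse = ""), "</tr>")
  }
  nh <- table$n_header_rows
  head_rows <- if (nh > 0) vapply(seq_len(nh), row_html, character(1), tag = "th")
  body_rows <- if (d[1] > nh) vapply(seq.int(nh + 1, d[1]), row_html, character(1), tag = "td")
  parts <- c("<table>",
             if (nh > 0) c("<thead>", head_rows, "</thead>"),
             "<tbody>", body_rows, "</tbody>", "</table>")
  # single line per structural token; cell text stays verbatim inside td/th
  writeLines(enc2utf8(paste0(parts, collapse = "")), path, useBytes = TRUE)
}

read_table_html <- function(path) {
  doc <- xml2::read_html(path, encoding = "UTF-8")
  tab <- xml2::xml_find_first(doc, ".//table")
  if (is.na(tab)) abort("read_table: no <table> element found")
  parse_html_table(tab)
}

# Shared grid-fill for HTML and JATS tables: expands rowspan/colspan,
# repeating the anchor content over covered positions and recording spans.
parse_html_table <- function(tab, id = NULL) {
  thead_rows <- xml2::xml_find_all(tab, "./thead/tr")
  body_rows <- xml2::xml_find_all(tab, "./tbody/tr | ./tr")
  n_header <- length(thead_rows)
  trs <- c(as.list(thead_rows), as.list(body_rows))
  if (length(trs) == 0) return(logical_table(matrix(character(), 0, 0)))
  grid <- list()    # grid[[i]][[j]] = text or NULL
  taken <- list()   # TRUE where occupied
  spans <- list()
  get_cell <- function(i, j) if (i <= length(taken) && j <= length(taken[[i]]))
    isTRUE(taken[[i]][[j]]) else FALSE
  set_cell <- function(i, j, text) {
    while (length(grid) < i) { grid[[length(grid) + 1]] <<- list(); taken[[length(taken) + 1]] <<- logical(0) }
    row <- grid[[i]]; row[[j]] <- text; grid[[i]] <<- row
    tk <- taken[[i]]; length(tk) <- max(length(tk), j); tk[j] <- TRUE; taken[[i]] <<- tk
  }
  for (i in seq_along(trs)) {
    cells <- xml2::xml_find_all(trs[[i]], "./td | ./th")
    j <- 1L
    for (cell in as.list(cells)) {
      while (get_cell(i, j)) j <- j + 1L
      txt <- xml2::xml_text(cell)
      rs <- suppressWarnings(as.integer(xml2::xml_attr(cell, "rowspan")))
      cs <- suppressWarnings(as.integer(xml2::xml_attr(cell, "colspan")))
      rs <- if (is.na(rs)) 1L else rs
      cs <- if (is.na(cs)) 1L else cs
      for (di in seq_len(rs)) for (dj in seq_len(cs)) set_cell(i + di - 1L, j + dj - 1L, txt)
      if (rs > 1 || cs > 1) {
        spans[[length(spans) + 1]] <- tibble(row_start = i - 1L, row_end = i - 1L + rs,
                                             col_start = j - 1L, col_end = j - 1L + cs)
      }
      j <- j + cs
    }
  }
  widths <- vapply(grid, length, integer(1))
  C <- max(widths)
  complete <- vapply(seq_along(grid), function(i) {
    length(grid[[i]]) == C && !any(vapply(grid[[i]], is.null, logical(1)))
  }, logical(1))
  if (!all(complete)) {
    abort(sprintf("non-rectangular table after span expansion%s (rows %s)",
                  if (!is.null(id) && !is.na(id)) paste0(" in table '", id, "'") else "",
                  paste(which(!complete), collapse = ", ")))
  }
  cells <- matrix(unlist(lapply(grid, function(r) vapply(r, identity, character(1)))),
                  nrow = length(grid), byrow = TRUE)
  logical_table(cells, n_header_rows = n_header,
                spans = if (length(spans)) dplyr::bind_rows(spans))
}

#' Read tables from a JATS XML article
#'
#' Parses every `<table>` inside a `<table-wrap>` element of a JATS
#' (Journal Archiving and Interchange) XML file, the format used by the
#' PubMed Central Open Access Subset. Header rows come from `<thead>`;
#' `rowspan`/`colspan` attributes are expanded onto the grid and recorded
#' as spans.
#'
#' @param path JATS XML file path.
#' @return list of [logical_table()], one per `<table>`.
#' @export
read_jats_tables <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) abort(sprintf("read_jats_tables: XML parse failure: %s",
                                                    conditionMessage(e))))
  wraps <- xml2::xml_find_all(doc, ".//*[local-name() = 'table-wrap']")
  out <- list()
  for (w in as.list(wraps)) {
    id <- xml2::xml_attr(w, "id")
    tabs <- xml2::xml_find_all(w, ".//*[local-name() = 'table']")
    for (tab in as.list(tabs)) {
      out[[length(out) + 1]] <- parse_html_table(tab, id = id)
    }
  }
  out
}

#' Collect the cell corpus of a set of tables
#'
#' One string per cell (headers included), the pre-training unit of the
#' table language model.
#'
#' @param tables list of [logical_table()].
#' @param drop_empty drop empty cells.
#' @return character vector of cell contents.
#' @export
cell_corpus <- function(tables, drop_empty = TRUE) {
  cells <- unlist(lapply(tables, function(t) as.vector(t$cells)), use.names = FALSE)
  if (drop_empty) cells <- cells[nzchar(cells)]
  cells
}
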