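#' Configuration of the simulated cell-overflow scheme
#'
#' Tables with at least one row whose total character width (the sum of
#' its cell lengths) exceeds `selection_threshold` are selected for
#' overflow simulation. The allowed total row width W is
#' `narrow_width` (80 characters) when the longest row's total width is
#' below `narrow_table_cutoff` (100), and `wide_width` (90, the maximum
#' number of characters fitting a single line at a reasonable font size)
#' otherwise.
#'
#' @param selection_threshold minimum longest-row width for selection.
#' @param narrow_table_cutoff longest-row width below which the narrow
#'   allowed width is used.
#' @param narrow_width,wide_width allowed total row widths (characters).
#' @param seed RNG seed used when sampling negative instances.
#' @return an `overflow_config` list.
#' @export
overflow_config <- function(selection_threshold = 90L,
                            narrow_table_cutoff = 100L,
                            narrow_width = 80L, wide_width = 90L,
                            seed = 1L) {
  if (!(narrow_width < selection_threshold &&
        selection_threshold < narrow_table_cutoff)) {
    abort("overflow_config: need narrow_width < selection_threshold < narrow_table_cutoff")
  }
  structure(list(selection_threshold = as.integer(selection_threshold),
                 narrow_table_cutoff = as.integer(narrow_table_cutoff),
                 narrow_width = as.integer(narrow_width),
                 wide_width = as.integer(wide_width),
                 seed = as.integer(seed)),
            class = "overflow_config")
}

row_widths <- function(table) {
  if (nrow(table$cells) == 0) return(integer(0))
  rowSums(nchar(table$cells, type = "chars"))
}

#' Decide whether a table qualifies for overflow simulation
#'
#' @param table a [logical_table()].
#' @param cfg an [overflow_config()].
#' @return list with `selected` (logical) and `width` (the allowed total
#'   row width W in characters, `NA` when not selected).
#' @export
select_for_overflow <- function(table, cfg = overflow_config()) {
  assert_logical_table(table)
  rw <- row_widths(table)
  max_rw <- if (length(rw)) max(rw) else 0L
  if (max_rw <= cfg$selection_threshold) {
    return(list(selected = FALSE, width = NA_integer_))
  }
  w <- if (max_rw < cfg$narrow_table_cutoff) cfg$narrow_width else cfg$wide_width
  list(selected = TRUE, width = w)
}

# Largest-remainder apportionment of `total` integer units over weights.
largest_remainder <- function(weights, total) {
  raw <- total * weights / sum(weights)
  base <- floor(raw)
  rem <- total - sum(base)
  if (rem > 0) {
    frac <- raw - base
    pick <- order(-frac, seq_along(frac))[seq_len(rem)]
    base[pick] <- base[pick] + 1
  }
  # every width at least 1, stolen from the widest column
  while (any(base < 1)) {
    i <- which.min(base); j <- which.max(base)
    base[i] <- base[i] + 1; base[j] <- base[j] - 1
  }
  as.integer(base)
}

#' Allocate column widths for overflow simulation
#'
#' The allowed total row width W is divided among the columns in
#' proportion to each column's mean cell length plus the standard
#' deviation of its cell lengths, giving extra room to columns with more
#' width variation (mimicking how authors size columns to avoid
#' spillover). Integer widths are obtained by largest-remainder rounding,
#' so they always sum to W exactly and each is at least 1.
#'
#' @param table a [logical_table()].
#' @param width allowed total row width W (characters), `>= ncol`.
#' @return integer vector of per-column character widths summing to `width`.
#' @export
allocate_column_widths <- function(table, width) {
  assert_logical_table(table)
  C <- ncol(table$cells)
  if (width < C) abort("allocate_column_widths: `width` must be >= number of columns")
  lens <- nchar(table$cells, type = "chars")
  mu <- colMeans(lens)
  sdev <- apply(lens, 2, function(v) if (length(v) > 1) sd(v) else 0)
  sdev[is.na(sdev)] <- 0
  w <- mu + sdev
  if (sum(w) <= 0) w <- rep(1, C)
  largest_remainder(w, width)
}

#' Wrap cell content to a character width
#'
#' Greedy word wrap at space characters; a single word longer than the
#' width is hard-split at the width boundary. Joining the fragments
#' (single space at space-split points, direct concatenation at hard
#' splits, recorded in `attr(, "joins")`) reproduces the content exactly,
#' and every fragment is at most `width` characters long.
#'
#' @param content cell string.
#' @param width maximum fragment width in characters (>= 1).
#' @return character vector of fragments with attribute `joins` (length
#'   `n - 1`, values `"space"` or `"none"`).
#' @export
split_cell <- function(content, width) {
  if (width < 1) abort("split_cell: `width` must be >= 1")
  frags <- character(0)
  joins <- character(0)
  push <- function(f, join) {
    if (length(frags) > 0) joins <<- c(joins, join)
    frags <<- c(frags, f)
  }
  line <- NULL       # open (unfinished) fragment
  line_join <- "space"  # junction between the previous fragment and `line`
  words <- strsplit(content, " ", fixed = TRUE)[[1]]
  if (length(words) == 0) words <- ""
  for (w in words) {
    if (!is.null(line)) {
      cand <- paste(line, w)
      if (nchar(cand) <= width) {
        line <- cand
        next
      }
      push(line, line_join)
      line <- NULL
      line_join <- "space"
    }
    while (nchar(w) > width) {  # word longer than the column: hard split
      push(substr(w, 1, width), line_join)
      line_join <- "none"
      w <- substr(w, width + 1, nchar(w))
    }
    line <- w
  }
  if (!is.null(line)) push(line, line_join)
  structure(frags, joins = if (length(frags) > 1) joins else character(0))
}

#' Join fragments produced by [split_cell()]
#'
#' @param frags fragment vector with a `joins` attribute (missing joins
#'   default to single spaces).
#' @return the reassembled string.
#' @export
join_fragments <- function(frags) {
  if (length(frags) <= 1) return(paste0(frags, collapse = ""))
  joins <- attr(frags, "joins") %||% rep("space", length(frags) - 1)
  out <- frags[1]
  for (k in 2:length(frags)) {
    sep <- if (joins[k - 1] == "space") " " else ""
    out <- paste0(out, sep, frags[k])
  }
  out
}

#' Simulate cell overflow: over-segment a table and label merge pairs
#'
#' Each logical row becomes as many physical rows as the largest fragment
#' count among its cells after wrapping to the allocated column widths.
#' Cells that fit keep the first physical row of their group, with the
#' remaining rows of that column left empty. Positive merge instances are
#' consecutive fragment pairs within a split cell; negatives are
#' vertically adjacent same-column pairs drawn from different logical
#' rows in which both cells fit their column (sampled `negative_ratio` :
#' 1 against positives, seeded from `cfg$seed`).
#'
#' @param table a [logical_table()] selected by [select_for_overflow()].
#' @param cfg an [overflow_config()].
#' @param negative_ratio negatives sampled per positive.
#' @return list with `oversegmented` ([logical_table()]),
#'   `gold_row_groups` (list of physical-row index vectors, one per
#'   logical row), `widths` (allocated column widths) and `instances`
#'   (tibble `upper`, `lower`, `label`).
#' @export
simulate_overflow <- function(table, cfg = overflow_config(),
                              negative_ratio = 1) {
  assert_logical_table(table)
  sel <- select_for_overflow(table, cfg)
  if (!sel$selected) {
    abort("simulate_overflow: table does not qualify (no row wider than the selection threshold)")
  }
  widths <- allocate_column_widths(table, sel$width)
  R <- nrow(table$cells); C <- ncol(table$cells)
  frag_grid <- vector("list", R)
  for (i in seq_len(R)) {
    frag_grid[[i]] <- lapply(seq_len(C), function(j) {
      cell <- table$cells[i, j]
      if (nchar(cell, type = "chars") > widths[j]) split_cell(cell, widths[j])
      else cell
    })
  }
  n_phys <- vapply(frag_grid, function(fr) max(lengths(fr)), integer(1))
  out <- matrix("", nrow = sum(n_phys), ncol = C)
  gold_row_groups <- vector("list", R)
  positives <- list()
  at <- 0L
  for (i in seq_len(R)) {
    rows_i <- at + seq_len(n_phys[i])
    gold_row_groups[[i]] <- rows_i
    for (j in seq_len(C)) {
      fr <- frag_grid[[i]][[j]]
      out[at + seq_along(fr), j] <- fr
      if (length(fr) > 1) {
        for (k in seq_len(length(fr) - 1)) {
          positives[[length(positives) + 1]] <-
            tibble(upper = fr[k], lower = fr[k + 1], label = 1L)
        }
      }
    }
    at <- at + n_phys[i]
  }
  pos <- if (length(positives)) dplyr::bind_rows(positives) else
    tibble(upper = character(), lower = character(), label = integer())
  neg_pool <- list()
  if (R > 1) {
    lens <- nchar(table$cells, type = "chars")
    for (i in seq_len(R - 1)) {
      for (j in seq_len(C)) {
        if (lens[i, j] <= widths[j] && lens[i + 1, j] <= widths[j]) {
          neg_pool[[length(neg_pool) + 1]] <-
            tibble(upper = table$cells[i, j], lower = table$cells[i + 1, j],
                   label = 0L)
        }
      }
    }
  }
  neg <- if (length(neg_pool)) dplyr::bind_rows(neg_pool) else
    tibble(upper = character(), lower = character(), label = integer())
  n_want <- round(nrow(pos) * negative_ratio)
  if (nrow(neg) > n_want) {
    neg <- withr::with_seed(cfg$seed, neg[sample.int(nrow(neg), n_want), ])
  }
  overseg <- logical_table(out, n_header_rows = table$n_header_rows)
  sup <- attr(table, "superscripts")
  if (!is.null(sup)) {
    starts <- vapply(gold_row_groups, `[`, integer(1), 1)
    sup$row <- starts[sup$row]
    attr(overseg, "superscripts") <- sup
  }
  list(oversegmented = overseg, gold_row_groups = gold_row_groups,
       widths = widths, instances = dplyr::bind_rows(pos, neg))
}

#' Rebuild the original table from an over-segmented one
#'
#' Space-joins the cells of each gold row group; the exact inverse of
#' [simulate_overflow()] for space-split content.
#'
#' @param oversegmented over-segmented [logical_table()].
#' @param row_groups list of physical-row index vectors.
#' @param n_header_rows header rows of the rebuilt table.
#' @return a [logical_table()].
#' @export
merge_row_groups <- function(oversegmented, row_groups,
                             n_header_rows = oversegmented$n_header_rows) {
  assert_logical_table(oversegmented, "oversegmented")
  C <- ncol(oversegmented$cells)
  cells <- matrix("", nrow = length(row_groups), ncol = C)
  for (i in seq_along(row_groups)) {
    for (j in seq_len(C)) {
      parts <- oversegmented$cells[row_groups[[i]], j]
      parts <- parts[nzchar(parts)]
      cells[i, j] <- paste(parts, collapse = " ")
    }
  }
  logical_table(cells, n_header_rows = n_header_rows)
}

#' Generate a labeled merge-instance corpus
#'
#' Draws synthetic resource tables, runs each through
#' [simulate_overflow()], and pools the labeled pairs until at least
#' `n_instances` are collected.
#'
#' @param n_instances minimum number of instances.
#' @param seed base RNG seed (table t uses `seed + t`).
#' @param n_rows body rows per table.
#' @param long_cells overflow-forcing cells per table.
#' @return tibble with columns `upper`, `lower`, `label`.
#' @export
generate_merge_instances <- function(n_instances, seed = 1L, n_rows = 12L,
                                     long_cells = 2L) {
  out <- list()
  total <- 0L
  t <- 0L
  while (total < n_instances) {
    t <- t + 1L
    tbl <- generate_resource_table(n_rows, seed = seed + t,
                                   long_cells = long_cells)
    sim <- simulate_overflow(tbl, overflow_config(seed = seed + t))
    out[[t]] <- sim$instances
    total <- total + nrow(sim$instances)
  }
  inst <- dplyr::bind_rows(out)
  withr::with_seed(seed, inst[sample.int(nrow(inst)), ])
}
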