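#' Cell content similarity: LCS ratio
#'
#' Ratio of the longest common subsequence length of the two cell strings
#' to the length of the ground-truth cell string. Both cells empty counts
#' as 1 (nothing to recover); an empty ground-truth cell against
#' non-empty prediction counts as 0.
#'
#' @param gt_cell ground-truth cell string.
#' @param pred_cell predicted cell string.
#' @return similarity in \[0, 1\].
#' @export
content_similarity <- function(gt_cell, pred_cell) {
  n <- nchar(gt_cell, type = "chars")
  if (n == 0) return(if (nchar(pred_cell, type = "chars") == 0) 1 else 0)
  lcs_length_int(utf8ToInt(gt_cell), utf8ToInt(pred_cell)) / n
}

# IoU of two half-open grid rectangles c(r0, c0, r1, c1).
grid_rect_iou <- function(a, b) {
  area_a <- (a[3] - a[1]) * (a[4] - a[2])
  area_b <- (b[3] - b[1]) * (b[4] - b[2])
  if (area_a <= 0 || area_b <= 0) abort("topology_similarity: degenerate (zero-area) span")
  ir <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  ic <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ir * ic
  inter / (area_a + area_b - inter)
}

#' Cell topology similarity: grid-span IoU
#'
#' Intersection-over-union of the two cells' grid-span rectangles,
#' expressed relative to their aligned grid positions (a simple 1 x 1
#' cell is the unit rectangle at the origin). Identical spans give 1,
#' disjoint spans 0.
#'
#' @param gt_span,pred_span numeric `c(row_start, col_start, row_end,
#'   col_end)` half-open rectangles relative to the aligned position.
#' @return similarity in \[0, 1\].
#' @export
topology_similarity <- function(gt_span, pred_span) {
  grid_rect_iou(gt_span, pred_span)
}

#' Cell location similarity: bounding-box IoU
#'
#' @param gt_bbox,pred_bbox numeric `c(x0, y0, x1, y1)` page boxes.
#' @return IoU in \[0, 1\].
#' @export
location_similarity <- function(gt_bbox, pred_bbox) {
  bbox_iou(gt_bbox, pred_bbox)
}

# Relative span rectangle of grid position (i, j) of a table: the span
# containing the position, translated so that (i, j) is the origin.
relative_spans <- function(table) {
  d <- dim(table)
  ids <- span_lookup(table)
  out <- array(0, dim = c(d[1], d[2], 4))
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    k <- ids[i, j]
    if (k > 0) {
      s <- table$spans[k, ]
      out[i, j, ] <- c(s$row_start - (i - 1), s$col_start - (j - 1),
                       s$row_end - (i - 1), s$col_end - (j - 1))
    } else {
      out[i, j, ] <- c(0, 0, 1, 1)
    }
  }
  out
}

# 4-d array of pairwise cell gains G[i, j, p, q] = f(A[i,j], B[p,q]).
# Gains are alignment-independent: content compares strings, topology
# compares spans relative to the cell's own position, location compares
# absolute cell boxes (attr(table, "cell_boxes"), an R x C x 4 array).
gain_array <- function(A, B, f = c("content", "topology", "location")) {
  f <- match.arg(f)
  da <- dim(A); db <- dim(B)
  G <- array(0, dim = c(da[1], da[2], db[1], db[2]))
  if (prod(da) == 0 || prod(db) == 0) return(G)
  if (f == "content") {
    ia <- lapply(as.vector(A$cells), utf8ToInt)
    ib <- lapply(as.vector(B$cells), utf8ToInt)
    na <- lengths(ia)
    for (i in seq_len(da[1])) for (j in seq_len(da[2])) {
      a_idx <- (j - 1) * da[1] + i
      av <- ia[[a_idx]]; n <- na[a_idx]
      for (p in seq_len(db[1])) for (q in seq_len(db[2])) {
        bv <- ib[[(q - 1) * db[1] + p]]
        G[i, j, p, q] <- if (n == 0) {
          if (length(bv) == 0) 1 else 0
        } else lcs_length_int(av, bv) / n
      }
    }
  } else if (f == "topology") {
    sa <- relative_spans(A); sb <- relative_spans(B)
    for (i in seq_len(da[1])) for (j in seq_len(da[2])) {
      ra <- sa[i, j, ]
      for (p in seq_len(db[1])) for (q in seq_len(db[2])) {
        G[i, j, p, q] <- grid_rect_iou(ra, sb[p, q, ])
      }
    }
  } else {
    ba <- attr(A, "cell_boxes"); bb <- attr(B, "cell_boxes")
    if (is.null(ba) || is.null(bb)) {
      abort("location similarity unavailable: tables carry no cell_boxes attribute")
    }
    for (i in seq_len(da[1])) for (j in seq_len(da[2])) {
      for (p in seq_len(db[1])) for (q in seq_len(db[2])) {
        a <- ba[i, j, ]; b <- bb[p, q, ]
        G[i, j, p, q] <- if (anyNA(a) || anyNA(b)) {
          if (anyNA(a) && anyNA(b)) 1 else 0
        } else bbox_iou(a, b)
      }
    }
  }
  G
}

# Order-preserving sequence alignment with free skips maximizing the sum
# of pairwise gains. Returns the optimum and one maximizing pairing.
align_sequences <- function(g) {
  n <- nrow(g); m <- ncol(g)
  M <- matrix(0, n + 1, m + 1)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    M[i + 1, j + 1] <- max(M[i, j + 1], M[i + 1, j], M[i, j] + g[i, j])
  }
  pairs <- matrix(integer(0), ncol = 2)
  i <- n; j <- m
  while (i > 0 && j > 0) {
    if (M[i + 1, j + 1] == M[i, j] + g[i, j]) {
      pairs <- rbind(c(i, j), pairs)
      i <- i - 1; j <- j - 1
    } else if (M[i + 1, j + 1] == M[i, j + 1]) {
      i <- i - 1
    } else {
      j <- j - 1
    }
  }
  list(score = M[n + 1, m + 1], pairs = pairs)
}

collapse_rows <- function(G, row_pairs) {
  # gains between columns given a fixed row pairing
  g <- matrix(0, dim(G)[2], dim(G)[4])
  for (t in seq_len(nrow(row_pairs))) {
    g <- g + G[row_pairs[t, 1], , row_pairs[t, 2], ]
  }
  g
}

collapse_cols <- function(G, col_pairs) {
  g <- matrix(0, dim(G)[1], dim(G)[3])
  for (t in seq_len(nrow(col_pairs))) {
    g <- g + G[, col_pairs[t, 1], , col_pairs[t, 2]]
  }
  g
}

#' Best order-preserving 2-d alignment of two tables
#'
#' Finds row and column selections of the ground-truth table `A` and the
#' predicted table `B` that (approximately) maximize the summed cell
#' similarity over aligned positions, using the factored iterative
#' dynamic program: columns are aligned given a row pairing by sequence
#' alignment with per-cell gains, rows are aligned given the column
#' pairing, and the two passes are iterated to a fixed point from both a
#' row-first and a column-first start, keeping the better solution. The
#' exact 2-d optimum is intractable in general; [grits_oracle()] provides
#' the exhaustive-enumeration optimum for small tables.
#'
#' @param A,B [logical_table()] objects (ground truth, prediction).
#' @param f similarity function: `"content"`, `"topology"` or `"location"`.
#' @param max_iter maximum row/column passes per start.
#' @return list with `score` (the summed similarity), `row_pairs` and
#'   `col_pairs` (2-column index matrices, strictly increasing in both
#'   columns).
#' @export
best_alignment <- function(A, B, f = "content", max_iter = 10) {
  assert_logical_table(A, "A"); assert_logical_table(B, "B")
  da <- dim(A); db <- dim(B)
  if (prod(da) == 0 || prod(db) == 0) abort("best_alignment: empty table")
  G <- gain_array(A, B, f)
  identity_pairs <- function(n, m) {
    k <- min(n, m)
    cbind(seq_len(k), seq_len(k))
  }
  refine <- function(rows) {
    # alternate column- and row-alignment passes to a fixed point
    best <- list(score = -Inf)
    for (it in seq_len(max_iter)) {
      cols <- align_sequences(collapse_rows(G, rows))
      opt <- align_sequences(collapse_cols(G, cols$pairs))
      if (opt$score <= best$score + 1e-12) break
      best <- list(score = opt$score, row_pairs = opt$pairs,
                   col_pairs = cols$pairs)
      rows <- opt$pairs
    }
    best
  }
  # seed row pairings: identity, column-identity-induced, and every
  # single row pair (cheap; escapes the local optima the plain
  # alternation can fall into on small tables with empty cells)
  seeds <- list(identity_pairs(da[1], db[1]))
  ci <- align_sequences(collapse_cols(G, identity_pairs(da[2], db[2])))
  seeds[[length(seeds) + 1]] <- ci$pairs
  if (da[1] * db[1] <= 64) {
    for (i in seq_len(da[1])) for (p in seq_len(db[1])) {
      seeds[[length(seeds) + 1]] <- cbind(i, p)
    }
  }
  best <- list(score = -Inf)
  for (s in seeds) {
    if (nrow(s) == 0) next
    cand <- refine(s)
    if (cand$score > best$score) best <- cand
  }
  best
}

#' GriTS: grid table similarity
#'
#' F-measure-style similarity over the best order-preserving 2-d
#' alignment of the ground-truth and predicted grids:
#' `GriTS = 2 * S / (|A| + |B|)`, `precision = S / |B|`,
#' `recall = S / |A|`, where `S` is the summed cell similarity over the
#' aligned substructure and `|.|` counts grid cells. Two empty tables
#' score 1.
#'
#' @inheritParams best_alignment
#' @param alignment optionally a precomputed [best_alignment()] result.
#' @return named list: `grits`, `precision`, `recall`, `score`, `n_gold`,
#'   `n_pred`.
#' @export
grits <- function(A, B, f = "content", alignment = NULL) {
  assert_logical_table(A, "A"); assert_logical_table(B, "B")
  nA <- prod(dim(A)); nB <- prod(dim(B))
  if (nA == 0 && nB == 0) {
    return(list(grits = 1, precision = 1, recall = 1, score = 0,
                n_gold = 0L, n_pred = 0L))
  }
  S <- if (nA == 0 || nB == 0) 0 else {
    (alignment %||% best_alignment(A, B, f))$score
  }
  list(grits = 2 * S / (nA + nB),
       precision = if (nB > 0) S / nB else 1,
       recall = if (nA > 0) S / nA else 1,
       score = S, n_gold = as.integer(nA), n_pred = as.integer(nB))
}

#' Exhaustive-enumeration GriTS alignment optimum
#'
#' Enumerates every order-preserving row and column subset selection of
#' both tables and returns the maximal summed cell similarity. Only
#' feasible for small tables; serves as the correctness oracle for
#' [best_alignment()].
#'
#' @inheritParams best_alignment
#' @return the optimal summed similarity (a number).
#' @export
grits_oracle <- function(A, B, f = "content") {
  da <- dim(A); db <- dim(B)
  if (prod(da) * prod(db) == 0) return(0)
  if (max(da, db) > 6) abort("grits_oracle: tables too large for enumeration")
  G <- gain_array(A, B, f)
  subsets <- function(n, k) {
    if (k == 0) return(list(integer(0)))
    utils::combn(n, k, simplify = FALSE)
  }
  best <- 0
  for (kr in 0:min(da[1], db[1])) {
    rsA <- subsets(da[1], kr); rsB <- subsets(db[1], kr)
    for (ra in rsA) for (rb in rsB) {
      M2 <- matrix(0, da[2], db[2])
      for (t in seq_len(kr)) M2 <- M2 + G[ra[t], , rb[t], ]
      for (kc in 0:min(da[2], db[2])) {
        csA <- subsets(da[2], kc); csB <- subsets(db[2], kc)
        for (ca in csA) for (cb in csB) {
          s <- 0
          for (t in seq_len(kc)) s <- s + M2[ca[t], cb[t]]
          if (s > best) best <- s
        }
      }
    }
  }
  best
}

#' Full GriTS report for a gold/predicted table pair
#'
#' @param gold,pred [logical_table()] objects.
#' @param similarities which similarity functions to report; location is
#'   only computed when both tables carry a `cell_boxes` attribute.
#' @return a tibble of class `grits_report` with one row per similarity
#'   function: `grits`, `precision`, `recall`, `n_gold`, `n_pred`.
#' @export
grits_report <- function(gold, pred,
                         similarities = c("content", "topology")) {
  rows <- lapply(similarities, function(f) {
    if (f == "location" &&
        (is.null(attr(gold, "cell_boxes")) || is.null(attr(pred, "cell_boxes")))) {
      return(tibble(similarity = f, grits = NA_real_, precision = NA_real_,
                    recall = NA_real_, n_gold = prod(dim(gold)),
                    n_pred = prod(dim(pred))))
    }
    g <- grits(gold, pred, f)
    tibble(similarity = f, grits = g$grits, precision = g$precision,
           recall = g$recall, n_gold = g$n_gold, n_pred = g$n_pred)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("grits_report", class(out))
  out
}

#' Pair predicted and gold tables by vocabulary overlap
#'
#' Vocabulary is the set of lowercased whitespace-delimited tokens of all
#' cells; overlap is normalized by the gold vocabulary. Pairs are formed
#' greedily best-first and accepted only when the overlap strictly
#' exceeds the threshold; each table is matched at most once.
#'
#' @param pred_tables,gold_tables lists of [logical_table()].
#' @param threshold minimum (strict) vocabulary overlap, default 0.40.
#' @return tibble with columns `pred`, `gold`, `overlap` (indices into
#'   the input lists).
#' @export
align_tables_by_vocab <- function(pred_tables, gold_tables, threshold = 0.40) {
  vocab <- function(t) {
    toks <- unlist(strsplit(tolower(as.vector(t$cells)), "\\s+"))
    unique(toks[nzchar(toks)])
  }
  vp <- lapply(pred_tables, vocab)
  vg <- lapply(gold_tables, vocab)
  cand <- list()
  for (i in seq_along(vp)) for (j in seq_along(vg)) {
    ov <- if (length(vg[[j]]) == 0) 0 else
      length(intersect(vp[[i]], vg[[j]])) / length(vg[[j]])
    cand[[length(cand) + 1]] <- tibble(pred = i, gold = j, overlap = ov)
  }
  out <- tibble(pred = integer(), gold = integer(), overlap = double())
  if (length(cand) == 0) return(out)
  cand <- dplyr::arrange(dplyr::bind_rows(cand), dplyr::desc(.data$overlap),
                         .data$pred, .data$gold)
  used_p <- logical(length(vp)); used_g <- logical(length(vg))
  for (k in seq_len(nrow(cand))) {
    i <- cand$pred[k]; j <- cand$gold[k]
    if (cand$overlap[k] > threshold && !used_p[i] && !used_g[j]) {
      used_p[i] <- TRUE; used_g[j] <- TRUE
      out <- dplyr::bind_rows(out, cand[k, ])
    }
  }
  out
}
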