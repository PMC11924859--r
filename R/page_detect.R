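#' Tokenize a line of page text
#'
#' Lowercased, split at whitespace and punctuation boundaries; runs of
#' digits collapse to a `<num>` token.
#'
#' @param text character vector of lines.
#' @return list of token vectors.
#' @export
tokenize_line <- function(text) {
  lapply(tolower(text), function(s) {
    toks <- unlist(stringr::str_extract_all(s, "[a-z]+|[0-9]+|[^a-z0-9\\s]"))
    if (length(toks) == 0) return(character(0))
    ifelse(grepl("^[0-9]+$", toks), "<num>", toks)
  })
}

#' Seeded static word embeddings
#'
#' A drop-in stand-in for pretrained word vectors: every vocabulary
#' token receives a fixed random Gaussian vector, plus a designated
#' out-of-vocabulary vector and a null (padding) vector. Any word-vector
#' table with the same shape (rows named by token) can be supplied to
#' the line classifier instead.
#'
#' @param tokens character vector (the embedding vocabulary).
#' @param dim embedding dimension.
#' @param seed RNG seed.
#' @return matrix with one row per token plus rows `"<oov>"` and
#'   `"<null>"`.
#' @export
random_embeddings <- function(tokens, dim = 50, seed = 1L) {
  tokens <- sort(unique(tokens))
  withr::with_seed(seed, {
    m <- matrix(rnorm((length(tokens) + 2) * dim, 0, 0.5),
                length(tokens) + 2, dim)
    rownames(m) <- c(tokens, "<oov>", "<null>")
    m[nrow(m), ] <- 0  # null token
    m
  })
}

# Physical text lines of a page: segments of build_text_lines joined per
# y-band, left to right.
page_text_lines <- function(page) {
  segs <- build_text_lines(page)
  if (nrow(segs) == 0) {
    return(tibble(y0 = double(), y1 = double(), text = character()))
  }
  dplyr::summarise(dplyr::group_by(segs, .data$band),
                   y0 = min(.data$y0), y1 = max(.data$y1),
                   text = paste(.data$text[order(.data$x0)], collapse = " "),
                   .groups = "drop")[c("y0", "y1", "text")]
}

graphics_indicators <- function(page, y0, y1) {
  gr <- page$graphics
  h <- 0; v <- 0
  if (nrow(gr) > 0) {
    band_ov <- interval_overlap(y0 - 2, y1 + 2, gr$y0, gr$y1 + 1e-9)
    hit <- band_ov > 0
    h <- as.numeric(any(hit & gr$orientation == "h"))
    v <- as.numeric(any(hit & gr$orientation == "v"))
  }
  c(h, v)
}

#' Line-level features for the first-level classifier
#'
#' The textual context is the token sequence of the current line
#' preceded by the previous `window` lines (older lines first, separated
#' by a null token); structural features indicate horizontal and
#' vertical graphics lines crossing the current and the previous line's
#' vertical band.
#'
#' @param page a [page_record()].
#' @param line_index 1-based index into the page's text lines.
#' @param window number of previous lines included.
#' @param lines optionally the precomputed [page_text_lines()] tibble.
#' @return list with `tokens` (character vector, null-padded at the page
#'   start) and `indicators` (length-4 0/1 vector: h/v at the current
#'   line, h/v at the previous line).
#' @export
extract_line_features <- function(page, line_index, window = 2, lines = NULL) {
  lines <- lines %||% page_text_lines(page)
  if (line_index < 1 || line_index > nrow(lines)) {
    abort("extract_line_features: `line_index` out of range")
  }
  ctx_idx <- seq(line_index - window, line_index)
  toks <- unlist(lapply(ctx_idx, function(i) {
    if (i < 1) "<null>" else c(tokenize_line(lines$text[i])[[1]], "<null>")
  }))
  cur <- graphics_indicators(page, lines$y0[line_index], lines$y1[line_index])
  prev <- if (line_index > 1) {
    graphics_indicators(page, lines$y0[line_index - 1], lines$y1[line_index - 1])
  } else c(0, 0)
  list(tokens = toks, indicators = c(cur, prev))
}

embed_tokens <- function(tokens, emb) {
  idx <- match(tokens, rownames(emb))
  idx[is.na(idx)] <- nrow(emb) - 1L  # <oov>
  emb[idx, , drop = FALSE]
}

# ---- recurrent line classifier (single-layer tanh RNN + logistic head) ----

rnn_init <- function(emb_dim, hidden, n_ind) {
  list(W_x = matrix(rnorm(emb_dim * hidden, 0, 1 / sqrt(emb_dim)), emb_dim, hidden),
       W_h = matrix(rnorm(hidden * hidden, 0, 1 / sqrt(hidden)), hidden, hidden),
       b_h = rep(0, hidden),
       w_out = rep(0, hidden + n_ind),
       b_out = 0)
}

rnn_forward <- function(p, X) {
  Tn <- nrow(X); Hd <- length(p$b_h)
  hs <- matrix(0, Tn + 1, Hd)
  for (t in seq_len(Tn)) {
    hs[t + 1, ] <- tanh(X[t, ] %*% p$W_x + hs[t, ] %*% p$W_h + p$b_h)
  }
  hs
}

rnn_line_prob <- function(p, X, ind) {
  hs <- rnn_forward(p, X)
  z <- sum(p$w_out * c(hs[nrow(hs), ], ind)) + p$b_out
  1 / (1 + exp(-z))
}

#' Train the first-level in-table line classifier
#'
#' A recurrent sequence encoder (single-layer tanh RNN over static token
#' embeddings) whose final state, concatenated with the structural
#' graphics indicators, feeds a logistic output. Errors on the positive
#' (in-table) class are weighted `class_weight_pos` times the negative
#' class (50 by default, compensating the heavy line imbalance of real
#' documents). Deterministic given `seed`.
#'
#' @param features list of [extract_line_features()] results.
#' @param labels 0/1 vector (1 = line inside a resource table).
#' @param embeddings embedding matrix (see [random_embeddings()]).
#' @param class_weight_pos positive-class error weight.
#' @param seed RNG seed.
#' @param hidden recurrent state size.
#' @param epochs,lr Adam schedule.
#' @param window context window the features were built with.
#' @return a `line_model`: parameters, embeddings, window, loss trace.
#' @export
train_line_classifier <- function(features, labels, embeddings,
                                  class_weight_pos = 50, seed = 1L,
                                  hidden = 32L, epochs = 3L, lr = 5e-3,
                                  window = 2L) {
  if (length(features) == 0) abort("train_line_classifier: empty dataset")
  if (length(unique(labels)) < 2) {
    abort("train_line_classifier: need both classes")
  }
  emb_dim <- ncol(embeddings)
  n_ind <- length(features[[1]]$indicators)
  Xs <- lapply(features, function(f) embed_tokens(f$tokens, embeddings))
  inds <- lapply(features, `[[`, "indicators")
  y <- as.numeric(labels)
  wts <- ifelse(y == 1, class_weight_pos, 1)
  withr::with_seed(seed, {
    p <- rnn_init(emb_dim, hidden, n_ind)
    st <- adam_state(p)
    trace <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(length(Xs))
      tot <- 0
      for (i in ord) {
        X <- Xs[[i]]; ind <- inds[[i]]
        hs <- rnn_forward(p, X)
        hT <- hs[nrow(hs), ]
        feat <- c(hT, ind)
        z <- sum(p$w_out * feat) + p$b_out
        pr <- 1 / (1 + exp(-z))
        eps <- 1e-12
        tot <- tot + wts[i] * -(y[i] * log(pr + eps) + (1 - y[i]) * log(1 - pr + eps))
        dz <- wts[i] * (pr - y[i])
        g <- list(w_out = dz * feat, b_out = dz)
        dh <- dz * p$w_out[seq_along(hT)]
        Tn <- nrow(X)
        gW_x <- p$W_x * 0; gW_h <- p$W_h * 0; gb_h <- p$b_h * 0
        for (t in rev(seq_len(Tn))) {
          da <- dh * (1 - hs[t + 1, ]^2)
          gW_x <- gW_x + outer(X[t, ], da)
          gW_h <- gW_h + outer(hs[t, ], da)
          gb_h <- gb_h + da
          dh <- as.vector(p$W_h %*% da)
        }
        g$W_x <- gW_x; g$W_h <- gW_h; g$b_h <- gb_h
        upd <- adam_step(p, g, st, lr)
        p <- upd$p; st <- upd$st
      }
      trace[ep] <- tot / length(Xs)
    }
    structure(list(params = p, embeddings = embeddings, window = window,
                   hidden = hidden, class_weight_pos = class_weight_pos,
                   loss_trace = trace),
              class = "line_model")
  })
}

#' @export
print.line_model <- function(x, ...) {
  cat(sprintf("<line_model: hidden=%d, window=%d, pos weight=%g, %d-dim embeddings>\n",
              x$hidden, x$window, x$class_weight_pos, ncol(x$embeddings)))
  invisible(x)
}

#' In-table probability of each text line of a page
#'
#' @param model a `line_model`.
#' @param page a [page_record()].
#' @return numeric vector, one probability per text line.
#' @export
predict_line_probs <- function(model, page) {
  lines <- page_text_lines(page)
  if (nrow(lines) == 0) return(numeric(0))
  vapply(seq_len(nrow(lines)), function(i) {
    f <- extract_line_features(page, i, window = model$window, lines = lines)
    rnn_line_prob(model$params, embed_tokens(f$tokens, model$embeddings),
                  f$indicators)
  }, numeric(1))
}

#' Number of predicted in-table lines on a page
#'
#' The level-1 summary passed to the page classifier: lines with
#' predicted in-table probability above 0.5.
#'
#' @inheritParams predict_line_probs
#' @return integer count.
#' @export
predict_in_table_lines <- function(model, page) {
  sum(predict_line_probs(model, page) > 0.5)
}

# ---- level 2: TF-IDF bag of words + linear SVM -----------------------------

page_tokens <- function(page) {
  unlist(tokenize_line(page_text_lines(page)$text))
}

#' Build a TF-IDF model from training pages
#'
#' Natural term frequency, smoothed inverse document frequency
#' `log((1 + N) / (1 + df)) + 1`, L2-normalized vectors; the vocabulary
#' is the unique words of the training corpus.
#'
#' @param token_lists list of token vectors, one per page.
#' @return a `tfidf_model` with `vocab` and `idf`.
#' @export
build_tfidf <- function(token_lists) {
  vocab <- sort(unique(unlist(token_lists)))
  if (length(vocab) == 0) abort("build_tfidf: empty corpus")
  df <- numeric(length(vocab))
  for (tl in token_lists) {
    df <- df + as.numeric(vocab %in% tl)
  }
  idf <- log((1 + length(token_lists)) / (1 + df)) + 1
  structure(list(vocab = vocab, idf = idf), class = "tfidf_model")
}

tfidf_vector <- function(tokens, model) {
  v <- numeric(length(model$vocab))
  idx <- match(tokens, model$vocab)
  idx <- idx[!is.na(idx)]
  if (length(idx) > 0) {
    tf <- tabulate(idx, nbins = length(model$vocab))
    v <- tf * model$idf
    n <- sqrt(sum(v^2))
    if (n > 0) v <- v / n
  }
  v
}

#' Train the second-level page classifier
#'
#' A linear support vector machine over the page's TF-IDF bag-of-words
#' vector augmented with the level-1 in-table line count; errors on the
#' positive class are weighted `class_weight_pos` (5) times the negative
#' class.
#'
#' @param pages list of [page_record()].
#' @param counts level-1 in-table line counts, one per page.
#' @param labels 0/1 page labels.
#' @param class_weight_pos positive-class error weight.
#' @param seed RNG seed.
#' @param cost SVM regularization constant.
#' @return a `page_model` embedding the TF-IDF model and the SVM.
#' @export
train_page_classifier <- function(pages, counts, labels, class_weight_pos = 5,
                                  seed = 1L, cost = 1) {
  if (length(unique(labels)) < 2) abort("train_page_classifier: need both classes")
  toks <- lapply(pages, page_tokens)
  tfidf <- build_tfidf(toks)
  X <- t(vapply(seq_along(pages), function(i) {
    c(tfidf_vector(toks[[i]], tfidf), count = counts[i] / 10)
  }, numeric(length(tfidf$vocab) + 1)))
  y <- factor(labels, levels = c(0, 1))
  svm_fit <- withr::with_seed(seed, {
    e1071::svm(X, y, kernel = "linear", cost = cost, scale = FALSE,
               class.weights = c("0" = 1, "1" = class_weight_pos))
  })
  structure(list(tfidf = tfidf, svm = svm_fit,
                 class_weight_pos = class_weight_pos),
            class = "page_model")
}

#' @export
print.page_model <- function(x, ...) {
  cat(sprintf("<page_model: linear SVM, %d-word TF-IDF vocabulary, pos weight %g>\n",
              length(x$tfidf$vocab), x$class_weight_pos))
  invisible(x)
}

predict_page <- function(page_model, page, count) {
  v <- c(tfidf_vector(page_tokens(page), page_model$tfidf), count = count / 10)
  as.integer(as.character(predict(page_model$svm, t(v))))
}

#' Detect candidate resource-table pages of a document
#'
#' The two-level stacked generalizer: the line classifier predicts the
#' number of in-table lines on each page, which joins the TF-IDF page
#' vector as a feature of the page-level SVM.
#'
#' @param doc list of [page_record()].
#' @param line_model a `line_model`.
#' @param page_model a `page_model`.
#' @return sorted integer vector of positive page indices.
#' @export
detect_candidate_pages <- function(doc, line_model, page_model) {
  if (length(doc) == 0) return(integer(0))
  hits <- vapply(doc, function(p) {
    cnt <- predict_in_table_lines(line_model, p)
    predict_page(page_model, p, cnt) == 1L
  }, logical(1))
  sort(vapply(doc[hits], `[[`, integer(1), "page_index"))
}

#' Generate a labeled synthetic page corpus
#'
#' Documents mixing prose pages with rendered resource-table pages
#' (with rule lines), the training material for the stacked page
#' detector. Deterministic given `seed`.
#'
#' @param n_pages total pages.
#' @param table_fraction fraction of table pages.
#' @param seed base RNG seed.
#' @param layout a [layout_spec()].
#' @return list with `pages`, `labels` (page-level 0/1), `line_labels`
#'   (list of per-line 0/1 vectors).
#' @export
generate_page_corpus <- function(n_pages = 40, table_fraction = 0.3,
                                 seed = 1L, layout = layout_spec()) {
  n_tab <- max(1L, round(n_pages * table_fraction))
  is_tab <- withr::with_seed(seed, sample(rep(c(TRUE, FALSE),
                                              c(n_tab, n_pages - n_tab))))
  pages <- vector("list", n_pages)
  line_labels <- vector("list", n_pages)
  for (i in seq_len(n_pages)) {
    if (is_tab[i]) {
      tbl <- generate_resource_table(withr::with_seed(seed + i, sample(4:9, 1)),
                                     seed = seed + i)
      r <- render_table(tbl, layout, seed = seed + i, rules = TRUE)
      pg <- r$pages[[1]]
      pg$page_index <- i - 1L
      pages[[i]] <- pg
      line_labels[[i]] <- rep(1L, nrow(page_text_lines(pg)))
    } else {
      pg <- render_prose_page(withr::with_seed(seed + i, sample(10:20, 1)),
                              seed = seed + i, layout = layout,
                              page_index = i - 1L)
      pages[[i]] <- pg
      line_labels[[i]] <- rep(0L, nrow(page_text_lines(pg)))
    }
  }
  list(pages = pages, labels = as.integer(is_tab), line_labels = line_labels)
}

#' Train the full stacked page detector on a labeled corpus
#'
#' @param corpus result of [generate_page_corpus()] (or the same shape).
#' @param seed RNG seed.
#' @param class_weight_line,class_weight_page positive-class weights of
#'   the two levels.
#' @param embedding_dim dimension of the seeded static embeddings.
#' @param epochs line-classifier epochs.
#' @return list with `line_model` and `page_model`.
#' @export
train_page_detector <- function(corpus, seed = 1L, class_weight_line = 50,
                                class_weight_page = 5, embedding_dim = 50,
                                epochs = 3L) {
  feats <- list(); labs <- integer(0)
  for (i in seq_along(corpus$pages)) {
    pg <- corpus$pages[[i]]
    lines <- page_text_lines(pg)
    for (li in seq_len(nrow(lines))) {
      feats[[length(feats) + 1]] <- extract_line_features(pg, li, lines = lines)
      labs <- c(labs, corpus$line_labels[[i]][li])
    }
  }
  all_tokens <- unique(unlist(lapply(feats, `[[`, "tokens")))
  emb <- random_embeddings(all_tokens, dim = embedding_dim, seed = seed)
  line_model <- train_line_classifier(feats, labs, emb,
                                      class_weight_pos = class_weight_line,
                                      seed = seed, epochs = epochs)
  counts <- vapply(corpus$pages, function(p) predict_in_table_lines(line_model, p),
                   integer(1))
  page_model <- train_page_classifier(corpus$pages, counts, corpus$labels,
                                      class_weight_pos = class_weight_page,
                                      seed = seed)
  list(line_model = line_model, page_model = page_model)
}
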