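toy_line_features <- function(texts) {
  lapply(texts, function(s) list(tokens = tokenize_line(s)[[1]],
                                 indicators = c(0, 0, 0, 0)))
}

test_that("tokenization lowercases, splits punctuation and maps numbers", {
  expect_equal(tokenize_line("RRID:AB_123456")[[1]],
               c("rrid", ":", "ab", "_", "<num>"))
  expect_equal(tokenize_line("Mouse anti-GFP")[[1]],
               c("mouse", "anti", "-", "gfp"))
  expect_equal(tokenize_line("")[[1]], character(0))
})

test_that("line features carry context tokens and graphics indicators", {
  f <- noiseless_fixture(seed = 71, n_rows = 4)
  tbl <- generate_resource_table(4, seed = 71)
  r <- render_table(tbl, layout_spec(char_width = 5), rules = TRUE)
  pg <- r$pages[[1]]
  lf <- extract_line_features(pg, 2)
  expect_equal(lf$indicators[1], 1)  # horizontal rules cross table lines
  lf1 <- extract_line_features(pg, 1)
  expect_true("<null>" %in% lf1$tokens)  # padded at the page start
  expect_error(extract_line_features(pg, 99), "out of range")
  # no graphics at all: indicators all zero
  plain <- render_table(tbl, layout_spec(char_width = 5))$pages[[1]]
  expect_equal(extract_line_features(plain, 2)$indicators, c(0, 0, 0, 0))
})

test_that("the recurrent line classifier separates a toy set", {
  set.seed(1)
  pos <- replicate(30, paste("antibody RRID:AB_", sample(1e5, 1)))
  neg <- replicate(30, prose_line(6))
  feats <- toy_line_features(c(pos, neg))
  labs <- rep(c(1L, 0L), each = 30)
  emb <- random_embeddings(unique(unlist(lapply(feats, `[[`, "tokens"))),
                           seed = 1)
  tr <- c(1:20, 31:50)
  model <- train_line_classifier(feats[tr], labs[tr], emb,
                                 class_weight_pos = 1, seed = 1,
                                 epochs = 8)
  pr <- vapply(feats[-tr], function(f) {
    keytables:::rnn_line_prob(model$params,
                              keytables:::embed_tokens(f$tokens, emb),
                              f$indicators)
  }, numeric(1))
  acc <- mean((pr > 0.5) == (labs[-tr] == 1))
  expect_gte(acc, 0.95)

  # independent separability oracle: the "rrid" token alone solves the
  # task, so any sequence model worth its salt must too
  rule <- vapply(feats[-tr], function(f) "rrid" %in% f$tokens, logical(1))
  expect_gte(mean(rule == (labs[-tr] == 1)), 0.95)

  expect_error(train_line_classifier(list(), integer(0), emb), "empty")
  expect_error(train_line_classifier(feats[1:3], c(1, 1, 1), emb),
               "both classes")
})

test_that("in-table line counts respond to page content", {
  corpus <- generate_page_corpus(n_pages = 14, table_fraction = 0.4, seed = 72)
  models <- train_page_detector(corpus, seed = 72, epochs = 2)
  tab_idx <- which(corpus$labels == 1)[1]
  prose_idx <- which(corpus$labels == 0)[1]
  n_lines <- length(corpus$line_labels[[tab_idx]])
  expect_equal(predict_in_table_lines(models$line_model,
                                      corpus$pages[[tab_idx]]), n_lines)
  expect_lte(predict_in_table_lines(models$line_model,
                                    corpus$pages[[prose_idx]]), 1)
  empty <- page_record(0L)
  expect_equal(predict_in_table_lines(models$line_model, empty), 0)

  # stacked prediction: candidate pages of a mixed document
  doc <- corpus$pages[c(prose_idx, tab_idx)]
  doc[[1]]$page_index <- 0L; doc[[2]]$page_index <- 3L
  hits <- detect_candidate_pages(doc, models$line_model, models$page_model)
  expect_identical(hits, 3L)
  expect_identical(detect_candidate_pages(list(), models$line_model,
                                          models$page_model), integer(0))
})

test_that("the page-level SVM fits a separable corpus perfectly", {
  corpus <- generate_page_corpus(n_pages = 12, table_fraction = 0.5, seed = 73)
  counts <- vapply(corpus$pages, function(p) {
    length(keytables:::page_text_lines(p)$text)
  }, integer(1)) * corpus$labels  # stand-in level-1 counts
  pm <- train_page_classifier(corpus$pages, counts, corpus$labels, seed = 73)
  pred <- vapply(seq_along(corpus$pages), function(i) {
    keytables:::predict_page(pm, corpus$pages[[i]], counts[i])
  }, integer(1))
  expect_equal(pred, corpus$labels)
  expect_error(train_page_classifier(corpus$pages, counts,
                                     rep(1, length(counts))), "both classes")
})

test_that("permuted labels give chance-level cross-validated accuracy", {
  corpus <- generate_page_corpus(n_pages = 16, table_fraction = 0.5, seed = 74)
  perm <- withr::with_seed(74, sample(corpus$labels))
  folds <- rep(1:4, length.out = 16)
  accs <- vapply(1:4, function(k) {
    tr <- which(folds != k); te <- which(folds == k)
    if (length(unique(perm[tr])) < 2) return(NA_real_)
    pm <- train_page_classifier(corpus$pages[tr], rep(0, length(tr)),
                                perm[tr], seed = 74)
    mean(vapply(te, function(i) {
      keytables:::predict_page(pm, corpus$pages[[i]], 0)
    }, integer(1)) == perm[te])
  }, numeric(1))
  expect_gt(mean(accs, na.rm = TRUE), 0.15)
  expect_lt(mean(accs, na.rm = TRUE), 0.85)
})

test_that("a count feature that was constant in training cannot flip pages", {
  corpus <- generate_page_corpus(n_pages = 12, table_fraction = 0.5, seed = 75)
  pm <- train_page_classifier(corpus$pages, rep(0, 12), corpus$labels,
                              seed = 75)
  for (i in c(1, 5, 9)) {
    p0 <- keytables:::predict_page(pm, corpus$pages[[i]], 0)
    p5 <- keytables:::predict_page(pm, corpus$pages[[i]], 5)
    expect_equal(p0, p5)
  }
})
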