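test_that("vocabulary is the code-point-sorted character set plus <EOS>", {
  v <- build_vocab(c("ab", "ba"))
  expect_equal(v$size, 3L)
  expect_equal(v$chars, c("a", "b"))
  expect_equal(v$eos_id, 3L)
  v2 <- build_vocab(c("µ", "α"))
  expect_true(all(c("µ", "α") %in% v2$chars))
  expect_identical(build_vocab(c("ab", "ba")), build_vocab(c("ab", "ba")))
  expect_error(build_vocab(character(0)), "empty")
})

test_that("encode_pair keeps the <EOS> boundary under truncation", {
  v <- build_vocab(c(paste0(letters, collapse = ""), "xyz"))
  ids <- encode_pair("ab", "cd", v, 64)
  expect_equal(ids, c(match(c("a", "b"), v$chars), v$eos_id,
                      match(c("c", "d"), v$chars)))
  # long upper: keep the last floor((L-1)/2) chars, then lower fills up
  long_u <- strrep("a", 300)
  long_l <- strrep("b", 300)
  ids2 <- encode_pair(long_u, long_l, v, 256)
  expect_length(ids2, 256)
  eos_at <- which(ids2 == v$eos_id)
  expect_equal(eos_at, floor((256 - 1) / 2) + 1)
  # empty upper is allowed
  expect_equal(encode_pair("", "x", v, 64), c(v$eos_id, match("x", v$chars)))
  expect_error(encode_pair("a", "b", v, 2), "context_len")
})

test_that("unknown characters are dropped at encoding time", {
  v <- build_vocab("abc")
  expect_equal(keytables:::encode_text("aZb", v), match(c("a", "b"), v$chars))
})

test_that("initial loss matches the uniform-prediction entropy", {
  corpus <- vapply(1:8, function(i) paste0(sample(letters[1:12], 30, TRUE),
                                           collapse = ""), "")
  lm <- pretrain_lm(corpus, lm_config(preset = "tiny"), seed = 1, steps = 1)
  expect_lt(abs(lm$loss_trace[1] - log(lm$vocab$size)),
            0.1 * log(lm$vocab$size))
})

test_that("causal masking: future characters cannot change past logits", {
  corpus <- c("abcabcabc", "bcabca")
  lm <- pretrain_lm(corpus, lm_config(preset = "tiny"), seed = 2, steps = 2)
  v <- lm$vocab
  ids <- keytables:::encode_text("abcabc", v)
  lg1 <- lm_logits(lm, ids)
  ids2 <- ids
  ids2[5:6] <- rev(ids2[5:6])  # permute characters after position 4
  lg2 <- lm_logits(lm, ids2)
  expect_identical(lg1[1:4, ], lg2[1:4, ])
})

test_that("a tiny model learns a short corpus quickly", {
  corpus <- c("RRID:AB_123456", "RRID:SCR_00421", "Rabbit anti-GFP")
  lm <- pretrain_lm(corpus, lm_config(preset = "tiny"), seed = 3,
                    steps = 60, lr = 3e-3)
  expect_lt(tail(lm$loss_trace, 1), 1.2)
  # loss trend is downward: late average well below early average
  expect_lt(mean(tail(lm$loss_trace, 10)), mean(head(lm$loss_trace, 10)) / 2)
})

test_that("an untrained classifier head sits at chance", {
  inst <- generate_merge_instances(120, seed = 8)
  corpus <- c(inst$upper, inst$lower)
  lm <- pretrain_lm(corpus, lm_config(preset = "tiny"), seed = 8, steps = 2)
  clf0 <- finetune_merger(lm, inst, epochs = 0, seed = 8)
  pr <- score_pairs(clf0, inst$upper[1:20], inst$lower[1:20])
  expect_true(all(pr == 0.5))  # zero head is exactly 0.5 before training
  expect_equal(score_pair(clf0, "a", "b"), score_pair(clf0, "a", "b"))
})

test_that("finetuning requires both classes", {
  inst <- generate_merge_instances(60, seed = 9)
  pos_only <- inst[inst$label == 1, ]
  lm <- pretrain_lm(c(inst$upper, inst$lower), lm_config(preset = "tiny"),
                    seed = 9, steps = 2)
  expect_error(finetune_merger(lm, pos_only, epochs = 1), "both classes")
})

test_that("max voting averages scored pairs with a strict threshold", {
  probs <- c(A = 0.9, B = 0.8, C = 0.7, D = 0.1, E = 0.2, F = 0.3)
  scorer <- function(upper, lower) unname(probs[upper])
  g1 <- matrix(c("A", "B", "C", "x", "y", "z"), 2, 3, byrow = TRUE)
  m1 <- merge_rows(g1, scorer)
  expect_equal(nrow(m1$cells), 1)  # mean 0.8 > 0.5: merged
  expect_equal(m1$cells[1, 1], "A x")

  g2 <- matrix(c("D", "E", "F", "x", "y", "z"), 2, 3, byrow = TRUE)
  expect_equal(nrow(merge_rows(g2, scorer)$cells), 2)  # mean 0.2: kept

  half <- function(upper, lower) rep(0.5, length(upper))
  expect_equal(nrow(merge_rows(g1, half)$cells), 2)  # exactly 0.5: no merge

  # empty-cell pairs are excluded from the vote; all-empty means no merge
  g3 <- matrix(c("A", "", "", "x", "", ""), 2, 3, byrow = TRUE)
  expect_equal(nrow(merge_rows(g3, scorer)$cells), 1)   # single 0.9 vote
  g4 <- matrix(c("A", "B", "", "", "", "z"), 2, 3, byrow = TRUE)
  expect_equal(nrow(merge_rows(g4, scorer)$cells), 2)   # no scorable pair
})

test_that("merging conserves per-column content up to joining spaces", {
  f <- overflow_fixture(seed = 51, n_rows = 6, long_cells = 1)
  t <- f$sim$oversegmented
  merged <- merge_rows(t, oracle_scorer(f$sim))
  for (j in 1:3) {
    expect_equal(gsub(" ", "", paste(merged$cells[, j], collapse = "")),
                 gsub(" ", "", paste(t$cells[, j], collapse = "")))
  }
})

test_that("the oracle merger recovers the gold row grouping exactly", {
  for (s in c(61, 62, 63)) {
    f <- overflow_fixture(seed = s, n_rows = 7, long_cells = 1 + s %% 2)
    merged <- merge_rows(f$sim$oversegmented, oracle_scorer(f$sim))
    expect_true(tables_equal(logical_table(merged$cells),
                             logical_table(f$gold$cells)))
    expect_equal(grits(f$gold, merged, "content")$grits, 1)
    expect_equal(attr(merged, "row_groups"), f$sim$gold_row_groups)
  }
})

test_that("model summaries expose architecture and training state", {
  corpus <- c("abc", "bcd")
  lm <- pretrain_lm(corpus, lm_config(preset = "tiny"), seed = 10, steps = 3)
  g <- glance(lm)
  expect_equal(g$n_layers, 2L)
  expect_equal(g$d_model, 64L)
  expect_equal(nrow(tidy(lm)), 3)
  expect_s3_class(autoplot(lm), "ggplot")
  # full-scale preset keeps the published architecture sizes
  cfg <- lm_config(preset = "paper")
  expect_equal(c(cfg$n_layers, cfg$n_heads, cfg$d_model, cfg$context_len),
               c(6L, 6L, 384L, 256L))
  expect_error(lm_config(n_heads = 5, d_model = 64), "divisible")
})
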