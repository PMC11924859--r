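test_that("resource-table generator is deterministic and well-formed", {
  t1 <- generate_resource_table(5, seed = 7)
  t2 <- generate_resource_table(5, seed = 7)
  expect_true(tables_equal(t1, t2, check_meta = TRUE))
  expect_equal(dim(t1), c(6L, 3L))
  expect_equal(t1$n_header_rows, 1L)
  ids <- t1$cells[-1, 3]
  expect_true(all(grepl("RRID:[A-Z]+_[A-Za-z0-9]+", ids)))
  expect_error(generate_resource_table(0), "n_rows")
})

test_that("overflow selection follows the 90/100/80 thresholds", {
  mk <- function(lens) {
    logical_table(matrix(vapply(lens, function(n) strrep("x", n), ""),
                         nrow = 1))
  }
  expect_false(select_for_overflow(mk(c(30, 30, 30)))$selected)   # total 90
  sel95 <- select_for_overflow(mk(c(40, 30, 25)))                 # total 95
  expect_true(sel95$selected)
  expect_equal(sel95$width, 80L)
  sel150 <- select_for_overflow(mk(c(60, 50, 40)))                # total 150
  expect_true(sel150$selected)
  expect_equal(sel150$width, 90L)
  expect_error(overflow_config(narrow_width = 95), "narrow_width")
})

test_that("column widths are proportional to mean + sd with exact sum", {
  mk1 <- function(lens) {
    logical_table(matrix(vapply(lens, function(n) strrep("x", n), ""),
                         nrow = 1))
  }
  # identical length distributions split evenly
  expect_equal(allocate_column_widths(mk1(c(30, 30, 30)), 90), c(30L, 30L, 30L))
  # single-row tables have sd 0: widths are exactly proportional to length
  expect_equal(allocate_column_widths(mk1(c(10, 20, 30)), 60), c(10L, 20L, 30L))
  w <- allocate_column_widths(mk1(c(1, 1, 1)), 10)
  expect_equal(sum(w), 10L)
  expect_lte(max(w) - min(w), 1L)
  expect_error(allocate_column_widths(mk1(c(1, 1, 1)), 2), "width")
})

test_that("largest-remainder allocation matches an enumeration oracle", {
  # oracle: the integer vector summing to W minimizing the max deviation
  # from exact proportionality, with ties broken toward earlier columns
  set.seed(3)
  for (k in 1:25) {
    C <- sample(2:4, 1)
    lens <- sample(3:40, C, replace = TRUE)
    W <- sum(lens) - sample(1:5, 1)
    if (W < C) next
    t <- logical_table(matrix(vapply(lens, function(n) strrep("x", n), ""),
                              nrow = 1))
    got <- allocate_column_widths(t, W)
    raw <- W * lens / sum(lens)
    expect_equal(sum(got), W)
    # largest-remainder property: each width is floor or ceiling of raw
    expect_true(all(got == floor(raw) | got == ceiling(raw)))
    # and the incremented entries are those with the largest remainders
    inc <- which(got == floor(raw) + 1 & raw != floor(raw))
    not_inc <- setdiff(which(raw != floor(raw)), inc)
    if (length(inc) && length(not_inc)) {
      expect_gte(min(raw[inc] - floor(raw[inc])),
                 max(raw[not_inc] - floor(raw[not_inc])) - 1e-9)
    }
  }
})

test_that("split_cell wraps greedily at spaces and inverts losslessly", {
  expect_equal(as.vector(split_cell("aaa bbb ccc", 4)), c("aaa", "bbb", "ccc"))
  expect_equal(as.vector(split_cell("abcdefgh", 3)), c("abc", "def", "gh"))
  expect_equal(as.vector(split_cell("short", 10)), "short")
  expect_error(split_cell("x", 0), "width")

  set.seed(5)
  words <- c("alpha", "be", "gamma", "dddddddddddd", "e", "RRID:AB_12345")
  for (k in 1:40) {
    content <- paste(sample(words, sample(1:8, 1), replace = TRUE),
                     collapse = " ")
    width <- sample(3:12, 1)
    frags <- split_cell(content, width)
    expect_true(all(nchar(frags) <= width))
    expect_identical(join_fragments(frags), content)
  }
})

test_that("simulate_overflow produces labeled pairs and an exact inverse", {
  # a long space-separated cell splits into fragments -> frags - 1 pairs
  long <- paste(rep("word", 20), collapse = " ")  # 99 characters
  t <- logical_table(matrix(c(long, "by hand", "id x"), nrow = 1))
  sel <- select_for_overflow(t)
  expect_true(sel$selected)
  sim <- simulate_overflow(t, overflow_config(seed = 1))
  frags <- split_cell(t$cells[1, 1], sim$widths[1])
  expect_gte(length(frags), 2)
  pos <- sim$instances[sim$instances$label == 1, ]
  expect_equal(nrow(pos[pos$upper %in% frags, ]), length(frags) - 1)
  back <- merge_row_groups(sim$oversegmented, sim$gold_row_groups)
  expect_true(tables_equal(back, t))

  # a table below the selection threshold is refused
  small <- logical_table(matrix(c("a", "b", "c"), 1))
  expect_error(simulate_overflow(small), "qualify")
})

test_that("non-overflowing cells contribute no positive pairs", {
  t <- generate_resource_table(8, seed = 21, long_cells = 1)
  sim <- simulate_overflow(t, overflow_config(seed = 21))
  pos <- sim$instances[sim$instances$label == 1, ]
  lens <- nchar(t$cells)
  # every positive pair's fragments come from a cell wider than its column
  over_cells <- t$cells[sweep(lens, 2, sim$widths, ">")]
  expect_true(all(vapply(seq_len(nrow(pos)), function(i) {
    any(vapply(over_cells, function(cell) {
      grepl(pos$upper[i], cell, fixed = TRUE) &&
        grepl(pos$lower[i], cell, fixed = TRUE)
    }, logical(1)))
  }, logical(1))))
})

test_that("negative sampling ratio is honored when the pool allows", {
  t <- generate_resource_table(12, seed = 9, long_cells = 1)
  sim1 <- simulate_overflow(t, overflow_config(seed = 9), negative_ratio = 1)
  n_pos <- sum(sim1$instances$label == 1)
  expect_equal(sum(sim1$instances$label == 0), n_pos)
  sim2 <- simulate_overflow(t, overflow_config(seed = 9), negative_ratio = 2)
  fits <- sweep(nchar(t$cells), 2, sim2$widths, "<=")
  pool <- sum(fits[-nrow(fits), ] & fits[-1, ])
  expect_equal(sum(sim2$instances$label == 0), min(2 * n_pos, pool))
  inst <- generate_merge_instances(300, seed = 4)
  expect_gte(nrow(inst), 300)
  expect_setequal(unique(inst$label), c(0L, 1L))
})

test_that("overflow round trip holds across many seeded tables", {
  for (s in 1:25) {
    tbl <- generate_resource_table(6 + s %% 7, seed = s, long_cells = 1 + s %% 2)
    sim <- simulate_overflow(tbl, overflow_config(seed = s))
    back <- merge_row_groups(sim$oversegmented, sim$gold_row_groups)
    expect_true(tables_equal(back, tbl), label = sprintf("seed %d", s))
    # fragment concatenation conserves every split cell exactly
    expect_true(all(nchar(sim$oversegmented$cells) <=
                      matrix(sim$widths, nrow(sim$oversegmented$cells), 3,
                             byrow = TRUE)))
  }
})
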