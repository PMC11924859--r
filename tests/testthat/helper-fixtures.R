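# Shared test helpers: small tables and an independent LCS oracle.

tiny_table <- function(cells, ...) {
  logical_table(matrix(cells[[1]], nrow = length(cells), byrow = TRUE,
                       dimnames = NULL), ...)
}

# build a logical_table from a character vector of rows given C
tbl_from_rows <- function(rows, C) {
  logical_table(matrix(unlist(rows), nrow = length(rows), ncol = C,
                       byrow = TRUE))
}

# Independent LCS oracle: plain O(nm) dynamic program in R, kept separate
# from the compiled implementation it checks.
lcs_oracle <- function(a, b) {
  x <- utf8ToInt(a); y <- utf8ToInt(b)
  n <- length(x); m <- length(y)
  if (n == 0 || m == 0) return(0L)
  M <- matrix(0L, n + 1, m + 1)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    M[i + 1, j + 1] <- if (x[i] == y[j]) M[i, j] + 1L else max(M[i, j + 1], M[i + 1, j])
  }
  M[n + 1, m + 1]
}

random_cells_table <- function(rmax = 4, cmax = 4, minlen = 0,
                               syms = c("a", "b", "c")) {
  R <- sample(seq_len(rmax), 1)
  C <- sample(seq_len(cmax), 1)
  cells <- matrix(replicate(R * C, paste0(sample(syms, sample(minlen:3, 1),
                                                 replace = TRUE),
                                          collapse = "")), R, C)
  logical_table(cells)
}

special_string_pool <- c("Pry[+t7.2]=hsFLP12", "anti-α-tubulin",
                         "5 µg/mL", "a,b\nc", "\"quoted\"",
                         "RRID:AB_2313773", "GCACTTCATCCTTTGGTTTTG", "")

random_special_table <- function() {
  R <- sample(1:4, 1); C <- sample(1:3, 1)
  logical_table(matrix(sample(special_string_pool, R * C, replace = TRUE),
                       R, C))
}
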