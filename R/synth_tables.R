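# Vocabulary pools for the synthetic key-resource table generator. Content
# mimics STAR*Methods tables: resource name / source / identifier with
# RRID-like strings, catalog numbers, organism nomenclature and superscript
# footnote markers. Words are kept short relative to allocated column
# widths so simulated overflow always splits at spaces.

kr_targets <- c("GFP", "beta-actin", "TH", "NeuN", "GFAP", "Iba1", "MAP2",
                "Synapsin-1", "PSD-95", "ChAT", "c-Fos", "Ki67", "DCX",
                "parvalbumin", "calbindin", "vimentin", "nestin", "Olig2")
kr_vendors <- c("Abcam", "Sigma Aldrich Inc", "Thermo Fisher Inc",
                "Jackson Immuno Labs", "Merck", "Santa Cruz Biotech",
                "Cell Signal Tech", "Addgene", "Charles River Labs",
                "Qiagen", "Roche", "This paper", "Promega",
                "Bio-Rad Labs", "Vector Labs", "Takara")
kr_organisms <- c("Mouse: C57BL/6J", "Rat: Sprague-Dawley", "Zebrafish: AB",
                  "Mouse: BALB/c", "Drosophila: w[1118]", "Mouse: CD-1",
                  "E. coli: DH5alpha", "Yeast: BY4741")
kr_chemicals <- c("DAPI", "Triton X-100", "Paraformaldehyde", "DMSO",
                  "Tamoxifen", "Doxycycline", "Poly-L-lysine", "Matrigel",
                  "TRIzol reagent", "Hoechst 33342")
kr_software <- c("ImageJ", "GraphPad Prism", "CellProfiler", "FlowJo",
                 "MATLAB", "Fiji", "R Project", "Bowtie2", "STAR aligner")
kr_desc_words <- c("rabbit", "mouse", "goat", "polyclonal", "monoclonal",
                   "antibody", "raised", "against", "synthetic", "peptide",
                   "conjugated", "purified", "recombinant", "protein",
                   "full", "length", "human", "murine", "epitope", "mapping",
                   "within", "the", "terminal", "region", "of", "validated",
                   "for", "western", "blot", "and", "staining", "dilution",
                   "used", "at", "titer", "lot", "tested", "in", "tissue",
                   "sections", "fixed", "with", "buffer", "stock", "solution",
                   "stored", "frozen", "aliquots", "clone", "isotype",
                   "control", "serum", "affinity", "column", "culture")

rrid_identifier <- function(n = 1) {
  kind <- sample(c("AB", "SCR", "CVCL"), n, replace = TRUE,
                 prob = c(0.6, 0.25, 0.15))
  num <- vapply(seq_len(n), function(i) {
    if (kind[i] == "CVCL") {
      paste0(sample(c(LETTERS, 0:9), 4, replace = TRUE), collapse = "")
    } else if (kind[i] == "SCR") {
      paste0(sample(0:9, 5, replace = TRUE), collapse = "")
    } else {
      paste0(sample(0:9, 6, replace = TRUE), collapse = "")
    }
  }, character(1))
  paste0("RRID:", kind, "_", num)
}

catalog_number <- function(n = 1) {
  vapply(seq_len(n), function(i) {
    paste0("Cat#", sample(c("A", "ab", "MAB", "sc-", ""), 1),
           paste0(sample(0:9, sample(4:6, 1), replace = TRUE), collapse = ""))
  }, character(1))
}

long_description <- function(target_len) {
  words <- character(0)
  len <- 0L
  while (len < target_len) {
    w <- sample(kr_desc_words, 1)
    words <- c(words, w)
    len <- len + nchar(w) + 1L
  }
  paste(words, collapse = " ")
}

#' Generate a synthetic key-resource table
#'
#' Produces a 3-column table (resource / source / identifier) with one
#' header row, in the style of STAR*Methods key resources tables:
#' antibodies, organisms, chemicals and software with RRID-like
#' identifiers and catalog numbers. `long_cells` body rows receive a long
#' lowercase description in the resource column (about 100-135
#' characters) so that the table qualifies for simulated cell overflow;
#' `superscripts` body rows get a trailing single-character footnote
#' marker which the renderer raises above the baseline.
#'
#' @param n_rows number of body rows (>= 1).
#' @param seed RNG seed; the same seed always yields the same table.
#' @param long_cells how many rows get an overflow-forcing long cell.
#' @param superscripts how many rows get a raised footnote marker.
#' @return a [logical_table()] with `n_header_rows = 1`; rows carrying a
#'   superscript marker are recorded in `attr(, "superscripts")`.
#' @export
generate_resource_table <- function(n_rows, seed = 1L, long_cells = 0L,
                                    superscripts = 0L) {
  if (n_rows < 1) abort("generate_resource_table: `n_rows` must be >= 1")
  if (long_cells > n_rows || superscripts > n_rows) {
    abort("generate_resource_table: more marked rows than rows")
  }
  withr::with_seed(seed, {
    kinds <- sample(c("antibody", "organism", "chemical", "software"),
                    n_rows, replace = TRUE, prob = c(0.45, 0.2, 0.2, 0.15))
    name <- vapply(kinds, function(k) {
      switch(k,
        antibody = paste0(sample(c("Rabbit", "Mouse", "Goat", "Chicken"), 1),
                          " anti-", sample(kr_targets, 1)),
        organism = sample(kr_organisms, 1),
        chemical = sample(kr_chemicals, 1),
        software = sample(kr_software, 1))
    }, character(1))
    source <- sample(kr_vendors, n_rows, replace = TRUE)
    id <- vapply(kinds, function(k) {
      if (k == "software") {
        if (runif(1) < 0.5) {
          paste0("v", sample(1:9, 1), ".", sample(0:9, 1), " ", rrid_identifier(1))
        } else rrid_identifier(1)
      } else if (runif(1) < 0.6) {
        paste(catalog_number(1), rrid_identifier(1))
      } else rrid_identifier(1)
    }, character(1))
    # every real key-resource table carries at least one multi-word source
    # ("This paper", vendor + Labs/Inc) and one catalog+RRID identifier;
    # they also give the width-allocation scheme its variance signal
    multi <- kr_vendors[grepl(" ", kr_vendors)]
    need <- min(n_rows, 2L) - sum(grepl(" ", source))
    if (need > 0) {
      source[sample.int(n_rows, need)] <- sample(multi, need)
    }
    need_id <- min(n_rows, 2L) - sum(grepl(" ", id))
    if (need_id > 0) {
      ri <- sample.int(n_rows, need_id)
      id[ri] <- paste(catalog_number(need_id), rrid_identifier(need_id))
    }
    if (long_cells > 0) {
      li <- sample.int(n_rows, long_cells)
      base <- tolower(name[li])
      # draw description lengths such that the width allocation leaves
      # every column at least its longest single word: simulated
      # wrapping then always splits at spaces (the lossless case)
      lo <- 100L; hi <- 135L
      for (attempt in 1:8) {
        name[li] <- vapply(base, function(nm) {
          paste(nm, long_description(sample(seq(lo, hi), 1)))
        }, character(1))
        cand <- rbind(c("REAGENT or RESOURCE", "SOURCE", "IDENTIFIER"),
                      cbind(name, source, id))
        tbl <- logical_table(unname(cand), n_header_rows = 1L)
        sel <- select_for_overflow(tbl)
        if (!sel$selected) break
        widths <- allocate_column_widths(tbl, sel$width)
        longest_word <- apply(cand, 2, function(col) {
          max(nchar(unlist(strsplit(col, " ", fixed = TRUE))))
        })
        if (all(longest_word <= widths)) break
        lo <- max(80L, lo - 7L); hi <- max(95L, hi - 10L)
      }
    }
    sup <- NULL
    if (superscripts > 0) {
      pool <- setdiff(seq_len(n_rows), if (long_cells > 0) li else integer(0))
      if (length(pool) == 0) pool <- seq_len(n_rows)
      si <- sample(pool, min(superscripts, length(pool)))
      name[si] <- paste(name[si], sample(letters[1:4], length(si), replace = TRUE))
      sup <- tibble(row = si + 1L, col = 1L)  # +1 for header row
    }
    cells <- rbind(c("REAGENT or RESOURCE", "SOURCE", "IDENTIFIER"),
                   cbind(name, source, id))
    dimnames(cells) <- NULL
    tbl <- logical_table(cells, n_header_rows = 1L)
    attr(tbl, "superscripts") <- sup
    tbl
  })
}

prose_words <- c("we", "performed", "immunostaining", "on", "coronal",
                 "sections", "after", "perfusion", "fixation", "the",
                 "animals", "were", "housed", "under", "standard",
                 "conditions", "with", "food", "and", "water", "available",
                 "all", "procedures", "approved", "by", "institutional",
                 "committee", "images", "acquired", "using", "confocal",
                 "microscope", "data", "analyzed", "statistical",
                 "significance", "assessed", "test", "results", "expressed",
                 "as", "mean", "error", "of", "independent", "experiments",
                 "cells", "cultured", "in", "medium", "supplemented",
                 "serum", "at", "degrees", "protein", "expression",
                 "quantified", "relative", "to", "control", "samples")

#' Generate a line of methods-section prose
#'
#' Negative material for the page classifier corpus.
#'
#' @param n_words words per line.
#' @return a single string.
#' @export
prose_line <- function(n_words = 9) {
  paste(sample(prose_words, n_words, replace = TRUE), collapse = " ")
}
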