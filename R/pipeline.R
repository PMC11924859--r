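#' Run configuration for the end-to-end extraction pipelines
#'
#' @param mode `"col"`, `"row"`, `"ocr"` or `"lm"`.
#' @param charboxes path to a charboxes JSONL file.
#' @param detections path to a detections JSON file.
#' @param classifier a `merge_classifier` (or its file path is resolved
#'   by the CLI); required for mode `"lm"`.
#' @param images cell-crop list (mode `"ocr"`).
#' @param line_model,page_model optional page-detection models; without
#'   them every page is a candidate.
#' @param pad,vote_threshold,rule1_overlap,rule2_overlap thresholds.
#' @param seed RNG seed recorded in the manifest.
#' @return a `run_config` list.
#' @export
run_config <- function(mode = c("col", "row", "ocr", "lm"),
                       charboxes = NULL, detections = NULL,
                       classifier = NULL, images = NULL,
                       line_model = NULL, page_model = NULL,
                       pad = 1, vote_threshold = 0.5,
                       rule1_overlap = 0.7, rule2_overlap = 0.5,
                       seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "lm" && is.null(classifier)) {
    abort("run_config: mode \"lm\" requires `classifier`")
  }
  if (mode == "ocr" && is.null(images)) {
    abort("run_config: mode \"ocr\" requires `images`")
  }
  structure(list(mode = mode, charboxes = charboxes, detections = detections,
                 classifier = classifier, images = images,
                 line_model = line_model, page_model = page_model,
                 pad = pad, vote_threshold = vote_threshold,
                 rule1_overlap = rule1_overlap, rule2_overlap = rule2_overlap,
                 seed = as.integer(seed)),
            class = "run_config")
}

# In-memory single-table extraction shared by run_pipeline and
# compare_modes; `fixture` carries pages/detections (and crops).
extract_fixture <- function(fixture, mode, config = run_config(mode = "col")) {
  switch(mode,
    col = reconstruct_table(fixture$detections, fixture$pages, mode = "col",
                            pad = config$pad),
    row = reconstruct_table(fixture$detections, fixture$pages, mode = "row",
                            pad = config$pad),
    ocr = reconstruct_table_ocr(fixture$detections, fixture$crops,
                                engine = fixture$engine %||% fake_ocr_engine()),
    lm = {
      raw <- reconstruct_table(fixture$detections, fixture$pages, mode = "col",
                               pad = config$pad)
      merge_rows(raw, config$classifier, threshold = config$vote_threshold)
    },
    abort(sprintf("unknown mode '%s'", mode)))
}

#' Run an extraction pipeline from input files
#'
#' Reads the character boxes and detections, optionally gates pages
#' through the stacked page detector, reconstructs every detected table
#' in the requested mode, and returns the tables with a reproducible run
#' manifest (package version, mode, thresholds, seed and input hashes).
#'
#' @param config a [run_config()].
#' @return list with `tables` (list of [logical_table()]) and `manifest`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) abort("run_pipeline: need a run_config")
  if (is.null(config$charboxes) && config$mode != "ocr") {
    abort("run_pipeline: `charboxes` path missing")
  }
  if (is.null(config$detections)) abort("run_pipeline: `detections` path missing")
  detections <- read_detections(config$detections)
  pages <- if (!is.null(config$charboxes)) read_charboxes(config$charboxes) else list()
  candidates <- if (!is.null(config$line_model) && !is.null(config$page_model)) {
    detect_candidate_pages(pages, config$line_model, config$page_model)
  } else {
    vapply(pages, `[[`, integer(1), "page_index")
  }
  table_pages <- intersect(unique(detections$page[detections$label == "table"]),
                           candidates)
  tables <- list()
  if (config$mode == "ocr") {
    tables[[1]] <- reconstruct_table_ocr(detections, config$images)
  } else if (length(table_pages) > 0) {
    keep <- vapply(pages, function(p) p$page_index %in% table_pages, logical(1))
    fixture <- list(pages = pages[keep],
                    detections = detections[detections$page %in% table_pages, ])
    tables[[1]] <- extract_fixture(fixture, config$mode, config)
  }
  manifest <- list(
    package = "keytables",
    version = as.character(utils::packageVersion("keytables")),
    mode = config$mode, seed = config$seed,
    thresholds = list(pad = config$pad, vote = config$vote_threshold,
                      rule1 = config$rule1_overlap, rule2 = config$rule2_overlap),
    candidate_pages = candidates,
    input_hash = list(
      charboxes = if (!is.null(config$charboxes)) rlang::hash_file(config$charboxes),
      detections = rlang::hash_file(config$detections)),
    output_hash = rlang::hash(lapply(tables, `[[`, "cells")))
  list(tables = tables, manifest = manifest)
}

#' Compare extraction pipelines on a fixture set
#'
#' Runs each mode on every fixture and summarizes the GriTS content and
#' topology scores (mean score, precision and recall per mode).
#'
#' @param fixtures list of fixtures: each needs `pages`, `detections`,
#'   `gold`, and for mode `"ocr"` also `crops` (and optionally
#'   `engine`).
#' @param modes subset of `c("col", "row", "ocr", "lm")`.
#' @param config a [run_config()] providing thresholds/classifier.
#' @return tibble: one row per mode x similarity with mean `grits`,
#'   `precision`, `recall`; per-fixture scores in `attr(, "per_fixture")`.
#' @export
compare_modes <- function(fixtures, modes = c("col", "row"),
                          config = run_config(mode = "col")) {
  if (length(fixtures) == 0) abort("compare_modes: empty fixture set")
  rows <- list()
  for (fi in seq_along(fixtures)) {
    for (m in modes) {
      pred <- extract_fixture(fixtures[[fi]], m, config)
      rep <- grits_report(fixtures[[fi]]$gold, pred)
      rep$mode <- m
      rep$fixture <- fi
      rows[[length(rows) + 1]] <- rep
    }
  }
  per <- dplyr::bind_rows(rows)
  out <- dplyr::summarise(
    dplyr::group_by(per, .data$mode, .data$similarity),
    grits = mean(.data$grits), precision = mean(.data$precision),
    recall = mean(.data$recall), n_fixtures = dplyr::n(), .groups = "drop")
  attr(out, "per_fixture") <- per
  out
}
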