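#' Tidy the training trace of a table language model
#'
#' @param x a `table_lm` or `merge_classifier`.
#' @param ... unused.
#' @return tibble with `step` and `loss`.
#' @export
tidy.table_lm <- function(x, ...) {
  tibble(step = seq_along(x$loss_trace), loss = x$loss_trace)
}

#' @rdname tidy.table_lm
#' @export
tidy.merge_classifier <- tidy.table_lm

#' One-row model summary
#'
#' @param x a `table_lm` or `merge_classifier`.
#' @param ... unused.
#' @return one-row tibble with architecture sizes, parameter count and
#'   final training loss.
#' @export
glance.table_lm <- function(x, ...) {
  tibble(n_layers = x$config$n_layers, n_heads = x$config$n_heads,
         d_model = x$config$d_model, context_len = x$config$context_len,
         vocab_size = x$vocab$size, n_params = n_params(x$params),
         final_loss = if (length(x$loss_trace)) tail(x$loss_trace, 1) else NA_real_)
}

#' @rdname glance.table_lm
#' @export
glance.merge_classifier <- glance.table_lm

#' @export
tidy.line_model <- function(x, ...) {
  tibble(epoch = seq_along(x$loss_trace), loss = x$loss_trace)
}

#' @export
glance.line_model <- function(x, ...) {
  tibble(hidden = x$hidden, window = x$window,
         class_weight_pos = x$class_weight_pos,
         embedding_dim = ncol(x$embeddings),
         final_loss = if (length(x$loss_trace)) tail(x$loss_trace, 1) else NA_real_)
}

#' Training-loss curve of a table language model
#'
#' @param object a `table_lm` or `merge_classifier`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.table_lm <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$loss)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = "optimizer step", y = "loss (nats/char)",
                  title = "Table LM training loss") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.table_lm
#' @export
autoplot.merge_classifier <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$loss)) +
    ggplot2::geom_line(color = "firebrick") +
    ggplot2::labs(x = "optimizer step", y = "binary cross-entropy",
                  title = "Row-merge classifier fine-tuning loss") +
    ggplot2::theme_minimal()
}

#' Bar chart of a GriTS report
#'
#' @param object a `grits_report` (see [grits_report()]) or the
#'   summary tibble of [compare_modes()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.grits_report <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object),
                            cols = c("grits", "precision", "recall"),
                            names_to = "measure", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$similarity, y = .data$value,
                                   fill = .data$measure)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, title = "Grid table similarity") +
    ggplot2::theme_minimal()
}

#' Plot mode comparison from [compare_modes()]
#'
#' @param summary the tibble returned by [compare_modes()].
#' @return a ggplot.
#' @export
plot_mode_comparison <- function(summary) {
  ggplot2::ggplot(summary, ggplot2::aes(x = .data$mode, y = .data$grits,
                                        fill = .data$similarity)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "pipeline", y = "GriTS",
                  title = "Extraction pipelines on synthetic fixtures") +
    ggplot2::theme_minimal()
}
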