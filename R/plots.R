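# ggplot2 views of the main result types.

#' Plot an SSN's edge statistics
#'
#' Differential correlation against `-log10(p)` per edge, with the
#' retention threshold marked.
#'
#' @param object An [build_ssn()] result (ideally with `keep_all = TRUE`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ssn <- function(object, ...) {
  df <- as.data.frame(object)
  alpha <- attr(object, "alpha")
  if (!"retained" %in% names(df)) df$retained <- TRUE
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta, y = -log10(.data$p),
                                   colour = .data$retained)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::labs(
      x = expression(Delta * "pcc"), y = expression(-log[10](p)),
      colour = sprintf("p < %g", alpha),
      title = sprintf("Sample-specific network: %s", attr(object, "sample_id"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot a module's degree distribution
#'
#' @param object A `driver_module`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.driver_module <- function(object, ...) {
  ct <- centralities(object)
  ggplot2::ggplot(ct, ggplot2::aes(x = .data$degree)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "module degree", y = "genes",
                  title = sprintf("%s driver module, sample %s",
                                  attr(object, "driver_type"),
                                  attr(object, "sample_id"))) +
    ggplot2::theme_minimal()
}

#' Plot an edge-frequency distribution with its cutoff
#'
#' @param freq_table An [edge_frequencies()] table.
#' @param cutoff Optional [monte_carlo_cutoff()] value to mark.
#' @return A ggplot.
#' @export
plot_edge_frequencies <- function(freq_table, cutoff = NULL) {
  p <- ggplot2::ggplot(as.data.frame(freq_table),
                       ggplot2::aes(x = .data$frequency)) +
    ggplot2::geom_histogram(bins = 40) +
    ggplot2::labs(x = "edge occurrence frequency", y = "edges") +
    ggplot2::theme_minimal()
  if (!is.null(cutoff)) {
    p <- p + ggplot2::geom_vline(xintercept = as.numeric(cutoff),
                                 linetype = "dashed", colour = "red")
  }
  p
}

#' Plot centrality distributions by gene class
#'
#' Boxplots of a chosen centrality across gene classes (seeds, 1-order
#' neighbours, other), mirroring the structural comparison of driver
#' modules.
#'
#' @param object A [centralities()] table built with `classes`.
#' @param metric `"degree"`, `"betweenness"` or `"eigenvector"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.centrality_table <- function(object,
                                      metric = c("degree", "betweenness",
                                                 "eigenvector"), ...) {
  metric <- match.arg(metric)
  df <- as.data.frame(object)
  if (!"class" %in% names(df)) df$class <- "all"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class,
                                   y = .data[[metric]])) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
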