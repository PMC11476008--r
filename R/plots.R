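#' Plot a junction map with shared junctions highlighted
#'
#' A merged-exon style diagram: one row per sequence, a point at each
#' projected junction column (shape = phase), with vertical guides at shared
#' junction anchors.
#'
#' @param jm Junction map from [project_junctions()].
#' @param shared Optional tibble from [call_shared_junctions()].
#' @return A ggplot object.
#' @export
plot_junction_map <- function(jm, shared = NULL) {
  p <- ggplot2::ggplot(jm, ggplot2::aes(x = .data$column, y = .data$id)) +
    ggplot2::geom_point(ggplot2::aes(shape = factor(.data$phase)), size = 2) +
    ggplot2::labs(x = "alignment column", y = NULL, shape = "phase") +
    ggplot2::theme_minimal()
  if (!is.null(shared) && nrow(shared)) {
    p <- p + ggplot2::geom_vline(data = shared,
                                 ggplot2::aes(xintercept = .data$column),
                                 linetype = "dashed", colour = "grey50")
  }
  p
}

#' @export
autoplot.profile_matrix <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$class, y = .data$clade,
                                       fill = .data$present)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(.data$count > 0,
                                                   .data$count, "")),
                       size = 3) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2166ac",
                                          `FALSE` = "grey92")) +
    ggplot2::labs(x = NULL, y = NULL, fill = "present") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.duplication_support <- function(object, ...) {
  d <- tibble(delta = object$bootstrap_deltas %||% numeric(0))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$delta)) +
    ggplot2::geom_histogram(bins = 30, fill = "#2166ac", colour = "white") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "bootstrap delta (parent - outgroup identity)",
                  y = "replicates") +
    ggplot2::theme_minimal()
}

#' Plot per-region conservation of targets against the reference
#'
#' @param cons Tibble from [region_conservation()].
#' @return A ggplot object.
#' @export
plot_region_conservation <- function(cons) {
  ggplot2::ggplot(cons, ggplot2::aes(x = .data$region_name,
                                     y = .data$identity,
                                     group = .data$target_id)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$target_id),
                      position = "dodge") +
    ggplot2::labs(x = NULL, y = "identity vs reference", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
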