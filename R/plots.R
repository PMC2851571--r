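# ggplot2 views of the main result types.

#' Stacked composition bars across libraries
#'
#' @param compositions Composition tibble with a `library` column (as in
#'   `run$compositions`), or a single [summarize_library()] table.
#' @return A ggplot.
#' @export
plot_composition <- function(compositions) {
  if (!"library" %in% names(compositions)) {
    compositions$library <- "library"
  }
  ggplot2::ggplot(
    compositions,
    ggplot2::aes(x = .data$library, y = .data$fraction,
                 fill = .data$category)
  ) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::scale_fill_viridis_d(name = "category") +
    ggplot2::labs(x = NULL, y = "fraction of mapped reads") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Ratio-versus-abundance scatter of enrichment records
#'
#' Log2 ratio (library A over library B) against log2 abundance in B;
#' points left of the zero line are depleted in A, points right are
#' enriched.
#'
#' @param records A [log2_enrichment()] table.
#' @param label_threshold Absolute log2 ratio beyond which points are
#'   labelled with their species id (default 2).
#' @return A ggplot.
#' @export
plot_enrichment <- function(records, label_threshold = 2) {
  extreme <- records |> filter(abs(.data$log2_ratio) >= label_threshold)
  ggplot2::ggplot(records, ggplot2::aes(x = .data$log2_ratio,
                                        y = .data$log2_abundance)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_text(data = extreme,
                       ggplot2::aes(label = .data$species),
                       size = 3, vjust = -0.6) +
    ggplot2::labs(x = "log2 ratio (A / B)", y = "log2 abundance in B") +
    ggplot2::theme_minimal()
}

#' Antisense coverage profile along a spliced transcript
#'
#' @param coverage Per-position coverage (e.g.
#'   [locus_antisense_coverage()]).
#' @param window Summing window in nt (default 25).
#' @return A ggplot (5' end left, 3' end right).
#' @export
plot_locus_coverage <- function(coverage, window = 25L) {
  idx <- ((seq_along(coverage) - 1L) %/% window) + 1L
  df <- tibble(window = unique(idx),
               reads = as.numeric(tapply(coverage, idx, sum)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$window, y = .data$reads)) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::labs(x = sprintf("transcript window (%d nt, 5' to 3')", window),
                  y = "antisense reads") +
    ggplot2::theme_minimal()
}

#' @describeIn plot_composition autoplot method for a pipeline run
#'   (composition overview).
#' @param object An `agoscan_run`.
#' @param ... Unused.
#' @export
autoplot.agoscan_run <- function(object, ...) {
  plot_composition(object$compositions)
}
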