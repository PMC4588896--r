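#' Plot a saturation (rarefaction) curve
#'
#' Unique-isoform counts across replicate subsample pools, one violin per
#' pool size, with the replicate mean overlaid.
#'
#' @param object A `saturation_curve` from [saturation_scan()] or
#'   [subsample_unique_isoforms()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method
autoplot.saturation_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$size),
                                       y = .data$unique)) +
    ggplot2::geom_violin(fill = "steelblue", alpha = 0.4, scale = "width") +
    ggplot2::stat_summary(fun = mean, geom = "point", size = 2) +
    ggplot2::labs(x = "reads subsampled", y = "distinct isoforms",
                  title = "Isoform saturation by subsampling") +
    ggplot2::theme_minimal()
}

#' Plot an isoform count table
#'
#' Rank-abundance view: isoforms ranked by read count, counts on a log10
#' axis.
#'
#' @param object An `isoform_table` from [tabulate_isoforms()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method
autoplot.isoform_table <- function(object, ...) {
  df <- cumulative_isoform_distribution(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$count)) +
    ggplot2::geom_point(size = 0.8, colour = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "isoform rank", y = "reads (log10)",
                  title = "Rank-ordered isoform expression") +
    ggplot2::theme_minimal()
}

#' Plot a chimera report
#'
#' Rank order versus log10 read count, input-pool isoforms in blue and
#' template-switched isoforms in red.
#'
#' @param object A `chimera_report` from [classify_isoforms()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method
autoplot.chimera_report <- function(object, ...) {
  df <- as_tibble(object) |>
    arrange(desc(.data$count), .data$isoform) |>
    mutate(rank = row_number())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$count,
                                   colour = .data$label)) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(values = c(genuine = "#2166ac",
                                            chimeric = "#b2182b")) +
    ggplot2::labs(x = "isoform rank", y = "reads (log10)", colour = NULL,
                  title = "Input versus template-switched isoforms") +
    ggplot2::theme_minimal()
}

#' Plot exon-variant discriminability
#'
#' Score distributions of each variant's best, second-best, third... hits
#' within its own cluster; a clean gap between rank 1 (self) and rank 2
#' means reads can be assigned unambiguously.
#'
#' @param object A `discriminability` table from
#'   [exon_discriminability()].
#' @param max_rank Show ranks up to this value (default 4).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method
autoplot.discriminability <- function(object, max_rank = 4, ...) {
  df <- filter(as_tibble(object), .data$rank <= max_rank)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$rank), y = .data$score)) +
    ggplot2::geom_boxplot(fill = "goldenrod", alpha = 0.5,
                          outlier.size = 0.5) +
    ggplot2::facet_wrap(~cluster, scales = "free_y") +
    ggplot2::labs(x = "alignment rank within cluster", y = "score",
                  title = "Within-cluster exon variant discriminability") +
    ggplot2::theme_minimal()
}

#' Read-length histogram data
#'
#' @param reads A reads tibble with `sequence` (and optionally
#'   `read_class`).
#' @param binwidth Histogram bin width in bases (default 50).
#' @return A ggplot.
#' @export
plot_read_lengths <- function(reads, binwidth = 50) {
  df <- mutate(as_tibble(reads), length = nchar(.data$sequence))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$length)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "steelblue",
                            colour = "white") +
    ggplot2::labs(x = "read length (bases)", y = "reads",
                  title = "Read length distribution") +
    ggplot2::theme_minimal()
  if ("read_class" %in% names(df)) {
    p <- p + ggplot2::facet_wrap(~read_class, ncol = 1, scales = "free_y")
  }
  p
}
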