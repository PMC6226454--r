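#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an identification result
#'
#' @param x A `famscan_identification` from [identify_family()].
#' @param ... Unused.
#' @return Per-protein tibble without the sequence column.
#' @export
tidy.famscan_identification <- function(x, ...) {
  dplyr::select(tibble::as_tibble(x), -"sequence")
}

#' One-row summary of an identification result
#'
#' @param x A `famscan_identification`.
#' @param ... Unused.
#' @return Tibble with proteome size, raw candidate and accepted counts.
#' @export
glance.famscan_identification <- function(x, ...) {
  tibble::tibble(
    n_proteins = nrow(x),
    raw_candidates = sum(x$raw_candidate),
    redundant = sum(x$redundant),
    incomplete = sum(x$incomplete & x$raw_candidate),
    accepted = sum(x$verdict == "accept")
  )
}

#' One-row summary of a pipeline report
#'
#' @param x A `famscan_report` from [run_all()].
#' @param ... Unused.
#' @return The headline tibble.
#' @export
glance.famscan_report <- function(x, ...) x$headline

#' Score/E-value overview of an identification result
#'
#' @param object A `famscan_identification`.
#' @param ... Unused.
#' @return A ggplot of family score against empirical E-value, coloured by
#'   verdict.
#' @export
autoplot.famscan_identification <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$score, .data$evalue,
                                   colour = .data$verdict)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "family score (core-motif match fraction)",
                  y = "empirical E-value", colour = "verdict") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Exon/intron structure diagram
#'
#' GSDS-style gene-structure plot: exons as boxes, introns as lines, one
#' row per gene, coordinates relative to each gene start.
#'
#' @param genes Gene tibble with `gene_id`, `start`, `end` and an `exons`
#'   list-column.
#' @return A ggplot object.
#' @export
plot_gene_structure <- function(genes) {
  ex <- purrr::map2_dfr(genes$gene_id, genes$exons, function(id, e) {
    tibble::tibble(gene_id = id, start = e$start, end = e$end)
  })
  offs <- stats::setNames(genes$start, genes$gene_id)
  ends <- stats::setNames(genes$end, genes$gene_id)
  ex$x0 <- ex$start - offs[ex$gene_id]
  ex$x1 <- ex$end - offs[ex$gene_id]
  ex$y <- match(ex$gene_id, genes$gene_id)
  spans <- tibble::tibble(y = seq_len(nrow(genes)), x0 = 0,
                          x1 = ends[genes$gene_id] - offs[genes$gene_id])
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = spans,
                          ggplot2::aes(x = .data$x0, xend = .data$x1,
                                       y = .data$y, yend = .data$y)) +
    ggplot2::geom_rect(data = ex,
                       ggplot2::aes(xmin = .data$x0, xmax = .data$x1,
                                    ymin = .data$y - 0.3,
                                    ymax = .data$y + 0.3),
                       fill = "goldenrod") +
    ggplot2::scale_y_continuous(breaks = seq_len(nrow(genes)),
                                labels = genes$gene_id) +
    ggplot2::labs(x = "bp from gene start", y = NULL) +
    ggplot2::theme_minimal()
}

#' Chromosome map of gene loci
#'
#' @param genes Gene tibble with `gene_id`, `chromosome`, `start`.
#' @param n_chromosomes Total chromosomes (default 12).
#' @return A ggplot object.
#' @export
plot_chromosome_map <- function(genes, n_chromosomes = 12) {
  df <- tibble::tibble(
    chromosome = factor(genes$chromosome, levels = seq_len(n_chromosomes)),
    pos_mb = genes$start / 1e6, gene_id = genes$gene_id)
  ggplot2::ggplot(df, ggplot2::aes(.data$chromosome, .data$pos_mb)) +
    ggplot2::geom_point(shape = 15, colour = "firebrick") +
    ggplot2::geom_text(ggplot2::aes(label = .data$gene_id), hjust = -0.1,
                       size = 2.6) +
    ggplot2::scale_x_discrete(drop = FALSE) +
    ggplot2::labs(x = "chromosome", y = "position (Mb)") +
    ggplot2::theme_minimal()
}
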