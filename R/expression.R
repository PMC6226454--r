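# Coerce an expression input (tibble with gene_id column, or matrix) to a
# numeric matrix with gene rownames.
as_expression_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  stopifnot(is.data.frame(x), "gene_id" %in% names(x))
  m <- as.matrix(x[, setdiff(names(x), "gene_id"), drop = FALSE])
  rownames(m) <- x$gene_id
  m
}

matrix_to_tibble <- function(m) {
  dplyr::bind_cols(tibble::tibble(gene_id = rownames(m)),
                   tibble::as_tibble(as.data.frame(m)))
}

#' Mean-ratio log2 normalization of an FPKM matrix
#'
#' Each value (plus a pseudocount) is divided by the grand mean of all
#' (pseudocounted) values, and the ratios are log2-transformed. By
#' construction the mean of the pre-log ratios is exactly 1.
#'
#' @param matrix Expression tibble (`gene_id` + one column per condition)
#'   or numeric matrix with gene rownames; FPKM values >= 0.
#' @param pseudocount Added to every cell before the ratio (default 0.01)
#'   to keep log2 finite at zero.
#' @return A tibble of log2 ratios, same shape as the input.
#' @export
#' @examples
#' normalize_expression(tibble::tibble(gene_id = "g1", a = 1, b = 3),
#'                      pseudocount = 0)
normalize_expression <- function(matrix, pseudocount = 0.01) {
  m <- as_expression_matrix(matrix)
  if (length(m) == 0) stop("empty expression matrix", call. = FALSE)
  if (any(m < 0)) stop("FPKM values must be non-negative", call. = FALSE)
  if (pseudocount < 0) stop("pseudocount must be >= 0", call. = FALSE)
  shifted <- m + pseudocount
  grand <- mean(shifted)
  if (grand == 0) stop("all-zero matrix with zero pseudocount", call. = FALSE)
  matrix_to_tibble(log2(shifted / grand))
}

#' Average-linkage hierarchical clustering of expression rows
#'
#' UPGMA agglomeration of genes (rows) on Euclidean distances, the MeV-style
#' processing chain for expression heatmaps. `stats::hclust` performs the
#' agglomeration; its merge heights are guaranteed non-decreasing for
#' average linkage.
#'
#' @param matrix Expression tibble or numeric matrix (typically the output
#'   of [normalize_expression()]); >= 2 rows, finite values.
#' @return An `hclust` object with gene labels.
#' @export
hcluster_expression <- function(matrix) {
  m <- as_expression_matrix(matrix)
  if (nrow(m) < 2) stop("need at least 2 rows to cluster", call. = FALSE)
  if (any(!is.finite(m))) stop("non-finite values in matrix", call. = FALSE)
  stats::hclust(stats::dist(m, method = "euclidean"), method = "average")
}

#' Number of conditions in which each gene is expressed
#'
#' @param matrix FPKM expression tibble or matrix.
#' @param threshold A gene counts as expressed in a condition when
#'   FPKM >= threshold (default 1; must be > 0).
#' @return Tibble with `gene_id` and `n_expressed`.
#' @export
expressed_tissue_counts <- function(matrix, threshold = 1) {
  if (threshold <= 0) stop("threshold must be > 0", call. = FALSE)
  m <- as_expression_matrix(matrix)
  tibble::tibble(gene_id = rownames(m),
                 n_expressed = as.integer(rowSums(m >= threshold)))
}

#' Heatmap of a (normalized) expression matrix
#'
#' Genes ordered by average-linkage clustering, tiles coloured by log2
#' ratio.
#'
#' @param matrix Expression tibble or matrix (log2 ratios recommended).
#' @param cluster Reorder rows by [hcluster_expression()] (default TRUE).
#' @return A ggplot object.
#' @export
plot_expression_heatmap <- function(matrix, cluster = TRUE) {
  m <- as_expression_matrix(matrix)
  if (cluster && nrow(m) >= 2) {
    hc <- hcluster_expression(m)
    m <- m[hc$order, , drop = FALSE]
  }
  df <- matrix_to_tibble(m) |>
    tidyr::pivot_longer(-"gene_id", names_to = "condition",
                        values_to = "value")
  df$gene_id <- factor(df$gene_id, levels = rev(rownames(m)))
  df$condition <- factor(df$condition, levels = colnames(m))
  ggplot2::ggplot(df, ggplot2::aes(.data$condition, .data$gene_id,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = "log2 ratio") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
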