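#' Smith-Waterman local alignment of two proteins
#'
#' Affine-gap local alignment with floor at zero, traceback from the global
#' maximum cell (ties: smallest row, then column). Defaults follow the
#' EMBOSS `water` conventions: BLOSUM62, gap open 10, gap extend 0.5.
#' Identity is exact matches over aligned columns (gap columns included in
#' the denominator's aligned length).
#'
#' @param a,b Amino-acid sequences (standard 20-letter alphabet).
#' @param matrix Substitution matrix with residue dimnames
#'   (default [blosum62()]).
#' @param gap_open,gap_extend Positive gap penalties.
#' @return A list of class `famscan_alignment`: `score`, `a_aln`, `b_aln`
#'   (aligned strings with `-` gaps), `identity`, `length` (aligned columns).
#' @export
#' @examples
#' smith_waterman("HEAGAWGHEE", "PAWHEAE")
smith_waterman <- function(a, b, matrix = blosum62(), gap_open = 10,
                           gap_extend = 0.5) {
  assert_protein(a); assert_protein(b)
  if (gap_open <= 0 || gap_extend <= 0)
    stop("gap penalties must be positive", call. = FALSE)
  sub <- matrix[AA_STANDARD, AA_STANDARD]
  res <- .sw_align(aa_codes(a), aa_codes(b), sub, gap_open, gap_extend)
  decode <- function(codes) {
    paste(ifelse(codes == 0, "-", AA_STANDARD[pmax(codes, 1)]), collapse = "")
  }
  len <- length(res$a_aln)
  matches <- sum(res$a_aln != 0 & res$a_aln == res$b_aln)
  structure(list(
    score = res$score,
    a_aln = decode(res$a_aln),
    b_aln = decode(res$b_aln),
    identity = if (len > 0) matches / len else 0,
    length = len
  ), class = "famscan_alignment")
}

#' @export
print.famscan_alignment <- function(x, ...) {
  cat(sprintf("<local alignment: score %.1f, identity %.1f%% over %d columns>\n",
              x$score, 100 * x$identity, x$length))
  if (x$length > 0) cat(x$a_aln, "\n", x$b_aln, "\n", sep = "")
  invisible(x)
}

#' Classify a paralog pair as tandem, segmental or ambiguous
#'
#' A pair is tandem when both genes sit on the same chromosome with a
#' start-to-start distance of at most `window_bp` (100 kb) and at most
#' `max_intervening` (5) annotated genes strictly between them; pairs on
#' different chromosomes are segmental (a simplification standing in for
#' duplicated-block lookup; supply `blocks` to refine); same-chromosome
#' pairs failing the tandem rule are ambiguous.
#'
#' @param gene_a,gene_b Gene ids.
#' @param gene_index Annotation tibble with `gene_id`, `chromosome`, `start`
#'   (all annotated genes, used to count intervening genes).
#' @param window_bp Tandem window (default 1e5).
#' @param max_intervening Maximum genes strictly between (default 5).
#' @param blocks Optional tibble of duplicated-block pairs (`chromosome_a`,
#'   `chromosome_b`); when given, different-chromosome pairs are segmental
#'   only if their chromosomes form a listed block pair, else ambiguous.
#' @return One-row tibble: `gene_a`, `gene_b`, `chromosome_a`,
#'   `chromosome_b`, `distance_bp` (same-chromosome only), `intervening`,
#'   `class`.
#' @export
classify_pair <- function(gene_a, gene_b, gene_index, window_bp = 1e5,
                          max_intervening = 5, blocks = NULL) {
  stopifnot(all(c("gene_id", "chromosome", "start") %in% names(gene_index)))
  ia <- gene_index[gene_index$gene_id == gene_a, ]
  ib <- gene_index[gene_index$gene_id == gene_b, ]
  if (nrow(ia) != 1 || nrow(ib) != 1)
    stop("gene missing from index: ",
         paste(c(gene_a, gene_b)[c(nrow(ia) != 1, nrow(ib) != 1)],
               collapse = ", "), call. = FALSE)
  same <- ia$chromosome == ib$chromosome
  dist_bp <- if (same) abs(ia$start - ib$start) else NA_real_
  intervening <- NA_integer_
  class <- "ambiguous"
  if (same) {
    lo <- min(ia$start, ib$start); hi <- max(ia$start, ib$start)
    between <- gene_index$chromosome == ia$chromosome &
      gene_index$start > lo & gene_index$start < hi &
      !gene_index$gene_id %in% c(gene_a, gene_b)
    intervening <- sum(between)
    if (dist_bp <= window_bp && intervening <= max_intervening)
      class <- "tandem"
  } else {
    class <- "segmental"
    if (!is.null(blocks)) {
      hit <- any((blocks$chromosome_a == ia$chromosome &
                    blocks$chromosome_b == ib$chromosome) |
                   (blocks$chromosome_a == ib$chromosome &
                      blocks$chromosome_b == ia$chromosome))
      if (!hit) class <- "ambiguous"
    }
  }
  tibble::tibble(
    gene_a = gene_a, gene_b = gene_b,
    chromosome_a = ia$chromosome, chromosome_b = ib$chromosome,
    distance_bp = dist_bp, intervening = intervening, class = class
  )
}

#' Classify a table of paralog pairs
#'
#' Vectorized front end to [classify_pair()], optionally attaching
#' Smith-Waterman identities when protein sequences are supplied.
#'
#' @param pairs Tibble with `gene_a`, `gene_b`.
#' @param gene_index Annotation tibble (`gene_id`, `chromosome`, `start`).
#' @param proteins Optional protein tibble (`protein_id`, `sequence`).
#' @inheritParams classify_pair
#' @return Tibble with one row per pair and an `identity` column when
#'   proteins are given.
#' @export
classify_pairs <- function(pairs, gene_index, proteins = NULL,
                           window_bp = 1e5, max_intervening = 5,
                           blocks = NULL) {
  out <- purrr::map2_dfr(pairs$gene_a, pairs$gene_b, classify_pair,
                         gene_index = gene_index, window_bp = window_bp,
                         max_intervening = max_intervening, blocks = blocks)
  if (!is.null(proteins)) {
    proteins <- as_protein_tbl(proteins)
    seqs <- stats::setNames(proteins$sequence, proteins$protein_id)
    out$identity <- purrr::map2_dbl(out$gene_a, out$gene_b, function(a, b) {
      smith_waterman(seqs[[a]], seqs[[b]])$identity
    })
  }
  out
}
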