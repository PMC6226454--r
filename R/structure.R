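# Validate one gene model: exon tibble (start, end), 1-based inclusive.
validate_exons <- function(exons, gene_id = "gene") {
  stopifnot(all(c("start", "end") %in% names(exons)))
  if (nrow(exons) == 0) stop(gene_id, ": gene has zero exons", call. = FALSE)
  exons <- exons[order(exons$start), ]
  if (any(exons$end < exons$start))
    stop(gene_id, ": exon end before start", call. = FALSE)
  if (nrow(exons) > 1 &&
      any(exons$start[-1] <= exons$end[-nrow(exons)]))
    stop(gene_id, ": overlapping exons", call. = FALSE)
  exons
}

#' Intron count of a gene model
#'
#' @param exons Exon tibble (`start`, `end`) of one gene, 1-based inclusive.
#' @param gene_id Optional id used in error messages.
#' @return Number of introns (`exons - 1`).
#' @export
intron_count <- function(exons, gene_id = "gene") {
  nrow(validate_exons(exons, gene_id)) - 1L
}

#' Splice phases of a gene model
#'
#' Phase of intron i = cumulative coding length upstream of the intron,
#' modulo 3 (the GSDS-style intron phase: 0 between codons, 1 after the
#' first base, 2 after the second). Exons are taken 5'->3' on the coding
#' strand; minus-strand genes are mirrored first.
#'
#' @param exons Exon tibble (`start`, `end`), 1-based inclusive coding exons.
#' @param strand `"+"` (default) or `"-"`.
#' @param gene_id Optional id used in error messages.
#' @return Integer vector of phases in \{0, 1, 2\}, one per intron (empty
#'   for single-exon genes).
#' @export
splice_phases <- function(exons, strand = "+", gene_id = "gene") {
  exons <- validate_exons(exons, gene_id)
  lens <- exons$end - exons$start + 1
  if (strand == "-") lens <- rev(lens)
  if (sum(lens) %% 3 != 0)
    stop(gene_id, ": CDS length not divisible by 3", call. = FALSE)
  if (length(lens) == 1) return(integer(0))
  as.integer(cumsum(lens[-length(lens)]) %% 3)
}

#' Convert GSDS intron phases to GFF3 CDS phase codes
#'
#' The GFF3 CDS `phase` column states how many bases must be removed from
#' the start of a CDS segment to reach a codon boundary — the complement of
#' the cumulative-length intron phase. The first CDS segment has phase 0.
#'
#' @param phases Integer intron phases from [splice_phases()].
#' @return Integer GFF3 phases for exons 2..n, preceded by 0 for exon 1.
#' @export
intron_phase_to_gff <- function(phases) {
  as.integer(c(0L, (3L - phases) %% 3L))
}

#' Per-gene structure report
#'
#' Intron counts, splice phases and exon lengths for a set of gene models.
#'
#' @param genes Gene tibble with `gene_id`, `strand` and a list-column
#'   `exons` of exon tibbles (as produced by [simulate_genome()]), or the
#'   `genes` element of a genome bundle.
#' @return Tibble with `gene_id`, `intron_count`, `phases` (list-column),
#'   `exon_lengths` (list-column).
#' @export
structure_report <- function(genes) {
  purrr::pmap_dfr(
    list(genes$gene_id, genes$exons,
         if ("strand" %in% names(genes)) genes$strand else "+"),
    function(id, ex, strand) {
      tibble::tibble(
        gene_id = id,
        intron_count = intron_count(ex, id),
        phases = list(splice_phases(ex, strand, id)),
        exon_lengths = list(as.integer(ex$end - ex$start + 1))
      )
    })
}

#' Per-chromosome gene counts
#'
#' @param genes Tibble with `gene_id` and `chromosome` (names or numbers
#'   1-12).
#' @param n_chromosomes Total chromosomes in the genome (default 12).
#' @return Tibble with `chromosome` (1..n) and `n_genes`; the number of
#'   occupied chromosomes is attached as `attr(, "n_occupied")`.
#' @export
chromosome_distribution <- function(genes, n_chromosomes = 12) {
  chrom <- as.integer(gsub("^chr", "", as.character(genes$chromosome)))
  if (any(is.na(chrom)) || any(chrom < 1 | chrom > n_chromosomes))
    stop("unknown chromosome name", call. = FALSE)
  counts <- tabulate(chrom, nbins = n_chromosomes)
  out <- tibble::tibble(chromosome = seq_len(n_chromosomes),
                        n_genes = as.integer(counts))
  attr(out, "n_occupied") <- sum(counts > 0)
  out
}

#' Motif presence/absence matrix
#'
#' Scans each protein for each motif and reports presence (best match
#' fraction at or above the threshold) as a gene-by-motif logical matrix.
#'
#' @param proteins Tibble with `protein_id`, `sequence`.
#' @param motifs Motif table as in [hsp70_motifs()].
#' @param threshold Presence threshold on the best match fraction
#'   (default 0.8).
#' @return A tibble with `protein_id` and one logical column per motif
#'   (`motif_1` ... `motif_10`); the numeric best-match fractions are kept
#'   in `attr(, "fractions")`.
#' @export
motif_presence_matrix <- function(proteins, motifs = hsp70_motifs(),
                                  threshold = 0.8) {
  proteins <- as_protein_tbl(proteins)
  motifs <- validate_motifs(motifs)
  profiles <- lapply(motifs$consensus, motif_profile)
  frac <- t(vapply(proteins$sequence, function(s) {
    purrr::map_dbl(scan_codes(aa_codes(s), profiles), "match")
  }, numeric(nrow(motifs))))
  dimnames(frac) <- list(proteins$protein_id,
                         paste0("motif_", motifs$motif))
  out <- tibble::as_tibble(as.data.frame(frac >= threshold))
  out <- dplyr::bind_cols(tibble::tibble(protein_id = proteins$protein_id),
                          out)
  attr(out, "fractions") <- frac
  out
}
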