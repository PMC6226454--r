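#' Write the synthetic bundle to standard formats
#'
#' Writes proteins FASTA, CDS FASTA, annotation GFF3 (1-based, CDS features
#' carry phase), expression TSV, CT TSV, the planted truth as JSON and the
#' generator configuration as YAML. Chromosome sequences are not
#' materialized: coordinates are annotation-level.
#'
#' @param bundle A `famscan_genome`.
#' @param dir Output directory (created if needed).
#' @param expression Optional expression tibble from
#'   [simulate_expression()].
#' @param ct Optional CT tibble from [simulate_ct()].
#' @return Invisibly, a named vector of written file paths.
#' @export
write_genome_files <- function(bundle, dir, expression = NULL, ct = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    proteins = file.path(dir, "proteins.fa"),
    cds = file.path(dir, "cds.fa"),
    gff = file.path(dir, "annotation.gff3"),
    truth = file.path(dir, "truth.json"),
    config = file.path(dir, "config.yaml")
  )
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(stats::setNames(bundle$proteins$sequence,
                                            bundle$proteins$protein_id)),
    paths[["proteins"]])
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(stats::setNames(bundle$genes$cds,
                                             bundle$genes$gene_id)),
    paths[["cds"]])
  write_annotation_gff3(bundle$genes, paths[["gff"]])
  truth <- bundle$truth
  jsonlite::write_json(list(
    family_members = truth$family_members,
    subfamily_of = as.list(truth$subfamily_of),
    decoys = truth$decoys,
    planted_pairs = truth$planted_pairs,
    expression_pattern = as.list(truth$expression_pattern),
    motif_losses = as.list(truth$motif_losses)
  ), paths[["truth"]], auto_unbox = TRUE, digits = NA)
  cfg <- bundle$config
  yaml::write_yaml(cfg[!vapply(cfg, is.null, logical(1))],
                   paths[["config"]])
  if (!is.null(expression)) {
    paths[["expression"]] <- file.path(dir, "expression.tsv")
    readr::write_tsv(expression, paths[["expression"]])
  }
  if (!is.null(ct)) {
    paths[["ct"]] <- file.path(dir, "ct.tsv")
    readr::write_tsv(ct, paths[["ct"]])
  }
  invisible(paths)
}

# Export gene + exon + phased CDS features as GFF3 via rtracklayer.
write_annotation_gff3 <- function(genes, path) {
  rows <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    ex <- g$exons[[1]]
    phases <- intron_phase_to_gff(splice_phases(ex, g$strand, g$gene_id))
    rows[[length(rows) + 1]] <- tibble::tibble(
      seqnames = paste0("chr", g$chromosome),
      start = c(g$start, ex$start, ex$start),
      end = c(g$end, ex$end, ex$end),
      type = c("gene", rep("exon", nrow(ex)), rep("CDS", nrow(ex))),
      ID = c(g$gene_id,
             sprintf("%s.exon%d", g$gene_id, seq_len(nrow(ex))),
             sprintf("%s.cds%d", g$gene_id, seq_len(nrow(ex)))),
      Parent = c(NA_character_, rep(g$gene_id, 2 * nrow(ex))),
      phase = c(NA_integer_, rep(NA_integer_, nrow(ex)), phases),
      strand = g$strand,
      role = g$role
    )
  }
  df <- dplyr::bind_rows(rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$seqnames,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = df$strand)
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$ID <- df$ID
  S4Vectors::mcols(gr)$Parent <- IRanges::CharacterList(
    lapply(df$Parent, function(p) if (is.na(p)) character(0) else p))
  S4Vectors::mcols(gr)$phase <- df$phase
  S4Vectors::mcols(gr)$role <- df$role
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a proteome FASTA into a protein tibble
#'
#' @param path FASTA file path.
#' @return Tibble with `protein_id`, `sequence`.
#' @export
read_proteome <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  tibble::tibble(protein_id = sub(" .*", "", names(aa)),
                 sequence = as.character(aa))
}

#' Read a GFF3 annotation into a gene tibble
#'
#' Genes are reconstructed from `gene` features; exon coordinates from
#' their `exon` children.
#'
#' @param path GFF3 file path.
#' @return Tibble with `gene_id`, `chromosome`, `start`, `end`, `strand`
#'   and an `exons` list-column.
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- tibble::tibble(
    seqnames = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(S4Vectors::mcols(gr)$type),
    ID = as.character(S4Vectors::mcols(gr)$ID),
    Parent = vapply(as.list(S4Vectors::mcols(gr)$Parent), function(p) {
      if (length(p) == 0) NA_character_ else as.character(p[1])
    }, character(1))
  )
  genes <- df[df$type == "gene", ]
  exons <- df[df$type == "exon", ]
  purrr::map_dfr(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    ex <- exons[exons$Parent == g$ID, c("start", "end")]
    tibble::tibble(
      gene_id = g$ID,
      chromosome = as.integer(gsub("^chr", "", g$seqnames)),
      start = g$start, end = g$end,
      strand = if (g$strand %in% c("+", "-")) g$strand else "+",
      exons = list(ex[order(ex$start), ]))
  })
}
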