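#' Consensus motifs of the potato Hsp70 family
#'
#' The ten conserved motifs shared by the potato Hsp70 proteins, as consensus
#' amino-acid strings. Motifs 1, 3 and 4 are the "core" motifs found in every
#' family member and anchor the identification scan; motifs map onto the
#' canonical Hsp70 architecture (N-terminal nucleotide-binding/ATPase domain,
#' substrate-binding domain, C-terminal lid). Consensus strings may contain
#' the ambiguity letters B (D/N), Z (E/Q), J (I/L) and X (any residue).
#'
#' @return A tibble with columns `motif` (integer 1-10), `width` (consensus
#'   width in residues) and `consensus` (consensus string).
#' @export
#' @examples
#' hsp70_motifs()
hsp70_motifs <- function() {
  tibble::tibble(
    motif = 1:10,
    width = c(50L, 50L, 50L, 50L, 50L, 29L, 24L, 50L, 41L, 41L),
    consensus = c(
      "VKNAVVTVPAYFNDSQRQATKDAGVIAGLNVMRIINEPTAAAJAYGLDKK",
      "PLSLGJETAGGVMTVLIPRNTTIPTKKEQVFSTYSDNQPGVLIQVYEGER",
      "FDLGGGTFDVSJLTIEEGIFEVKATAGDTHLGGEDFDNRLVNHFVQEFKR",
      "TRARFEELNMDLFRKCMEPVEKCLRDAKLDKSDIHEVVLVGGSTRIPKVQ",
      "LGKFELSGIPPAPRGVPQIEVCFDIDANGILNVSAEDKTTGQKNKITITN",
      "FNGKELCKSINPDEAVAYGAAVQAAILSG",
      "VEIIANDQGNRTTPSYVAFTDTER",
      "KHKKDISGBPRALRRLRTACERAKRTLSSTAQTTIEIDSLYEGIDFYSTI",
      "GDAAKNQVAMNPENTVFDAKRLIGRRFSDPSVQSDMKLWPF",
      "AVDZAIEWLDSNQLAEADEFEDKMKELESICNPIIAKMYQG"
    )
  )
}

#' Reference loci of the potato Hsp70 genes
#'
#' Published characteristics of the 20 StHsp70 genes: chromosome, genomic
#' span (kb), ORF length (bp), intron number, protein length (aa), molecular
#' weight (kDa) and isoelectric point. These coordinates and counts drive the
#' synthetic genome generator and the chromosome-distribution and duplication
#' worked examples.
#'
#' The intron column carries two readings for StHsp70-10 and StHsp70-11: the
#' table prints 1 while the accompanying text states both genes lack introns.
#' `intron_text` holds the narrative reading (the generator default),
#' `intron_table` the printed one.
#'
#' Subfamily labels (A-E) are reconstructed from intron counts and sister
#' pairs: A = the ten 0-1 intron members, B/C = the 5-7 intron triples,
#' D = the intronless singleton StHsp70-14, E = the >7 intron triple.
#'
#' @return A tibble with one row per gene.
#' @export
#' @examples
#' potato_hsp70_loci()
potato_hsp70_loci <- function() {
  tab <- tibble::tribble(
    ~gene_id,     ~chromosome, ~start_kb, ~end_kb,  ~orf_bp, ~intron_table, ~length_aa, ~mw_kda, ~pi,
    "StHsp70-1",  1L,  80158.5, 80162.9, 2121L,  7L, 706L, 75.15, 5.16,
    "StHsp70-2",  12L, 50389.4, 50395.4, 2613L,  9L, 870L, 95.99, 5.34,
    "StHsp70-3",  12L, 50378.3, 50384.1, 2550L,  8L, 849L, 93.57, 5.23,
    "StHsp70-4",  1L,  82924.1, 82928.6, 2025L,  5L, 674L, 72.41, 5.95,
    "StHsp70-5",  1L,  82849.8, 82853.6, 2034L,  5L, 677L, 72.78, 5.82,
    "StHsp70-6",  7L,  42050.3, 42058.2, 2673L, 12L, 890L, 98.96, 5.83,
    "StHsp70-7",  11L, 38747.6, 38749.9, 1959L,  1L, 652L, 71.31, 5.14,
    "StHsp70-8",  6L,  56528.0, 56531.0, 1947L,  1L, 648L, 71.02, 5.04,
    "StHsp70-9",  10L, 51360.2, 51363.5, 1944L,  1L, 647L, 70.89, 5.03,
    "StHsp70-10", 3L,  57412.2, 57414.4, 1965L,  1L, 654L, 71.89, 5.21,
    "StHsp70-11", 12L, 49581.3, 49583.7, 1920L,  1L, 639L, 70.80, 5.42,
    "StHsp70-12", 9L,   1958.6,  1962.0, 1950L,  1L, 649L, 71.24, 5.13,
    "StHsp70-13", 11L, 38717.6, 38720.3, 1950L,  1L, 649L, 71.20, 5.09,
    "StHsp70-14", 9L,  53571.5, 53573.5, 1722L,  0L, 573L, 62.41, 5.53,
    "StHsp70-15", 7L,   1089.7,  1092.7, 1845L,  1L, 614L, 67.47, 5.11,
    "StHsp70-16", 6L,   5489.7,  5492.1, 1461L,  1L, 486L, 53.27, 5.48,
    "StHsp70-17", 4L,   7035.0,  7037.9, 1950L,  1L, 649L, 71.23, 5.07,
    "StHsp70-18", 8L,  56395.4, 56399.8, 2004L,  7L, 667L, 73.46, 5.04,
    "StHsp70-19", 3L,  45718.2, 45722.3, 2007L,  7L, 668L, 73.61, 5.10,
    "StHsp70-20", 1L,  77390.8, 77394.2, 2010L,  6L, 669L, 74.68, 5.32
  )
  subfam <- c(
    "StHsp70-1" = "C", "StHsp70-2" = "E", "StHsp70-3" = "E", "StHsp70-4" = "C",
    "StHsp70-5" = "C", "StHsp70-6" = "E", "StHsp70-7" = "A", "StHsp70-8" = "A",
    "StHsp70-9" = "A", "StHsp70-10" = "A", "StHsp70-11" = "A",
    "StHsp70-12" = "A", "StHsp70-13" = "A", "StHsp70-14" = "D",
    "StHsp70-15" = "A", "StHsp70-16" = "A", "StHsp70-17" = "A",
    "StHsp70-18" = "B", "StHsp70-19" = "B", "StHsp70-20" = "B"
  )
  tab$intron_text <- ifelse(tab$gene_id %in% c("StHsp70-10", "StHsp70-11"),
                            0L, tab$intron_table)
  tab$subfamily <- unname(subfam[tab$gene_id])
  tab$start_bp <- as.integer(round(tab$start_kb * 1000))
  tab$end_bp <- as.integer(round(tab$end_kb * 1000))
  tab
}

#' Published sister pairs of the potato Hsp70 family
#'
#' The five sister (cherry) pairs of the family and their reported
#' duplication classes: three tandem pairs and two segmental pairs.
#'
#' @return A tibble with columns `gene_a`, `gene_b`, `class`.
#' @export
hsp70_sister_pairs <- function() {
  tibble::tribble(
    ~gene_a,      ~gene_b,      ~class,
    "StHsp70-4",  "StHsp70-5",  "tandem",
    "StHsp70-7",  "StHsp70-13", "tandem",
    "StHsp70-2",  "StHsp70-3",  "tandem",
    "StHsp70-18", "StHsp70-19", "segmental",
    "StHsp70-9",  "StHsp70-12", "segmental"
  )
}

#' Tissues of the potato expression atlas
#'
#' The eleven tissues profiled for family-wide expression.
#'
#' @return Character vector of tissue names.
#' @export
hsp70_tissues <- function() {
  c("root", "leaf", "tuber", "stolon", "stamen", "petiole",
    "flower", "petal", "sepal", "carpel", "stem")
}

#' Treatments of the stress/hormone qPCR design
#'
#' @return A list with elements `abiotic`, `hormone`, `biotic` and `control`.
#' @export
hsp70_treatments <- function() {
  list(
    abiotic = c("salt", "drought", "heat", "cold"),
    hormone = c("IAA", "ABA", "GA3", "SA"),
    biotic = c("P.infestans", "BAP", "BABA", "BTH"),
    control = "control"
  )
}
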