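# Average (not monoisotopic) residue masses in Da, ProtParam convention.
AA_MASS_AVG <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_MASS_DA <- 18.01524

# Bjellqvist pKa values (ExPASy-compatible): terminal and side-chain groups.
PKA_BJELLQVIST <- list(
  nterm = 9.094, cterm = 3.55,
  side = c(D = 4.05, E = 4.45, C = 9.0, Y = 10.0, H = 5.98, K = 10.0, R = 12.0)
)

#' ORF length implied by a protein length
#'
#' The coding ORF spans one codon per residue plus the stop codon, i.e.
#' `3 * (aa + 1)` bp. This relation reproduces the published ORF column for
#' every reference locus (e.g. 706 aa -> 2121 bp).
#'
#' @param length_aa Protein length(s) in amino acids (non-negative).
#' @return ORF length(s) in bp.
#' @export
#' @examples
#' orf_length(706)
orf_length <- function(length_aa) {
  stopifnot(is.numeric(length_aa))
  if (any(length_aa < 0)) stop("protein length must be non-negative", call. = FALSE)
  as.integer(3 * (length_aa + 1))
}

#' Molecular weight of a protein
#'
#' Sum of average residue masses plus one water, in kDa. Ambiguity letters
#' are rejected: a definite sequence is required for a definite mass.
#'
#' @param sequence Amino-acid sequence over the 20 standard residues.
#' @return Molecular weight in kDa.
#' @export
#' @examples
#' molecular_weight("G") # free glycine, ~0.075 kDa
molecular_weight <- function(sequence) {
  assert_protein(sequence)
  chars <- strsplit(sequence, "")[[1]]
  (sum(AA_MASS_AVG[chars]) + WATER_MASS_DA) / 1000
}

# Net charge of a peptide at the given pH values (Henderson-Hasselbalch).
peptide_charge <- function(sequence, ph, pka = PKA_BJELLQVIST) {
  chars <- strsplit(sequence, "")[[1]]
  pos <- 10^(pka$nterm - ph) / (1 + 10^(pka$nterm - ph))
  neg <- 10^(ph - pka$cterm) / (1 + 10^(ph - pka$cterm))
  for (res in names(pka$side)) {
    n <- sum(chars == res)
    if (n == 0) next
    pk <- pka$side[[res]]
    if (res %in% c("K", "R", "H")) {
      pos <- pos + n * 10^(pk - ph) / (1 + 10^(pk - ph))
    } else {
      neg <- neg + n * 10^(ph - pk) / (1 + 10^(ph - pk))
    }
  }
  pos - neg
}

#' Theoretical isoelectric point
#'
#' pH at which the peptide's net charge crosses zero, found by bisection on
#' (0, 14) under a Henderson-Hasselbalch charge model with Bjellqvist pKa
#' values (ProtParam-style). The pKa table is injectable for EMBOSS-style
#' comparisons.
#'
#' @param sequence Amino-acid sequence over the 20 standard residues.
#' @param pka pKa set: list with `nterm`, `cterm` and named `side` vector.
#' @param tol Stop when |charge| < `tol` or the bracket is narrower than
#'   1e-7 pH units.
#' @return pI in pH units.
#' @export
#' @examples
#' isoelectric_point("ACDEFGHIKLMNPQRSTVWY")
isoelectric_point <- function(sequence, pka = PKA_BJELLQVIST, tol = 1e-4) {
  assert_protein(sequence)
  lo <- 0; hi <- 14
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    q <- peptide_charge(sequence, mid, pka)
    if (abs(q) < tol || (hi - lo) < 1e-7) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
  mid
}

#' Physicochemical characterization of proteins
#'
#' Computes the published table's per-protein characteristics: length, ORF
#' length, molecular weight and isoelectric point.
#'
#' @param proteins A tibble with columns `protein_id` and `sequence`, or a
#'   named character vector of sequences.
#' @return A tibble with columns `protein_id`, `length_aa`, `orf_bp`,
#'   `mw_kda` (2 decimals), `pi` (2 decimals).
#' @export
#' @examples
#' protein_properties(c(p1 = "MKKLV"))
protein_properties <- function(proteins) {
  proteins <- as_protein_tbl(proteins)
  tibble::tibble(
    protein_id = proteins$protein_id,
    length_aa = nchar(proteins$sequence),
    orf_bp = orf_length(nchar(proteins$sequence)),
    mw_kda = round(purrr::map_dbl(proteins$sequence, molecular_weight), 2),
    pi = round(purrr::map_dbl(proteins$sequence, isoelectric_point), 2)
  )
}

# Accept either a tibble (protein_id, sequence) or a named character vector.
as_protein_tbl <- function(proteins) {
  if (is.character(proteins)) {
    ids <- names(proteins)
    if (is.null(ids)) ids <- paste0("protein-", seq_along(proteins))
    proteins <- tibble::tibble(protein_id = ids, sequence = unname(proteins))
  }
  stopifnot(all(c("protein_id", "sequence") %in% names(proteins)))
  if (anyDuplicated(proteins$protein_id))
    stop("duplicate protein ids", call. = FALSE)
  tibble::as_tibble(proteins[, c("protein_id", "sequence")])
}
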