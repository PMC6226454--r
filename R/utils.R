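#' @importFrom Rcpp sourceCpp
#' @useDynLib famscan, .registration = TRUE
#' @importFrom rlang .data
NULL

# The 20 standard amino acids, in one-letter code.
AA_STANDARD <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Residues each ambiguity letter may stand for.
AA_AMBIGUITY <- list(B = c("D", "N"), Z = c("E", "Q"), J = c("I", "L"),
                     X = AA_STANDARD)

# One codon per residue (standard genetic code) for reverse translation.
AA_CODON <- c(
  A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT", Q = "CAA",
  E = "GAA", G = "GGT", H = "CAT", I = "ATT", L = "CTT", K = "AAA",
  M = "ATG", F = "TTT", P = "CCT", S = "TCT", T = "ACT", W = "TGG",
  Y = "TAT", V = "GTT"
)

#' Derive a stage-specific seed from a top-level seed
#'
#' All pipeline randomness flows from one top-level seed; each stage draws
#' from a stream keyed by the stage name, so toggling one stage does not
#' shift another stage's random numbers. The derived seed is kept inside the
#' 32-bit integer range.
#'
#' @param seed Integer top-level seed.
#' @param stage Character stage name.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  h <- 0
  for (cc in utf8ToInt(stage)) h <- (h * 131 + cc) %% 1000003L
  as.integer((abs(seed) %% 1000003L) * 2047 + h) %% 2147483629L
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

assert_protein <- function(sequence, allow_ambiguity = FALSE) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  if (nchar(sequence) == 0) stop("empty protein sequence", call. = FALSE)
  letters_ok <- AA_STANDARD
  if (allow_ambiguity) letters_ok <- c(letters_ok, names(AA_AMBIGUITY))
  chars <- strsplit(sequence, "")[[1]]
  bad <- which(!chars %in% letters_ok)
  if (length(bad) > 0) {
    stop(sprintf("invalid residue '%s' at position %d", chars[bad[1]], bad[1]),
         call. = FALSE)
  }
  invisible(sequence)
}

# Random protein of length n over the standard alphabet (uses current RNG).
random_protein <- function(n) {
  paste(sample(AA_STANDARD, n, replace = TRUE), collapse = "")
}

#' Reverse-translate a protein into a coding sequence
#'
#' Deterministically maps each residue to one standard codon and appends a
#' TAA stop, so the CDS length is 3 * (aa + 1) and translation round-trips.
#'
#' @param protein Amino-acid sequence (standard 20-letter alphabet).
#' @return A DNA string (character scalar).
#' @export
reverse_translate <- function(protein) {
  assert_protein(protein)
  chars <- strsplit(protein, "")[[1]]
  paste0(paste(AA_CODON[chars], collapse = ""), "TAA")
}

#' Translate a coding sequence
#'
#' Thin wrapper over [Biostrings::translate()] returning the protein without
#' its trailing stop.
#'
#' @param cds DNA coding sequence including the stop codon.
#' @return Amino-acid sequence (character scalar).
#' @export
translate_cds <- function(cds) {
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
  sub("\\*$", "", aa)
}

#' BLOSUM62 substitution matrix
#'
#' The BLOSUM62 matrix shipped with Biostrings, restricted by default to the
#' standard residues used throughout this package.
#'
#' @return A numeric matrix with residue dimnames.
#' @export
blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62
  m[AA_STANDARD, AA_STANDARD]
}
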