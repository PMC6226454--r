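# Integer-code a protein over the standard alphabet.
aa_codes <- function(sequence) {
  match(strsplit(sequence, "")[[1]], AA_STANDARD)
}

# width x 20 logical compatibility profile of a consensus string.
motif_profile <- function(consensus) {
  chars <- strsplit(consensus, "")[[1]]
  prof <- matrix(FALSE, nrow = length(chars), ncol = length(AA_STANDARD),
                 dimnames = list(NULL, AA_STANDARD))
  for (j in seq_along(chars)) {
    cc <- chars[j]
    allowed <- if (cc %in% names(AA_AMBIGUITY)) AA_AMBIGUITY[[cc]] else cc
    prof[j, allowed] <- TRUE
  }
  prof
}

validate_motifs <- function(motifs) {
  stopifnot(all(c("motif", "width", "consensus") %in% names(motifs)))
  missing <- setdiff(1:10, motifs$motif)
  if (length(missing) > 0) {
    stop("motif list incomplete; missing motif(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(motifs$width != nchar(motifs$consensus)))
    stop("motif width does not match consensus length", call. = FALSE)
  if (any(motifs$width < 6 | motifs$width > 200))
    stop("motif widths must lie in [6, 200]", call. = FALSE)
  motifs
}

#' Fraction of a window compatible with a motif consensus
#'
#' Position-wise comparison of a sequence window against a consensus of the
#' same width. A position matches when the residues are identical or the
#' consensus letter is an ambiguity code covering the window residue
#' (B = D/N, Z = E/Q, J = I/L, X = any).
#'
#' @param window Residue string, same length as the consensus.
#' @param motif One-row tibble (or list) with `width` and `consensus`, as in
#'   [hsp70_motifs()].
#' @return Match fraction in \[0, 1\].
#' @export
#' @examples
#' match_fraction("IAY", list(width = 3, consensus = "JAY"))
match_fraction <- function(window, motif) {
  if (nchar(window) != motif$width)
    stop("window length must equal motif width", call. = FALSE)
  assert_protein(window)
  prof <- motif_profile(motif$consensus)
  codes <- aa_codes(window)
  mean(prof[cbind(seq_len(motif$width), codes)])
}

# Best-window match fractions of one coded protein against prepared profiles.
# Returns list of (start, match) per motif; NA start when protein shorter
# than the motif.
scan_codes <- function(codes, profiles) {
  L <- length(codes)
  lapply(profiles, function(prof) {
    w <- nrow(prof)
    if (L < w) return(list(start = NA_integer_, match = 0))
    nwin <- L - w + 1L
    hits <- numeric(nwin)
    for (j in seq_len(w)) {
      hits <- hits + prof[j, ][codes[j:(j + nwin - 1L)]]
    }
    best <- which.max(hits) # leftmost on ties
    list(start = best, match = hits[best] / w)
  })
}

#' Scan a protein for all family motifs
#'
#' Reports, for each motif, the best-scoring window (leftmost on ties) and
#' whether its match fraction reaches the presence threshold.
#'
#' @param protein Amino-acid sequence, or a one-row tibble with
#'   `protein_id`/`sequence`.
#' @param motifs Motif table as in [hsp70_motifs()].
#' @param presence_threshold Minimum best-match fraction for a motif to be
#'   called present (default 0.8).
#' @return A tibble with columns `protein_id`, `motif`, `start`, `match`,
#'   `present`.
#' @export
scan_protein <- function(protein, motifs = hsp70_motifs(),
                         presence_threshold = 0.8) {
  if (is.data.frame(protein)) {
    stopifnot(nrow(protein) == 1)
    id <- protein$protein_id
    sequence <- protein$sequence
  } else {
    id <- if (!is.null(names(protein))) names(protein)[1] else "protein"
    sequence <- unname(protein[1])
  }
  assert_protein(sequence)
  motifs <- validate_motifs(motifs)
  if (nchar(sequence) < min(motifs$width))
    stop("protein shorter than the smallest motif", call. = FALSE)
  profiles <- lapply(motifs$consensus, motif_profile)
  hits <- scan_codes(aa_codes(sequence), profiles)
  frac <- purrr::map_dbl(hits, "match")
  tibble::tibble(
    protein_id = id,
    motif = motifs$motif,
    start = purrr::map_int(hits, "start"),
    match = frac,
    present = frac >= presence_threshold
  )
}

#' Family score of a scanned protein
#'
#' Mean best-match fraction over the core motifs (1, 3, 4 by default), the
#' motifs present in every member of the family.
#'
#' @param scan Scan tibble from [scan_protein()].
#' @param core_motifs Integer motif indices (default `c(1, 3, 4)`).
#' @return Scalar score in \[0, 1\].
#' @export
family_score <- function(scan, core_motifs = c(1L, 3L, 4L)) {
  core <- scan[scan$motif %in% core_motifs, ]
  stopifnot(nrow(core) == length(core_motifs))
  mean(core$match)
}

# Family scores for every protein in a proteome tibble.
proteome_scores <- function(proteome, motifs, core_motifs = c(1L, 3L, 4L)) {
  motifs <- validate_motifs(motifs)
  core <- motifs[motifs$motif %in% core_motifs, ]
  profiles <- lapply(core$consensus, motif_profile)
  purrr::map_dbl(proteome$sequence, function(s) {
    hits <- scan_codes(aa_codes(s), profiles)
    mean(purrr::map_dbl(hits, "match"))
  })
}

#' Empirical E-value of a family score
#'
#' Permutation-based stand-in for a profile-search E-value: null scores are
#' family scores of residue-permuted proteome members, and
#' `E = N_db * (1 + #\{null >= score\}) / (1 + n_shuffles)` where `N_db` is
#' the proteome size. The smallest attainable E is therefore
#' `N_db / (n_shuffles + 1)`.
#'
#' @param score Observed family score(s).
#' @param proteome Tibble with `protein_id`, `sequence`.
#' @param motifs Motif table.
#' @param n_shuffles Number of residue permutations (default 999).
#' @param seed Integer seed for the permutations.
#' @param core_motifs Core motif indices used for the score.
#' @return E-value(s), one per element of `score`.
#' @export
empirical_evalue <- function(score, proteome, motifs = hsp70_motifs(),
                             n_shuffles = 999, seed = 1,
                             core_motifs = c(1L, 3L, 4L)) {
  stopifnot(n_shuffles >= 1)
  proteome <- as_protein_tbl(proteome)
  null_scores <- null_score_distribution(proteome, motifs, n_shuffles, seed,
                                         core_motifs)
  n_db <- nrow(proteome)
  vapply(score, function(s) {
    n_db * (1 + sum(null_scores >= s)) / (1 + n_shuffles)
  }, numeric(1))
}

null_score_distribution <- function(proteome, motifs, n_shuffles, seed,
                                    core_motifs = c(1L, 3L, 4L)) {
  motifs <- validate_motifs(motifs)
  core <- motifs[motifs$motif %in% core_motifs, ]
  profiles <- lapply(core$consensus, motif_profile)
  codes_list <- lapply(proteome$sequence, aa_codes)
  with_seed(seed, {
    vapply(seq_len(n_shuffles), function(b) {
      codes <- codes_list[[((b - 1) %% length(codes_list)) + 1]]
      hits <- scan_codes(sample(codes), profiles)
      mean(purrr::map_dbl(hits, "match"))
    }, numeric(1))
  })
}

#' Identify family candidates in a proteome
#'
#' Scans every protein for the ten family motifs, scores it on the core
#' motifs, attaches an empirical permutation E-value, and applies the
#' redundancy and domain-completeness filters. A protein is a raw candidate
#' when its E-value passes `evalue_max`; it is accepted when it additionally
#' is neither redundant nor missing a core motif.
#'
#' @param proteome Tibble with `protein_id`, `sequence` (or named vector).
#' @param motifs Motif table as in [hsp70_motifs()].
#' @param annotation Optional gene-locus tibble (`gene_id`, `chromosome`,
#'   `start`, `end`) used for the locus-overlap redundancy rule; gene ids are
#'   matched to protein ids.
#' @param evalue_max E-value acceptance threshold (default 0.1; the empirical
#'   scale bottoms out at `N_db / (n_shuffles + 1)`).
#' @param presence_threshold Best-match fraction needed to call a motif
#'   present (default 0.8).
#' @param core_motifs Core motif indices (default 1, 3, 4).
#' @param n_shuffles Permutations for the null distribution (default 999).
#' @param seed Integer seed for the permutation null.
#' @return An object of class `famscan_identification`: a tibble with one row
#'   per protein (`protein_id`, `score`, `evalue`, `raw_candidate`,
#'   `redundant`, `incomplete`, `verdict`) plus the per-motif scan in
#'   `attr(, "scan")`.
#' @export
identify_family <- function(proteome, motifs = hsp70_motifs(),
                            annotation = NULL, evalue_max = 0.1,
                            presence_threshold = 0.8,
                            core_motifs = c(1L, 3L, 4L),
                            n_shuffles = 999, seed = 1) {
  proteome <- as_protein_tbl(proteome)
  motifs <- validate_motifs(motifs)
  profiles <- lapply(motifs$consensus, motif_profile)
  scan <- purrr::map2_dfr(proteome$protein_id, proteome$sequence,
    function(id, s) {
      hits <- scan_codes(aa_codes(s), profiles)
      frac <- purrr::map_dbl(hits, "match")
      tibble::tibble(
        protein_id = id, motif = motifs$motif,
        start = purrr::map_int(hits, "start"),
        match = frac,
        present = frac >= presence_threshold
      )
    })
  core <- scan[scan$motif %in% core_motifs, ]
  scores <- as.numeric(tapply(core$match,
                              factor(core$protein_id,
                                     levels = proteome$protein_id), mean))
  reports <- tibble::tibble(
    protein_id = proteome$protein_id,
    sequence = proteome$sequence,
    score = scores,
    evalue = empirical_evalue(scores, proteome, motifs, n_shuffles,
                              seed, core_motifs),
    incomplete = purrr::map_lgl(proteome$protein_id, function(id) {
      any(!scan$present[scan$protein_id == id & scan$motif %in% core_motifs])
    })
  )
  reports$raw_candidate <- reports$evalue < evalue_max
  out <- filter_candidates(reports, annotation)
  attr(out, "scan") <- scan
  attr(out, "params") <- list(evalue_max = evalue_max,
                              presence_threshold = presence_threshold,
                              core_motifs = core_motifs,
                              n_shuffles = n_shuffles, seed = seed,
                              redundancy_rule = "identical sequence or >=50% locus overlap")
  class(out) <- c("famscan_identification", class(out))
  out
}

#' Apply redundancy and completeness filters to candidate reports
#'
#' Candidates passing the E-value threshold are processed in decreasing
#' score order (ties by lexicographically smaller id). A candidate is
#' redundant when its sequence is byte-identical to an already accepted one,
#' or when its locus overlaps an accepted candidate's locus by at least 50%
#' of the shorter span. A candidate is incomplete when any core motif is
#' absent. Survivors of both filters are accepted.
#'
#' @param reports Tibble with `protein_id`, `sequence`, `score`, `evalue`,
#'   `raw_candidate`, `incomplete`.
#' @param annotation Optional locus tibble (`gene_id`, `chromosome`, `start`,
#'   `end`).
#' @return The reports tibble with added `redundant` and `verdict` columns,
#'   ordered as input.
#' @export
filter_candidates <- function(reports, annotation = NULL) {
  stopifnot(all(c("protein_id", "sequence", "score", "raw_candidate",
                  "incomplete") %in% names(reports)))
  loci <- NULL
  if (!is.null(annotation)) {
    stopifnot(all(c("gene_id", "chromosome", "start", "end") %in% names(annotation)))
    loci <- annotation
  }
  # radix = byte-wise (C locale) ordering: deterministic across locales
  ord <- order(-reports$score, reports$protein_id, method = "radix")
  redundant <- rep(FALSE, nrow(reports))
  accepted_idx <- integer(0)
  for (i in ord) {
    if (!reports$raw_candidate[i]) next
    dup <- FALSE
    for (j in accepted_idx) {
      if (identical(reports$sequence[i], reports$sequence[j])) { dup <- TRUE; break }
      if (!is.null(loci)) {
        li <- loci[loci$gene_id == reports$protein_id[i], ]
        lj <- loci[loci$gene_id == reports$protein_id[j], ]
        if (nrow(li) == 1 && nrow(lj) == 1 && li$chromosome == lj$chromosome) {
          ov <- min(li$end, lj$end) - max(li$start, lj$start) + 1
          shorter <- min(li$end - li$start + 1, lj$end - lj$start + 1)
          if (ov >= 0.5 * shorter) { dup <- TRUE; break }
        }
      }
    }
    redundant[i] <- dup
    if (!dup && !reports$incomplete[i]) accepted_idx <- c(accepted_idx, i)
  }
  reports$redundant <- redundant
  reports$verdict <- ifelse(
    reports$raw_candidate & !reports$redundant & !reports$incomplete,
    "accept", "reject")
  reports
}

#' @export
print.famscan_identification <- function(x, ...) {
  cat(sprintf(
    "<famscan identification: %d proteins, %d raw candidates, %d accepted>\n",
    nrow(x), sum(x$raw_candidate), sum(x$verdict == "accept")))
  NextMethod()
}
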