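#' Generator configuration
#'
#' Bundles every tunable of the synthetic potato-like genome generator.
#' Defaults are the study conditions the downstream analyses assume: 20
#' true family members at the published coordinates, five decoys (two
#' redundant, three truncated) for 25 raw candidates, three biological
#' replicates, and divergence rates that separate subfamilies from within-
#' subfamily variation.
#'
#' @param seed Top-level integer seed; every stage derives its own stream.
#' @param n_background Background (non-family) genes scattered through the
#'   genome (default 30).
#' @param substitution_rate_within Expected substitutions/site on within-
#'   subfamily branches (default 0.03).
#' @param substitution_rate_between Expected substitutions/site on the
#'   subfamily-ancestor branches (default 0.10).
#' @param motif_conservation Rate multiplier inside motif segments
#'   (default 0.35): conserved motifs evolve slower than linkers.
#' @param cherry_factor Rate multiplier on the terminal branches of planted
#'   sister pairs (default 0.1), keeping cherries tight.
#' @param linker_length_range Length range (aa) of the random inter-motif
#'   linkers (default c(2, 6)).
#' @param fpkm_high,fpkm_low Mean FPKM for expressed / lowly-expressed
#'   cells (defaults 100, 0.2).
#' @param fpkm_noise_sdlog sdlog of the multiplicative log-normal expression
#'   noise (default 0.2).
#' @param ct_effect Planted |ddCT| magnitude in cycles for up/down genes
#'   (default 2, i.e. 4-fold).
#' @param ct_noise_sd SD of the biological-replicate CT noise in cycles
#'   (default 0.15).
#' @param ct_tech_sd SD of the technical-replicate CT noise (default 0.05).
#' @param replicates Biological replicates (default 3, >= 2).
#' @param tech_replicates Technical replicates (default 3).
#' @param introns_follow_text Use the narrative intron reading (StHsp70-10
#'   and -11 intronless) rather than the printed table column
#'   (default TRUE).
#' @param intron_length_range Intron length range in bp (default
#'   c(100, 500)).
#' @return A list of class `famscan_config`.
#' @export
generator_config <- function(seed = 42,
                             n_background = 30,
                             substitution_rate_within = 0.03,
                             substitution_rate_between = 0.10,
                             motif_conservation = 0.35,
                             cherry_factor = 0.1,
                             linker_length_range = c(2, 6),
                             fpkm_high = 100, fpkm_low = 0.2,
                             fpkm_noise_sdlog = 0.2,
                             ct_effect = 2, ct_noise_sd = 0.15,
                             ct_tech_sd = 0.05,
                             replicates = 3, tech_replicates = 3,
                             introns_follow_text = TRUE,
                             intron_length_range = c(100, 500)) {
  rates <- c(substitution_rate_within, substitution_rate_between)
  if (any(rates < 0 | rates > 0.9))
    stop("substitution rates must lie in [0, 0.9]", call. = FALSE)
  if (replicates < 2)
    stop("need at least 2 biological replicates", call. = FALSE)
  structure(as.list(environment()), class = "famscan_config")
}

#' Planted truth of the default synthetic family
#'
#' The ground truth the generator plants and the integration tests recover:
#' family membership, subfamily labels (sizes 10/3/3/1/3 for A-E), decoy
#' kinds (2 redundant + 3 truncated), the five planted sister pairs with
#' intended duplication classes, tissue expression pattern classes, and the
#' per-treatment regulation pattern.
#'
#' @param config A [generator_config()].
#' @return A list of class `famscan_truth`.
#' @export
planted_truth <- function(config = generator_config()) {
  loci <- potato_hsp70_loci()
  members <- loci$gene_id
  subfam <- stats::setNames(loci$subfamily, loci$gene_id)
  decoys <- tibble::tribble(
    ~gene_id,          ~kind,        ~source,      ~lost_motif,
    "decoy-red-1",     "redundant",  "StHsp70-8",  NA_integer_,
    "decoy-red-2",     "redundant",  "StHsp70-17", NA_integer_,
    "decoy-trunc-1",   "truncated",  "StHsp70-7",  1L,
    "decoy-trunc-2",   "truncated",  "StHsp70-12", 3L,
    "decoy-trunc-3",   "truncated",  "StHsp70-9",  4L
  )
  expr_pattern <- stats::setNames(rep("broad", length(members)), members)
  expr_pattern[c("StHsp70-15", "StHsp70-16")] <- "silent"
  expr_pattern["StHsp70-11"] <- "root_tuber"
  expr_pattern["StHsp70-20"] <- "root_tuber_stolon"
  expr_pattern["StHsp70-4"] <- "all_but_stamen"
  expr_pattern[c("StHsp70-10", "StHsp70-14")] <- "vegetative_high"
  structure(list(
    family_members = members,
    subfamily_of = subfam,
    decoys = decoys,
    planted_pairs = hsp70_sister_pairs(),
    expression_pattern = expr_pattern,
    regulation_pattern = regulation_truth(),
    motif_losses = c("StHsp70-6" = 7L, "StHsp70-14" = 8L)
  ), class = "famscan_truth")
}

# The planted regulation pattern: one row per (gene, treatment) with the
# intended direction. Encodes the reported stress/hormone/biotic responses:
# five genes up and four down under all four abiotic stresses, changed-gene
# counts 6/8/8/4 under IAA/ABA/GA3/SA, and the named single responders.
regulation_truth <- function() {
  g <- function(i) paste0("StHsp70-", i)
  pat <- tidyr::expand_grid(
    gene_id = g(1:20),
    treatment = unlist(hsp70_treatments()[c("abiotic", "hormone", "biotic")],
                       use.names = FALSE))
  pat$direction <- "unchanged"
  set_dir <- function(pat, genes, treatments, dir) {
    sel <- pat$gene_id %in% genes & pat$treatment %in% treatments
    pat$direction[sel] <- dir
    pat
  }
  ab <- hsp70_treatments()$abiotic
  pat <- set_dir(pat, g(c(1, 8, 9, 10, 17)), ab, "up")
  pat <- set_dir(pat, g(c(2, 4, 13, 18)), ab, "down")
  pat <- set_dir(pat, g(7), "drought", "up")
  pat <- set_dir(pat, g(7), c("salt", "heat", "cold"), "down")
  pat <- set_dir(pat, g(11), c("salt", "drought"), "up")
  pat <- set_dir(pat, g(16), c("drought", "cold"), "up")
  pat <- set_dir(pat, g(20), c("drought", "heat", "cold"), "up")
  pat <- set_dir(pat, g(19), c("heat", "cold"), "down")
  pat <- set_dir(pat, g(8), c("IAA", "ABA", "GA3"), "up")
  pat <- set_dir(pat, g(c(7, 17)), c("ABA", "GA3"), "up")
  pat <- set_dir(pat, g(17), "SA", "up")
  pat <- set_dir(pat, g(c(2, 4, 13, 18, 5)), "IAA", "down")
  pat <- set_dir(pat, g(c(2, 4, 13, 18, 12)), "ABA", "down")
  pat <- set_dir(pat, g(c(2, 4, 13, 18, 6)), "GA3", "down")
  pat <- set_dir(pat, g(c(2, 4, 18)), "SA", "down")
  pat <- set_dir(pat, g(12), "P.infestans", "up")
  pat <- set_dir(pat, g(setdiff(1:20, c(15, 16, 20))), "BAP", "down")
  pat <- set_dir(pat, g(c(1, 2, 3, 4, 5, 6, 7, 9, 10)), "BABA", "down")
  pat <- set_dir(pat, g(c(8, 11, 12, 13, 17)), "BABA", "up")
  pat <- set_dir(pat, g(c(1, 2, 3, 4, 6, 7, 9, 13, 18)), "BTH", "down")
  pat
}

# Segment representation: tibble(kind, motif, seq) in N->C order.
scaffold_segments <- function(motifs, seed, linker_length_range,
                              order = c(7, 9, 1, 4, 2, 3, 5, 10, 6, 8),
                              tail_length = NULL) {
  motifs <- validate_motifs(motifs)
  with_seed(seed, {
    resolve <- function(consensus) {
      chars <- strsplit(consensus, "")[[1]]
      amb <- chars %in% names(AA_AMBIGUITY)
      chars[amb] <- vapply(chars[amb], function(cc) {
        sample(AA_AMBIGUITY[[cc]], 1)
      }, character(1))
      paste(chars, collapse = "")
    }
    rand_linker <- function() {
      n <- sample(seq(linker_length_range[1], linker_length_range[2]), 1)
      if (n == 0) "" else random_protein(n)
    }
    segs <- list(tibble::tibble(kind = "linker", motif = NA_integer_,
                                seq = rand_linker()))
    for (m in order) {
      cons <- motifs$consensus[motifs$motif == m]
      segs <- c(segs,
                list(tibble::tibble(kind = "motif", motif = as.integer(m),
                                    seq = resolve(cons))),
                list(tibble::tibble(kind = "linker", motif = NA_integer_,
                                    seq = rand_linker())))
    }
    segs <- dplyr::bind_rows(segs)
    # The final linker is the variable C-terminal tail. It is generated once
    # here, inherited (and mutated) down the family topology, and trimmed per
    # member, so sister sequences share their tails. By default it pads the
    # scaffold to the family's maximum length.
    if (is.null(tail_length))
      tail_length <- max(0, 890 - sum(nchar(segs$seq)))
    segs$seq[nrow(segs)] <- if (tail_length == 0) "" else
      random_protein(tail_length)
    segs
  })
}

#' Build the family scaffold protein
#'
#' Concatenates one resolved instance of each of the ten motifs, in the
#' domain order of the family architecture (ATPase-domain motifs 7, 9, 1,
#' 4, 2, 3, then substrate-binding/lid motifs 5, 10, 6, 8), joined by
#' random linkers. Ambiguity letters are resolved uniformly at random among
#' their allowed residues.
#'
#' @param motifs Motif table as in [hsp70_motifs()]; all ten required.
#' @param seed Integer seed.
#' @param linker_length_range Linker length range in aa.
#' @param order Motif order along the scaffold.
#' @param tail_length Length of the C-terminal tail linker; by default pads
#'   the scaffold to the family's maximum length (890 aa). With
#'   `tail_length = 0` and `linker_length_range = c(0, 0)` the scaffold
#'   length equals the summed motif widths.
#' @return A list of class `famscan_scaffold`: `sequence`, `segments`
#'   (tibble of kind/motif/seq in order).
#' @export
build_scaffold <- function(motifs = hsp70_motifs(), seed = 42,
                           linker_length_range = c(2, 6),
                           order = c(7, 9, 1, 4, 2, 3, 5, 10, 6, 8),
                           tail_length = NULL) {
  segs <- scaffold_segments(motifs, seed, linker_length_range, order,
                            tail_length)
  structure(list(sequence = paste(segs$seq, collapse = ""),
                 segments = segs),
            class = "famscan_scaffold")
}

# Substitute each residue independently with probability rate (motif
# segments attenuated by `conservation`).
mutate_segments <- function(segs, rate, conservation = 1) {
  if (rate == 0) return(segs)
  segs$seq <- purrr::map2_chr(segs$seq, segs$kind, function(s, kind) {
    if (nchar(s) == 0) return(s)
    r <- if (kind == "motif") rate * conservation else rate
    chars <- strsplit(s, "")[[1]]
    hit <- stats::runif(length(chars)) < r
    if (any(hit)) {
      chars[hit] <- vapply(chars[hit], function(old) {
        sample(setdiff(AA_STANDARD, old), 1)
      }, character(1))
    }
    paste(chars, collapse = "")
  })
  segs
}

# Fit a member's segments to the target length: extend the C-terminal tail
# with random residues, or trim linkers from the C-terminal end inward.
fit_length <- function(segs, target) {
  cur <- sum(nchar(segs$seq))
  if (cur < target) {
    segs$seq[nrow(segs)] <- paste0(segs$seq[nrow(segs)],
                                   random_protein(target - cur))
  } else if (cur > target) {
    excess <- cur - target
    for (i in rev(seq_len(nrow(segs)))) {
      if (excess == 0) break
      if (segs$kind[i] != "linker") next
      cut <- min(excess, nchar(segs$seq[i]))
      if (cut > 0) {
        segs$seq[i] <- substr(segs$seq[i], 1, nchar(segs$seq[i]) - cut)
        excess <- excess - cut
      }
    }
    if (excess > 0)
      stop("cannot fit member to target length without cutting motifs",
           call. = FALSE)
  }
  segs
}

#' Evolve the family members from the scaffold
#'
#' Simulates divergence along the planted subfamily topology: a star of
#' subfamily ancestors around the scaffold, with planted sister pairs
#' descending from shared cherry ancestors on shortened branches.
#' Substitutions are i.i.d. per site; motif segments evolve at an
#' attenuated rate (`motif_conservation`). The subfamily-specific motif
#' losses are applied (StHsp70-6 loses motif 7, StHsp70-14 motif 8), and
#' every member's length is matched to its published protein length by
#' linker adjustment.
#'
#' @param scaffold A [build_scaffold()] result.
#' @param truth A [planted_truth()] result.
#' @param config A [generator_config()].
#' @return Tibble with `protein_id`, `sequence`, `subfamily` and a
#'   list-column `segments`.
#' @export
evolve_family <- function(scaffold, truth = planted_truth(config),
                          config = generator_config()) {
  rates <- c(config$substitution_rate_within,
             config$substitution_rate_between)
  if (any(rates < 0 | rates > 0.9))
    stop("substitution rates must lie in [0, 0.9]", call. = FALSE)
  loci <- potato_hsp70_loci()
  stopifnot(setequal(truth$family_members, loci$gene_id))
  target_len <- stats::setNames(loci$length_aa, loci$gene_id)
  with_seed(derive_seed(config$seed, "evolve_family"), {
    members <- list()
    for (sf in sort(unique(truth$subfamily_of))) {
      ids <- names(truth$subfamily_of)[truth$subfamily_of == sf]
      anc <- mutate_segments(scaffold$segments,
                             config$substitution_rate_between,
                             config$motif_conservation)
      pairs <- truth$planted_pairs
      pairs <- pairs[pairs$gene_a %in% ids & pairs$gene_b %in% ids, ]
      done <- character(0)
      if (nrow(pairs) > 0) {
        for (p in seq_len(nrow(pairs))) {
          cherry_anc <- mutate_segments(anc, config$substitution_rate_within,
                                        config$motif_conservation)
          for (id in c(pairs$gene_a[p], pairs$gene_b[p])) {
            members[[id]] <- mutate_segments(
              cherry_anc,
              config$substitution_rate_within * config$cherry_factor,
              config$motif_conservation)
            done <- c(done, id)
          }
        }
      }
      for (id in setdiff(ids, done)) {
        members[[id]] <- mutate_segments(anc,
                                         config$substitution_rate_within,
                                         config$motif_conservation)
      }
    }
    out <- purrr::map_dfr(names(truth$subfamily_of), function(id) {
      segs <- members[[id]]
      if (id %in% names(truth$motif_losses)) {
        lost <- truth$motif_losses[[id]]
        segs <- segs[!(segs$kind == "motif" & segs$motif == lost), ]
      }
      segs <- fit_length(segs, target_len[[id]])
      tibble::tibble(protein_id = id,
                     sequence = paste(segs$seq, collapse = ""),
                     subfamily = truth$subfamily_of[[id]],
                     segments = list(segs))
    })
    out
  })
}

# Build exon coordinates for a CDS of cds_len bp starting at `start`, with
# `n_introns` introns of lengths sampled from `intron_range`.
make_exons <- function(start, cds_len, n_introns, intron_range) {
  if (n_introns == 0) {
    return(tibble::tibble(start = start, end = start + cds_len - 1))
  }
  breaks <- sort(sample(seq_len(cds_len - 1), n_introns))
  exon_lens <- diff(c(0, breaks, cds_len))
  intron_lens <- sample(seq(intron_range[1], intron_range[2]), n_introns,
                        replace = TRUE)
  starts <- integer(n_introns + 1)
  ends <- integer(n_introns + 1)
  pos <- start
  for (i in seq_len(n_introns + 1)) {
    starts[i] <- pos
    ends[i] <- pos + exon_lens[i] - 1
    pos <- ends[i] + 1
    if (i <= n_introns) pos <- pos + intron_lens[i]
  }
  tibble::tibble(start = starts, end = ends)
}

#' Place family members, decoys and background genes on the genome
#'
#' True members are placed at the published chromosome/kb coordinates (kb
#' x 1000, 1-based, strand +) with their published intron counts; introns
#' fall uniformly at random inside the CDS with lengths in the configured
#' range. Background genes are interleaved, including two inside each
#' planted tandem gap so the intervening-gene rule is exercised, and five
#' decoy loci are added: two exact-duplicate (redundant) copies and three
#' truncated copies each missing one core motif.
#'
#' @param members Member tibble from [evolve_family()].
#' @param truth A [planted_truth()].
#' @param config A [generator_config()].
#' @return A list of class `famscan_genome`: `chromosomes`, `genes` (with
#'   exon list-column, CDS and role), `proteins`, `truth`.
#' @export
place_genes <- function(members, truth = planted_truth(config),
                        config = generator_config()) {
  loci <- potato_hsp70_loci()
  intron_col <- if (config$introns_follow_text) loci$intron_text else
    loci$intron_table
  introns <- stats::setNames(intron_col, loci$gene_id)
  seqs <- stats::setNames(members$sequence, members$protein_id)
  with_seed(derive_seed(config$seed, "place_genes"), {
    gene_rows <- list()
    add_gene <- function(id, chrom, start, protein, n_introns, role) {
      cds <- reverse_translate(protein)
      exons <- make_exons(start, nchar(cds), n_introns,
                          config$intron_length_range)
      exons <- validate_exons(exons, id)
      gene_rows[[id]] <<- tibble::tibble(
        gene_id = id, chromosome = chrom, start = start,
        end = max(exons$end), strand = "+", role = role,
        protein = protein, cds = cds, exons = list(exons))
    }
    for (i in seq_len(nrow(loci))) {
      id <- loci$gene_id[i]
      add_gene(id, loci$chromosome[i], loci$start_bp[i], seqs[[id]],
               introns[[id]], "family")
    }
    # decoys: 2 redundant exact copies + 3 truncated copies
    decoy_chrom <- c(4L, 10L, 2L, 5L, 8L)
    decoy_start <- c(30e6, 20e6, 15e6, 25e6, 10e6)
    motifs <- hsp70_motifs()
    for (d in seq_len(nrow(truth$decoys))) {
      dk <- truth$decoys[d, ]
      src <- seqs[[dk$source]]
      if (dk$kind == "redundant") {
        prot <- src
      } else {
        scan <- scan_protein(c(x = src), motifs)
        hit <- scan[scan$motif == dk$lost_motif, ]
        w <- motifs$width[motifs$motif == dk$lost_motif]
        prot <- paste0(substr(src, 1, hit$start - 1),
                       substr(src, hit$start + w, nchar(src)))
      }
      add_gene(dk$gene_id, decoy_chrom[d], as.integer(decoy_start[d]),
               prot, sample(0:2, 1), "decoy")
    }
    # background genes: two inside each tandem gap, the rest on a grid
    bg_id <- 0
    add_background <- function(chrom, start, len_aa, n_introns = NULL) {
      bg_id <<- bg_id + 1
      if (is.null(n_introns)) n_introns <- sample(0:3, 1)
      add_gene(sprintf("bg-%03d", bg_id), chrom, as.integer(start),
               random_protein(len_aa), n_introns, "background")
    }
    for (p in seq_len(nrow(truth$planted_pairs))) {
      pr <- truth$planted_pairs[p, ]
      if (pr$class != "tandem") next
      la <- loci[loci$gene_id == pr$gene_a, ]
      lb <- loci[loci$gene_id == pr$gene_b, ]
      lo_row <- if (la$start_bp < lb$start_bp) la else lb
      hi_row <- if (la$start_bp < lb$start_bp) lb else la
      lo_end <- lo_row$start_bp + orf_length(lo_row$length_aa) + 3000
      gap <- hi_row$start_bp - lo_end
      for (off in c(0.35, 0.65)) {
        add_background(la$chromosome, lo_end + round(off * gap), 220,
                       n_introns = 0)
      }
    }
    n_grid <- config$n_background - bg_id
    if (n_grid > 0) {
      chroms <- rep(1:12, length.out = n_grid)
      for (i in seq_len(n_grid)) {
        add_background(chroms[i], 1e6 + (i - 1) %/% 12 * 3e6 +
                         sample(0:5e5, 1), sample(200:500, 1))
      }
    }
    genes <- dplyr::bind_rows(gene_rows)
    if (anyDuplicated(genes$gene_id)) stop("duplicate gene ids")
    chromosomes <- tibble::tibble(name = 1:12, length = 9e7)
    if (any(genes$end > 9e7))
      stop("gene exceeds chromosome bounds", call. = FALSE)
    proteins <- tibble::tibble(protein_id = genes$gene_id,
                               sequence = genes$protein,
                               role = genes$role)
    structure(list(chromosomes = chromosomes, genes = genes,
                   proteins = proteins, truth = truth, config = config),
              class = "famscan_genome")
  })
}

#' @export
print.famscan_genome <- function(x, ...) {
  cat(sprintf(paste0("<famscan synthetic genome: %d chromosomes, ",
                     "%d genes (%d family, %d decoy, %d background)>\n"),
              nrow(x$chromosomes), nrow(x$genes),
              sum(x$genes$role == "family"), sum(x$genes$role == "decoy"),
              sum(x$genes$role == "background")))
  invisible(x)
}

#' Simulate the full synthetic genome bundle
#'
#' Scaffold construction, family divergence and gene placement in one call.
#'
#' @param config A [generator_config()].
#' @return A `famscan_genome` bundle.
#' @export
#' @examples
#' \donttest{
#' bundle <- simulate_genome(generator_config(seed = 1))
#' bundle
#' }
simulate_genome <- function(config = generator_config()) {
  scaffold <- build_scaffold(hsp70_motifs(),
                             seed = derive_seed(config$seed, "scaffold"),
                             linker_length_range = config$linker_length_range)
  truth <- planted_truth(config)
  members <- evolve_family(scaffold, truth, config)
  place_genes(members, truth, config)
}

# Tissue mean-FPKM profile for one expression pattern class.
pattern_means <- function(pattern, tissues, high, low) {
  m <- stats::setNames(rep(0, length(tissues)), tissues)
  switch(pattern,
    broad = m[] <- high,
    silent = m[] <- low / 2,
    root_tuber = m[c("root", "tuber")] <- high,
    root_tuber_stolon = m[c("root", "tuber", "stolon")] <- high,
    all_but_stamen = m[setdiff(tissues, "stamen")] <- high,
    vegetative_high = {
      m[] <- low
      m[c("root", "tuber", "stolon", "leaf")] <- high
    },
    stop("unknown expression pattern: ", pattern))
  m
}

#' Simulate the tissue expression matrix
#'
#' FPKM for every family member across the eleven atlas tissues, honouring
#' the planted pattern classes (two near-silent members, one expressed only
#' in root+tuber, one only in root+tuber+stolon, one everywhere but the
#' stamen, two high in vegetative tissues) with multiplicative log-normal
#' noise. Cells with zero mean stay exactly zero; values are never
#' negative.
#'
#' @param bundle A `famscan_genome` from [simulate_genome()].
#' @param config A [generator_config()]; defaults to the bundle's.
#' @param tissues Tissue names (default [hsp70_tissues()]).
#' @return Tibble with `gene_id` and one FPKM column per tissue.
#' @export
simulate_expression <- function(bundle, config = bundle$config,
                                tissues = hsp70_tissues()) {
  if (length(tissues) == 0) stop("tissue list is empty", call. = FALSE)
  truth <- bundle$truth
  with_seed(derive_seed(config$seed, "expression"), {
    rows <- purrr::map_dfr(truth$family_members, function(id) {
      mu <- pattern_means(truth$expression_pattern[[id]], tissues,
                          config$fpkm_high, config$fpkm_low)
      noise <- if (config$fpkm_noise_sdlog > 0) {
        stats::rlnorm(length(mu), meanlog = 0,
                      sdlog = config$fpkm_noise_sdlog)
      } else rep(1, length(mu))
      vals <- pmax(mu * noise, 0)
      dplyr::bind_cols(tibble::tibble(gene_id = id),
                       tibble::as_tibble(as.list(vals)))
    })
    rows
  })
}

#' Simulate replicate CT tables for the qPCR design
#'
#' Reference-gene CT is constant in expectation across treatments; the
#' target CT of genes planted up (down) under a treatment is shifted by
#' `-ct_effect` (`+ct_effect`) cycles relative to control, so the expected
#' fold change is `2^ct_effect` (`2^-ct_effect`). Gaussian noise is added
#' per biological replicate (shared by that replicate's technical
#' replicates) and per technical replicate.
#'
#' @param bundle A `famscan_genome`.
#' @param design Treatment design (default [hsp70_treatments()]); the
#'   control is always included.
#' @param config A [generator_config()]; `replicates` must be >= 2.
#' @return CT tibble with columns `gene_id`, `treatment`, `bio_rep`,
#'   `tech_rep`, `ct_target`, `ct_reference`, `reference_gene`.
#' @export
simulate_ct <- function(bundle, design = hsp70_treatments(),
                        config = bundle$config) {
  if (config$replicates < 2)
    stop("need at least 2 biological replicates", call. = FALSE)
  treatments <- unlist(design[c("abiotic", "hormone", "biotic")],
                       use.names = FALSE)
  pat <- bundle$truth$regulation_pattern
  pat <- pat[pat$treatment %in% treatments, ]
  genes <- bundle$truth$family_members
  with_seed(derive_seed(config$seed, "qpcr"), {
    base_dct <- stats::setNames(stats::runif(length(genes), 3, 8), genes)
    grid <- tidyr::expand_grid(gene_id = genes,
                               treatment = c("control", treatments),
                               bio_rep = seq_len(config$replicates),
                               tech_rep = seq_len(config$tech_replicates))
    key <- paste(grid$gene_id, grid$treatment)
    dir <- stats::setNames(pat$direction, paste(pat$gene_id, pat$treatment))
    shift <- dplyr::case_when(
      grid$treatment == "control" ~ 0,
      dir[key] == "up" ~ -config$ct_effect,
      dir[key] == "down" ~ config$ct_effect,
      TRUE ~ 0)
    bio_key <- paste(grid$gene_id, grid$treatment, grid$bio_rep)
    ubio <- unique(bio_key)
    bio_noise <- stats::setNames(
      stats::rnorm(length(ubio), 0, config$ct_noise_sd), ubio)
    grid$ct_reference <- 20 +
      stats::rnorm(nrow(grid), 0, config$ct_tech_sd)
    grid$ct_target <- grid$ct_reference + base_dct[grid$gene_id] + shift +
      bio_noise[bio_key] + stats::rnorm(nrow(grid), 0, config$ct_tech_sd)
    grid$reference_gene <- "EF1a"
    grid
  })
}
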