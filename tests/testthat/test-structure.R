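ex_tbl <- function(...) {
  lens <- c(...)
  starts <- cumsum(c(1, head(lens, -1) + 200)) # 200 bp introns between
  tibble::tibble(start = starts, end = starts + lens - 1)
}

test_that("intron count is exons minus one", {
  expect_identical(intron_count(ex_tbl(300)), 0L)
  expect_identical(intron_count(ex_tbl(300, 150, 99)), 2L)
  expect_error(intron_count(tibble::tibble(start = integer(0),
                                           end = integer(0))),
               "zero exons")
  # merging two abutting exons lowers the count by one
  ex <- tibble::tibble(start = c(1, 301), end = c(300, 450))
  merged <- tibble::tibble(start = 1, end = 450)
  expect_identical(intron_count(ex) - intron_count(merged), 1L)
  expect_error(intron_count(tibble::tibble(start = c(1, 50),
                                           end = c(100, 120))),
               "overlapping")
})

test_that("splice phases are cumulative coding length mod 3", {
  expect_identical(splice_phases(ex_tbl(300, 150)), 0L)
  expect_identical(splice_phases(ex_tbl(301, 149)), 1L)
  expect_identical(splice_phases(ex_tbl(100, 101, 99)), c(1L, 0L))
  expect_error(splice_phases(ex_tbl(300, 100)), "divisible by 3")
  # translation invariance
  ex <- ex_tbl(233, 301, 120)
  shifted <- dplyr::mutate(ex, start = start + 1000, end = end + 1000)
  expect_identical(splice_phases(ex), splice_phases(shifted))
})

test_that("minus-strand genes mirror the exon order", {
  ex <- ex_tbl(300, 150)
  expect_identical(splice_phases(ex, strand = "-"),
                   as.integer(150 %% 3))
  expect_identical(intron_count(ex), intron_count(ex))
})

test_that("GFF3 CDS phase is the complement of the intron phase", {
  expect_identical(intron_phase_to_gff(c(0L, 1L, 2L)), c(0L, 0L, 2L, 1L))
  expect_identical(intron_phase_to_gff(integer(0)), 0L)
})

test_that("reference coordinates occupy 10 of 12 chromosomes", {
  loci <- potato_hsp70_loci()
  dist <- chromosome_distribution(
    tibble::tibble(gene_id = loci$gene_id, chromosome = loci$chromosome))
  expect_identical(attr(dist, "n_occupied"), 10L)
  expect_identical(dist$n_genes[dist$chromosome == 1], 4L)
  expect_identical(dist$n_genes[dist$chromosome == 12], 3L)
  expect_identical(dist$n_genes[dist$chromosome == 2], 0L)
  expect_identical(dist$n_genes[dist$chromosome == 5], 0L)
  expect_identical(sum(dist$n_genes), nrow(loci))
})

test_that("chromosome distribution handles edge cases", {
  empty <- chromosome_distribution(tibble::tibble(gene_id = character(0),
                                                  chromosome = integer(0)))
  expect_true(all(empty$n_genes == 0))
  expect_error(chromosome_distribution(
    tibble::tibble(gene_id = "g", chromosome = "chr13")), "unknown")
})

test_that("structure report matches the published intron counts", {
  b <- fam_bundle()
  fam <- b$genes[b$genes$role == "family", ]
  rep <- structure_report(fam)
  loci <- potato_hsp70_loci()
  want <- setNames(loci$intron_text, loci$gene_id)
  got <- setNames(rep$intron_count, rep$gene_id)
  expect_identical(got[names(want)], want)
  expect_identical(got[["StHsp70-14"]], 0L)
  expect_identical(got[["StHsp70-18"]], 7L)
  expect_identical(got[["StHsp70-10"]], 0L) # narrative reading
  expect_true(all(unlist(rep$phases) %in% 0:2))
})

test_that("the printed intron column is available as an alternative", {
  cfg <- generator_config(seed = 4, introns_follow_text = FALSE)
  b <- simulate_genome(cfg)
  rep <- structure_report(b$genes[b$genes$gene_id == "StHsp70-10", ])
  expect_identical(rep$intron_count, 1L)
})

test_that("motif presence matrix reproduces the published pattern", {
  pres <- motif_presence_matrix(fam_accepted())
  expect_true(all(pres$motif_1 & pres$motif_3 & pres$motif_4))
  expect_false(pres$motif_7[pres$protein_id == "StHsp70-6"])
  expect_false(pres$motif_8[pres$protein_id == "StHsp70-14"])
  # threshold 0 trivially marks everything present
  all_true <- motif_presence_matrix(fam_accepted()[1:3, ], threshold = 0)
  expect_true(all(as.matrix(all_true[, -1])))
})

test_that("same-subfamily members share presence rows at zero rate", {
  cfg <- generator_config(seed = 9, substitution_rate_within = 0,
                          substitution_rate_between = 0)
  b <- simulate_genome(cfg)
  fam <- b$proteins[b$proteins$role == "family", c("protein_id", "sequence")]
  pres <- motif_presence_matrix(fam)
  sf <- b$truth$subfamily_of
  rows <- apply(as.matrix(pres[, -1]), 1, paste, collapse = "")
  names(rows) <- pres$protein_id
  for (s in unique(sf)) {
    ids <- names(sf)[sf == s]
    ids <- setdiff(ids, names(b$truth$motif_losses))
    if (length(ids) > 1) expect_identical(unname(rows[ids]),
                                          rep(rows[[ids[1]]], length(ids)))
  }
})
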