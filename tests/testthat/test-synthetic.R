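test_that("scaffold with zero-length linkers is the motif concatenation", {
  sc <- build_scaffold(seed = 3, linker_length_range = c(0, 0),
                       tail_length = 0)
  expect_identical(nchar(sc$sequence), sum(hsp70_motifs()$width))
  scan <- scan_protein(c(x = sc$sequence))
  expect_true(all(scan$present))
})

test_that("motif widths equal their consensus-string lengths", {
  motifs <- hsp70_motifs()
  expect_identical(motifs$width, nchar(motifs$consensus))
  expect_identical(motifs$width[1], 50L)
  expect_true(all(motifs$width >= 6 & motifs$width <= 200))
})

test_that("scaffold construction is deterministic in the seed", {
  expect_identical(build_scaffold(seed = 17)$sequence,
                   build_scaffold(seed = 17)$sequence)
  expect_false(build_scaffold(seed = 17)$sequence ==
                 build_scaffold(seed = 18)$sequence)
})

test_that("an incomplete motif list is rejected with the missing indices", {
  expect_error(build_scaffold(motifs = hsp70_motifs()[-c(2, 5), ]),
               "missing motif.*2, 5")
})

test_that("zero substitution rates reproduce the scaffold up to edits", {
  cfg <- generator_config(seed = 9, substitution_rate_within = 0,
                          substitution_rate_between = 0)
  sc <- build_scaffold(seed = derive_seed(cfg$seed, "scaffold"),
                       linker_length_range = cfg$linker_length_range)
  members <- evolve_family(sc, config = cfg)
  # members are scaffold prefixes (trimmed tails), except motif deletions
  plain <- members[!members$protein_id %in% c("StHsp70-6", "StHsp70-14"), ]
  for (i in seq_len(nrow(plain))) {
    expect_identical(plain$sequence[i],
                     substr(sc$sequence, 1, nchar(plain$sequence[i])))
  }
  expect_error(generator_config(substitution_rate_within = 0.95),
               "0, 0.9")
})

test_that("generated member lengths match the published extremes", {
  b <- fam_bundle()
  lens <- nchar(b$proteins$sequence[b$proteins$role == "family"])
  expect_identical(max(lens), 890L)
  expect_identical(min(lens), 486L)
  loci <- potato_hsp70_loci()
  got <- setNames(nchar(b$proteins$sequence), b$proteins$protein_id)
  expect_identical(unname(got[loci$gene_id]), as.integer(loci$length_aa))
})

test_that("within-subfamily identity exceeds between-subfamily identity", {
  b <- fam_bundle()
  seqs <- setNames(b$proteins$sequence, b$proteins$protein_id)
  sf <- b$truth$subfamily_of
  within <- c(smith_waterman(seqs[["StHsp70-7"]], seqs[["StHsp70-8"]])$identity,
              smith_waterman(seqs[["StHsp70-18"]], seqs[["StHsp70-20"]])$identity,
              smith_waterman(seqs[["StHsp70-1"]], seqs[["StHsp70-4"]])$identity)
  between <- c(smith_waterman(seqs[["StHsp70-7"]], seqs[["StHsp70-18"]])$identity,
               smith_waterman(seqs[["StHsp70-1"]], seqs[["StHsp70-2"]])$identity,
               smith_waterman(seqs[["StHsp70-14"]], seqs[["StHsp70-8"]])$identity)
  expect_gt(mean(within), mean(between))
})

test_that("gene placement reproduces the published chromosome layout", {
  b <- fam_bundle()
  fam <- b$genes[b$genes$role == "family", ]
  expect_identical(sum(fam$chromosome == 2), 0L)
  expect_identical(sum(fam$chromosome == 5), 0L)
  expect_identical(sum(fam$chromosome == 1), 4L)
  ex14 <- fam$exons[fam$gene_id == "StHsp70-14"][[1]]
  expect_identical(nrow(ex14), 1L)
  expect_true(all(fam$end <= 9e7 & fam$start >= 1))
  expect_false(anyDuplicated(b$genes$gene_id) > 0)
})

test_that("translated CDS equals the protein for every gene and seed", {
  for (seed in c(42, 7)) {
    b <- if (seed == 42) fam_bundle() else
      simulate_genome(generator_config(seed = seed))
    ok <- vapply(seq_len(nrow(b$genes)), function(i) {
      translate_cds(b$genes$cds[i]) == b$genes$protein[i]
    }, logical(1))
    expect_true(all(ok))
    # exon lengths sum to the CDS length
    ok2 <- vapply(seq_len(nrow(b$genes)), function(i) {
      ex <- b$genes$exons[[i]]
      sum(ex$end - ex$start + 1) == nchar(b$genes$cds[i])
    }, logical(1))
    expect_true(all(ok2))
  }
})

test_that("noise-free expression equals the pattern means exactly", {
  cfg <- generator_config(seed = 5, fpkm_noise_sdlog = 0)
  b <- simulate_genome(cfg)
  ex <- simulate_expression(b, cfg)
  m <- as.matrix(ex[, -1]); rownames(m) <- ex$gene_id
  expect_true(all(m >= 0))
  expect_setequal(unique(as.numeric(m)),
                  c(0, cfg$fpkm_low / 2, cfg$fpkm_low, cfg$fpkm_high))
  expect_identical(as.numeric(m["StHsp70-11", ]),
                   ifelse(colnames(m) %in% c("root", "tuber"),
                          cfg$fpkm_high, 0))
})

test_that("planted tissue patterns survive multiplicative noise", {
  ex <- fam_expression()
  m <- as.matrix(ex[, -1]); rownames(m) <- ex$gene_id
  expect_true(all(m >= 0))
  expect_identical(sum(m["StHsp70-11", ] > 0 & colnames(m) %in%
                         c("root", "tuber")), 2L)
  expect_true(all(m["StHsp70-11", !colnames(m) %in% c("root", "tuber")] == 0))
})

test_that("CT simulation plants the configured fold changes", {
  cfg <- generator_config(seed = 13, ct_noise_sd = 0, ct_tech_sd = 0)
  b <- simulate_genome(cfg)
  ct <- simulate_ct(b, config = cfg)
  d <- delta_ct(ct)
  # a planted 4-fold (ct_effect = 2) up gene: treated dCT lower by 2 cycles
  d1 <- d[d$gene_id == "StHsp70-1", ]
  expect_equal(unique(d1$delta_ct[d1$treatment == "salt"]) -
                 unique(d1$delta_ct[d1$treatment == "control"]),
               -cfg$ct_effect)
  # noise-free folds follow the 2^-ddCT inversion exactly
  expect_equal(fold_change(mean(d1$delta_ct[d1$treatment == "salt"]),
                           mean(d1$delta_ct[d1$treatment == "control"])),
               2^cfg$ct_effect)
  # zero effect, low noise: every call is unchanged
  cfg0 <- generator_config(seed = 13, ct_noise_sd = 0.05, ct_effect = 0)
  ct0 <- simulate_ct(b, config = cfg0)
  calls0 <- regulation_calls(ct0, fold_min = 1.5)
  expect_true(all(calls0$call == "unchanged"))
  expect_true(all(abs(log2(calls0$fold)) < 0.5))
  cfg_bad <- generator_config(seed = 1)
  cfg_bad$replicates <- 1
  expect_error(simulate_ct(b, config = cfg_bad), "replicates")
})

test_that("generator output files are byte-identical across reruns", {
  d1 <- file.path(tempdir(), "genA"); d2 <- file.path(tempdir(), "genB")
  cfg <- generator_config(seed = 3)
  b1 <- simulate_genome(cfg); b2 <- simulate_genome(cfg)
  p1 <- write_genome_files(b1, d1, expression = simulate_expression(b1, cfg),
                           ct = simulate_ct(b1, config = cfg))
  p2 <- write_genome_files(b2, d2, expression = simulate_expression(b2, cfg),
                           ct = simulate_ct(b2, config = cfg))
  for (k in setdiff(names(p1), "gff")) { # gff header carries a date stamp
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]))
  }
  g1 <- readLines(p1[["gff"]]); g2 <- readLines(p2[["gff"]])
  expect_identical(g1[!grepl("^##date", g1)], g2[!grepl("^##date", g2)])
})
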