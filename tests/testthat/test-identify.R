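test_that("match_fraction honours exact matches and ambiguity codes", {
  m <- list(width = 3L, consensus = "JAY")
  expect_equal(match_fraction("IAY", m), 1)
  expect_equal(match_fraction("LAY", m), 1)
  expect_equal(match_fraction("VAY", m), 2 / 3)
  motif1 <- hsp70_motifs()[1, ]
  window <- gsub("J", "I", motif1$consensus)
  expect_equal(match_fraction(window, motif1), 1)
  expect_error(match_fraction("AA", m), "width")
})

test_that("random windows match a no-ambiguity motif at the 1/20 rate", {
  motif7 <- hsp70_motifs()[7, ] # no ambiguity letters
  set.seed(21)
  fracs <- replicate(2000, match_fraction(random_aa(motif7$width), motif7))
  expect_equal(mean(fracs), 1 / 20, tolerance = 0.1)
  expect_lt(abs(mean(fracs) - 0.05), 0.005)
})

test_that("scan_protein finds all planted motifs on the scaffold", {
  sc <- build_scaffold(seed = 5)
  scan <- scan_protein(c(scaffold = sc$sequence))
  expect_identical(nrow(scan), 10L)
  expect_true(all(scan$match == 1))
  expect_true(all(scan$present))
  expect_error(scan_protein(c(x = "MK")), "smallest motif")
})

test_that("planted motif losses are invisible to the scan", {
  b <- fam_bundle()
  seqs <- setNames(b$proteins$sequence, b$proteins$protein_id)
  s6 <- scan_protein(c(`StHsp70-6` = seqs[["StHsp70-6"]]))
  expect_false(s6$present[s6$motif == 7])
  s14 <- scan_protein(c(`StHsp70-14` = seqs[["StHsp70-14"]]))
  expect_false(s14$present[s14$motif == 8])
  # truncated decoy lacks its excised core motif
  trunc <- scan_protein(c(d = seqs[["decoy-trunc-1"]]))
  expect_false(trunc$present[trunc$motif == 1])
})

test_that("family score is the core-motif mean and is monotone", {
  sc <- build_scaffold(seed = 5)
  scan <- scan_protein(c(x = sc$sequence))
  expect_equal(family_score(scan), 1)
  # restoring a degraded core-motif instance toward consensus never lowers
  # the score
  motifs <- hsp70_motifs()
  hit <- scan[scan$motif == 1, ]
  cons <- strsplit(motifs$consensus[1], "")[[1]]
  chars <- strsplit(sc$sequence, "")[[1]]
  pos <- hit$start + c(4, 14, 24, 34) # degrade four motif-1 positions
  orig <- chars[pos]
  chars[pos] <- ifelse(cons[c(5, 15, 25, 35)] == "G", "P", "G")
  prev <- family_score(scan_protein(c(x = paste(chars, collapse = ""))))
  expect_lt(prev, 1)
  for (k in seq_along(pos)) {
    chars[pos[k]] <- orig[k]
    cur <- family_score(scan_protein(c(x = paste(chars, collapse = ""))))
    expect_gte(cur, prev - 1e-12)
    prev <- cur
  }
  expect_equal(prev, 1)
})

test_that("empirical E-value follows the permutation formula", {
  set.seed(9)
  proteome <- tibble::tibble(
    protein_id = sprintf("p%02d", 1:25),
    sequence = replicate(25, random_aa(60)))
  e <- empirical_evalue(c(1.01, -1), proteome, n_shuffles = 999, seed = 3)
  expect_equal(e[1], 25 / 1000)  # score above every null
  expect_equal(e[2], 25)         # score below every null: E = N_db
  scores <- seq(0, 1, by = 0.25)
  es <- empirical_evalue(scores, proteome, n_shuffles = 99, seed = 3)
  expect_true(all(diff(es) <= 0)) # monotone non-increasing in score
})

test_that("the synthetic proteome yields 25 raw candidates and 20 accepted", {
  idf <- fam_identification()
  expect_identical(sum(idf$raw_candidate), 25L)
  expect_identical(sum(idf$verdict == "accept"), 20L)
  expect_identical(sum(idf$redundant), 2L)
  expect_identical(sum(idf$incomplete & idf$raw_candidate), 3L)
  # accepted set is exactly the planted family
  expect_setequal(idf$protein_id[idf$verdict == "accept"],
                  fam_bundle()$truth$family_members)
})

test_that("redundancy filter keeps one of two identical sequences", {
  s <- build_scaffold(seed = 2)$sequence
  set.seed(4)
  proteome <- tibble::tibble(
    protein_id = c("a", "b", paste0("r", 1:6)),
    sequence = c(s, s, replicate(6, random_aa(300))))
  idf <- identify_family(proteome, n_shuffles = 99, seed = 1)
  acc <- idf$protein_id[idf$verdict == "accept"]
  expect_identical(acc, "a")
  expect_true(idf$redundant[idf$protein_id == "b"])
})

test_that("acceptance decisions are invariant under input order", {
  s <- build_scaffold(seed = 2)$sequence
  set.seed(8)
  proteome <- tibble::tibble(
    protein_id = c("a", "b", paste0("r", 1:5)),
    sequence = c(s, s, replicate(5, random_aa(250))))
  idf1 <- identify_family(proteome, n_shuffles = 99, seed = 1)
  idf2 <- identify_family(proteome[rev(seq_len(nrow(proteome))), ],
                          n_shuffles = 99, seed = 1)
  v1 <- setNames(idf1$verdict, idf1$protein_id)
  v2 <- setNames(idf2$verdict, idf2$protein_id)
  expect_identical(v1[sort(names(v1))], v2[sort(names(v2))])
})

test_that("a candidate missing a core motif is rejected as incomplete", {
  idf <- fam_identification()
  trunc <- idf[grepl("^decoy-trunc", idf$protein_id), ]
  expect_true(all(trunc$raw_candidate))
  expect_true(all(trunc$incomplete))
  expect_true(all(trunc$verdict == "reject"))
})
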