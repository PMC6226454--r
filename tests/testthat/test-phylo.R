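test_that("pairwise distances count mismatches over gap-deleted columns", {
  dm <- pairwise_distances(c(a = "AAAA", b = "AAAT"))
  expect_equal(dm["a", "b"], 0.25)
  expect_equal(dm["a", "a"], 0)
  dm2 <- pairwise_distances(c(a = "MKVLAAGG", b = "MKVLAAGG"))
  expect_equal(dm2["a", "b"], 0)
  # a gapped pair: the inserted run is gap-deleted, not counted
  long <- "MKVICEWLDSNQLAEADEFEDKMKELESQNPIIAKMY"
  short <- sub("CEWLDSNQ", "", long) # internal deletion
  dm3 <- pairwise_distances(setNames(c(long, short), c("a", "b")))
  expect_equal(dm3["a", "b"], 0)
  expect_error(pairwise_distances(c(a = "AAA")), "at least 2")
})

test_that("poisson distances transform p and reject saturated pairs", {
  dm <- pairwise_distances(c(a = "AAAA", b = "AAAT"), model = "poisson")
  expect_equal(dm["a", "b"], -log(1 - 0.25))
})

test_that("three-taxon NJ uses the closed-form branch lengths", {
  d <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["a"]], (2 + 3 - 4) / 2)
  expect_equal(bl[["b"]], (2 + 4 - 3) / 2)
  expect_equal(bl[["c"]], (3 + 4 - 2) / 2)
  dbad <- d; dbad[1, 2] <- 5
  expect_error(nj_tree(dbad), "symmetric")
})

test_that("NJ recovers additive matrices exactly", {
  # ((a:1,b:2):1.5,(c:0.5,d:1):0.5,e:3); path metric is additive
  nwk <- "((a:1,b:2):1.5,(c:0.5,d:1):0.5,e:3);"
  ref <- ape::read.tree(text = nwk)
  d <- ape::cophenetic.phylo(ref)
  d <- d[order(rownames(d)), order(colnames(d))]
  tr <- nj_tree(d)
  got <- ape::cophenetic.phylo(tr)[rownames(d), colnames(d)]
  expect_equal(got, d, tolerance = 1e-9)
  expect_equal(phangorn::RF.dist(ape::unroot(ref), tr), 0)
})

test_that("NJ agrees with an independent implementation on random inputs", {
  set.seed(33)
  for (i in 1:5) {
    n <- sample(5:8, 1)
    m <- matrix(stats::runif(n * n, 0.1, 1), n, n)
    d <- (m + t(m)) / 2; diag(d) <- 0
    dimnames(d) <- list(letters[1:n], letters[1:n])
    expect_equal(phangorn::RF.dist(nj_tree(d), ape::nj(as.dist(d))), 0)
  }
})

test_that("NJ output is invariant to taxon input order", {
  set.seed(14)
  n <- 7
  m <- matrix(stats::runif(n * n, 0.1, 1), n, n)
  d <- (m + t(m)) / 2; diag(d) <- 0
  dimnames(d) <- list(letters[1:n], letters[1:n])
  perm <- sample(n)
  dp <- d[perm, perm]
  expect_equal(phangorn::RF.dist(nj_tree(d), nj_tree(dp)), 0)
})

test_that("bootstrap without resampling gives full support everywhere", {
  prots <- fam_accepted()[1:8, ]
  tr <- bootstrap_supports(prots, n_reps = 1, seed = 2, resample = FALSE)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  expect_true(all(sup[!is.na(sup)] == 100))
})

test_that("bootstrap supports are deterministic and favour planted splits", {
  base <- strsplit(build_scaffold(seed = 6, tail_length = 0)$sequence,
                   "")[[1]][1:120]
  alt <- base; alt[30:45] <- rev(alt[30:45]) # diagnostic block
  mk <- function(chars, k, res) { chars[k] <- res; paste(chars, collapse = "") }
  prots <- tibble::tibble(
    protein_id = c("a1", "a2", "a3", "b1", "b2", "b3"),
    sequence = c(mk(base, 1, "W"), mk(base, 2, "W"), mk(base, 3, "W"),
                 mk(alt, 1, "W"), mk(alt, 2, "W"), mk(alt, 3, "W")))
  t1 <- bootstrap_supports(prots, n_reps = 10, seed = 4)
  t2 <- bootstrap_supports(prots, n_reps = 10, seed = 4)
  expect_identical(t1$node.label, t2$node.label)
  sup <- suppressWarnings(as.numeric(t1$node.label))
  expect_true(all(sup[!is.na(sup)] >= 0 & sup[!is.na(sup)] <= 100))
  # the planted a|b split must carry the maximum support
  keys <- famscan:::tree_bipartition_keys(t1)
  planted <- paste(sort(c("b1", "b2", "b3")), collapse = "|")
  planted_node <- as.integer(names(keys)[keys == planted])
  expect_length(planted_node, 1)
  planted_sup <- sup[planted_node - 6]
  expect_equal(max(sup, na.rm = TRUE), planted_sup)
})

test_that("subfamily cutting matches the planted five-group structure", {
  sf <- cut_subfamilies(fam_nj(), 5)
  sizes <- sort(as.integer(table(sf$subfamily)), decreasing = TRUE)
  expect_identical(sizes, c(10L, 3L, 3L, 3L, 1L))
  truth <- fam_bundle()$truth$subfamily_of
  got <- setNames(sf$subfamily, sf$gene_id)
  expect_gte(rand_index(truth, got), 0.95)
  # labels are assigned by decreasing clade size
  expect_identical(sum(sf$subfamily == "A"), 10L)
})

test_that("subfamily cut handles the degenerate k values", {
  tr <- fam_nj()
  expect_identical(unique(cut_subfamilies(tr, 1)$subfamily), "A")
  singletons <- cut_subfamilies(tr, 20)
  expect_identical(dplyr::n_distinct(singletons$subfamily), 20L)
  expect_error(cut_subfamilies(tr, 21), "leaves")
})

test_that("sister pairs are exactly the planted pairs", {
  sp <- sister_pairs(fam_nj(), fam_accepted())
  planted <- fam_bundle()$truth$planted_pairs
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  expect_setequal(key(sp$gene_a, sp$gene_b),
                  key(planted$gene_a, planted$gene_b))
  expect_identical(nrow(sp), 5L)
  # an unattainable identity floor empties the list
  expect_identical(nrow(sister_pairs(fam_nj(), fam_accepted(),
                                     identity_min = 1.01)), 0L)
})

test_that("path metric of the family NJ tree approximates its input", {
  dm <- fam_distances()
  tr <- fam_nj()
  got <- ape::cophenetic.phylo(tr)[rownames(dm), colnames(dm)]
  expect_lt(max(abs(got - unclass(dm)[, ])), 0.1)
})
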