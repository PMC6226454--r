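# Shared fixtures, computed once per test run (lazily, memoized).
.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

fam_config <- function() generator_config(seed = 42)

fam_bundle <- function() memo("bundle", simulate_genome(fam_config()))

fam_identification <- function() memo("identification", {
  b <- fam_bundle()
  identify_family(b$proteins[, c("protein_id", "sequence")],
                  annotation = b$genes[, c("gene_id", "chromosome",
                                           "start", "end")],
                  seed = 7)
})

fam_accepted <- function() memo("accepted", {
  idf <- fam_identification()
  b <- fam_bundle()
  b$proteins[b$proteins$protein_id %in%
               idf$protein_id[idf$verdict == "accept"],
             c("protein_id", "sequence")]
})

fam_distances <- function() memo("distances", {
  pairwise_distances(fam_accepted())
})

fam_nj <- function() memo("nj", nj_tree(fam_distances()))

fam_boot_tree <- function() memo("boot_tree", {
  bootstrap_supports(fam_accepted(), n_reps = 100, seed = 11)
})

fam_expression <- function() memo("expression", {
  simulate_expression(fam_bundle())
})

fam_ct <- function() memo("ct", simulate_ct(fam_bundle()))

fam_calls <- function() memo("calls", regulation_calls(fam_ct()))

# Rand index of two labelings given as named vectors over the same ids.
rand_index <- function(a, b) {
  ids <- names(a)
  b <- b[ids]
  agree <- 0; total <- 0
  for (i in seq_along(ids)[-length(ids)]) {
    for (j in seq((i + 1), length(ids))) {
      total <- total + 1
      same_a <- a[i] == a[j]; same_b <- b[i] == b[j]
      if (same_a == same_b) agree <- agree + 1
    }
  }
  agree / total
}
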