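# Independent brute-force local-alignment oracle: the best local alignment
# is the best global affine alignment over all substring pairs (or the
# empty alignment, score 0). The global score uses a three-state recursion
# with memoization, written independently of the package's single-pass DP.
bf_global_affine <- function(a, b, sub, gap_open, gap_extend) {
  n <- nchar(a); m <- nchar(b)
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  NEG <- -1e18
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j, state) {
    key <- paste(i, j, state)
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (i == 0 && j == 0) {
      if (state == "M") 0 else NEG
    } else if (i == 0) {
      if (state == "E") -gap_open - (j - 1) * gap_extend else NEG
    } else if (j == 0) {
      if (state == "F") -gap_open - (i - 1) * gap_extend else NEG
    } else {
      switch(state,
        M = max(rec(i - 1, j - 1, "M"), rec(i - 1, j - 1, "E"),
                rec(i - 1, j - 1, "F")) + sub[av[i], bv[j]],
        E = max(rec(i, j - 1, "M") - gap_open,
                rec(i, j - 1, "E") - gap_extend),
        F = max(rec(i - 1, j, "M") - gap_open,
                rec(i - 1, j, "F") - gap_extend))
    }
    memo[[key]] <- val
    val
  }
  max(rec(n, m, "M"), rec(n, m, "E"), rec(n, m, "F"))
}

bf_local_score <- function(a, b, sub, gap_open, gap_extend) {
  best <- 0
  for (i1 in seq_len(nchar(a))) for (i2 in i1:nchar(a)) {
    sa <- substr(a, i1, i2)
    for (j1 in seq_len(nchar(b))) for (j2 in j1:nchar(b)) {
      sb <- substr(b, j1, j2)
      best <- max(best, bf_global_affine(sa, sb, sub, gap_open, gap_extend))
    }
  }
  best
}

# Dense-grid isoelectric-point oracle: pH minimizing |net charge| on a
# 1e-4-step grid.
grid_pi <- function(sequence, step = 1e-4) {
  ph <- seq(0, 14, by = step)
  q <- famscan:::peptide_charge(sequence, ph)
  ph[which.min(abs(q))]
}

random_aa <- function(n) {
  paste(sample(famscan:::AA_STANDARD, n, replace = TRUE), collapse = "")
}
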