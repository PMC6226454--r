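# Gap-deleted mismatch columns for every protein pair, from global pairwise
# alignments (BLOSUM62, affine 10/0.5). Returned as a list indexed "i|j"
# (i < j, positions in the input order) of logical mismatch vectors; these
# are the columns the bootstrap resamples.
pair_alignment_columns <- function(proteins, gap_open = 10, gap_extend = 0.5) {
  proteins <- as_protein_tbl(proteins)
  n <- nrow(proteins)
  sub <- blosum62()
  cols <- list()
  aa <- Biostrings::AAStringSet(stats::setNames(proteins$sequence,
                                                proteins$protein_id))
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      pa <- Biostrings::pairwiseAlignment(
        aa[[i]], aa[[j]], substitutionMatrix = sub,
        gapOpening = gap_open, gapExtension = gap_extend, type = "global")
      p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
      s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
      keep <- p != "-" & s != "-"
      cols[[paste0(i, "|", j)]] <- p[keep] != s[keep]
    }
  }
  attr(cols, "taxa") <- proteins$protein_id
  cols
}

dist_from_columns <- function(cols, model = c("p", "poisson"),
                              resample = FALSE) {
  model <- match.arg(model)
  taxa <- attr(cols, "taxa")
  n <- length(taxa)
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (key in names(cols)) {
    ij <- as.integer(strsplit(key, "|", fixed = TRUE)[[1]])
    v <- cols[[key]]
    if (resample) v <- v[sample.int(length(v), replace = TRUE)]
    p <- mean(v)
    if (model == "poisson") {
      if (p >= 1) stop("Poisson distance undefined at p = 1", call. = FALSE)
      p <- -log(1 - p)
    }
    d[ij[1], ij[2]] <- d[ij[2], ij[1]] <- p
  }
  d
}

#' Pairwise evolutionary distances with pairwise gap deletion
#'
#' For each protein pair, a global alignment is computed (BLOSUM62, affine
#' gaps 10/0.5), columns containing a gap in either sequence are deleted
#' (pairwise gap deletion), and the distance is the mismatch proportion
#' (`model = "p"`) or its Poisson correction `-ln(1 - p)`.
#'
#' @param proteins Tibble with `protein_id`, `sequence` (>= 2 rows), or a
#'   named character vector.
#' @param model `"p"` (default) or `"poisson"`.
#' @return A symmetric distance matrix with taxa dimnames; the gap-deleted
#'   per-pair alignment columns are kept in `attr(, "columns")` for
#'   bootstrap resampling.
#' @export
pairwise_distances <- function(proteins, model = c("p", "poisson")) {
  model <- match.arg(model)
  proteins <- as_protein_tbl(proteins)
  if (nrow(proteins) < 2) stop("need at least 2 sequences", call. = FALSE)
  cols <- pair_alignment_columns(proteins)
  d <- dist_from_columns(cols, model)
  attr(d, "columns") <- cols
  attr(d, "model") <- model
  d
}

#' Neighbor-joining tree
#'
#' Standard Saitou-Nei agglomeration: repeatedly join the pair minimizing
#' `Q(i,j) = (n-2) d(i,j) - sum_k d(i,k) - sum_k d(j,k)`, with branch
#' lengths from the usual closed forms. Ties are broken by the
#' lexicographically smallest pair of cluster representatives (each
#' cluster represented by its smallest member label). Negative branch
#' length estimates are clamped to zero with the deficit moved to the
#' sibling branch.
#'
#' @param dm Symmetric distance matrix with taxa dimnames (>= 3 taxa).
#' @return An unrooted `phylo` tree (ape).
#' @export
nj_tree <- function(dm) {
  d <- unclass(dm)
  attr(d, "columns") <- NULL; attr(d, "model") <- NULL
  if (!is.matrix(d) || !isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    stop("distance matrix must be symmetric", call. = FALSE)
  taxa <- rownames(d)
  n <- length(taxa)
  if (n < 3) stop("need at least 3 taxa", call. = FALSE)
  labels <- taxa               # newick fragment per active cluster
  reps <- taxa                 # smallest member label per cluster
  while (n > 3) {
    r <- rowSums(d)
    # find Q-minimizing pair with deterministic tie-break
    best <- NULL; bestq <- Inf; bestkey <- NULL
    for (i in seq_len(n - 1)) {
      for (j in seq((i + 1), n)) {
        q <- (n - 2) * d[i, j] - r[i] - r[j]
        key <- sort(c(reps[i], reps[j]))
        better <- q < bestq - 1e-12 ||
          (abs(q - bestq) <= 1e-12 &&
             (key[1] < bestkey[1] ||
                (key[1] == bestkey[1] && key[2] < bestkey[2])))
        if (is.null(best) || better) {
          best <- c(i, j); bestq <- q; bestkey <- key
        }
      }
    }
    i <- best[1]; j <- best[2]
    bi <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    bj <- d[i, j] - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    newlab <- sprintf("(%s:%.10g,%s:%.10g)", labels[i], bi, labels[j], bj)
    newrep <- min(reps[i], reps[j])
    duk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], duk[keep]),
               c(duk[keep], 0))
    labels <- c(labels[keep], newlab)
    reps <- c(reps[keep], newrep)
    n <- n - 1
  }
  b1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  b2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  b3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  bl <- pmax(c(b1, b2, b3), 0)
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 labels[1], bl[1], labels[2], bl[2], labels[3], bl[3])
  ape::read.tree(text = nwk)
}

# Canonical keys of the non-trivial bipartitions of an unrooted tree: each
# internal edge is keyed by the tip set on the side NOT containing the
# alphabetically smallest taxon.
tree_bipartition_keys <- function(tree) {
  ntip <- length(tree$tip.label)
  ref <- min(tree$tip.label)
  internal_children <- tree$edge[tree$edge[, 2] > ntip, 2]
  keys <- character(0)
  nodes <- integer(0)
  for (node in internal_children) {
    tips <- tip_set(tree, node)
    if (ref %in% tips) tips <- setdiff(tree$tip.label, tips)
    if (length(tips) < 2 || length(tips) > ntip - 2) next
    keys <- c(keys, paste(sort(tips), collapse = "|"))
    nodes <- c(nodes, node)
  }
  stats::setNames(keys, nodes)
}

# Tip labels descending from a node (the node itself if a tip).
tip_set <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  stack <- node; tips <- integer(0)
  while (length(stack) > 0) {
    cur <- stack[length(stack)]; stack <- stack[-length(stack)]
    kids <- tree$edge[tree$edge[, 1] == cur, 2]
    tips <- c(tips, kids[kids <= ntip])
    stack <- c(stack, kids[kids > ntip])
  }
  tree$tip.label[tips]
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Builds the reference NJ tree, then for each bootstrap replicate resamples
#' (with replacement) the gap-deleted columns of every pairwise alignment,
#' recomputes distances and the NJ tree, and scores each internal edge of
#' the reference tree by the percentage of replicate trees containing its
#' bipartition. With `resample = FALSE` every replicate reuses the original
#' columns (so every internal edge gets support 100).
#'
#' @param proteins Tibble with `protein_id`, `sequence`.
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param seed Integer seed for column resampling.
#' @param model Distance model, `"p"` or `"poisson"`.
#' @param resample Resample columns (default TRUE).
#' @return A `phylo` tree whose `node.label` holds supports in \[0, 100\]
#'   (empty for the root); replicate trees in `attr(, "replicates")`.
#' @export
bootstrap_supports <- function(proteins, n_reps = 100, seed = 1,
                               model = c("p", "poisson"), resample = TRUE) {
  stopifnot(n_reps >= 1)
  model <- match.arg(model)
  dm <- pairwise_distances(proteins, model)
  cols <- attr(dm, "columns")
  ref <- nj_tree(dm)
  boot <- with_seed(seed, {
    lapply(seq_len(n_reps), function(b) {
      nj_tree(dist_from_columns(cols, model, resample = resample))
    })
  })
  ref_keys <- tree_bipartition_keys(ref)
  counts <- stats::setNames(rep(0, length(ref_keys)), ref_keys)
  for (tr in boot) {
    hit <- ref_keys %in% tree_bipartition_keys(tr)
    counts[hit] <- counts[hit] + 1
  }
  ntip <- length(ref$tip.label)
  labs <- rep("", ref$Nnode)
  for (k in seq_along(ref_keys)) {
    node <- as.integer(names(ref_keys)[k])
    labs[node - ntip] <- sprintf("%g", 100 * counts[k] / n_reps)
  }
  ref$node.label <- labs
  attr(ref, "replicates") <- boot
  ref
}

#' Cut a tree into subfamilies
#'
#' Removes the `k - 1` longest internal edges (ties broken by higher
#' support, then by the smallest descendant tip label) and groups the
#' leaves of the resulting components. When fewer than `k - 1` internal
#' edges exist, terminal edges are cut next, longest first. Groups are
#' labelled A, B, C, ... by decreasing size, ties by smallest member id.
#'
#' @param tree A `phylo` tree (node labels, when present and numeric, are
#'   used as supports for tie-breaking).
#' @param k Number of groups, `1 <= k <=` number of leaves.
#' @return Tibble with `gene_id` and `subfamily`.
#' @export
cut_subfamilies <- function(tree, k) {
  ntip <- length(tree$tip.label)
  if (k < 1 || k > ntip) stop("k must lie in [1, number of leaves]",
                              call. = FALSE)
  edges <- tree$edge
  lens <- tree$edge.length
  is_internal <- edges[, 2] > ntip
  support <- rep(Inf, nrow(edges))
  if (!is.null(tree$node.label)) {
    sup <- suppressWarnings(as.numeric(tree$node.label))
    idx <- edges[, 2] - ntip
    support[is_internal] <- ifelse(is.na(sup[idx[is_internal]]), Inf,
                                   sup[idx[is_internal]])
  }
  mintip <- vapply(edges[, 2], function(nd) min(tip_set(tree, nd)),
                   character(1))
  ord_key <- order(-lens, -support, mintip)
  ord <- c(ord_key[is_internal[ord_key]], ord_key[!is_internal[ord_key]])
  # remove edges longest-first, keeping only removals that split a leaf
  # group, until k groups exist
  leaf_groups <- function(drop) {
    parent <- seq_len(ntip + tree$Nnode)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    for (e in setdiff(seq_len(nrow(edges)), drop)) {
      a <- find(edges[e, 1]); b <- find(edges[e, 2])
      if (a != b) parent[a] <- b
    }
    comp <- vapply(seq_len(ntip), find, integer(1))
    unname(split(tree$tip.label, comp))
  }
  drop <- integer(0)
  n_groups <- 1L
  for (e in ord) {
    if (n_groups >= k) break
    cand <- leaf_groups(c(drop, e))
    if (length(cand) > n_groups) {
      drop <- c(drop, e)
      n_groups <- length(cand)
    }
  }
  groups <- leaf_groups(drop)
  sizes <- vapply(groups, length, integer(1))
  firsts <- vapply(groups, min, character(1))
  groups <- groups[order(-sizes, firsts)]
  out <- purrr::map_dfr(seq_along(groups), function(i) {
    tibble::tibble(gene_id = sort(groups[[i]]), subfamily = LETTERS[i])
  })
  out[order(out$gene_id), ]
}

#' Sister pairs (cherries) of a tree
#'
#' All leaf pairs attached to the same internal node whose Smith-Waterman
#' identity reaches `identity_min`.
#'
#' @param tree A `phylo` tree.
#' @param proteins Tibble with `protein_id`, `sequence` covering the tips.
#' @param identity_min Minimum local-alignment identity (default 0.98).
#' @return Tibble with `gene_a`, `gene_b`, `identity` (gene_a < gene_b).
#' @export
sister_pairs <- function(tree, proteins, identity_min = 0.98) {
  proteins <- as_protein_tbl(proteins)
  seqs <- stats::setNames(proteins$sequence, proteins$protein_id)
  ntip <- length(tree$tip.label)
  out <- tibble::tibble(gene_a = character(0), gene_b = character(0),
                        identity = numeric(0))
  for (node in unique(tree$edge[, 1])) {
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    tipkids <- kids[kids <= ntip]
    if (length(tipkids) != 2) next
    pair <- sort(tree$tip.label[tipkids])
    id <- smith_waterman(seqs[[pair[1]]], seqs[[pair[2]]])$identity
    if (id >= identity_min) {
      out <- dplyr::bind_rows(out, tibble::tibble(
        gene_a = pair[1], gene_b = pair[2], identity = id))
    }
  }
  dplyr::arrange(out, .data$gene_a)
}
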