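# Shared fixtures and independent oracles for the test suite.

# A perfect tandem-repeat protein built from the canonical 24-residue unit:
# 8-residue LxxLxLxx core followed by a spacer free of aliphatic-class
# residues, so the detector can only match at the designed offsets.
perfectRepeatProtein <- function(n_repeats = 5L,
                                 unit = "LRALDLSNKTGEKDNSGQRPHSTE") {
  strrep(unit, n_repeats)
}

# Small alignment with known column composition.
toyAlignment <- function(rows, ids = NULL, ...) {
  if (is.null(ids)) ids <- paste0("s", seq_along(rows))
  cladeAlignment(stats::setNames(rows, ids), ...)
}

# Random rooted tree with random bootstrap labels (some missing).
randomSupportTree <- function(n, p_missing = 0.2) {
  tr <- ape::rtree(n)
  lab <- as.character(sample(0:100, tr$Nnode, replace = TRUE))
  lab[runif(tr$Nnode) < p_missing] <- ""
  tr$node.label <- lab
  tr
}

# Independent brute-force implementation of the initial clade assignment:
# membership by recursive tip collection, explicit lexicographic
# comparison for selection, pairwise subset tests for de-nesting.
oracleInitialAssignment <- function(tree, cfg) {
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  tipsBelow <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    sort(unlist(lapply(kids, tipsBelow)))
  }
  nodes <- seq_len(ntip + nnode)
  sets <- lapply(nodes, tipsBelow)
  supp <- c(rep(NA_real_, ntip),
            suppressWarnings(as.numeric(tree$node.label)))
  supp[is.na(supp)] <- 0
  parentOf <- function(node) {
    row <- which(tree$edge[, 2] == node)
    if (length(row) == 0L) NA_integer_ else tree$edge[row, 1]
  }
  depthOf <- function(node) {
    d <- 0L
    while (!is.na(p <- parentOf(node))) { node <- p; d <- d + 1L }
    d
  }
  depth <- vapply(nodes, depthOf, integer(1))
  size <- lengths(sets)

  pickBest <- function(cand) {
    best <- cand[1L]
    for (x in cand[-1L]) {
      if (supp[x] > supp[best] ||
          (supp[x] == supp[best] && size[x] > size[best]) ||
          (supp[x] == supp[best] && size[x] == size[best] &&
           depth[x] < depth[best]))
        best <- x
    }
    best
  }
  chosen <- integer(ntip)
  for (leaf in seq_len(ntip)) {
    lab <- tree$tip.label[leaf]
    containing <- nodes[vapply(sets, function(s) lab %in% s, logical(1))]
    elig <- containing[size[containing] >= cfg$min_clade_size &
                         size[containing] <= cfg$max_clade_size]
    if (length(elig) == 0L)
      elig <- containing[size[containing] < cfg$min_clade_size]
    chosen[leaf] <- pickBest(elig)
  }
  selected <- unique(chosen)
  nested <- vapply(selected, function(a) {
    any(vapply(selected, function(b)
      a != b && all(sets[[a]] %in% sets[[b]]), logical(1)))
  }, logical(1))
  kept <- selected[!nested]
  out <- lapply(kept, function(n) sets[[n]])
  names(out) <- paste0("Int", kept)
  out
}

# Canonical form of a partition for set-wise comparison.
canonicalPartition <- function(clades) {
  sets <- lapply(clades, function(x) sort(unname(x)))
  unname(sets[order(vapply(sets, `[`, character(1), 1L))])
}

# Brute-force precision/recall by explicit set arithmetic.
oraclePR <- function(H_by_residue, truth, cutoffs) {
  t(vapply(cutoffs, function(cc) {
    pred <- as.integer(names(H_by_residue))[H_by_residue >= cc]
    tp <- sum(pred %in% truth)
    c(precision = if (length(pred)) tp / length(pred) else NA_real_,
      recall = tp / length(truth))
  }, c(precision = 0, recall = 0)))
}
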