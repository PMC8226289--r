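#' Configuration for clade partitioning and refinement
#'
#' Holds the thresholds of the phylogeny partition: the clade size window
#' and support rule for the initial assignment, the branch-length rules for
#' iterative refinement (branches longer than `long_branch_cutoff`
#' substitutions/site are always cut; branches at or below
#' `short_branch_cutoff` are always retained; intermediate branches are cut
#' when bootstrap support is at least `intermediate_support_min` and the
#' ecotype-set Jaccard index across the branch is at most
#' `intermediate_ecotype_jaccard_max`), and the gap-masking cutoff applied
#' to gappy alignment columns.
#'
#' @param min_clade_size,max_clade_size Clade size window (default 40-500).
#' @param long_branch_cutoff Substitutions/site above which a branch is
#'   always cut (default 0.3).
#' @param short_branch_cutoff Substitutions/site at or below which a branch
#'   is always retained (default 0.1).
#' @param intermediate_support_min Minimum bootstrap (percent) for cutting
#'   an intermediate branch (default 70).
#' @param intermediate_ecotype_jaccard_max Maximum ecotype-set Jaccard for
#'   cutting an intermediate branch (default 0.25).
#' @param gap_mask_fraction Columns with at least this gap fraction are
#'   masked (default 0.90).
#' @return A validated list of class `PartitionConfig`.
#' @export
partitionConfig <- function(min_clade_size = 40L, max_clade_size = 500L,
                            long_branch_cutoff = 0.3, short_branch_cutoff = 0.1,
                            intermediate_support_min = 70,
                            intermediate_ecotype_jaccard_max = 0.25,
                            gap_mask_fraction = 0.90) {
  cfg <- list(min_clade_size = as.integer(min_clade_size),
              max_clade_size = as.integer(max_clade_size),
              long_branch_cutoff = long_branch_cutoff,
              short_branch_cutoff = short_branch_cutoff,
              intermediate_support_min = intermediate_support_min,
              intermediate_ecotype_jaccard_max = intermediate_ecotype_jaccard_max,
              gap_mask_fraction = gap_mask_fraction)
  if (cfg$min_clade_size <= 0L || cfg$min_clade_size > cfg$max_clade_size)
    stop("require 0 < min_clade_size <= max_clade_size")
  if (cfg$short_branch_cutoff < 0 || cfg$short_branch_cutoff > cfg$long_branch_cutoff)
    stop("require 0 <= short_branch_cutoff <= long_branch_cutoff")
  class(cfg) <- c("PartitionConfig", "list")
  cfg
}

# Topological depth (edges from root) of every node of a rooted tree.
nodeDepths <- function(tree) {
  n <- ape::Ntip(tree) + tree$Nnode
  depth <- integer(n)
  tr <- stats::reorder(tree, "cladewise")  # parents before children
  for (i in seq_len(nrow(tr$edge)))
    depth[tr$edge[i, 2L]] <- depth[tr$edge[i, 1L]] + 1L
  depth
}

#' Enumerate all candidate clades of a tree
#'
#' Lists, for every internal node and every leaf (singleton clade), the
#' clade it subtends: its leaf set, size and bootstrap support. Singleton
#' and unlabeled clades carry `NA` support.
#'
#' @param tree A rooted [ape::phylo] with at least 2 leaves.
#' @return A data.frame with columns `node`, `size`, `support`, and a
#'   `leaves` list-column of tip-label vectors.
#' @export
enumerateClades <- function(tree) {
  stopifnot(inherits(tree, "phylo"), ape::Ntip(tree) >= 2L)
  ntip <- ape::Ntip(tree)
  nodes <- seq_len(ntip + tree$Nnode)
  desc <- phangorn::Descendants(tree, nodes, type = "tips")
  supports <- c(rep(NA_real_, ntip), nodeSupports(tree))
  out <- data.frame(node = nodes,
                    size = lengths(desc),
                    support = supports)
  out$leaves <- lapply(desc, function(i) tree$tip.label[i])
  out
}

#' Root a tree on the branch defined by a leaf bipartition
#'
#' Places the root in the middle of the branch separating the two given
#' leaf sets (for a pan-NLRome NB-ARC tree, typically the branch between
#' the TNL and non-TNL receptors). Branch supports are treated as edge
#' labels so they stay attached to the correct bipartitions.
#'
#' @param tree An [ape::phylo].
#' @param side Character vector of tip labels forming one side of the
#'   bipartition (the complement forms the other side).
#' @return A rooted [ape::phylo]; total branch length is preserved.
#' @export
rootBetween <- function(tree, side) {
  stopifnot(inherits(tree, "phylo"))
  side <- as.character(side)
  if (!all(side %in% tree$tip.label))
    stop("unknown tip labels: ",
         paste(setdiff(side, tree$tip.label), collapse = ", "))
  other <- setdiff(tree$tip.label, side)
  if (length(side) == 0L || length(other) == 0L)
    stop("bipartition sides must both be non-empty")
  ur <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  # the bipartition is a branch iff one side is the tip set of some node
  nodes <- seq_len(ape::Ntip(ur) + ur$Nnode)
  desc <- phangorn::Descendants(ur, nodes, type = "tips")
  hit <- FALSE
  for (d in desc) {
    labs <- ur$tip.label[d]
    if (setequal(labs, side) || setequal(labs, other)) { hit <- TRUE; break }
  }
  if (!hit) stop("the given bipartition does not correspond to a branch of the tree")
  rooted <- ape::root(ur, outgroup = side, resolve.root = TRUE, edgelabel = TRUE)
  # split the subdivided branch's length evenly between the two root edges
  rootNode <- ape::Ntip(rooted) + 1L
  rootEdges <- which(rooted$edge[, 1L] == rootNode)
  if (length(rootEdges) == 2L) {
    tot <- sum(rooted$edge.length[rootEdges])
    rooted$edge.length[rootEdges] <- tot / 2
  }
  rooted
}

#' Initial assignment of tree leaves to size-bounded, maximally supported clades
#'
#' For each leaf, the containing clade with size inside
#' `[min_clade_size, max_clade_size]` and the strongest bootstrap support is
#' selected; leaves with no size-eligible clade fall back to clades smaller
#' than the minimum (again taking maximal support). The union of selected
#' clades is then made non-nesting by discarding every selected clade fully
#' contained in another selected clade, whose leaves it inherits. The
#' result assigns every leaf to exactly one clade.
#'
#' Ties on support are broken towards the larger clade, then towards the
#' clade whose defining node is closest to the root; missing supports count
#' as 0 during selection. Clades are named `Int<node-id>`.
#'
#' @param tree A rooted [ape::phylo] with supports as node labels.
#' @param cfg A [partitionConfig()].
#' @return A [CladePartition-class].
#' @export
initialAssignment <- function(tree, cfg = partitionConfig()) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree))
    stop("tree is unrooted; root it first (see rootBetween)")
  ntip <- ape::Ntip(tree)
  clades <- enumerateClades(tree)
  size <- clades$size
  supp <- ifelse(is.na(clades$support), 0, clades$support)
  depth <- nodeDepths(tree)

  anc <- phangorn::Ancestors(tree, seq_len(ntip), type = "all")
  chosen <- integer(ntip)
  for (leaf in seq_len(ntip)) {
    cand <- c(leaf, anc[[leaf]])
    elig <- cand[size[cand] >= cfg$min_clade_size & size[cand] <= cfg$max_clade_size]
    if (length(elig) == 0L)
      elig <- cand[size[cand] < cfg$min_clade_size]
    if (length(elig) == 0L)
      stop("no eligible clade for leaf ", tree$tip.label[leaf])
    o <- order(-supp[elig], -size[elig], depth[elig])
    chosen[leaf] <- elig[o[1L]]
  }

  selected <- sort(unique(chosen))
  # de-nest: drop any selected node that has a selected strict ancestor
  ancAll <- phangorn::Ancestors(tree, selected, type = "all")
  if (!is.list(ancAll)) ancAll <- list(ancAll)  # single selected node
  keep <- !vapply(ancAll, function(a) any(a %in% selected), logical(1))
  final <- selected[keep]

  leafSets <- clades$leaves[final]
  names(leafSets) <- paste0("Int", final)
  part <- new("CladePartition",
              clades = leafSets,
              stats = data.frame(clade = names(leafSets),
                                 node = final,
                                 size = size[final],
                                 support = clades$support[final]))
  stopifnot(setequal(unlist(part@clades, use.names = FALSE), tree$tip.label))
  validObject(part)
  part
}

# Jaccard index of two sets given as character vectors.
jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

#' Refine a clade tree by cutting long and weakly shared branches
#'
#' Applies the refinement rules to every internal branch of a clade's
#' full-length-alignment tree: branches longer than
#' `cfg$long_branch_cutoff` substitutions/site are always cut; branches at
#' or below `cfg$short_branch_cutoff` are always retained; for intermediate
#' branches the cut is made when the bootstrap support of the branch is at
#' least `cfg$intermediate_support_min` and the Jaccard index of the
#' ecotype sets on the two sides is at most
#' `cfg$intermediate_ecotype_jaccard_max` (an automated stand-in for visual
#' tree inspection). Terminal branches are never cut. Leaves of the
#' connected components left after cutting form the refined subclades.
#'
#' @param tree A rooted [ape::phylo] for the clade (midpoint-root it with
#'   [phangorn::midpoint()] if needed; an unrooted tree is midpoint-rooted
#'   automatically).
#' @param cfg A [partitionConfig()].
#' @param ecotypes Named character vector, leaf label -> ecotype. Required
#'   when intermediate-length branches exist.
#' @return A list with `subclades` (list of tip-label vectors, largest
#'   first) and `log` (a data.frame recording, per internal branch, its
#'   length, support, ecotype Jaccard, the rule fired, and the decision).
#' @export
refineClade <- function(tree, cfg = partitionConfig(), ecotypes = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) tree <- phangorn::midpoint(tree)
  ntip <- ape::Ntip(tree)
  if (ntip < 2L)
    return(list(subclades = list(tree$tip.label),
                log = data.frame()))
  supports <- nodeSupports(tree)
  internal <- which(tree$edge[, 2L] > ntip)
  len <- tree$edge.length[internal]

  needEco <- any(len > cfg$short_branch_cutoff & len <= cfg$long_branch_cutoff)
  if (needEco && is.null(ecotypes))
    stop("ecotype labels are required to judge intermediate-length branches")
  if (!is.null(ecotypes) && !all(tree$tip.label %in% names(ecotypes)))
    stop("missing ecotype labels for: ",
         paste(setdiff(tree$tip.label, names(ecotypes)), collapse = ", "))

  desc <- phangorn::Descendants(tree, tree$edge[internal, 2L], type = "tips")
  log <- data.frame(parent = tree$edge[internal, 1L],
                    child = tree$edge[internal, 2L],
                    length = len,
                    support = supports[tree$edge[internal, 2L] - ntip],
                    jaccard = NA_real_,
                    rule = NA_character_,
                    cut = FALSE)
  for (i in seq_along(internal)) {
    if (len[i] > cfg$long_branch_cutoff) {
      log$rule[i] <- "long"; log$cut[i] <- TRUE
    } else if (len[i] <= cfg$short_branch_cutoff) {
      log$rule[i] <- "short"; log$cut[i] <- FALSE
    } else {
      below <- tree$tip.label[desc[[i]]]
      above <- setdiff(tree$tip.label, below)
      j <- jaccard(unique(ecotypes[below]), unique(ecotypes[above]))
      s <- log$support[i]
      log$jaccard[i] <- j
      log$cut[i] <- !is.na(s) && s >= cfg$intermediate_support_min &&
        j <= cfg$intermediate_ecotype_jaccard_max
      log$rule[i] <- "intermediate"
    }
  }

  # connected components over nodes joined by retained edges
  nNodes <- ntip + tree$Nnode
  parent <- seq_len(nNodes)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  isCut <- rep(FALSE, nrow(tree$edge))
  isCut[internal[log$cut]] <- TRUE
  for (i in seq_len(nrow(tree$edge))) {
    if (isCut[i]) next
    a <- find(tree$edge[i, 1L]); b <- find(tree$edge[i, 2L])
    if (a != b) parent[a] <- b
  }
  comp <- vapply(seq_len(ntip), find, integer(1))
  subclades <- split(tree$tip.label, comp)
  subclades <- subclades[order(-lengths(subclades))]
  names(subclades) <- NULL
  list(subclades = subclades, log = log)
}

#' Allelic-series statistics of a clade partition
#'
#' Summarises how closely a partition approximates allelic series: the
#' fraction of clades with at most one gene per represented ecotype, the
#' fraction of sequences falling into clades of at least `large_clade_min`
#' genes, the per-clade maximum gene count per ecotype, and a clade size
#' histogram.
#'
#' @param partition A [CladePartition-class] (or a named list of leaf-label
#'   vectors).
#' @param ecotypes Named character vector, leaf label -> ecotype; every
#'   leaf must be labelled.
#' @param large_clade_min Size threshold for the "large clade" fraction
#'   (default 20).
#' @return A list with `allelic_fraction`, `fraction_in_large_clades`,
#'   `per_clade` (data.frame), and `size_histogram` (table).
#' @export
allelicSeriesStats <- function(partition, ecotypes, large_clade_min = 20L) {
  clades <- if (is(partition, "CladePartition")) partition@clades else partition
  leaves <- unlist(clades, use.names = FALSE)
  if (!all(leaves %in% names(ecotypes)))
    stop("missing ecotype labels for: ",
         paste(utils::head(setdiff(leaves, names(ecotypes)), 5L), collapse = ", "))
  maxPerEco <- vapply(clades, function(l) max(table(ecotypes[l])), numeric(1))
  sizes <- lengths(clades)
  per_clade <- data.frame(clade = names(clades), size = sizes,
                          max_genes_per_ecotype = maxPerEco,
                          allelic = maxPerEco <= 1, row.names = NULL)
  list(allelic_fraction = mean(per_clade$allelic),
       fraction_in_large_clades = sum(sizes[sizes >= large_clade_min]) / sum(sizes),
       per_clade = per_clade,
       size_histogram = table(sizes))
}

#' Write a clade partition and its statistics to TSV
#'
#' @param partition A [CladePartition-class].
#' @param path Output path for the two-column (leaf, clade) table.
#' @param stats_path Optional path for the per-clade statistics table.
#' @return Invisibly, `path`.
#' @export
writePartition <- function(partition, path, stats_path = NULL) {
  stopifnot(is(partition, "CladePartition"))
  df <- data.frame(
    leaf = unlist(partition@clades, use.names = FALSE),
    clade = rep(names(partition@clades), lengths(partition@clades)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(stats_path))
    utils::write.table(partition@stats, stats_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}
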