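test_that("enumerateClades lists one entry per internal node plus singletons", {
  caterpillar <- ape::read.tree(text = "(((A:1,B:1):1,C:1):1,D:1);")
  e <- enumerateClades(caterpillar)
  expect_equal(nrow(e), 3L + 4L)
  expect_equal(sort(e$size), c(1, 1, 1, 1, 2, 3, 4))

  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1,E:1);")
  es <- enumerateClades(star)
  expect_equal(nrow(es), 1L + 5L)

  # every clade's leaf set is nested within its ancestors' leaf sets
  tr <- randomSupportTree(10)
  e <- enumerateClades(tr)
  for (i in seq_len(nrow(e))) {
    anc <- phangorn::Ancestors(tr, e$node[i], type = "all")
    for (a in anc)
      expect_true(all(e$leaves[[i]] %in% e$leaves[[which(e$node == a)]]))
  }
})

test_that("initialAssignment matches the brute-force oracle on a fixed 8-leaf tree", {
  set.seed(42)
  tr <- randomSupportTree(8)
  cfg <- partitionConfig(min_clade_size = 2, max_clade_size = 4)
  part <- initialAssignment(tr, cfg)
  expect_equal(canonicalPartition(cladeLeaves(part)),
               canonicalPartition(oracleInitialAssignment(tr, cfg)))
})

test_that("the root clade wins when it alone has top support within bounds", {
  set.seed(7)
  tr <- ape::rtree(12)
  tr$node.label <- as.character(sample(0:90, tr$Nnode, replace = TRUE))
  tr$node.label[1] <- "100"  # root
  part <- initialAssignment(tr, partitionConfig(min_clade_size = 2,
                                                max_clade_size = 12))
  expect_equal(length(cladeLeaves(part)), 1L)
  expect_setequal(cladeLeaves(part)[[1]], tr$tip.label)
})

test_that("leaves with no size-eligible clade fall back to smaller clades", {
  # two sister cherries under the root; bounds [4,10] exclude them but the
  # 6-leaf root clade is excluded too by support when smaller clades exist
  tr <- ape::read.tree(text = "(((A:1,B:1,C:1)90:1,(D:1,E:1,F:1)95:1)50:1,(G:1,H:1,I:1,J:1)99:1);")
  part <- initialAssignment(tr, partitionConfig(min_clade_size = 4,
                                                max_clade_size = 4))
  leaves <- cladeLeaves(part)
  sizes <- sort(lengths(leaves))
  # GHIJ is size-eligible; ABC and DEF fall back to their size-3 clades
  expect_equal(sort(unname(lengths(leaves))), c(3, 3, 4))
})

test_that("initialAssignment yields a disjoint, exhaustive, non-nesting partition", {
  set.seed(11)
  for (i in 1:25) {
    tr <- randomSupportTree(sample(4:15, 1))
    cfg <- partitionConfig(min_clade_size = sample(1:3, 1),
                           max_clade_size = sample(4:8, 1))
    part <- initialAssignment(tr, cfg)
    leaves <- cladeLeaves(part)
    all_leaves <- unlist(leaves, use.names = FALSE)
    expect_equal(sort(all_leaves), sort(tr$tip.label))
    expect_equal(anyDuplicated(all_leaves), 0L)
    if (length(leaves) > 1) {
      for (a in seq_along(leaves)) for (b in seq_along(leaves)) {
        if (a != b) expect_false(all(leaves[[a]] %in% leaves[[b]]))
      }
    }
  }
})

test_that("unrooted trees are refused by initialAssignment", {
  tr <- ape::unroot(ape::rtree(5))
  expect_error(initialAssignment(tr), "unrooted")
})

test_that("rootBetween splits the named branch, preserves length, is idempotent", {
  tr <- ape::read.tree(text = "((A:1,B:1):2,(C:1,D:1):2);")
  r1 <- rootBetween(tr, c("A", "B"))
  expect_true(ape::is.rooted(r1))
  expect_equal(sum(r1$edge.length), sum(tr$edge.length))
  rootKids <- r1$edge[r1$edge[, 1] == ape::Ntip(r1) + 1L, 2]
  kidSets <- lapply(phangorn::Descendants(r1, rootKids, "tips"),
                    function(i) sort(r1$tip.label[i]))
  expect_setequal(vapply(kidSets, paste, character(1), collapse = ","),
                  c("A,B", "C,D"))
  r2 <- rootBetween(r1, c("A", "B"))
  expect_true(ape::all.equal.phylo(r1, r2, use.edge.length = TRUE))
  expect_error(rootBetween(tr, c("A", "C")), "not correspond to a branch")
})

test_that("refinement cuts long branches, keeps short ones, logs decisions", {
  tr <- ape::read.tree(text = "((A:0.05,B:0.05)90:0.35,(C:0.05,D:0.05)90:0.05);")
  res <- refineClade(tr, partitionConfig())
  expect_equal(length(res$subclades), 2L)
  expect_true(all(res$log$cut[res$log$rule == "long"]))

  tr2 <- ape::read.tree(text = "((A:0.05,B:0.05)90:0.08,(C:0.05,D:0.05)90:0.05);")
  res2 <- refineClade(tr2, partitionConfig())
  expect_equal(length(res2$subclades), 1L)
  expect_setequal(res2$subclades[[1]], c("A", "B", "C", "D"))
})

test_that("intermediate branches are cut only with strong support and low ecotype overlap", {
  tr <- ape::read.tree(text = "((A:0.05,B:0.05)100:0.2,(C:0.05,D:0.05)100:0.05);")
  disjoint <- c(A = "e1", B = "e2", C = "e3", D = "e4")
  res <- refineClade(tr, partitionConfig(), ecotypes = disjoint)
  expect_equal(length(res$subclades), 2L)
  expect_equal(res$log$rule[res$log$length > 0.1 & res$log$length <= 0.3],
               "intermediate")

  shared <- c(A = "e1", B = "e2", C = "e1", D = "e2")  # Jaccard 1
  res2 <- refineClade(tr, partitionConfig(), ecotypes = shared)
  expect_equal(length(res2$subclades), 1L)

  weak <- tr; weak$node.label <- c("", "50", "100")
  res3 <- refineClade(weak, partitionConfig(), ecotypes = disjoint)
  expect_equal(length(res3$subclades), 1L)

  expect_error(refineClade(tr, partitionConfig()), "ecotype")
})

test_that("refinement with infinite cutoffs is the identity", {
  set.seed(5)
  tr <- ape::rtree(10)
  tr$edge.length <- runif(nrow(tr$edge), 0, 0.6)
  res <- refineClade(tr, partitionConfig(long_branch_cutoff = Inf,
                                         short_branch_cutoff = Inf))
  expect_equal(length(res$subclades), 1L)
  expect_setequal(res$subclades[[1]], tr$tip.label)
})

test_that("refinement decisions are invariant to clade rotation", {
  set.seed(9)
  tr <- ape::rtree(8)
  tr$edge.length <- runif(nrow(tr$edge), 0, 0.5)
  tr$node.label <- as.character(sample(60:100, tr$Nnode, replace = TRUE))
  eco <- setNames(sample(paste0("e", 1:4), 8, replace = TRUE), tr$tip.label)
  rot <- ape::rotate(tr, ape::Ntip(tr) + 2L)
  a <- refineClade(tr, partitionConfig(), ecotypes = eco)
  b <- refineClade(rot, partitionConfig(), ecotypes = eco)
  expect_equal(canonicalPartition(a$subclades), canonicalPartition(b$subclades))
})

test_that("refined clades are monotone subsets of the input clade", {
  set.seed(13)
  for (i in 1:10) {
    tr <- ape::rtree(sample(5:12, 1))
    tr$edge.length <- runif(nrow(tr$edge), 0, 0.6)
    tr$node.label <- as.character(sample(0:100, tr$Nnode, replace = TRUE))
    eco <- setNames(sample(paste0("e", 1:5), ape::Ntip(tr), replace = TRUE),
                    tr$tip.label)
    res <- refineClade(tr, partitionConfig(), ecotypes = eco)
    expect_setequal(unlist(res$subclades), tr$tip.label)
    expect_equal(anyDuplicated(unlist(res$subclades)), 0L)
  }
})

test_that("allelic-series statistics match hand counts", {
  part <- list(C1 = c("x1", "x2"), C2 = c("y1", "y2"))
  eco <- c(x1 = "ecoA", x2 = "ecoB", y1 = "ecoA", y2 = "ecoA")
  s <- allelicSeriesStats(part, eco)
  expect_equal(s$allelic_fraction, 0.5)
  expect_equal(s$per_clade$max_genes_per_ecotype, c(1, 2))

  oneEach <- list(C1 = c("a", "b"), C2 = c("c", "d"))
  eco2 <- c(a = "e1", b = "e2", c = "e1", d = "e2")
  expect_equal(allelicSeriesStats(oneEach, eco2)$allelic_fraction, 1.0)

  # 19-sequence clade sits below the large-clade threshold
  big <- list(C1 = paste0("s", 1:19))
  eco3 <- setNames(paste0("e", 1:19), paste0("s", 1:19))
  expect_equal(allelicSeriesStats(big, eco3)$fraction_in_large_clades, 0.0)
  expect_equal(allelicSeriesStats(big, eco3, large_clade_min = 19)$fraction_in_large_clades, 1.0)
})
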