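test_that("designed toy complexes yield exactly the planted contacts", {
  tc <- makeToyComplex(10, c(3, 7), cutoff = 4.5, margin = 1)
  cs <- contactsFromStructure(tc$atoms, "A", "B", cutoff = 4.5)
  expect_equal(cs$contacts, c(3L, 7L))
  expect_equal(cs$contacts, tc$truth$contacts)

  none <- makeToyComplex(6, integer(0))
  expect_length(contactsFromStructure(none$atoms, "A", "B")$contacts, 0)

  # a vanishing cutoff on non-clashing chains finds nothing
  expect_length(contactsFromStructure(tc$atoms, "A", "B", cutoff = 0.1)$contacts, 0)
})

test_that("contacts survive a PDB round trip", {
  tc <- makeToyComplex(8, c(2, 5))
  f <- withr::local_tempfile(fileext = ".pdb")
  writePdb(tc$atoms, f)
  cs <- contactsFromStructure(f, "A", "B")
  expect_equal(cs$contacts, c(2L, 5L))
})

test_that("contacts are monotone in cutoff and symmetric under chain swap", {
  set.seed(41)
  atoms <- data.frame(
    chain = rep(c("A", "B"), each = 30),
    resno = rep(1:10, 6),
    x = runif(60, 0, 20), y = runif(60, 0, 20), z = runif(60, 0, 20))
  c1 <- contactsFromStructure(atoms, "A", "B", cutoff = 3)
  c2 <- contactsFromStructure(atoms, "A", "B", cutoff = 6)
  expect_true(all(c1$contacts %in% c2$contacts))

  # swap: residue pair test is symmetric, so A-contacts at cutoff c are
  # the A residues with a B atom nearby iff the mirrored evaluation from
  # B's side recovers the same pairs
  fwd <- contactsFromStructure(atoms, "A", "B", cutoff = 4)
  bwd <- contactsFromStructure(atoms, "B", "A", cutoff = 4)
  aXyz <- atoms[atoms$chain == "A", ]
  bXyz <- atoms[atoms$chain == "B", ]
  d <- as.matrix(dist(rbind(aXyz[, c("x", "y", "z")], bXyz[, c("x", "y", "z")])))
  cross <- d[1:30, 31:60]
  expect_equal(fwd$contacts, sort(unique(aXyz$resno[apply(cross <= 4, 1, any)])))
  expect_equal(bwd$contacts, sort(unique(bXyz$resno[apply(cross <= 4, 2, any)])))
})

test_that("missing or empty chains are reported", {
  tc <- makeToyComplex(5, 2)
  expect_error(contactsFromStructure(tc$atoms, "A", "Z"), "ligand chain")
  expect_error(contactsFromStructure(tc$atoms, "Q", "B"), "receptor chain")
})

test_that("toy complex construction validates its arguments", {
  expect_error(makeToyComplex(5, 2, cutoff = 4.5, margin = 5), "margin")
  expect_error(makeToyComplex(5, 9), "receptor residues")
})

test_that("precision/recall matches the set-arithmetic oracle on random instances", {
  set.seed(77)
  for (trial in 1:200) {
    nRes <- sample(5:50, 1)
    H <- runif(nRes, 0, 4.3)
    tab <- data.frame(column = seq_len(nRes), H = H, n_obs = 10L,
                      hydrophobic_pct = 0, hv = H >= 1.5)
    prof <- new("EntropyProfile", table = tab,
                criteria = unclass(hvCriteria()))
    cmap <- setNames(seq_len(nRes), seq_len(nRes))
    truth <- sample(nRes, sample(1:nRes, 1))
    cutoffs <- sort(runif(4, 0, 4.5))
    pr <- precisionRecall(prof, cmap, truth, cutoffs)
    oracle <- oraclePR(setNames(H, seq_len(nRes)), truth, cutoffs)
    expect_equal(pr$precision, unname(oracle[, "precision"]))
    expect_equal(pr$recall, unname(oracle[, "recall"]))
    expect_true(all(diff(pr$recall) <= 1e-12))
    expect_true(all(diff(pr$n_predicted) <= 0L))
  }
})

test_that("precision/recall endpoints behave as defined", {
  tab <- data.frame(column = 1:4, H = c(2, 2, 0, 0), n_obs = 5L,
                    hydrophobic_pct = 0, hv = c(TRUE, TRUE, FALSE, FALSE))
  prof <- new("EntropyProfile", table = tab, criteria = unclass(hvCriteria()))
  cmap <- setNames(1:4, 1:4)
  # predictions equal truth
  pr <- precisionRecall(prof, cmap, c(1, 2), cutoffs = 1)
  expect_equal(pr$precision, 1)
  expect_equal(pr$recall, 1)
  # 3 predicted, 2 true, 1 overlap
  tab2 <- data.frame(column = 1:5, H = c(2, 2, 2, 0, 0), n_obs = 5L,
                     hydrophobic_pct = 0, hv = TRUE)
  prof2 <- new("EntropyProfile", table = tab2, criteria = unclass(hvCriteria()))
  pr2 <- precisionRecall(prof2, setNames(1:5, 1:5), c(3, 4), cutoffs = 1)
  expect_equal(pr2$precision, 1 / 3)
  expect_equal(pr2$recall, 1 / 2)
  # cutoff above the maximum entropy: nothing predicted
  pr3 <- precisionRecall(prof, cmap, c(1, 2), cutoffs = 4)
  expect_equal(pr3$n_predicted, 0L)
  expect_true(is.na(pr3$precision))
  expect_equal(pr3$recall, 0)
  expect_error(precisionRecall(prof, cmap, integer(0)), "empty truth")
})

test_that("entropy transfers to structure residues without rescaling", {
  tc <- makeToyComplex(3, integer(0))
  tab <- data.frame(column = 1:3, H = c(0.5, 1.5, 4.0), n_obs = 8L,
                    hydrophobic_pct = 0, hv = c(FALSE, TRUE, TRUE))
  prof <- new("EntropyProfile", table = tab, criteria = unclass(hvCriteria()))
  cmap <- setNames(1:3, 1:3)
  sc <- entropyToStructure(prof, cmap, tc$atoms, "A")
  expect_equal(unname(sc), c(0.5, 1.5, 4.0), ignore_attr = TRUE)
  expect_equal(attr(sc, "n_unmapped"), 0L)

  # unmapped chain residues are omitted and counted
  sc2 <- entropyToStructure(prof, setNames(1:2, 1:2), tc$atoms, "A")
  expect_length(sc2, 2)
  expect_equal(attr(sc2, "n_unmapped"), 1L)

  expect_error(entropyToStructure(prof, setNames(1, 99), tc$atoms, "A"),
               "no chain residues")
  f <- withr::local_tempfile()
  writeAttributeFile(sc, "chimera", f)
  expect_equal(sum(grepl("^\t:", readLines(f))), 3L)
})
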