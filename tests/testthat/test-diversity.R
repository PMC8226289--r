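test_that("column entropy reproduces the analytic landmark values", {
  expect_equal(columnEntropy("AAAA"), 0)
  expect_equal(columnEntropy("AC"), 1)
  expect_equal(columnEntropy(paste(c("A","C","D","E","F","G","H","I","K","L",
                                     "M","N","P","Q","R","S","T","V","W","Y"),
                                   collapse = "")), log2(20))
  expect_equal(columnEntropy("AAAC"), -(0.75 * log2(0.75) + 0.25 * log2(0.25)))
})

test_that("gaps and ambiguity codes are not counted", {
  expect_equal(columnEntropy("A-A--"), 0)
  expect_equal(columnEntropy("ACXX--**"), 1)  # only A and C counted
  expect_equal(columnEntropy("----"), 0)
  expect_error(columnEntropy(character(0)), "empty")
})

test_that("entropy stays within [0, log2 20] and is 0 iff <= 1 distinct residue", {
  set.seed(31)
  for (i in 1:50) {
    col <- sample(c(hvnlr:::AA20, "-", "X"), sample(2:40, 1), replace = TRUE)
    H <- columnEntropy(col)
    expect_gte(H, 0)
    expect_lte(H, log2(20) + 1e-12)
    counted <- col[col %in% hvnlr:::AA20]
    if (length(unique(counted)) <= 1L) expect_equal(H, 0)
    else expect_gt(H, 0)
  }
})

test_that("hydrophobic fraction excludes gaps from the denominator", {
  expect_equal(hydrophobicFraction("VVLL"), 100)
  expect_equal(hydrophobicFraction("VVSS"), 50)
  expect_equal(hydrophobicFraction("V-SS"), 100 / 3)
  expect_equal(hydrophobicFraction("----"), 0)
})

test_that("profileAlignment computes column-wise entropy in order", {
  aln <- toyAlignment(c("AAA", "AAC"))
  prof <- profileAlignment(aln)
  expect_equal(unname(entropies(prof)), c(0, 0, 1))
  expect_equal(profileTable(prof)$n_obs, c(2L, 2L, 2L))
})

test_that("profiles are invariant to sequence order, duplication, and gap-only rows", {
  set.seed(17)
  rows <- vapply(1:8, function(i)
    paste(sample(c(hvnlr:::AA20, "-"), 30, replace = TRUE), collapse = ""),
    character(1))
  aln <- toyAlignment(rows)
  ref <- profileTable(profileAlignment(aln))

  shuffled <- toyAlignment(rows[sample(8)])
  expect_equal(profileTable(profileAlignment(shuffled))$H, ref$H)

  doubled <- toyAlignment(c(rows, rows), ids = paste0("d", 1:16))
  expect_equal(profileTable(profileAlignment(doubled))$H, ref$H)

  withGapRow <- toyAlignment(c(rows, strrep("-", 30)), ids = paste0("g", 1:9))
  expect_equal(profileTable(profileAlignment(withGapRow))$H, ref$H)
})

test_that("gap masking removes columns at the 90% boundary and maps indices", {
  rows <- c(paste0("A", "A", "C"), rep("-" , 0))
  # 10 sequences; column 1 has 9 gaps (0.9), column 2 has 8 gaps, column 3 none
  col1 <- c(rep("-", 9), "A")
  col2 <- c(rep("-", 8), "A", "A")
  col3 <- rep("A", 10)
  rows <- vapply(1:10, function(i) paste0(col1[i], col2[i], col3[i]), character(1))
  aln <- toyAlignment(rows)
  m <- maskGappyColumns(aln, 0.90)
  expect_equal(m$kept_columns, c(2L, 3L))
  expect_equal(alignmentLength(m$alignment), 2L)

  ident <- maskGappyColumns(aln, 1.01)
  expect_equal(ident$kept_columns, 1:3)

  allGap <- toyAlignment(c("--", "--"))
  expect_error(maskGappyColumns(allGap, 0.5), "masked")
})

test_that("hv classification respects the 10-position boundary", {
  mkProfile <- function(nHv) {
    # nHv columns split evenly between two residues (1.6 bits needs k>2;
    # use 3 residues ~1.585 bits), the rest invariant
    hvCol <- paste(rep(c("A", "C", "D"), 4), collapse = "")
    loCol <- strrep("A", 12)
    rows <- vapply(1:12, function(i) {
      paste0(paste(vapply(seq_len(nHv), function(j)
        substr(hvCol, i, i), character(1)), collapse = ""),
        strrep("A", 20 - nHv))
    }, character(1))
    profileAlignment(toyAlignment(rows))
  }
  expect_true(classifyHv(mkProfile(10))$is_hv)
  expect_false(classifyHv(mkProfile(9))$is_hv)
  ten <- classifyHv(mkProfile(10))
  expect_equal(ten$hv_positions, 1:10)

  zero <- profileAlignment(toyAlignment(c("AAAA", "AAAA")))
  cz <- classifyHv(zero)
  expect_false(cz$is_hv)
  expect_length(cz$hv_positions, 0)
})

test_that("hv classification is monotone in cutoff and min_positions", {
  set.seed(23)
  rows <- vapply(1:16, function(i)
    paste(sample(hvnlr:::AA20, 40, replace = TRUE), collapse = ""), character(1))
  prof <- profileAlignment(toyAlignment(rows))
  grid <- expand.grid(cutoff = c(0.5, 1.5, 2.5, 3.5), minpos = c(1, 10, 30))
  calls <- mapply(function(cc, mp)
    classifyHv(prof, hvCriteria(entropy_cutoff = cc, min_positions = mp))$is_hv,
    grid$cutoff, grid$minpos)
  for (i in seq_len(nrow(grid))) for (j in seq_len(nrow(grid))) {
    if (grid$cutoff[j] >= grid$cutoff[i] && grid$minpos[j] >= grid$minpos[i])
      expect_false(!calls[i] && calls[j])
  }
})

test_that("high-entropy residues are attributed to the right domains", {
  # reference: 10 residues preNB (1-10), 40 residues LRR (11-50)
  dom <- data.frame(domain = c("preNB", "LRR"), start = c(1L, 11L),
                    end = c(10L, 50L))
  n <- 50
  hvAt <- c(20, 30)  # inside LRR
  rows <- vapply(1:10, function(i) {
    chars <- rep("A", n)
    chars[hvAt] <- sample(c("A", "C", "D", "E"), 2, replace = TRUE)
    paste(chars, collapse = "")
  }, character(1))
  # force genuinely high entropy at the two sites
  rows <- vapply(1:10, function(i) {
    chars <- strsplit(rows[i], "")[[1]]
    chars[hvAt] <- hvnlr:::AA20[((i - 1) %% 8) + 1]
    paste(chars, collapse = "")
  }, character(1))
  aln <- toyAlignment(rows, referenceId = "s1", domains = dom)
  prof <- profileAlignment(aln)
  out <- countHvByDomain(prof, aln)
  expect_equal(out$n_hv[out$domain == "LRR"], 2L)
  expect_equal(out$percent[out$domain == "LRR"], 5.0)
  expect_equal(out$n_hv[out$domain == "preNB"], 0L)

  expect_error(countHvByDomain(prof, toyAlignment(rows, referenceId = "s1")),
               "domain annotation")
})

test_that("hv columns on reference gaps go to the nearest preceding domain", {
  # reference gapped at column 3; hv column 3 precedes any annotated domain
  # start... place domains so column 3 maps between preNB and LRR
  dom <- data.frame(domain = c("preNB", "LRR"), start = c(1L, 3L), end = c(2L, 4L))
  rows <- c(ref = "AC-GT", s2 = "ACAGT", s3 = "ACCGT", s4 = "ACDGT",
            s5 = "ACEGT", s6 = "ACFGT", s7 = "ACGGT", s8 = "ACHGT")
  aln <- toyAlignment(unname(rows), ids = names(rows),
                      referenceId = "ref", domains = dom)
  prof <- profileAlignment(aln)
  out <- countHvByDomain(prof, aln, hvCriteria(entropy_cutoff = 1.5,
                                               min_positions = 1))
  # column 3 is hv (7 distinct residues) and a reference gap following
  # reference residue 2 (preNB)
  expect_equal(out$n_hv[out$domain == "preNB"], 1L)
  expect_equal(out$n_gap_attributed[out$domain == "preNB"], 1L)
})
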