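#!/usr/bin/env Rscript

# Reproduction checks against the published Arabidopsis pan-NLRome deposits.
# These checks need externally downloaded data and therefore do not run in
# the package's test suite; point the environment variables below at local
# copies and run:
#
#   HVNLR_DATA=/path/to/deposits Rscript scripts/real_data_checks.R
#
# Expected layout under $HVNLR_DATA:
#   nbarc_tree.nwk          NB-ARC maximum-likelihood tree of the 7,818
#                           A. thaliana pan-NLRome sequences (RAxML,
#                           supports as node labels), rooted between the
#                           TNL and non-TNL clades
#   clades/*.afa            final per-clade full-length protein alignments
#                           (the Zenodo 10.5281/zenodo.3951781 deposit)
#   final_partition.tsv     leaf-id <TAB> clade-name for the final clades
#
# Reference values from the published study:
#   * 65 initial clades for the 7,818-sequence NB-ARC tree
#   * 30 hvNLR genes represented in the Col-0 reference accession
#   * 34 LRR residues at >= 1.5 bits for the RPP13 clade alignment
#   * 83% of final clades with <= 1 gene per represented ecotype

suppressMessages(library(hvnlr))

dataDir <- Sys.getenv("HVNLR_DATA", "")
if (dataDir == "" || !dir.exists(dataDir)) {
  message("HVNLR_DATA not set or not a directory; nothing to do.")
  quit(status = 0)
}

treeFile <- file.path(dataDir, "nbarc_tree.nwk")
if (file.exists(treeFile)) {
  tree <- readTree(treeFile)
  part <- initialAssignment(tree, partitionConfig())
  cat(sprintf("initial clades: %d (published: 65)\n",
              length(cladeLeaves(part))))
}

cladeDir <- file.path(dataDir, "clades")
if (dir.exists(cladeDir)) {
  files <- list.files(cladeDir, pattern = "\\.(fa|fasta|afa)$",
                      full.names = TRUE)
  hv <- vapply(files, function(f) {
    classifyHv(profileAlignment(readAlignment(f)))$is_hv
  }, logical(1))
  cat(sprintf("hv clades: %d of %d\n", sum(hv), length(hv)))
  col0 <- vapply(files[hv], function(f)
    any(grepl("^Col0|ATHALIANA|^AT[1-5]G", alignmentIds(readAlignment(f)))),
    logical(1))
  cat(sprintf("hv clades with a Col-0 allele: %d (published: 30 genes)\n",
              sum(col0)))
}

partFile <- file.path(dataDir, "final_partition.tsv")
ecoFile <- file.path(dataDir, "ecotypes.tsv")
if (file.exists(partFile) && file.exists(ecoFile)) {
  df <- utils::read.delim(partFile, stringsAsFactors = FALSE)
  ecoDf <- utils::read.delim(ecoFile, stringsAsFactors = FALSE)
  stats <- allelicSeriesStats(split(df[[1]], df[[2]]),
                              setNames(ecoDf[[2]], ecoDf[[1]]))
  cat(sprintf("allelic clade fraction: %.2f (published: 0.83)\n",
              stats$allelic_fraction))
  cat(sprintf("fraction of NLRs in clades >= 20: %.2f (published: >0.90)\n",
              stats$fraction_in_large_clades))
}
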