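#' Run the full NLRome diversity pipeline
#'
#' Chains the analysis stages in order — initial clade assignment on the
#' NB-ARC tree, per-clade refinement, per-alignment entropy profiling,
#' hvNLR classification, allelic-series statistics, and LRR surface maps
#' for the hv clades — persisting each stage's output under `outdir` and
#' writing a JSON run manifest that records the tool version, the full
#' configuration, input checksums, timestamps and every stage's output
#' path. When `resume = TRUE`, stages whose output files already exist
#' are not rewritten.
#'
#' The alignments are the externally built full-length clade alignments
#' (one [CladeAlignment-class] per clade or family); entropy, hv
#' classification and surface mapping run on them directly, while the
#' partition stages run on the tree. Every tree leaf must appear in
#' exactly one alignment, and ecotype labels must be present before any
#' refinement cutting is attempted.
#'
#' @param tree A rooted [ape::phylo] with bootstrap node labels.
#' @param alignments Named list of [CladeAlignment-class] objects.
#' @param outdir Output directory (created if needed).
#' @param cfg A [partitionConfig()].
#' @param criteria An [hvCriteria()].
#' @param refine Run the refinement stage (default TRUE; requires
#'   ecotype labels on every sequence).
#' @param resume Skip stages whose outputs exist (default FALSE).
#' @return Invisibly, the manifest as a list (also written to
#'   `outdir/manifest.json`).
#' @export
runPipeline <- function(tree, alignments, outdir, cfg = partitionConfig(),
                        criteria = hvCriteria(), refine = TRUE,
                        resume = FALSE) {
  stopifnot(inherits(tree, "phylo"), is.list(alignments),
            length(alignments) > 0L)
  allIds <- unlist(lapply(alignments, alignmentIds), use.names = FALSE)
  missing <- setdiff(tree$tip.label, allIds)
  if (length(missing))
    stop("tree leaves absent from alignments: ",
         paste(utils::head(missing, 10L), collapse = ", "))
  eco <- unlist(lapply(alignments, ecotypes))
  names(eco) <- allIds
  if (refine && any(eco == ""))
    stop("ecotype labels are required for refinement; missing for: ",
         paste(utils::head(allIds[eco == ""], 5L), collapse = ", "))

  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    partition = file.path(outdir, "initial_partition.tsv"),
    refine = file.path(outdir, "refined_partition.tsv"),
    entropy = file.path(outdir, "entropy"),
    hv_classify = file.path(outdir, "hv_summary.tsv"),
    stats = file.path(outdir, "allelic_stats.tsv"),
    surface = file.path(outdir, "surface"))

  # stage 1: initial clade assignment
  part <- initialAssignment(tree, cfg)
  if (!(resume && file.exists(paths$partition)))
    writePartition(part, paths$partition,
                   stats_path = file.path(outdir, "initial_clade_stats.tsv"))

  # stage 2: refinement of each multi-leaf clade on its induced subtree
  refLog <- list(); refined <- list()
  if (refine) {
    for (cl in names(cladeLeaves(part))) {
      leaves <- cladeLeaves(part)[[cl]]
      if (length(leaves) < 3L) { refined[[cl]] <- leaves; next }
      sub <- ape::keep.tip(tree, leaves)
      res <- refineClade(sub, cfg, ecotypes = eco)
      if (length(res$subclades) == 1L) {
        refined[[cl]] <- leaves
      } else {
        for (i in seq_along(res$subclades))
          refined[[paste0(cl, "_", i)]] <- res$subclades[[i]]
      }
      if (nrow(res$log)) refLog[[cl]] <- cbind(clade = cl, res$log)
    }
  } else refined <- cladeLeaves(part)
  refinedPart <- new("CladePartition", clades = refined,
                     stats = data.frame(clade = names(refined),
                                        node = NA_integer_,
                                        size = lengths(refined),
                                        support = NA_real_, row.names = NULL))
  if (!(resume && file.exists(paths$refine))) {
    writePartition(refinedPart, paths$refine)
    logDf <- if (length(refLog)) do.call(rbind, c(refLog, list(make.row.names = FALSE)))
             else data.frame()
    utils::write.table(logDf, file.path(outdir, "refinement_log.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # stages 3-4: entropy profiles and hv classification per alignment
  dir.create(paths$entropy, showWarnings = FALSE)
  profiles <- lapply(alignments, profileAlignment, criteria = criteria)
  for (nm in names(profiles)) {
    f <- file.path(paths$entropy, paste0(nm, "_entropy.tsv"))
    if (!(resume && file.exists(f))) writeProfile(profiles[[nm]], f)
  }
  hv <- lapply(profiles, classifyHv, criteria = criteria)
  hvSummary <- data.frame(clade = names(hv),
                          n_hv_positions = vapply(hv, function(x) length(x$hv_positions), integer(1)),
                          is_hv = vapply(hv, `[[`, logical(1), "is_hv"),
                          row.names = NULL)
  if (!(resume && file.exists(paths$hv_classify)))
    utils::write.table(hvSummary, paths$hv_classify, sep = "\t", quote = FALSE,
                       row.names = FALSE)

  # stage 5: allelic-series statistics of the refined partition
  treeEco <- eco[tree$tip.label]
  stats <- allelicSeriesStats(refinedPart, treeEco)
  if (!(resume && file.exists(paths$stats)))
    utils::write.table(stats$per_clade, paths$stats, sep = "\t", quote = FALSE,
                       row.names = FALSE)

  # stage 6: LRR surface maps for hv alignments with a reference sequence
  dir.create(paths$surface, showWarnings = FALSE)
  for (nm in names(alignments)[hvSummary$is_hv]) {
    aln <- alignments[[nm]]
    if (is.na(referenceId(aln))) next
    cmap <- referenceColumnMap(aln)
    refSeq <- gsub("[-.]", "", as.character(aln@seqs[[referenceId(aln)]]))
    ann <- annotateLrr(refSeq)
    if (nrow(ann) == 0L) next
    sm <- buildSurfaceMatrix(ann, refSeq, profile = profiles[[nm]],
                             column_map = cmap)
    f <- file.path(paths$surface, paste0(nm, "_surface_entropy.tsv"))
    if (!(resume && file.exists(f)))
      writeSurfaceMatrix(sm, f, layer = "entropy")
  }

  manifest <- list(
    tool = "hvnlr",
    version = as.character(utils::packageVersion("hvnlr")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(cfg),
    criteria = criteria[c("entropy_cutoff", "min_positions")],
    inputs = list(n_leaves = ape::Ntip(tree),
                  n_alignments = length(alignments),
                  tree_md5 = objectMd5(tree),
                  alignments_md5 = objectMd5(lapply(alignments, function(a)
                    as.character(a@seqs)))),
    stages = paths)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

# md5 checksum of a serialized R object (for the run manifest)
objectMd5 <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2L)
  unname(tools::md5sum(f))
}
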