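#' @include hvnlr-package.R
NULL

setOldClass("phylo")

#' CladeAlignment: a gapped protein alignment with NLR metadata
#'
#' Container for a clade's multiple protein sequence alignment together with
#' the per-sequence ecotype (accession) labels, an optional designated
#' reference sequence, and optional domain intervals (preNB, NB-ARC, linker,
#' LRR, postLRR) in 1-based inclusive residue coordinates on the ungapped
#' reference.
#'
#' @slot seqs An [Biostrings::AAStringSet] of gapped sequences, all the same
#'   width, uniquely named.
#' @slot ecotype Character vector parallel to `seqs` (may be empty strings).
#' @slot referenceId Length-one character, `NA_character_` when unset.
#' @slot domains A data.frame with columns `domain`, `start`, `end`
#'   (zero rows when unset); intervals non-overlapping and ordered.
#'
#' @seealso [readAlignment()], [profileAlignment()]
#' @export
setClass("CladeAlignment",
  representation(
    seqs = "AAStringSet",
    ecotype = "character",
    referenceId = "character",
    domains = "data.frame"
  )
)

setValidity("CladeAlignment", function(object) {
  msgs <- character()
  w <- Biostrings::width(object@seqs)
  if (length(w) == 0L) msgs <- c(msgs, "alignment has no sequences")
  if (length(unique(w)) > 1L) {
    bad <- names(object@seqs)[w != w[1L]][1L]
    msgs <- c(msgs, sprintf("ragged alignment: record '%s' has length %d, expected %d",
                            bad, w[w != w[1L]][1L], w[1L]))
  }
  if (anyDuplicated(names(object@seqs)))
    msgs <- c(msgs, "duplicated sequence ids")
  if (length(object@ecotype) != length(object@seqs))
    msgs <- c(msgs, "ecotype vector length differs from number of sequences")
  if (length(object@referenceId) != 1L)
    msgs <- c(msgs, "referenceId must be length one (NA allowed)")
  if (!is.na(object@referenceId) && !object@referenceId %in% names(object@seqs))
    msgs <- c(msgs, sprintf("referenceId '%s' not among sequence ids", object@referenceId))
  if (nrow(object@domains) > 0L) {
    d <- object@domains
    if (!all(c("domain", "start", "end") %in% colnames(d)))
      msgs <- c(msgs, "domains must have columns domain, start, end")
    else {
      if (!all(d$domain %in% DOMAIN_NAMES))
        msgs <- c(msgs, "unknown domain name(s)")
      if (any(d$start > d$end)) msgs <- c(msgs, "domain start > end")
      if (nrow(d) > 1L) {
        o <- order(d$start)
        if (any(d$start[o][-1L] <= d$end[o][-nrow(d)]))
          msgs <- c(msgs, "domain intervals overlap")
      }
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a CladeAlignment
#'
#' @param seqs An [Biostrings::AAStringSet] or named character vector of
#'   gapped sequences of identical length.
#' @param ecotype Character vector of ecotype labels, or `NULL` to fill with
#'   empty strings.
#' @param referenceId Optional id of the reference sequence.
#' @param domains Optional data.frame of domain intervals (`domain`,
#'   `start`, `end`), 1-based inclusive on the ungapped reference.
#' @return A [CladeAlignment-class] object.
#' @examples
#' aln <- cladeAlignment(c(a = "AR-ND", b = "ARCND"))
#' alignmentLength(aln)
#' @export
cladeAlignment <- function(seqs, ecotype = NULL, referenceId = NA_character_,
                           domains = NULL) {
  if (is.character(seqs)) seqs <- Biostrings::AAStringSet(seqs)
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    stop("all sequences must be named")
  if (is.null(ecotype)) ecotype <- rep("", length(seqs))
  if (is.null(domains))
    domains <- data.frame(domain = character(), start = integer(),
                          end = integer(), stringsAsFactors = FALSE)
  new("CladeAlignment", seqs = seqs, ecotype = as.character(ecotype),
      referenceId = as.character(referenceId), domains = domains)
}

#' @describeIn cladeAlignment Number of alignment columns.
#' @param x A `CladeAlignment`.
#' @export
alignmentLength <- function(x) {
  stopifnot(is(x, "CladeAlignment"))
  unname(Biostrings::width(x@seqs)[1L])
}

#' @describeIn cladeAlignment Sequence ids.
#' @export
alignmentIds <- function(x) names(x@seqs)

#' @describeIn cladeAlignment Ecotype labels, named by sequence id.
#' @export
ecotypes <- function(x) setNames(x@ecotype, names(x@seqs))

#' @describeIn cladeAlignment Domain interval table.
#' @export
alignmentDomains <- function(x) x@domains

#' @describeIn cladeAlignment Id of the designated reference sequence.
#' @export
referenceId <- function(x) x@referenceId

#' @describeIn cladeAlignment Character matrix (sequences x columns).
#' @export
alignmentMatrix <- function(x) {
  m <- do.call(rbind, strsplit(as.character(x@seqs), "", fixed = TRUE))
  rownames(m) <- names(x@seqs)
  m
}

setMethod("show", "CladeAlignment", function(object) {
  cat(sprintf("CladeAlignment: %d sequences x %d columns\n",
              length(object@seqs), alignmentLength(object)))
  eco <- unique(object@ecotype[object@ecotype != ""])
  if (length(eco)) cat(sprintf("  ecotypes: %d distinct\n", length(eco)))
  if (!is.na(object@referenceId))
    cat(sprintf("  reference: %s\n", object@referenceId))
  if (nrow(object@domains))
    cat(sprintf("  domains: %s\n", paste(object@domains$domain, collapse = ", ")))
})

#' Subset a CladeAlignment by sequence id
#'
#' @param x A `CladeAlignment`.
#' @param ids Sequence ids to keep.
#' @return A `CladeAlignment` with the selected records; the reference id is
#'   dropped if not retained.
#' @export
subsetAlignment <- function(x, ids) {
  stopifnot(is(x, "CladeAlignment"))
  keep <- match(ids, names(x@seqs))
  if (anyNA(keep))
    stop("ids not in alignment: ", paste(ids[is.na(keep)], collapse = ", "))
  ref <- if (!is.na(x@referenceId) && x@referenceId %in% ids) x@referenceId else NA_character_
  new("CladeAlignment", seqs = x@seqs[keep], ecotype = x@ecotype[keep],
      referenceId = ref, domains = x@domains)
}

#' CladePartition: disjoint exhaustive assignment of tree leaves to clades
#'
#' @slot clades Named list; each element a character vector of leaf labels.
#' @slot stats data.frame with one row per clade: `clade`, `node`, `size`,
#'   `support`.
#' @seealso [initialAssignment()]
#' @export
setClass("CladePartition",
  representation(clades = "list", stats = "data.frame")
)

setValidity("CladePartition", function(object) {
  msgs <- character()
  all_leaves <- unlist(object@clades, use.names = FALSE)
  if (anyDuplicated(all_leaves))
    msgs <- c(msgs, "clades are not disjoint")
  if (is.null(names(object@clades)) || anyDuplicated(names(object@clades)))
    msgs <- c(msgs, "clade names must be unique")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn initialAssignment Named list of leaf-label vectors.
#' @export
cladeLeaves <- function(partition) {
  stopifnot(is(partition, "CladePartition"))
  partition@clades
}

#' @describeIn initialAssignment Per-clade statistics table.
#' @export
cladeStats <- function(partition) {
  stopifnot(is(partition, "CladePartition"))
  partition@stats
}

setMethod("show", "CladePartition", function(object) {
  sizes <- lengths(object@clades)
  cat(sprintf("CladePartition: %d clades over %d leaves (sizes %d-%d)\n",
              length(object@clades), sum(sizes), min(sizes), max(sizes)))
})

#' EntropyProfile: per-column diversity profile of a clade alignment
#'
#' One row per alignment column carrying the plug-in Shannon entropy in bits
#' (frequencies over the 20 standard amino acids, gaps and ambiguity codes
#' excluded), the number of counted residues, the hydrophobic-residue
#' percentage, and the highly-variable flag at the configured cutoff.
#'
#' @slot table data.frame with columns `column`, `H`, `n_obs`,
#'   `hydrophobic_pct`, `hv`.
#' @slot criteria The [hvCriteria()] list used for the `hv` flags.
#' @seealso [profileAlignment()], [classifyHv()]
#' @export
setClass("EntropyProfile",
  representation(table = "data.frame", criteria = "list")
)

setValidity("EntropyProfile", function(object) {
  msgs <- character()
  need <- c("column", "H", "n_obs", "hydrophobic_pct", "hv")
  if (!all(need %in% colnames(object@table)))
    msgs <- c(msgs, "profile table missing required columns")
  else {
    H <- object@table$H
    if (any(H < 0 | H > log2(20) + 1e-9))
      msgs <- c(msgs, "entropy outside [0, log2 20]")
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn profileAlignment The per-column table.
#' @export
profileTable <- function(profile) {
  stopifnot(is(profile, "EntropyProfile"))
  profile@table
}

#' @describeIn profileAlignment Vector of per-column entropies (bits).
#' @export
entropies <- function(profile) {
  stopifnot(is(profile, "EntropyProfile"))
  setNames(profile@table$H, profile@table$column)
}

setMethod("show", "EntropyProfile", function(object) {
  t <- object@table
  cat(sprintf("EntropyProfile: %d columns; H in [%.3f, %.3f] bits; %d hv at >=%.2f bits\n",
              nrow(t), min(t$H), max(t$H), sum(t$hv),
              object@criteria$entropy_cutoff))
})

#' SurfaceMatrix: 2D map of the LRR concave surface
#'
#' Rows are LRR repeat units (row 1 = first repeat); columns are
#' repeat-relative positions labelled -5..-1, 1..8, 9..13 around the
#' 8-residue LxxLxLxx core (conserved positions 1, 4, 6). Cells hold the
#' residue character, the reference residue number, and optionally the
#' column entropy (bits) and hydrophobic percentage. Empty cells (`NA`)
#' arise where flanks of adjacent repeats overlap or run off the sequence.
#'
#' @slot residues character matrix, repeats x positions.
#' @slot resno integer matrix of reference residue numbers.
#' @slot entropy numeric matrix of entropies (NA when no overlay).
#' @slot hydro numeric matrix of hydrophobic percentages.
#' @slot positions integer vector of column position labels.
#' @slot coreStarts integer vector of repeat core start residues.
#' @seealso [buildSurfaceMatrix()], [trimMatrix()]
#' @export
setClass("SurfaceMatrix",
  representation(
    residues = "matrix", resno = "matrix", entropy = "matrix",
    hydro = "matrix", positions = "integer", coreStarts = "integer"
  )
)

setValidity("SurfaceMatrix", function(object) {
  msgs <- character()
  dims <- dim(object@residues)
  for (s in c("resno", "entropy", "hydro"))
    if (!identical(dim(slot(object, s)), dims))
      msgs <- c(msgs, sprintf("slot '%s' dimensions differ from residues", s))
  if (ncol(object@residues) != length(object@positions))
    msgs <- c(msgs, "positions length must equal column count")
  if (nrow(object@residues) != length(object@coreStarts))
    msgs <- c(msgs, "row count must equal repeat count")
  rn <- object@resno[!is.na(object@resno)]
  if (anyDuplicated(rn))
    msgs <- c(msgs, "a reference residue appears in more than one cell")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn buildSurfaceMatrix Position labels of the matrix columns.
#' @export
surfacePositions <- function(matrix) {
  stopifnot(is(matrix, "SurfaceMatrix"))
  matrix@positions
}

#' @describeIn buildSurfaceMatrix Residue-character matrix.
#' @export
surfaceResidues <- function(matrix) {
  stopifnot(is(matrix, "SurfaceMatrix"))
  matrix@residues
}

#' @describeIn buildSurfaceMatrix Entropy overlay matrix (bits).
#' @export
surfaceEntropy <- function(matrix) {
  stopifnot(is(matrix, "SurfaceMatrix"))
  matrix@entropy
}

setMethod("show", "SurfaceMatrix", function(object) {
  cat(sprintf("SurfaceMatrix: %d repeats x %d positions (%s)\n",
              nrow(object@residues), length(object@positions),
              paste(range(object@positions), collapse = "..")))
})
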