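#' Detector settings for LxxLxLxx repeat annotation
#'
#' The concave beta-sheet face of an LRR domain is built from tandem
#' repeats whose 8-residue core follows the LxxLxLxx pattern, with the
#' conserved leucine-class positions at core offsets 1, 4 and 6. Manual
#' annotations in the field tolerate other aliphatic residues at the
#' conserved positions, so the detector's residue class is configurable.
#'
#' @param aliphatic_class Residues accepted at the conserved positions
#'   (default L, I, V, F, M, C, A).
#' @param min_spacing Minimum distance between successive core starts
#'   (default 8, i.e. non-overlapping cores).
#' @return A list of class `LrrDetectorConfig`.
#' @export
lrrDetectorConfig <- function(aliphatic_class = c("L", "I", "V", "F", "M", "C", "A"),
                              min_spacing = 8L) {
  if (min_spacing < 8L) stop("min_spacing must be >= 8 (core length)")
  structure(list(aliphatic_class = toupper(aliphatic_class),
                 min_spacing = as.integer(min_spacing)),
            class = c("LrrDetectorConfig", "list"))
}

#' Annotate LxxLxLxx repeats on an ungapped protein sequence
#'
#' Scans left to right for the 8-residue core pattern (aliphatic-class
#' residues at offsets 1, 4, 6), greedily accepting matches at least
#' `min_spacing` residues apart. User-supplied annotations bypass
#' detection and are returned verbatim. Matching is case-insensitive.
#'
#' @param sequence Ungapped protein string (>= 24 residues for detection).
#' @param params An [lrrDetectorConfig()].
#' @param repeats Optional user annotation: data.frame with column
#'   `core_start` (1-based residue of the first conserved position).
#' @return A data.frame of class `LRRAnnotation` with columns
#'   `repeat_index`, `core_start`, and attribute `source`
#'   (`"detector"` or `"user-supplied"`). Zero rows is a valid result.
#' @examples
#' annotateLrr(strrep(paste0("LRALDLSN", strrep("T", 16)), 4))
#' @export
annotateLrr <- function(sequence, params = lrrDetectorConfig(), repeats = NULL) {
  if (!is.null(repeats)) {
    stopifnot("core_start" %in% colnames(repeats))
    out <- data.frame(repeat_index = seq_len(nrow(repeats)),
                      core_start = as.integer(repeats$core_start))
    attr(out, "source") <- "user-supplied"
    class(out) <- c("LRRAnnotation", "data.frame")
    return(out)
  }
  chars <- toupper(strsplit(sequence, "", fixed = TRUE)[[1L]])
  n <- length(chars)
  if (n < 24L) stop("sequence too short for repeat detection (< 24 residues)")
  cls <- chars %in% params$aliphatic_class
  starts <- integer(0)
  i <- 1L
  while (i <= n - 7L) {
    if (cls[i] && cls[i + 3L] && cls[i + 5L]) {
      starts <- c(starts, i)
      i <- i + params$min_spacing
    } else i <- i + 1L
  }
  out <- data.frame(repeat_index = seq_along(starts), core_start = starts)
  attr(out, "source") <- "detector"
  class(out) <- c("LRRAnnotation", "data.frame")
  out
}

# Position labels of the full surface matrix: five flanking residues on
# either side of the 8-residue core; there is no position 0.
surfacePositionLabels <- function(flank = 5L) {
  c(seq.int(-flank, -1L), 1:8, seq.int(9L, 8L + flank))
}

# Residue index addressed by (core_start, position label).
positionToResidue <- function(core_start, p) {
  ifelse(p > 0L, core_start + p - 1L, core_start + p)
}

#' Build the 2D LRR concave-surface matrix
#'
#' Arranges the annotated repeats as rows (repeat 1 first; render bottom
#' to top to reproduce the concave-face array) and repeat-relative
#' positions as columns: the 8-residue core at positions 1-8 plus
#' `flank` additional residues on either side (labels -5..-1 and 9..13 by
#' default). Inter-core residues claimed by the flanks of two adjacent
#' repeats are assigned to the nearer core, with ties going to the
#' preceding repeat, so each reference residue occupies at most one cell.
#' Hiding columns 1, 4 and 6 (the conserved leucines) leaves the
#' surface-exposed positions. When an entropy profile and a column map
#' are given, each cell also carries its column's entropy and hydrophobic
#' percentage.
#'
#' @param annotation An `LRRAnnotation` from [annotateLrr()].
#' @param sequence The ungapped reference protein string.
#' @param profile Optional [EntropyProfile-class] of the clade alignment.
#' @param column_map Optional named integer vector, reference residue
#'   number -> alignment column (see [referenceColumnMap()]); required
#'   with `profile`, and it must cover every residue placed in the
#'   matrix.
#' @param flank Flanking residues on either side of the core (default 5).
#' @return A [SurfaceMatrix-class].
#' @export
buildSurfaceMatrix <- function(annotation, sequence, profile = NULL,
                               column_map = NULL, flank = 5L) {
  stopifnot(inherits(annotation, "LRRAnnotation"))
  if (nrow(annotation) == 0L) stop("annotation has no repeats")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  cs <- annotation$core_start
  if (is.unsorted(cs)) stop("repeats must be ordered by core_start")
  if (any(cs < 1L) || any(cs + 7L > n))
    stop("repeat core outside sequence bounds")
  nr <- length(cs)
  pos <- as.integer(surfacePositionLabels(flank))

  # owner of every residue: which repeat's row may display it
  coreEnd <- cs + 7L
  owner <- integer(n)            # 0 = unassigned
  for (r in seq_len(nr)) owner[cs[r]:coreEnd[r]] <- r
  for (r in seq_len(nr)) {
    lo <- if (r == 1L) 1L else coreEnd[r - 1L] + 1L
    hi <- if (r == nr) n else cs[r + 1L] - 1L
    gapRes <- setdiff(lo:hi, cs[r]:coreEnd[r])
    for (res in gapRes) {
      if (res < cs[r]) {
        dPrev <- if (r == 1L) Inf else res - coreEnd[r - 1L]
        dThis <- cs[r] - res
        owner[res] <- if (dPrev <= dThis) r - 1L else r
      } else {
        dThis <- res - coreEnd[r]
        dNext <- if (r == nr) Inf else cs[r + 1L] - res
        owner[res] <- if (dThis <= dNext) r else r + 1L
      }
    }
  }

  resno <- matrix(NA_integer_, nr, length(pos),
                  dimnames = list(paste0("LRR", seq_len(nr)), pos))
  for (r in seq_len(nr)) for (k in seq_along(pos)) {
    res <- positionToResidue(cs[r], pos[k])
    if (res >= 1L && res <= n && owner[res] == r) resno[r, k] <- res
  }
  residues <- matrix(NA_character_, nr, length(pos), dimnames = dimnames(resno))
  residues[!is.na(resno)] <- chars[resno[!is.na(resno)]]

  entropy <- matrix(NA_real_, nr, length(pos), dimnames = dimnames(resno))
  hydro <- matrix(NA_real_, nr, length(pos), dimnames = dimnames(resno))
  if (!is.null(profile)) {
    if (is.null(column_map)) stop("column_map is required with a profile overlay")
    filled <- resno[!is.na(resno)]
    missing <- setdiff(as.character(filled), names(column_map))
    if (length(missing))
      stop("residues absent from column_map: ", paste(missing, collapse = ", "))
    tab <- profileTable(profile)
    cols <- column_map[as.character(resno)]
    entropy[] <- tab$H[cols]
    hydro[] <- tab$hydrophobic_pct[cols]
  }
  new("SurfaceMatrix", residues = residues, resno = resno, entropy = entropy,
      hydro = hydro, positions = pos, coreStarts = as.integer(cs))
}

#' Trim a surface matrix to selected repeat positions
#'
#' Keeps only the given position labels (default: the nine
#' surface-informative positions -2, -1, 2, 3, 5, 7, 8, 10, 11), leaving
#' cell contents and row order unchanged.
#'
#' @param matrix A [SurfaceMatrix-class].
#' @param keep_positions Integer position labels to keep.
#' @return A [SurfaceMatrix-class] with the selected columns.
#' @export
trimMatrix <- function(matrix, keep_positions = c(-2L, -1L, 2L, 3L, 5L, 7L, 8L, 10L, 11L)) {
  stopifnot(is(matrix, "SurfaceMatrix"))
  keep_positions <- as.integer(keep_positions)
  unknown <- setdiff(keep_positions, matrix@positions)
  if (length(unknown))
    stop("unknown position label(s): ", paste(unknown, collapse = ", "))
  k <- which(matrix@positions %in% keep_positions)
  new("SurfaceMatrix",
      residues = matrix@residues[, k, drop = FALSE],
      resno = matrix@resno[, k, drop = FALSE],
      entropy = matrix@entropy[, k, drop = FALSE],
      hydro = matrix@hydro[, k, drop = FALSE],
      positions = matrix@positions[k],
      coreStarts = matrix@coreStarts)
}

#' Tabular entropy/hydrophobicity report of an LRR surface
#'
#' Produces the two aligned repeat-by-position tables (entropy in bits and
#' hydrophobic percentage) plus the candidate binding residues: cells
#' whose entropy reaches the cutoff and whose column contains hydrophobic
#' residues.
#'
#' @param matrix A [SurfaceMatrix-class] with entropy overlay.
#' @param criteria An [hvCriteria()].
#' @return A list with `entropy` and `hydrophobicity` matrices (rows
#'   ordered bottom-to-top, i.e. last repeat first, as the surface is
#'   drawn) and `flagged` (data.frame of candidate binding cells).
#' @export
surfaceReport <- function(matrix, criteria = hvCriteria()) {
  stopifnot(is(matrix, "SurfaceMatrix"))
  if (all(is.na(matrix@entropy))) stop("surface matrix has no entropy overlay")
  flag <- !is.na(matrix@entropy) & matrix@entropy >= criteria$entropy_cutoff &
    !is.na(matrix@hydro) & matrix@hydro > 0
  idx <- which(flag, arr.ind = TRUE)
  flagged <- data.frame(repeat_index = idx[, 1L],
                        position = matrix@positions[idx[, 2L]],
                        residue = matrix@residues[idx],
                        resno = matrix@resno[idx],
                        entropy = matrix@entropy[idx],
                        hydrophobic_pct = matrix@hydro[idx])
  flagged <- flagged[order(flagged$repeat_index, flagged$position), , drop = FALSE]
  rownames(flagged) <- NULL
  bottomUp <- rev(seq_len(nrow(matrix@entropy)))
  list(entropy = matrix@entropy[bottomUp, , drop = FALSE],
       hydrophobicity = matrix@hydro[bottomUp, , drop = FALSE],
       flagged = flagged)
}

#' Write a surface matrix to TSV
#'
#' Rows are written bottom-to-top (last repeat first), the orientation
#' used for concave-face figures.
#'
#' @param matrix A [SurfaceMatrix-class].
#' @param path Output path.
#' @param layer `"residues"`, `"entropy"`, or `"hydro"`.
#' @return Invisibly, `path`.
#' @export
writeSurfaceMatrix <- function(matrix, path, layer = c("residues", "entropy", "hydro")) {
  stopifnot(is(matrix, "SurfaceMatrix"))
  layer <- match.arg(layer)
  m <- slot(matrix, layer)
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  utils::write.table(cbind(repeat_unit = rownames(m), as.data.frame(m)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
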