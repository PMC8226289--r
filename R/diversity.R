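#' Criteria for calling a clade highly variable (hvNLR)
#'
#' A clade alignment is classified highly variable when it contains at
#' least `min_positions` columns whose Shannon entropy reaches
#' `entropy_cutoff` bits. The hydrophobic residue set is used for the
#' per-column hydrophobic percentage; the default set covers the aliphatic
#' and aromatic side chains commonly found at protein-protein interface
#' cores, including tryptophan and phenylalanine.
#'
#' @param entropy_cutoff Entropy threshold in bits (default 1.5).
#' @param min_positions Minimum number of columns at or above the cutoff
#'   (default 10).
#' @param hydrophobic_set Amino acids counted as hydrophobic (default
#'   A, V, L, I, M, F, W, C).
#' @return A validated list of class `HvCriteria`.
#' @export
hvCriteria <- function(entropy_cutoff = 1.5, min_positions = 10L,
                       hydrophobic_set = c("A", "V", "L", "I", "M", "F", "W", "C")) {
  if (entropy_cutoff <= 0) stop("entropy_cutoff must be > 0")
  if (min_positions < 1L) stop("min_positions must be >= 1")
  if (!all(hydrophobic_set %in% AA20)) stop("hydrophobic_set must be standard amino acids")
  structure(list(entropy_cutoff = entropy_cutoff,
                 min_positions = as.integer(min_positions),
                 hydrophobic_set = hydrophobic_set),
            class = c("HvCriteria", "list"))
}

#' Shannon entropy of one alignment column
#'
#' Plug-in Shannon entropy \eqn{H = -\sum_{i=1}^{20} p_i \log_2 p_i} where
#' \eqn{p_i} is the fraction of each of the 20 standard amino acids among
#' the counted residues of the column. Gap characters (`-`, `.`) and
#' ambiguity codes (`X`, `B`, `Z`, `*`) are not counted: they enter neither
#' the numerator nor the denominator of the frequencies. A column with at
#' most one distinct counted residue has entropy 0; the maximum, reached
#' when all 20 amino acids occur in equal ratios, is
#' \eqn{\log_2 20 \approx 4.32} bits.
#'
#' @param column Character vector of single residues, or a single string.
#' @return Entropy in bits.
#' @examples
#' columnEntropy("AAAA")          # 0
#' columnEntropy(c("A", "C"))     # 1 bit
#' @export
columnEntropy <- function(column) {
  chars <- splitColumn(column)
  if (length(chars) == 0L) stop("empty column")
  counts <- tabulate(match(chars, AA20), nbins = 20L)
  n <- sum(counts)
  if (n <= 1L) return(0)
  p <- counts[counts > 0L] / n
  max(0, -sum(p * log2(p)))  # guard against -0 for invariant columns
}

splitColumn <- function(column) {
  if (length(column) == 1L && nchar(column) > 1L)
    column <- strsplit(column, "", fixed = TRUE)[[1L]]
  toupper(as.character(column))
}

#' Hydrophobic residue percentage of one alignment column
#'
#' Returns 100 times the fraction of counted residues that belong to the
#' hydrophobic set; gaps and ambiguity codes are excluded from numerator
#' and denominator alike. An all-gap column yields 0.
#'
#' @param column Character vector of single residues, or a single string.
#' @param hydrophobic_set See [hvCriteria()].
#' @return Percentage in `[0, 100]`.
#' @examples
#' hydrophobicFraction("VVSS")  # 50
#' @export
hydrophobicFraction <- function(column,
                                hydrophobic_set = hvCriteria()$hydrophobic_set) {
  chars <- splitColumn(column)
  if (length(chars) == 0L) stop("empty column")
  counted <- chars[chars %in% AA20]
  if (length(counted) == 0L) return(0)
  100 * sum(counted %in% hydrophobic_set) / length(counted)
}

#' Per-column entropy and hydrophobicity profile of an alignment
#'
#' Computes, for every column of a clade alignment, the Shannon entropy
#' (bits), the number of counted (non-gap, non-ambiguous) residues, the
#' hydrophobic percentage, and the highly-variable flag
#' `H >= entropy_cutoff`.
#'
#' @param aln A [CladeAlignment-class].
#' @param criteria An [hvCriteria()].
#' @return An [EntropyProfile-class].
#' @export
profileAlignment <- function(aln, criteria = hvCriteria()) {
  stopifnot(is(aln, "CladeAlignment"))
  m <- alignmentMatrix(aln)
  idx <- matrix(match(toupper(m), AA20), nrow = nrow(m))
  ncol_aln <- ncol(m)
  H <- numeric(ncol_aln); nObs <- integer(ncol_aln); hyd <- numeric(ncol_aln)
  hydroIdx <- match(criteria$hydrophobic_set, AA20)
  for (j in seq_len(ncol_aln)) {
    counts <- tabulate(idx[, j], nbins = 20L)
    n <- sum(counts)
    nObs[j] <- n
    if (n >= 1L) hyd[j] <- 100 * sum(counts[hydroIdx]) / n
    if (n > 1L) {
      p <- counts[counts > 0L] / n
      H[j] <- max(0, -sum(p * log2(p)))
    }
  }
  tab <- data.frame(column = seq_len(ncol_aln), H = H, n_obs = nObs,
                    hydrophobic_pct = hyd, hv = H >= criteria$entropy_cutoff)
  new("EntropyProfile", table = tab, criteria = unclass(criteria))
}

#' Mask gappy alignment columns
#'
#' Removes columns whose gap fraction is at least `fraction` (the masking
#' applied to full-length clade alignments before the first refinement
#' round) and returns the masked alignment together with the map from new
#' to original column indices.
#'
#' @param aln A [CladeAlignment-class].
#' @param fraction Gap-fraction cutoff (default 0.90); columns with gap
#'   fraction `>= fraction` are dropped.
#' @return A list with `alignment` (masked [CladeAlignment-class]) and
#'   `kept_columns` (integer vector: original index of each kept column).
#' @export
maskGappyColumns <- function(aln, fraction = 0.90) {
  stopifnot(is(aln, "CladeAlignment"))
  m <- alignmentMatrix(aln)
  gapFrac <- colMeans(matrix(m %in% GAP_CHARS, nrow = nrow(m)))
  keep <- which(gapFrac < fraction)
  if (length(keep) == 0L) stop("all columns masked at fraction ", fraction)
  masked <- apply(m[, keep, drop = FALSE], 1L, paste, collapse = "")
  out <- cladeAlignment(setNames(masked, rownames(m)),
                        ecotype = aln@ecotype,
                        referenceId = aln@referenceId,
                        domains = aln@domains)
  list(alignment = out, kept_columns = keep)
}

#' Classify a clade as highly variable (hvNLR)
#'
#' A clade is an hvNLR when its alignment profile has at least
#' `min_positions` columns with entropy at or above `entropy_cutoff` bits.
#'
#' @param profile An [EntropyProfile-class].
#' @param criteria An [hvCriteria()]; defaults to the criteria stored in
#'   the profile.
#' @return A list with `is_hv` (logical) and `hv_positions` (ascending
#'   column indices at or above the cutoff).
#' @export
classifyHv <- function(profile, criteria = NULL) {
  stopifnot(is(profile, "EntropyProfile"))
  if (is.null(criteria)) criteria <- profile@criteria
  pos <- profile@table$column[profile@table$H >= criteria$entropy_cutoff]
  list(is_hv = length(pos) >= criteria$min_positions,
       hv_positions = sort(pos))
}

#' Map alignment columns to reference residue numbers
#'
#' Ungaps the designated reference sequence of an alignment and returns
#' the map from reference residue number (1-based) to alignment column.
#'
#' @param aln A [CladeAlignment-class] with a reference sequence set.
#' @return Named integer vector: names are residue numbers, values are
#'   alignment columns.
#' @export
referenceColumnMap <- function(aln) {
  stopifnot(is(aln, "CladeAlignment"))
  if (is.na(aln@referenceId)) stop("alignment has no reference sequence set")
  refRow <- strsplit(as.character(aln@seqs[[aln@referenceId]]), "", fixed = TRUE)[[1L]]
  cols <- which(!refRow %in% GAP_CHARS)
  setNames(cols, seq_along(cols))
}

#' Count high-entropy columns per annotated domain
#'
#' Attributes each highly-variable alignment column to a domain of the
#' reference gene (preNB, NB-ARC, linker, LRR, postLRR). Columns that are
#' gaps in the reference, or fall between annotated intervals, are
#' attributed to the nearest preceding domain (preNB when none precedes)
#' and flagged. Percentages are relative to annotated domain length.
#'
#' @param profile An [EntropyProfile-class].
#' @param aln A [CladeAlignment-class] with reference and domain
#'   annotation.
#' @param criteria Optional [hvCriteria()] overriding the profile's.
#' @return A data.frame with one row per annotated domain: `domain`,
#'   `n_hv`, `domain_length`, `percent`, `n_gap_attributed`.
#' @export
countHvByDomain <- function(profile, aln, criteria = NULL) {
  stopifnot(is(profile, "EntropyProfile"), is(aln, "CladeAlignment"))
  if (nrow(aln@domains) == 0L) stop("alignment has no domain annotation")
  if (is.null(criteria)) criteria <- profile@criteria
  cmap <- referenceColumnMap(aln)  # residue -> column
  colToRes <- integer(alignmentLength(aln))  # 0 where reference is gapped
  colToRes[cmap] <- as.integer(names(cmap))
  # residue number governing each column: its own, else nearest preceding
  governing <- cummax(colToRes)

  hvCols <- profile@table$column[profile@table$H >= criteria$entropy_cutoff]
  dom <- aln@domains[order(aln@domains$start), , drop = FALSE]

  assignDomain <- function(res) {
    inside <- which(dom$start <= res & dom$end >= res)
    if (length(inside)) return(dom$domain[inside[1L]])
    prev <- which(dom$end < res)
    if (length(prev)) dom$domain[max(prev)] else "preNB"
  }
  hvRes <- governing[hvCols]
  hvDomains <- vapply(hvRes, function(r) if (r == 0L) "preNB" else assignDomain(r),
                      character(1))
  direct <- colToRes[hvCols] > 0L &
    vapply(hvCols, function(cc) {
      r <- colToRes[cc]
      r > 0L && any(dom$start <= r & dom$end >= r)
    }, logical(1))

  out <- data.frame(domain = dom$domain,
                    n_hv = vapply(dom$domain, function(d) sum(hvDomains == d), integer(1)),
                    domain_length = dom$end - dom$start + 1L,
                    row.names = NULL)
  out$percent <- round(100 * out$n_hv / out$domain_length, 1L)
  out$n_gap_attributed <- vapply(dom$domain, function(d)
    sum(hvDomains == d & !direct), integer(1))
  out
}

#' Write an entropy profile to TSV
#'
#' @param profile An [EntropyProfile-class].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeProfile <- function(profile, path) {
  stopifnot(is(profile, "EntropyProfile"))
  utils::write.table(profileTable(profile), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
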