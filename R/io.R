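#' Read a gapped protein alignment from FASTA
#'
#' Reads a multiple sequence alignment in (gapped) FASTA and extracts an
#' ecotype label from each record id using a configurable naming rule. The
#' default rule takes the prefix before the first separator character, the
#' convention used by pan-genome datasets that join accession and gene id
#' (e.g. `"Ler0|AT1G12345.1"` gives ecotype `"Ler0"`). Ambiguity codes
#' (X, B, Z, *) are retained in the sequence text but excluded from all
#' downstream frequency computations.
#'
#' @param path Path to a FASTA file.
#' @param ecotypeParser Either a function `id -> ecotype` or a single
#'   separator character; `NA` disables extraction (empty labels).
#' @param referenceId Optional id of the reference sequence.
#' @param domains Optional domain-interval data.frame (see
#'   [cladeAlignment()]).
#' @return A [CladeAlignment-class].
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">Ler0|g1", "AR-ND", ">Col0|g2", "ARCND"), fa)
#' aln <- readAlignment(fa)
#' ecotypes(aln)
#' @export
readAlignment <- function(path, ecotypeParser = "|", referenceId = NA_character_,
                          domains = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  # keep only the first whitespace-delimited token of each FASTA header
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  w <- Biostrings::width(seqs)
  if (length(unique(w)) > 1L) {
    bad <- which(w != w[1L])[1L]
    stop(sprintf("ragged alignment: record '%s' has length %d, expected %d",
                 names(seqs)[bad], w[bad], w[1L]))
  }
  eco <- parseEcotypes(names(seqs), ecotypeParser)
  cladeAlignment(seqs, ecotype = eco, referenceId = referenceId,
                 domains = domains)
}

parseEcotypes <- function(ids, ecotypeParser) {
  if (is.function(ecotypeParser)) return(vapply(ids, ecotypeParser, character(1)))
  if (length(ecotypeParser) == 1L && is.na(ecotypeParser))
    return(rep("", length(ids)))
  stopifnot(is.character(ecotypeParser), nchar(ecotypeParser) == 1L)
  out <- vapply(strsplit(ids, ecotypeParser, fixed = TRUE), `[`, character(1), 1L)
  # no separator present -> no ecotype, not the whole id
  out[out == ids & !grepl(ecotypeParser, ids, fixed = TRUE)] <- ""
  out
}

#' Write a CladeAlignment to FASTA
#'
#' @param aln A [CladeAlignment-class].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
writeAlignment <- function(aln, path) {
  stopifnot(is(aln, "CladeAlignment"))
  Biostrings::writeXStringSet(aln@seqs, path, width = 80L)
  invisible(path)
}

#' Read a Newick tree with support values
#'
#' Wraps [ape::read.tree()], normalising how bootstrap supports are stored.
#' In the RAxML convention supports are internal-node labels; some tools
#' instead attach them as branch metadata comments such as `[&support=95]`.
#' Either dialect yields a `phylo` whose `node.label` holds the supports as
#' character; absent supports remain empty strings (reported as `NA`, never
#' coerced to zero).
#'
#' @param path Path to a Newick file.
#' @param supportDialect `"internal-node-label"` (default) or
#'   `"branch-metadata"`.
#' @return An [ape::phylo] object.
#' @export
readTree <- function(path, supportDialect = c("internal-node-label", "branch-metadata")) {
  supportDialect <- match.arg(supportDialect)
  if (!file.exists(path)) stop("no such file: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  if (supportDialect == "branch-metadata") {
    # convert "[&support=95]" comments into node labels before parsing
    txt <- gsub("\\)\\[&support=([0-9.]+)\\]", ")\\1", txt)
    txt <- gsub("\\[&support=([0-9.]+)\\]", "", txt)
  }
  tr <- tryCatch(suppressWarnings(ape::read.tree(text = txt)),
                 error = function(e) stop("malformed Newick in ", path, ": ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("malformed Newick in ", path)
  tr
}

#' Write a tree to Newick with supports as node labels
#'
#' @param tree An [ape::phylo].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeTree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Numeric support values of a tree's internal nodes
#'
#' @param tree An [ape::phylo].
#' @return Numeric vector of length `tree$Nnode` (NA where absent).
#' @export
nodeSupports <- function(tree) {
  if (is.null(tree$node.label)) return(rep(NA_real_, tree$Nnode))
  s <- suppressWarnings(as.numeric(tree$node.label))
  s[!is.na(s) & (s < 0 | s > 100)] <- NA_real_
  s
}

#' Write residue scores as a Chimera attribute or iTOL annotation file
#'
#' The `chimera` target writes the UCSF Chimera "attribute file" layout
#' used to colour a model surface by per-residue scores (header naming the
#' attribute, then one `\t:<resnum>\t<value>` line per residue, ascending).
#' The `itol` target writes an iTOL `DATASET_SIMPLEBAR` annotation block
#' with one `leaf<TAB>value` row per named element.
#'
#' @param values Named numeric vector: names are positive residue numbers
#'   (chimera) or leaf ids (itol); values finite scores.
#' @param target `"chimera"` or `"itol"`.
#' @param path Output path.
#' @param name Attribute / dataset label.
#' @return Invisibly, `path`.
#' @examples
#' f <- tempfile()
#' writeAttributeFile(c(`5` = 1.5), "chimera", f)
#' readLines(f)
#' @export
writeAttributeFile <- function(values, target = c("chimera", "itol"), path,
                               name = "shannonEntropy") {
  target <- match.arg(target)
  if (length(values) == 0L) stop("empty value map")
  if (!all(is.finite(values))) stop("scores must be finite")
  if (is.null(names(values)) || any(names(values) == ""))
    stop("values must be named")
  if (target == "chimera") {
    resnum <- suppressWarnings(as.integer(names(values)))
    if (anyNA(resnum) || any(resnum <= 0L))
      stop("chimera target requires positive integer residue numbers as names")
    o <- order(resnum)
    lines <- c(
      paste0("attribute: ", name),
      "match mode: 1-to-1",
      "recipient: residues",
      sprintf("\t:%d\t%.6g", resnum[o], values[o])
    )
  } else {
    lines <- c(
      "DATASET_SIMPLEBAR",
      "SEPARATOR TAB",
      paste0("DATASET_LABEL\t", name),
      "COLOR\t#1f77b4",
      "DATA",
      sprintf("%s\t%.6g", names(values), values)
    )
  }
  writeLines(lines, path)
  invisible(path)
}
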