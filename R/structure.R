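#' Read a structure into an atom table
#'
#' Parses a PDB file (via [bio3d::read.pdb()]) into the plain atom table
#' used by the contact and colouring functions: one row per heavy atom
#' with chain id, residue number, residue name, atom name and coordinates.
#' Hydrogens are dropped.
#'
#' @param path Path to a PDB file, or an object already acceptable to
#'   [asAtomTable()].
#' @return A data.frame with columns `chain`, `resno`, `resid`, `elety`,
#'   `x`, `y`, `z`.
#' @export
readStructure <- function(path) {
  pdb <- bio3d::read.pdb(path)
  asAtomTable(pdb)
}

#' Normalise a structure object to an atom table
#'
#' @param model A bio3d `pdb` object, or a data.frame with columns
#'   `chain`, `resno`, `x`, `y`, `z` (and optionally `elety`, `resid`).
#' @return Atom data.frame restricted to heavy atoms with finite
#'   coordinates.
#' @export
asAtomTable <- function(model) {
  if (inherits(model, "pdb")) {
    a <- model$atom
    elem <- if (!is.null(a$elesy) && any(nzchar(a$elesy))) a$elesy
            else substr(trimws(a$elety), 1L, 1L)
    a <- a[toupper(trimws(elem)) != "H", , drop = FALSE]
    model <- data.frame(chain = a$chain, resno = a$resno, resid = a$resid,
                        elety = a$elety, x = a$x, y = a$y, z = a$z,
                        stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(model),
            all(c("chain", "resno", "x", "y", "z") %in% colnames(model)))
  if (!all(is.finite(model$x) & is.finite(model$y) & is.finite(model$z)))
    stop("non-finite atom coordinates")
  model
}

#' Receptor residues in contact with a ligand chain
#'
#' A receptor residue is a contact when any of its heavy atoms lies within
#' `cutoff` angstroms of any heavy atom of the ligand chain.
#'
#' @param model A structure (path, bio3d `pdb`, or atom table; see
#'   [asAtomTable()]).
#' @param receptor,ligand Chain ids.
#' @param cutoff Distance cutoff in angstroms (default 4.5).
#' @return A list of class `ContactSet`: `receptor_chain`, `ligand_chain`,
#'   `contacts` (sorted receptor residue numbers), `cutoff`.
#' @export
contactsFromStructure <- function(model, receptor, ligand, cutoff = 4.5) {
  if (cutoff <= 0) stop("cutoff must be positive")
  if (is.character(model) && length(model) == 1L && file.exists(model))
    model <- readStructure(model)
  atoms <- asAtomTable(model)
  rec <- atoms[atoms$chain == receptor, , drop = FALSE]
  lig <- atoms[atoms$chain == ligand, , drop = FALSE]
  if (nrow(rec) == 0L) stop("receptor chain '", receptor, "' missing or empty")
  if (nrow(lig) == 0L) stop("ligand chain '", ligand, "' missing or empty")
  rxyz <- as.matrix(rec[, c("x", "y", "z")])
  lxyz <- as.matrix(lig[, c("x", "y", "z")])
  d2 <- outer(rowSums(rxyz^2), rowSums(lxyz^2), "+") - 2 * (rxyz %*% t(lxyz))
  close <- apply(d2 <= cutoff^2 + 1e-9, 1L, any)
  structure(list(receptor_chain = receptor, ligand_chain = ligand,
                 contacts = sort(unique(rec$resno[close])),
                 cutoff = cutoff),
            class = c("ContactSet", "list"))
}

#' Precision/recall of entropy-based binding-site prediction
#'
#' At each entropy cutoff, the predicted binding residues are the mapped
#' receptor residues whose alignment column reaches the cutoff. Precision
#' is the fraction of predictions that are true contacts (`NA` when
#' nothing is predicted); recall is the fraction of true contacts
#' predicted. The default cutoff grid spans 0.1-3.0 bits in 0.1-bit
#' steps, bracketing the useful range in which recall peaks near 0.8 bit
#' and precision keeps improving up to about 1.8 bits.
#'
#' @param profile An [EntropyProfile-class].
#' @param column_map Named integer vector, receptor residue number ->
#'   alignment column (see [referenceColumnMap()]).
#' @param truth A `ContactSet` from [contactsFromStructure()], or a
#'   numeric vector of true contact residue numbers.
#' @param cutoffs Entropy cutoff grid in bits.
#' @return A data.frame of class `PRCurve`: `cutoff`, `n_predicted`,
#'   `n_true`, `tp`, `precision`, `recall`.
#' @export
precisionRecall <- function(profile, column_map, truth,
                            cutoffs = seq(0.1, 3.0, by = 0.1)) {
  stopifnot(is(profile, "EntropyProfile"))
  if (is(truth, "ContactSet")) truth <- truth$contacts
  truth <- unique(as.integer(truth))
  if (length(truth) == 0L) stop("empty truth contact set")
  res <- as.integer(names(column_map))
  H <- profileTable(profile)$H[column_map]
  out <- data.frame(cutoff = cutoffs, n_predicted = NA_integer_,
                    n_true = length(truth), tp = NA_integer_,
                    precision = NA_real_, recall = NA_real_)
  for (i in seq_along(cutoffs)) {
    pred <- res[H >= cutoffs[i]]
    tp <- length(intersect(pred, truth))
    out$n_predicted[i] <- length(pred)
    out$tp[i] <- tp
    out$precision[i] <- if (length(pred) > 0L) tp / length(pred) else NA_real_
    out$recall[i] <- tp / length(truth)
  }
  class(out) <- c("PRCurve", "data.frame")
  out
}

#' Per-residue entropy scores for structure colouring
#'
#' Transfers each mapped alignment column's entropy onto the matching
#' residue of a structure chain, for export with [writeAttributeFile()]
#' (Chimera target) to colour a model surface by sequence diversity.
#' Chain residues with no alignment column are omitted and counted.
#'
#' @param profile An [EntropyProfile-class].
#' @param column_map Named integer vector, residue number -> column.
#' @param model A structure (see [asAtomTable()]).
#' @param chain Chain id to colour.
#' @return Named numeric vector of entropies (names are residue numbers),
#'   with attribute `n_unmapped` counting chain residues left out.
#' @export
entropyToStructure <- function(profile, column_map, model, chain) {
  stopifnot(is(profile, "EntropyProfile"))
  atoms <- asAtomTable(if (is.character(model)) readStructure(model) else model)
  chainRes <- sort(unique(atoms$resno[atoms$chain == chain]))
  if (length(chainRes) == 0L) stop("chain '", chain, "' missing or empty")
  mapped <- chainRes[as.character(chainRes) %in% names(column_map)]
  if (length(mapped) == 0L) stop("no chain residues covered by column_map")
  scores <- profileTable(profile)$H[column_map[as.character(mapped)]]
  out <- setNames(scores, mapped)
  attr(out, "n_unmapped") <- length(chainRes) - length(mapped)
  out
}

#' Write a contact set or PR curve to TSV
#'
#' @param x A `ContactSet` or `PRCurve`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeStructureEval <- function(x, path) {
  if (is(x, "ContactSet")) {
    df <- data.frame(receptor_chain = x$receptor_chain,
                     ligand_chain = x$ligand_chain,
                     resno = x$contacts, cutoff = x$cutoff)
  } else df <- as.data.frame(x)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
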