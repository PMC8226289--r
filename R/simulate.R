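#' Configuration of the synthetic pan-NLRome generator
#'
#' Defines the study conditions the generator emulates: a multi-ecotype
#' pan-genome in which each NLR family forms a clade with one gene per
#' ecotype (an allelic series, unless duplications are injected), a
#' minority of families carries planted high-diversity columns at
#' surface-exposed LRR positions against a near-invariant background, and
#' inter-family branches are long while within-family branches are short.
#' Sequence evolution is by independent per-column sampling: background
#' columns keep a fixed consensus residue with a small per-sequence
#' substitution probability, and planted columns draw i.i.d. from `hv_k`
#' equiprobable amino acids, giving an analytically known expected
#' entropy of `log2(hv_k)` bits.
#'
#' @param seed Integer RNG seed; the same configuration yields
#'   byte-identical outputs.
#' @param n_ecotypes Ecotypes (accessions) in the pan-genome (default 62).
#' @param n_families NLR families (default 20).
#' @param hv_family_fraction Fraction of families planted as highly
#'   variable (default 0.25).
#' @param n_hv_columns Planted high-diversity columns per hv family
#'   (default 15).
#' @param hv_k Equiprobable residues per planted column (2-20; default 6,
#'   expected entropy about 2.58 bits).
#' @param background_substitution_rate Per-residue, per-sequence
#'   substitution probability outside planted columns (default 0.005).
#' @param gap_rate Per-residue probability of starting a short internal
#'   deletion (default 0.01).
#' @param truncation_prob Probability that a sequence is truncated at
#'   either terminus (default 0.1), by up to `truncation_max` residues.
#' @param truncation_max Maximum terminal truncation length (default 30).
#' @param duplication_rate Per-ecotype probability of carrying a second
#'   gene copy of a family (default 0: pure allelic series).
#' @param repeat_count LRR repeat units per gene (default 14).
#' @param repeat_template 24-residue repeat unit; the first 8 residues are
#'   the LxxLxLxx core, the spacer must not create spurious cores.
#' @param intra_branch_scale Depth of each family subtree in
#'   substitutions/site (default 0.04, below the short-branch cutoff).
#' @param inter_branch_length Backbone branch length between families
#'   (default 0.6, above the long-branch cutoff).
#' @return A validated list of class `SimConfig`.
#' @export
simConfig <- function(seed = 1L, n_ecotypes = 62L, n_families = 20L,
                      hv_family_fraction = 0.25, n_hv_columns = 15L,
                      hv_k = 6L, background_substitution_rate = 0.005,
                      gap_rate = 0.01, truncation_prob = 0.1,
                      truncation_max = 30L, duplication_rate = 0,
                      repeat_count = 14L,
                      repeat_template = "LRALDLSNKTGEKDNSGQRPHSTE",
                      intra_branch_scale = 0.04, inter_branch_length = 0.6) {
  cfg <- list(seed = as.integer(seed), n_ecotypes = as.integer(n_ecotypes),
              n_families = as.integer(n_families),
              hv_family_fraction = hv_family_fraction,
              n_hv_columns = as.integer(n_hv_columns), hv_k = as.integer(hv_k),
              background_substitution_rate = background_substitution_rate,
              gap_rate = gap_rate, truncation_prob = truncation_prob,
              truncation_max = as.integer(truncation_max),
              duplication_rate = duplication_rate,
              repeat_count = as.integer(repeat_count),
              repeat_template = toupper(repeat_template),
              intra_branch_scale = intra_branch_scale,
              inter_branch_length = inter_branch_length)
  rates <- c(cfg$hv_family_fraction, cfg$background_substitution_rate,
             cfg$gap_rate, cfg$truncation_prob, cfg$duplication_rate)
  if (any(rates < 0 | rates > 1)) stop("rates and fractions must lie in [0, 1]")
  if (cfg$hv_k < 2L || cfg$hv_k > 20L) stop("hv_k must be in [2, 20]")
  if (nchar(cfg$repeat_template) != 24L) stop("repeat_template must be 24 residues")
  if (cfg$n_ecotypes < 2L || cfg$n_families < 1L)
    stop("need at least 2 ecotypes and 1 family")
  nVariable <- cfg$repeat_count * length(variableCoreOffsets())
  if (cfg$n_hv_columns > nVariable)
    stop(sprintf("infeasible config: %d hv columns exceed the %d variable LRR positions",
                 cfg$n_hv_columns, nVariable))
  class(cfg) <- c("SimConfig", "list")
  cfg
}

# Surface-exposed offsets within the 8-residue core (1, 4, 6 are the
# conserved leucine-class positions).
variableCoreOffsets <- function() c(2L, 3L, 5L, 7L, 8L)

# Domain layout of the simulated gene (1-based inclusive residues).
simDomainLayout <- function(cfg) {
  lens <- c(preNB = 50L, `NB-ARC` = 160L, linker = 20L,
            LRR = cfg$repeat_count * 24L, postLRR = 40L)
  end <- cumsum(lens)
  data.frame(domain = names(lens), start = c(1L, utils::head(end, -1L) + 1L),
             end = unname(end), row.names = NULL)
}

#' Simulate a synthetic pan-NLRome with ground truth
#'
#' Generates an ecotype-structured gene tree (one subclade per family,
#' short within-family branches, long well-supported inter-family
#' branches), one gapped alignment per family with planted high-entropy
#' columns at variable LRR surface positions for the hv families, and the
#' machine-readable ground truth needed to verify every downstream step.
#' The first sequence of each family (`Eco01`) is kept gap-free and serves
#' as the reference for domain and repeat coordinates. Output is
#' deterministic given the configuration.
#'
#' @param cfg A [simConfig()].
#' @return A list: `tree` (rooted [ape::phylo] with bootstrap node
#'   labels), `alignments` (named list of [CladeAlignment-class], one per
#'   family), and `truth` (list with `families`, `hv_columns`,
#'   `membership`, `repeats`, `domains`, `seed`).
#' @export
simulateNlrome <- function(cfg = simConfig()) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed)
  layout <- simDomainLayout(cfg)
  lrrStart <- layout$start[layout$domain == "LRR"]
  L <- layout$end[nrow(layout)]
  template <- strsplit(cfg$repeat_template, "", fixed = TRUE)[[1L]]
  lrrConsensus <- rep(template, cfg$repeat_count)
  coreStarts <- lrrStart + (seq_len(cfg$repeat_count) - 1L) * 24L
  variableRes <- as.vector(outer(variableCoreOffsets() - 1L, coreStarts, "+"))

  famNames <- sprintf("Fam%02d", seq_len(cfg$n_families))
  nHv <- round(cfg$hv_family_fraction * cfg$n_families)
  hvFams <- sort(sample(cfg$n_families, nHv))

  alignments <- list()
  hvColumns <- list()
  membership <- list()
  famNewick <- character(cfg$n_families)

  for (f in seq_len(cfg$n_families)) {
    fam <- famNames[f]
    dup <- which(stats::runif(cfg$n_ecotypes) < cfg$duplication_rate)
    eco <- c(seq_len(cfg$n_ecotypes), dup)
    gene <- c(rep(1L, cfg$n_ecotypes), rep(2L, length(dup)))
    ids <- sprintf("Eco%02d|%s_g%d", eco, fam, gene)
    nSeq <- length(ids)

    consensus <- c(sample(AA20, lrrStart - 1L, replace = TRUE),
                   lrrConsensus,
                   sample(AA20, L - lrrStart + 1L - length(lrrConsensus),
                          replace = TRUE))
    m <- matrix(rep(consensus, each = nSeq), nrow = nSeq)
    mut <- matrix(stats::runif(nSeq * L) < cfg$background_substitution_rate,
                  nrow = nSeq)
    mut[1L, ] <- FALSE  # the reference carries the family consensus verbatim
    m[mut] <- sample(AA20, sum(mut), replace = TRUE)

    if (f %in% hvFams) {
      planted <- sort(sample(variableRes, cfg$n_hv_columns))
      for (p in planted) {
        resSet <- sample(AA20, cfg$hv_k)
        m[, p] <- sample(resSet, nSeq, replace = TRUE)
      }
      hvColumns[[fam]] <- planted
    }

    # gap structure: terminal truncations plus short internal deletions;
    # sequence 1 (the reference) stays gap-free
    for (s in seq_len(nSeq)[-1L]) {
      if (stats::runif(1) < cfg$truncation_prob)
        m[s, seq_len(sample(cfg$truncation_max, 1L))] <- "-"
      if (stats::runif(1) < cfg$truncation_prob)
        m[s, (L - sample(cfg$truncation_max, 1L) + 1L):L] <- "-"
      delStarts <- which(stats::runif(L) < cfg$gap_rate)
      for (d in delStarts) {
        dl <- sample(4L, 1L)
        m[s, d:min(L, d + dl - 1L)] <- "-"
      }
    }

    seqs <- setNames(apply(m, 1L, paste, collapse = ""), ids)
    alignments[[fam]] <- cladeAlignment(seqs,
                                        ecotype = sprintf("Eco%02d", eco),
                                        referenceId = ids[1L],
                                        domains = layout)
    membership[[fam]] <- data.frame(leaf = ids, family = fam,
                                    ecotype = sprintf("Eco%02d", eco))

    subtree <- ape::rcoal(nSeq, tip.label = ids)
    depth <- max(ape::node.depth.edgelength(subtree))
    subtree$edge.length <- subtree$edge.length / depth * cfg$intra_branch_scale
    labs <- as.character(sample(50:99, subtree$Nnode, replace = TRUE))
    labs[1L] <- "100"  # family MRCA: full support for the family clade
    subtree$node.label <- labs
    famNewick[f] <- sub(";$", "", ape::write.tree(subtree))
  }

  b <- cfg$inter_branch_length
  if (cfg$n_families == 1L) {
    nwk <- paste0(famNewick[1L], ";")
  } else {
    acc <- sprintf("(%s:%g,%s:%g)20", famNewick[1L], b, famNewick[2L], b)
    for (f in seq_len(cfg$n_families)[-(1:2)])
      acc <- sprintf("(%s:%g,%s:%g)20", acc, b, famNewick[f], b)
    nwk <- paste0(acc, ";")
  }
  tree <- ape::read.tree(text = nwk)

  truth <- list(
    families = data.frame(family = famNames,
                          is_hv = seq_len(cfg$n_families) %in% hvFams,
                          n_planted = ifelse(seq_len(cfg$n_families) %in% hvFams,
                                             cfg$n_hv_columns, 0L)),
    hv_columns = hvColumns,
    membership = do.call(rbind, c(membership, list(make.row.names = FALSE))),
    repeats = data.frame(repeat_index = seq_len(cfg$repeat_count),
                         core_start = coreStarts),
    domains = layout,
    seed = cfg$seed)
  list(tree = tree, alignments = alignments, truth = truth)
}

#' Build a toy receptor-ligand complex with known contacts
#'
#' Places one heavy atom per receptor residue along a line and one ligand
#' atom opposite each designated contact residue at distance
#' `cutoff - margin`; all other receptor-ligand atom pairs are farther
#' than `cutoff + margin`. The returned contact set is therefore the
#' exact ground truth for [contactsFromStructure()] at the same cutoff.
#'
#' @param n_receptor_res Number of receptor residues (chain A).
#' @param contact_positions Residue numbers designated as contacts
#'   (subset of `1:n_receptor_res`; may be empty).
#' @param cutoff Contact cutoff in angstroms (default 4.5).
#' @param margin Safety margin in angstroms, `0 < margin < cutoff`
#'   (default 1).
#' @return A list with `atoms` (atom table, chains A and B) and `truth`
#'   (a `ContactSet`).
#' @export
makeToyComplex <- function(n_receptor_res = 10L, contact_positions = integer(0),
                           cutoff = 4.5, margin = 1) {
  if (margin >= cutoff) stop("margin must be smaller than cutoff")
  if (margin <= 0) stop("margin must be positive")
  contact_positions <- sort(unique(as.integer(contact_positions)))
  if (length(contact_positions) &&
      (min(contact_positions) < 1L || max(contact_positions) > n_receptor_res))
    stop("contact positions must be receptor residues")
  spacing <- max(10, 2 * (cutoff + margin))
  rec <- data.frame(chain = "A", resno = seq_len(n_receptor_res),
                    resid = "ALA", elety = "CA",
                    x = spacing * seq_len(n_receptor_res), y = 0, z = 0)
  if (length(contact_positions)) {
    lig <- data.frame(chain = "B", resno = seq_along(contact_positions),
                      resid = "GLY", elety = "CA",
                      x = spacing * contact_positions, y = 0,
                      z = cutoff - margin)
  } else {
    lig <- data.frame(chain = "B", resno = 1L, resid = "GLY", elety = "CA",
                      x = 0, y = 10 * spacing, z = 0)
  }
  list(atoms = rbind(rec, lig),
       truth = structure(list(receptor_chain = "A", ligand_chain = "B",
                              contacts = contact_positions, cutoff = cutoff),
                         class = c("ContactSet", "list")))
}

#' Write an atom table as a minimal PDB file
#'
#' @param atoms Atom table (see [asAtomTable()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writePdb <- function(atoms, path) {
  atoms <- asAtomTable(atoms)
  resid <- if ("resid" %in% colnames(atoms)) atoms$resid else "ALA"
  elety <- if ("elety" %in% colnames(atoms)) atoms$elety else "CA"
  lines <- sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
                   seq_len(nrow(atoms)), sprintf(" %-3s", elety), resid,
                   atoms$chain, atoms$resno, atoms$x, atoms$y, atoms$z,
                   substr(trimws(elety), 1L, 1L))
  writeLines(c(lines, "END"), path)
  invisible(path)
}
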