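# Synthetic reaction corpora with known ground truth.  Each class is a
# nucleophilic-substitution rule R-Br + H-Z -> R-Z with a class-specific
# nucleophile Z installed at a primary (classes 1-20) or secondary (classes
# 21-40) alkyl center.  The Z groups are chosen so that the radius-1
# retro-templates (which record H counts) are pairwise distinct, and so that
# the products of different classes are structurally disjoint: every class is
# recoverable both by template extraction and by a product-only classifier.
# Scaffolds are random alkyl chains whose atom next to the reaction center is
# always a CH2, which makes the template of a class invariant to the
# scaffold.

# Z-group table: atom 1 is the attach atom; nH values are the PRODUCT state
# (the free nucleophile H-Z has one more H on atom 1).
.Z_GROUPS <- list(
  list(name = "hydroxyl",   elem = "O",                nH = 1L),
  list(name = "methoxy",    elem = c("O", "C"),        nH = c(0L, 3L),
       bonds = rbind(c(1, 2, 1))),
  list(name = "ethoxy",     elem = c("O", "C", "C"),   nH = c(0L, 2L, 3L),
       bonds = rbind(c(1, 2, 1), c(2, 3, 1))),
  list(name = "amino",      elem = "N",                nH = 2L),
  list(name = "methylamino", elem = c("N", "C"),       nH = c(1L, 3L),
       bonds = rbind(c(1, 2, 1))),
  list(name = "dimethylamino", elem = c("N", "C", "C"), nH = c(0L, 3L, 3L),
       bonds = rbind(c(1, 2, 1), c(1, 3, 1))),
  list(name = "sulfanyl",   elem = "S",                nH = 1L),
  list(name = "methylthio", elem = c("S", "C"),        nH = c(0L, 3L),
       bonds = rbind(c(1, 2, 1))),
  list(name = "cyano",      elem = c("C", "N"),        nH = c(0L, 0L),
       bonds = rbind(c(1, 2, 3))),
  list(name = "ethynyl",    elem = c("C", "C"),        nH = c(0L, 1L),
       bonds = rbind(c(1, 2, 3))),
  list(name = "acetoxy",    elem = c("O", "C", "O", "C"),
       nH = c(0L, 0L, 0L, 3L),
       bonds = rbind(c(1, 2, 1), c(2, 3, 2), c(2, 4, 1))),
  list(name = "ethylthio",  elem = c("S", "C", "C"),   nH = c(0L, 2L, 3L),
       bonds = rbind(c(1, 2, 1), c(2, 3, 1))),
  list(name = "ethylamino", elem = c("N", "C", "C"),   nH = c(1L, 2L, 3L),
       bonds = rbind(c(1, 2, 1), c(2, 3, 1))),
  list(name = "fluoro",     elem = "F",                nH = 0L),
  list(name = "chloro",     elem = "Cl",               nH = 0L),
  list(name = "iodo",       elem = "I",                nH = 0L),
  list(name = "isopropoxy", elem = c("O", "C", "C", "C"),
       nH = c(0L, 1L, 3L, 3L),
       bonds = rbind(c(1, 2, 1), c(2, 3, 1), c(2, 4, 1))),
  list(name = "acetamido",  elem = c("N", "C", "O", "C"),
       nH = c(1L, 0L, 0L, 3L),
       bonds = rbind(c(1, 2, 1), c(2, 3, 2), c(2, 4, 1))),
  list(name = "acetylthio", elem = c("S", "C", "O", "C"),
       nH = c(0L, 0L, 0L, 3L),
       bonds = rbind(c(1, 2, 1), c(2, 3, 2), c(2, 4, 1))),
  list(name = "methylethylamino", elem = c("N", "C", "C", "C"),
       nH = c(0L, 3L, 2L, 3L),
       bonds = rbind(c(1, 2, 1), c(1, 3, 1), c(3, 4, 1)))
)

.MAX_SYNTH_CLASSES <- 2L * length(.Z_GROUPS)

# random alkyl scaffold; returns mol (all carbons, implicit H filled later)
# and the center atom index.  The atom bonded to the center is always an
# unbranched CH2 so that the radius-1 template environment is scaffold
# independent.
.random_scaffold <- function(secondary) {
  mol <- .new_mol()
  addC <- function(m) .mol_add_atom(m, "C")
  if (!secondary) {
    nChain <- sample(3:7, 1)
    for (i in seq_len(nChain)) mol <- addC(mol)
    for (i in seq_len(nChain - 1L)) mol <- .mol_add_bond(mol, i, i + 1L)
    center <- 1L
    if (nChain >= 4L) {
      for (i in 3:(nChain - 1L)) {
        if (stats::runif(1) < 0.3) {
          mol <- addC(mol)
          mol <- .mol_add_bond(mol, as.integer(i), .mol_natoms(mol))
        }
      }
    }
  } else {
    mol <- addC(mol)                    # center
    center <- 1L
    for (arm in 1:2) {
      len <- sample(2:4, 1)
      prev <- center
      for (i in seq_len(len)) {
        mol <- addC(mol)
        mol <- .mol_add_bond(mol, prev, .mol_natoms(mol))
        prev <- .mol_natoms(mol)
      }
    }
  }
  list(mol = mol, center = center)
}

.add_z_group <- function(mol, z, attachTo) {
  base <- .mol_natoms(mol)
  for (i in seq_along(z$elem))
    mol <- .mol_add_atom(mol, z$elem[i], nH = z$nH[i])
  mol <- .mol_add_bond(mol, attachTo, base + 1L)
  if (!is.null(z$bonds))
    for (r in seq_len(nrow(z$bonds)))
      mol <- .mol_add_bond(mol, base + z$bonds[r, 1], base + z$bonds[r, 2],
                           z$bonds[r, 3])
  mol
}

# build one atom-mapped reaction SMILES for a rule class
.build_reaction <- function(classIdx) {
  secondary <- classIdx > length(.Z_GROUPS)
  z <- .Z_GROUPS[[if (secondary) classIdx - length(.Z_GROUPS) else classIdx]]
  sc <- .random_scaffold(secondary)
  nScaf <- .mol_natoms(sc$mol)

  product <- .add_z_group(sc$mol, z, sc$center)
  product <- .mol_finalize_h(product)
  product$map <- seq_len(.mol_natoms(product))

  halide <- .mol_add_atom(sc$mol, "Br", nH = 0L)   # unmapped leaving group
  halide <- .mol_add_bond(halide, sc$center, .mol_natoms(halide))
  halide <- .mol_finalize_h(halide)
  halide$map <- c(seq_len(nScaf), 0L)

  nucleophile <- .new_mol()
  for (i in seq_along(z$elem)) {
    nH <- z$nH[i] + if (i == 1L) 1L else 0L
    nucleophile <- .mol_add_atom(nucleophile, z$elem[i], nH = nH)
  }
  if (!is.null(z$bonds))
    for (r in seq_len(nrow(z$bonds)))
      nucleophile <- .mol_add_bond(nucleophile, z$bonds[r, 1], z$bonds[r, 2],
                                   z$bonds[r, 3])
  nucleophile$map <- nScaf + seq_along(z$elem)

  paste0(.write_smiles(halide), ".", .write_smiles(nucleophile), ">>",
         .write_smiles(product))
}

#' Generate a synthetic reaction corpus with known classes
#'
#' Emits atom-mapped, single-product reaction SMILES in which each class is a
#' distinct functional-group installation on a random alkyl scaffold, plus
#' the ground-truth class of every reaction. Running the corpus through
#' \code{\link{preprocessReactions}} recovers exactly \code{nClasses}
#' template classes that coincide with the truth up to relabeling.
#'
#' @param nClasses number of rule classes T (2..40).
#' @param samplesPerClass mean reactions per class; the default 5 mirrors the
#'   per-class abundance of large patent reaction corpora.
#' @param seed RNG seed; the output is a deterministic function of the
#'   arguments.
#' @param distribution "constant" (exactly samplesPerClass each) or
#'   "longtail" (geometric sizes with mean samplesPerClass, singletons
#'   common).
#' @return data.frame with columns \code{id}, \code{reaction_smiles},
#'   \code{class_label}.
#' @export
generateSyntheticReactions <- function(nClasses = 20L, samplesPerClass = 5L,
                                       seed = 1L,
                                       distribution = c("constant",
                                                        "longtail")) {
  distribution <- match.arg(distribution)
  nClasses <- as.integer(nClasses)
  if (nClasses < 2L || nClasses > .MAX_SYNTH_CLASSES)
    stop("nClasses must be between 2 and ", .MAX_SYNTH_CLASSES)
  set.seed(as.integer(seed))
  sizes <- if (distribution == "constant") rep(as.integer(samplesPerClass),
                                               nClasses)
           else 1L + stats::rgeom(nClasses, 1 / as.numeric(samplesPerClass))
  classes <- rep(seq_len(nClasses), sizes)
  rx <- vapply(classes, .build_reaction, character(1))
  data.frame(id = paste0("syn", seq_along(rx)), reaction_smiles = rx,
             class_label = classes, stringsAsFactors = FALSE)
}

#' Write / read the synthetic corpus files
#'
#' The reaction file is a two-column TSV (id, reaction SMILES) readable by
#' \code{\link{readReactions}}; the truth table a TSV of (id, class_label).
#'
#' @param reactions data.frame from \code{\link{generateSyntheticReactions}}.
#' @param path reaction file path.
#' @param truthPath optional path for the ground-truth table.
#' @export
writeReactions <- function(reactions, path, truthPath = NULL) {
  stopifnot(all(c("id", "reaction_smiles") %in% names(reactions)))
  writeLines(paste(reactions$id, reactions$reaction_smiles, sep = "\t"), path)
  if (!is.null(truthPath))
    utils::write.table(reactions[, c("id", "class_label")], truthPath,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Generate a separable labeled dataset
#'
#' The classification view of the synthetic corpus: canonical products with
#' their true class labels and the per-class retro-templates as library. By
#' construction each class carries a distinct functional-group motif, so the
#' classes are separable from both the fingerprint and the SMILES descriptor;
#' a nearest-neighbour fingerprint classifier reaches near-perfect accuracy,
#' which is the bar a trained model is compared against.
#'
#' @inheritParams generateSyntheticReactions
#' @param samplesPerClass reactions per class (constant; default 50).
#' @return a \linkS4class{LabeledDataset} with ground-truth reactants
#'   retained.
#' @export
generateSeparableSet <- function(nClasses = 20L, samplesPerClass = 50L,
                                 seed = 1L) {
  rxdf <- generateSyntheticReactions(nClasses, samplesPerClass, seed,
                                     distribution = "constant")
  sides <- strsplit(rxdf$reaction_smiles, ">>", fixed = TRUE)
  prods <- canonicalSmiles(vapply(sides, `[`, character(1), 2))
  reacts <- lapply(sides, function(s) {
    canonicalSmiles(strsplit(s[1], ".", fixed = TRUE)[[1]])
  })
  firstOf <- match(seq_len(max(rxdf$class_label)), rxdf$class_label)
  tmpl <- vapply(firstOf, function(i)
    extractTemplate(parseReaction(rxdf$reaction_smiles[i], rxdf$id[i])),
    character(1))
  if (anyDuplicated(tmpl))
    stop("synthetic rule classes yielded non-distinct templates")
  .make_dataset(prods, rxdf$class_label, reacts,
                new("TemplateLibrary", templates = tmpl))
}
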