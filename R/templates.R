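# Retro-template extraction from atom-mapped reactions and template
# application to products.  Templates are reaction SMARTS written product
# side first ("retro" direction).  Every template atom records element,
# H count and formal charge; mapped atoms keep their map number.  Recording
# H counts on the radius-1 environment (not only on changed atoms) makes
# templates more specific: functional groups that differ one bond away from
# the reaction center yield distinct classes.

# --- graph helpers ----------------------------------------------------------

.mol_bond_between <- function(mol, a, b) {
  hit <- which((mol$b1 == a & mol$b2 == b) | (mol$b1 == b & mol$b2 == a))
  if (length(hit)) hit[1] else 0L
}

.mol_components <- function(mol) {
  n <- .mol_natoms(mol)
  nb <- .mol_neighbors(mol)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      a <- queue[1]; queue <- queue[-1]
      nbr <- nb[[a]]
      if (is.null(nbr)) next
      for (r in seq_len(nrow(nbr))) {
        j <- nbr[r, 1]
        if (comp[j] == 0L) { comp[j] <- cur; queue <- c(queue, j) }
      }
    }
  }
  split(seq_len(n), comp)
}

.mol_subgraph <- function(mol, idx) {
  idx <- sort(unique(as.integer(idx)))
  newIdx <- integer(.mol_natoms(mol))
  newIdx[idx] <- seq_along(idx)
  out <- .new_mol()
  out$elem <- mol$elem[idx]; out$arom <- mol$arom[idx]
  out$charge <- mol$charge[idx]; out$nH <- mol$nH[idx]
  out$hExplicit <- mol$hExplicit[idx]; out$map <- mol$map[idx]
  keep <- which(mol$b1 %in% idx & mol$b2 %in% idx)
  out$b1 <- newIdx[mol$b1[keep]]; out$b2 <- newIdx[mol$b2[keep]]
  out$order <- mol$order[keep]
  out
}

.merge_mols <- function(mols) {
  out <- .new_mol()
  frag <- integer(0)
  for (fi in seq_along(mols)) {
    m <- mols[[fi]]
    off <- .mol_natoms(out)
    out$elem <- c(out$elem, m$elem); out$arom <- c(out$arom, m$arom)
    out$charge <- c(out$charge, m$charge); out$nH <- c(out$nH, m$nH)
    out$hExplicit <- c(out$hExplicit, m$hExplicit)
    out$map <- c(out$map, m$map)
    out$b1 <- c(out$b1, m$b1 + off); out$b2 <- c(out$b2, m$b2 + off)
    out$order <- c(out$order, m$order)
    frag <- c(frag, rep.int(fi, .mol_natoms(m)))
  }
  attr(out, "fragment") <- frag
  out
}

.bfs_within <- function(mol, seeds, radius) {
  nb <- .mol_neighbors(mol)
  dist <- rep(Inf, .mol_natoms(mol))
  dist[seeds] <- 0
  queue <- seeds
  while (length(queue)) {
    a <- queue[1]; queue <- queue[-1]
    if (dist[a] >= radius) next
    nbr <- nb[[a]]
    if (is.null(nbr)) next
    for (r in seq_len(nrow(nbr))) {
      j <- nbr[r, 1]
      if (dist[j] > dist[a] + 1) { dist[j] <- dist[a] + 1; queue <- c(queue, j) }
    }
  }
  which(is.finite(dist))
}

# --- template serialization -------------------------------------------------

.pattern_atom_token <- function(mol, i) {
  sym <- if (mol$arom[i]) tolower(mol$elem[i]) else mol$elem[i]
  ch <- mol$charge[i]
  cs <- if (ch >= 0) paste0("+", ch) else paste0("-", -ch)
  tok <- paste0("[", sym, ";H", mol$nH[i], ";", cs)
  if (mol$map[i] > 0) tok <- paste0(tok, ":", mol$map[i])
  paste0(tok, "]")
}

.pattern_bond_token <- function(order) c("-", "=", "#")[order]

# Deterministic linear serialization of a pattern subgraph: fragments and
# neighbor visits are ordered by atom map (unmapped atoms sort last, by
# position), so identical reactions give byte-identical templates.
.serialize_pattern <- function(mol) {
  n <- .mol_natoms(mol)
  key <- ifelse(mol$map > 0, mol$map, 1e6 + seq_len(n))
  nb <- .mol_neighbors(mol)
  visited <- logical(n)
  usedBond <- logical(length(mol$b1))

  emit <- function(i, parentBond) {
    visited[i] <<- TRUE
    out <- if (parentBond > 0L) .pattern_bond_token(mol$order[parentBond]) else ""
    out <- paste0(out, .pattern_atom_token(mol, i))
    nbr <- nb[[i]]
    if (is.null(nbr)) return(out)
    ord <- order(key[nbr[, 1]])
    segs <- character(0)
    for (r in ord) {
      j <- nbr[r, 1]; bi <- nbr[r, 3]
      if (usedBond[bi]) next
      usedBond[bi] <<- TRUE
      if (visited[j]) {
        # ring bond inside the template: rare; serialize with a closure digit
        segs <- c(segs, paste0(.pattern_bond_token(mol$order[bi]), "1"))
      } else {
        segs <- c(segs, emit(j, bi))
      }
    }
    if (length(segs) > 1)
      out <- paste0(out, paste0("(", segs[-length(segs)], ")", collapse = ""),
                    segs[length(segs)])
    else if (length(segs) == 1)
      out <- paste0(out, segs)
    out
  }

  comps <- .mol_components(mol)
  mins <- vapply(comps, function(ix) min(key[ix]), numeric(1))
  comps <- comps[order(mins)]
  frags <- vapply(comps, function(ix) emit(ix[which.min(key[ix])], 0L),
                  character(1))
  paste(frags, collapse = ".")
}

# --- extraction -------------------------------------------------------------

#' Extract a retro-template from an atom-mapped single-product reaction
#'
#' Finds the changed atoms (bonds to mapped neighbors gained, lost or with a
#' changed order; changed H count or formal charge; or a bond to an atom that
#' does not survive into the product), grows the environment by
#' \code{radius} bonds, and serializes both sides as reaction SMARTS,
#' product side first. Unmapped reactant atoms adjacent to the reaction
#' center (leaving groups) are kept on the reactant side. Identical input
#' reactions give byte-identical template strings.
#'
#' @param raw a single-product, atom-mapped \linkS4class{RawReaction}.
#' @param radius environment radius in bonds around changed atoms
#'   (default 1).
#' @return the template string \code{productPattern>>reactantPatterns}.
#' @export
extractTemplate <- function(raw, radius = 1L) {
  stopifnot(is(raw, "RawReaction"))
  if (length(raw@productSmiles) != 1)
    stop("template extraction needs a single-product reaction; use splitMultiProduct()")
  radius <- as.integer(radius)
  if (radius < 0) stop("radius must be >= 0")

  gp <- .parse_smiles(raw@productSmiles)
  gr <- .merge_mols(lapply(raw@reactantSmiles, .parse_smiles))

  if (all(gp$map == 0) && all(gr$map == 0))
    stop("reaction has no atom mapping; templates cannot be extracted")
  if (any(gp$map == 0))
    stop("every product atom must be atom-mapped")
  if (anyDuplicated(gp$map[gp$map > 0]))
    stop("duplicate atom map in product")
  if (anyDuplicated(gr$map[gr$map > 0]))
    stop("duplicate atom map in reactants")

  # mapped reactant atoms that do not survive into the product behave like
  # unmapped leaving-group atoms
  gr$map[!(gr$map %in% gp$map) & gr$map > 0] <- 0L

  rIdxOfMap <- stats::setNames(seq_len(.mol_natoms(gr)), gr$map)
  missing <- setdiff(gp$map, gr$map)
  if (length(missing))
    stop("inconsistent atom mapping: product map(s) ",
         paste(missing, collapse = ","), " absent from reactants")

  pBonds <- function(mol, i) {
    nbr <- .mol_neighbors(mol)[[i]]
    if (is.null(nbr)) return(character(0))
    maps <- mol$map[nbr[, 1]]
    keep <- maps > 0
    sort(paste(maps[keep], nbr[keep, 2], sep = ":"))
  }

  nbP <- .mol_neighbors(gp)
  changedP <- integer(0)
  for (i in seq_len(.mol_natoms(gp))) {
    j <- rIdxOfMap[[as.character(gp$map[i])]]
    changed <- gp$charge[i] != gr$charge[j] || gp$nH[i] != gr$nH[j] ||
      !identical(pBonds(gp, i), pBonds(gr, j))
    if (!changed) {
      nbr <- .mol_neighbors(gr)[[j]]
      if (!is.null(nbr) && any(gr$map[nbr[, 1]] == 0)) changed <- TRUE
    }
    if (changed) changedP <- c(changedP, i)
  }
  if (length(changedP) == 0)
    stop("no changed atoms between reactants and product")

  prodSel <- .bfs_within(gp, changedP, radius)
  selMaps <- gp$map[prodSel]

  changedR <- unname(rIdxOfMap[as.character(gp$map[changedP])])
  nearR <- .bfs_within(gr, changedR, radius)
  reactSel <- union(which(gr$map %in% selMaps), nearR[gr$map[nearR] == 0])

  # renumber maps 1..k by rank so the template is independent of the absolute
  # map numbers (and hence of the scaffold size) of the source reaction
  sp <- .mol_subgraph(gp, prodSel)
  sr <- .mol_subgraph(gr, reactSel)
  renum <- stats::setNames(seq_along(sort(selMaps)), sort(selMaps))
  sp$map <- as.integer(renum[as.character(sp$map)])
  sr$map <- ifelse(sr$map > 0, as.integer(renum[as.character(sr$map)]), 0L)

  paste0(.serialize_pattern(sp), ">>", .serialize_pattern(sr))
}

# --- pattern parsing --------------------------------------------------------

.parse_pattern_bracket <- function(body, s) {
  parts <- strsplit(body, ";", fixed = TRUE)[[1]]
  m <- regmatches(parts[1], regexpr("^(Cl|Br|[A-Z][a-z]?|[bcnops])$", parts[1]))
  if (length(m) == 0) stop("cannot read pattern atom '[", body, "]' in '", s, "'")
  arom <- m %in% c("b", "c", "n", "o", "p", "s")
  elem <- if (arom) toupper(m) else m
  nH <- NA_integer_; charge <- NA_integer_; map <- 0L
  for (p in parts[-1]) {
    if (grepl("^H[0-9]+$", p)) nH <- as.integer(substring(p, 2))
    else if (grepl("^[+-][0-9]+$", p)) charge <- as.integer(p)
    else stop("unsupported pattern primitive '", p, "' in '", s, "'")
  }
  # trailing :map may sit inside the last primitive
  lastColon <- regmatches(body, regexpr(":[0-9]+$", body))
  if (length(lastColon)) map <- as.integer(substring(lastColon, 2))
  list(elem = elem, arom = arom, nH = nH, charge = charge, map = map)
}

.parse_pattern_side <- function(s) {
  mol <- .new_mol()
  chars <- strsplit(s, "")[[1]]
  i <- 1L; nchr <- length(chars)
  prev <- 0L; bond <- 1L; bondSet <- FALSE
  stack <- integer(0); rings <- list()
  while (i <= nchr) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= nchr && chars[j] != "]") j <- j + 1L
      if (j > nchr) stop("unclosed bracket in pattern '", s, "'")
      body <- paste(chars[(i + 1):(j - 1)], collapse = "")
      body2 <- sub(":[0-9]+$", "", body)
      at <- .parse_pattern_bracket(body2, s)
      mm <- regmatches(body, regexpr(":[0-9]+$", body))
      if (length(mm)) at$map <- as.integer(substring(mm, 2))
      mol <- .mol_add_atom(mol, at$elem, at$arom, ifelse(is.na(at$charge), 0L,
                                                         at$charge),
                           at$nH, at$map)
      # remember which constraints were actually specified
      mol$hExplicit[.mol_natoms(mol)] <- !is.na(at$nH)
      attr(mol, "chargeSpec") <- c(attr(mol, "chargeSpec"), !is.na(at$charge))
      if (prev > 0L) mol <- .mol_add_bond(mol, prev, .mol_natoms(mol), bond)
      prev <- .mol_natoms(mol); bond <- 1L; bondSet <- FALSE
      i <- j + 1L
    } else if (ch == "-") { bond <- 1L; bondSet <- TRUE; i <- i + 1L
    } else if (ch == "=") { bond <- 2L; bondSet <- TRUE; i <- i + 1L
    } else if (ch == "#") { bond <- 3L; bondSet <- TRUE; i <- i + 1L
    } else if (ch == "(") { stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch == ".") { prev <- 0L; bond <- 1L; i <- i + 1L
    } else if (grepl("^[0-9]$", ch)) {
      if (!is.null(rings[[ch]])) {
        op <- rings[[ch]]
        mol <- .mol_add_bond(mol, op[1], prev, max(op[2], bond))
        rings[[ch]] <- NULL
      } else rings[[ch]] <- c(prev, bond)
      bond <- 1L; i <- i + 1L
    } else {
      stop("unsupported pattern character '", ch, "' in '", s, "'")
    }
  }
  if (.mol_natoms(mol) == 0) stop("empty pattern side '", s, "'")
  # NA-out unspecified constraints
  mol$nH[!mol$hExplicit] <- NA_integer_
  cs <- attr(mol, "chargeSpec")
  mol$charge[!cs] <- NA_integer_
  mol
}

.parse_template <- function(template) {
  sides <- strsplit(template, ">>", fixed = TRUE)[[1]]
  if (length(sides) != 2)
    stop("template must have the form productPattern>>reactantPatterns")
  list(product = .parse_pattern_side(sides[1]),
       reactant = .parse_pattern_side(sides[2]))
}

# --- subgraph matching ------------------------------------------------------

.atom_matches <- function(pat, pi, mol, mi) {
  if (pat$elem[pi] != mol$elem[mi]) return(FALSE)
  if (pat$arom[pi] != mol$arom[mi]) return(FALSE)
  if (!is.na(pat$nH[pi]) && pat$nH[pi] != mol$nH[mi]) return(FALSE)
  if (!is.na(pat$charge[pi]) && pat$charge[pi] != mol$charge[mi]) return(FALSE)
  TRUE
}

# All embeddings of the (possibly multi-component) pattern into the molecule.
# Non-induced matching: pattern bonds must exist with equal order; extra
# molecule bonds between matched atoms are allowed.
.match_pattern <- function(pat, mol) {
  np <- .mol_natoms(pat)
  comps <- .mol_components(pat)
  nbP <- .mol_neighbors(pat)
  nbM <- .mol_neighbors(mol)
  results <- list()

  orderOf <- function(comp) {
    # BFS order within a component so each atom after the first has an
    # already-placed neighbor
    ord <- comp[1]
    while (length(ord) < length(comp)) {
      nxt <- NULL
      for (a in setdiff(comp, ord)) {
        nbr <- nbP[[a]]
        if (!is.null(nbr) && any(nbr[, 1] %in% ord)) { nxt <- a; break }
      }
      if (is.null(nxt)) nxt <- setdiff(comp, ord)[1]
      ord <- c(ord, nxt)
    }
    ord
  }
  ordAll <- unlist(lapply(comps, orderOf))

  assign <- integer(np)
  recurse <- function(k) {
    if (k > length(ordAll)) {
      results[[length(results) + 1L]] <<- assign
      return(invisible())
    }
    pi <- ordAll[k]
    nbr <- nbP[[pi]]
    anchored <- !is.null(nbr) && any(assign[nbr[, 1]] > 0)
    cand <- if (anchored) {
      placed <- nbr[assign[nbr[, 1]] > 0, , drop = FALSE]
      a0 <- placed[1, ]
      mnbr <- nbM[[assign[a0[1]]]]
      if (is.null(mnbr)) integer(0)
      else mnbr[mnbr[, 2] == a0[2], 1]
    } else {
      seq_len(.mol_natoms(mol))
    }
    for (mi in cand) {
      if (mi %in% assign) next
      if (!.atom_matches(pat, pi, mol, mi)) next
      ok <- TRUE
      if (!is.null(nbr)) {
        for (r in seq_len(nrow(nbr))) {
          pj <- nbr[r, 1]
          if (assign[pj] > 0) {
            bi <- .mol_bond_between(mol, mi, assign[pj])
            if (bi == 0L || mol$order[bi] != nbr[r, 2]) { ok <- FALSE; break }
          }
        }
      }
      if (!ok) next
      assign[pi] <<- mi
      recurse(k + 1L)
      assign[pi] <<- 0L
    }
  }
  recurse(1L)
  unique(results)
}

# --- application ------------------------------------------------------------

#' Apply a retro-template to a product molecule
#'
#' Matches the template's product pattern against the molecule and, for every
#' embedding, rewrites the matched bonds and atoms according to the reactant
#' pattern (bond edits, H-count updates, leaving-group atoms added). The
#' resulting fragments are canonicalized and returned as reactant sets.
#'
#' @param product a product SMILES string.
#' @param template a retro-template string as produced by
#'   \code{\link{extractTemplate}}.
#' @return list of character vectors, each a sorted set of canonical
#'   reactant SMILES; empty list when the template does not apply.
#' @export
applyTemplate <- function(product, template) {
  stopifnot(is.character(product), length(product) == 1,
            is.character(template), length(template) == 1)
  pat <- .parse_template(template)
  mol <- .parse_smiles(product)
  pp <- pat$product; rp <- pat$reactant

  matches <- .match_pattern(pp, mol)
  if (length(matches) == 0) return(list())

  prodMapIdx <- stats::setNames(seq_len(.mol_natoms(pp)), pp$map)
  reactMaps <- rp$map

  out <- list()
  seen <- character(0)
  for (assign in matches) {
    g <- mol
    # remove every product-pattern bond from the molecule
    for (bi in seq_along(pp$b1)) {
      mb <- .mol_bond_between(g, assign[pp$b1[bi]], assign[pp$b2[bi]])
      if (mb > 0L) {
        g$b1 <- g$b1[-mb]; g$b2 <- g$b2[-mb]; g$order <- g$order[-mb]
      }
    }
    # atoms for reactant-pattern nodes: mapped ones resolve through the
    # match; unmapped ones are new leaving-group atoms
    ratom <- integer(.mol_natoms(rp))
    for (ri in seq_len(.mol_natoms(rp))) {
      m <- reactMaps[ri]
      if (m > 0 && as.character(m) %in% names(prodMapIdx)) {
        ratom[ri] <- assign[prodMapIdx[[as.character(m)]]]
        if (!is.na(rp$nH[ri])) g$nH[ratom[ri]] <- rp$nH[ri]
        if (!is.na(rp$charge[ri])) g$charge[ratom[ri]] <- rp$charge[ri]
      } else {
        g <- .mol_add_atom(g, rp$elem[ri], rp$arom[ri],
                           ifelse(is.na(rp$charge[ri]), 0L, rp$charge[ri]),
                           ifelse(is.na(rp$nH[ri]), 0L, rp$nH[ri]), 0L)
        ratom[ri] <- .mol_natoms(g)
      }
    }
    for (bi in seq_along(rp$b1))
      g <- .mol_add_bond(g, ratom[rp$b1[bi]], ratom[rp$b2[bi]], rp$order[bi])
    # product-pattern atoms with no reactant counterpart disappear
    gone <- which(!(pp$map %in% reactMaps))
    if (length(gone)) {
      keep <- setdiff(seq_len(.mol_natoms(g)), assign[gone])
      g <- .mol_subgraph(g, keep)
    }
    comps <- .mol_components(g)
    smis <- try(sort(canonicalSmiles(vapply(
      comps, function(ix) .write_smiles(.mol_subgraph(g, ix), withMaps = FALSE),
      character(1)))), silent = TRUE)
    if (inherits(smis, "try-error")) next  # chemically invalid rewrite
    key <- paste(smis, collapse = "|")
    if (!key %in% seen) {
      seen <- c(seen, key)
      out[[length(out) + 1L]] <- smis
    }
  }
  out
}
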