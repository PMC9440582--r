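# Internal molecular-graph representation for atom-mapped SMILES.
#
# Atom-mapped reaction handling (template extraction and application) needs
# direct access to atoms, bonds and map numbers, which the format converters
# do not expose.  This is a deliberately restricted SMILES dialect covering
# the organic subset plus bracket atoms with H counts, charges and atom maps,
# branches, ring closures and the bond orders -, =, #.  Stereochemistry,
# isotopes and multi-character ring closures beyond %nn are rejected with a
# clear error.  Plain (unmapped) SMILES handed to the rest of the package are
# validated and canonicalized through OpenBabel instead.

.ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
.ELEMENTS <- c(.ORGANIC_SUBSET, "H", "Si", "Se", "Sn", "As", "Li", "Na",
               "K", "Mg", "Ca", "Zn", "Cu", "Fe", "Mn", "Al")

.new_mol <- function() {
  list(elem = character(0), arom = logical(0), charge = integer(0),
       nH = integer(0), hExplicit = logical(0), map = integer(0),
       b1 = integer(0), b2 = integer(0), order = integer(0))
}

.mol_add_atom <- function(mol, elem, arom = FALSE, charge = 0L, nH = NA_integer_,
                          map = 0L) {
  mol$elem <- c(mol$elem, elem)
  mol$arom <- c(mol$arom, arom)
  mol$charge <- c(mol$charge, as.integer(charge))
  mol$nH <- c(mol$nH, as.integer(nH))
  mol$hExplicit <- c(mol$hExplicit, !is.na(nH))
  mol$map <- c(mol$map, as.integer(map))
  mol
}

.mol_add_bond <- function(mol, a1, a2, order = 1L) {
  mol$b1 <- c(mol$b1, as.integer(a1))
  mol$b2 <- c(mol$b2, as.integer(a2))
  mol$order <- c(mol$order, as.integer(order))
  mol
}

.mol_natoms <- function(mol) length(mol$elem)

# bond-order sum per atom (aromatic bonds counted as 1, plus 1 for the ring)
.mol_degree_sum <- function(mol) {
  n <- .mol_natoms(mol)
  deg <- numeric(n)
  if (length(mol$b1)) {
    ord <- mol$order
    for (i in seq_along(mol$b1)) {
      deg[mol$b1[i]] <- deg[mol$b1[i]] + ord[i]
      deg[mol$b2[i]] <- deg[mol$b2[i]] + ord[i]
    }
  }
  deg
}

.default_valence <- function(elem, degsum) {
  vs <- switch(elem,
               B = 3L, C = 4L, N = c(3L, 5L), O = 2L, P = c(3L, 5L),
               S = c(2L, 4L, 6L), F = 1L, Cl = 1L, Br = 1L, I = 1L,
               stop("no default valence for element '", elem, "'"))
  ok <- vs[vs >= degsum]
  if (length(ok) == 0) degsum else ok[1]
}

# fill implicit hydrogen counts for atoms written without brackets
.mol_finalize_h <- function(mol) {
  need <- !mol$hExplicit
  if (!any(need)) return(mol)
  deg <- .mol_degree_sum(mol)
  for (i in which(need)) {
    # organic-subset atoms are neutral (charges require brackets, where the
    # H count is explicit); aromatic atoms get one extra bond equivalent
    ds <- deg[i] + if (mol$arom[i]) 1 else 0
    v <- .default_valence(mol$elem[i], ds)
    mol$nH[i] <- as.integer(max(0, v - ds))
  }
  mol
}

.mol_neighbors <- function(mol) {
  n <- .mol_natoms(mol)
  nb <- vector("list", n)
  for (i in seq_along(mol$b1)) {
    a <- mol$b1[i]; b <- mol$b2[i]
    nb[[a]] <- rbind(nb[[a]], c(b, mol$order[i], i))
    nb[[b]] <- rbind(nb[[b]], c(a, mol$order[i], i))
  }
  nb
}

# --- parser ----------------------------------------------------------------

.parse_bracket <- function(body, s) {
  # body without the enclosing []; returns list(elem, arom, nH, charge, map)
  rest <- body
  if (grepl("^[0-9]+", rest)) stop("isotope labels are not supported in '", s, "'")
  m <- regmatches(rest, regexpr("^(Cl|Br|[A-Z][a-z]?|[bcnops])", rest))
  if (length(m) == 0) stop("cannot read atom in bracket '[", body, "]' of '", s, "'")
  sym <- m
  arom <- sym %in% c("b", "c", "n", "o", "p", "s")
  elem <- if (arom) toupper(sym) else sym
  if (!elem %in% .ELEMENTS) stop("unknown element '", sym, "' in '", s, "'")
  rest <- substring(rest, nchar(sym) + 1)
  if (grepl("^[@]", rest)) stop("stereo descriptors are not supported in '", s, "'")
  nH <- 0L
  if (grepl("^H", rest)) {
    rest <- substring(rest, 2)
    hm <- regmatches(rest, regexpr("^[0-9]+", rest))
    if (length(hm)) {
      nH <- as.integer(hm)
      rest <- substring(rest, nchar(hm) + 1)
    } else nH <- 1L
  }
  charge <- 0L
  cm <- regmatches(rest, regexpr("^(\\+\\+|--|[+-][0-9]*)", rest))
  if (length(cm)) {
    charge <- switch(cm, "+" = 1L, "-" = -1L, "++" = 2L, "--" = -2L,
                     as.integer(paste0(substring(cm, 1, 1), substring(cm, 2))))
    if (cm %in% c("+", "-")) charge <- if (cm == "+") 1L else -1L
    rest <- substring(rest, nchar(cm) + 1)
  }
  map <- 0L
  if (grepl("^:", rest)) {
    mm <- regmatches(rest, regexpr("^:[0-9]+", rest))
    if (length(mm) == 0) stop("malformed atom map in '", s, "'")
    map <- as.integer(substring(mm, 2))
    rest <- substring(rest, nchar(mm) + 1)
  }
  if (nchar(rest)) stop("unsupported bracket content '", body, "' in '", s, "'")
  list(elem = elem, arom = arom, nH = nH, charge = charge, map = map)
}

# Parse one (possibly disconnected) SMILES string into a molecular graph.
.parse_smiles <- function(s) {
  if (!is.character(s) || length(s) != 1 || is.na(s) || !nchar(s))
    stop("expected a single non-empty SMILES string")
  mol <- .new_mol()
  chars <- strsplit(s, "")[[1]]
  i <- 1L
  nchr <- length(chars)
  prev <- 0L                       # previous atom index (0 = none)
  bond <- 1L                       # pending bond order
  bondSet <- FALSE
  stack <- integer(0)
  rings <- list()                  # digit -> c(atom, order)

  attach_atom <- function(idx) {
    if (prev > 0L) mol <<- .mol_add_bond(mol, prev, idx, bond)
    else if (bondSet) stop("bond symbol with no preceding atom in '", s, "'")
    prev <<- idx
    bond <<- 1L
    bondSet <<- FALSE
  }

  while (i <= nchr) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= nchr && chars[j] != "]") j <- j + 1L
      if (j > nchr) stop("unclosed bracket in '", s, "'")
      at <- .parse_bracket(paste(chars[(i + 1):(j - 1)], collapse = ""), s)
      mol <- .mol_add_atom(mol, at$elem, at$arom, at$charge, at$nH, at$map)
      attach_atom(.mol_natoms(mol))
      i <- j + 1L
    } else if (ch %in% c("C", "B") && i < nchr && chars[i + 1] %in% c("l", "r") &&
               paste0(ch, chars[i + 1]) %in% c("Cl", "Br")) {
      mol <- .mol_add_atom(mol, paste0(ch, chars[i + 1]))
      attach_atom(.mol_natoms(mol))
      i <- i + 2L
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      mol <- .mol_add_atom(mol, ch)
      attach_atom(.mol_natoms(mol))
      i <- i + 1L
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      mol <- .mol_add_atom(mol, toupper(ch), arom = TRUE)
      attach_atom(.mol_natoms(mol))
      i <- i + 1L
    } else if (ch == "-") { bond <- 1L; bondSet <- TRUE; i <- i + 1L
    } else if (ch == "=") { bond <- 2L; bondSet <- TRUE; i <- i + 1L
    } else if (ch == "#") { bond <- 3L; bondSet <- TRUE; i <- i + 1L
    } else if (ch == "(") {
      if (prev == 0L) stop("branch with no preceding atom in '", s, "'")
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0) stop("unbalanced ')' in '", s, "'")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch == ".") {
      prev <- 0L; bond <- 1L; bondSet <- FALSE; i <- i + 1L
    } else if (grepl("^[0-9]$", ch) || ch == "%") {
      if (ch == "%") {
        if (i + 2L > nchr) stop("malformed %nn ring closure in '", s, "'")
        key <- paste(chars[(i + 1):(i + 2)], collapse = "")
        i <- i + 3L
      } else {
        key <- ch
        i <- i + 1L
      }
      if (prev == 0L) stop("ring closure before any atom in '", s, "'")
      if (!is.null(rings[[key]])) {
        op <- rings[[key]]
        ord <- max(op[2], if (bondSet) bond else 1L)
        mol <- .mol_add_bond(mol, op[1], prev, ord)
        rings[[key]] <- NULL
      } else {
        rings[[key]] <- c(prev, if (bondSet) bond else 1L)
      }
      bond <- 1L; bondSet <- FALSE
    } else {
      stop("SMILES character '", ch, "' is not supported (in '", s, "')")
    }
  }
  if (length(stack)) stop("unbalanced '(' in '", s, "'")
  open <- names(rings)[!vapply(rings, is.null, logical(1))]
  if (length(open)) stop("unclosed ring bond in '", s, "'")
  if (.mol_natoms(mol) == 0) stop("no atoms parsed from '", s, "'")
  .mol_finalize_h(mol)
}

# --- writer ----------------------------------------------------------------

.atom_token <- function(mol, i, withMaps = TRUE, withH = TRUE) {
  sym <- if (mol$arom[i]) tolower(mol$elem[i]) else mol$elem[i]
  h <- if (withH && mol$nH[i] > 0) {
    if (mol$nH[i] == 1) "H" else paste0("H", mol$nH[i])
  } else ""
  ch <- mol$charge[i]
  cs <- if (ch == 0) "" else if (ch == 1) "+" else if (ch == -1) "-"
        else if (ch > 1) paste0("+", ch) else paste0("-", -ch)
  ms <- if (withMaps && mol$map[i] > 0) paste0(":", mol$map[i]) else ""
  paste0("[", sym, h, cs, ms, "]")
}

.bond_token <- function(order) c("", "=", "#")[order]

# Serialize a molecular graph as SMILES with every atom bracketed (explicit
# H counts), so no implicit-valence model is needed downstream.  Two passes:
# a DFS that classifies bonds into tree and ring bonds, then emission with
# ring-closure digits attached to both endpoints.
.write_smiles <- function(mol, withMaps = TRUE) {
  n <- .mol_natoms(mol)
  if (n == 0) stop("cannot write an empty molecule")
  nb <- .mol_neighbors(mol)
  visited <- logical(n)
  treeChildren <- vector("list", n)   # list of c(child, bondIndex)
  ringBonds <- integer(0)
  roots <- integer(0)

  dfs <- function(i) {
    visited[i] <<- TRUE
    nbr <- nb[[i]]
    if (is.null(nbr)) return(invisible())
    for (r in seq_len(nrow(nbr))) {
      j <- nbr[r, 1]; bi <- nbr[r, 3]
      if (bi %in% usedBond) next
      if (visited[j]) {
        usedBond <<- c(usedBond, bi)
        ringBonds <<- c(ringBonds, bi)
      } else {
        usedBond <<- c(usedBond, bi)
        treeChildren[[i]] <<- c(treeChildren[[i]], list(c(j, bi)))
        dfs(j)
      }
    }
  }
  usedBond <- integer(0)
  for (i in seq_len(n)) {
    if (!visited[i]) {
      roots <- c(roots, i)
      dfs(i)
    }
  }

  # ring digits at both endpoints (bond-order token written at both; legal
  # as long as the orders agree, which they do by construction)
  ringAt <- vector("list", n)
  if (length(ringBonds)) {
    for (rn in seq_along(ringBonds)) {
      bi <- ringBonds[rn]
      dig <- if (rn < 10) as.character(rn) else paste0("%", sprintf("%02d", rn))
      tok <- paste0(.bond_token(mol$order[bi]), dig)
      ringAt[[mol$b1[bi]]] <- c(ringAt[[mol$b1[bi]]], tok)
      ringAt[[mol$b2[bi]]] <- c(ringAt[[mol$b2[bi]]], tok)
    }
  }

  emit <- function(i, parentBond) {
    out <- if (parentBond > 0L) .bond_token(mol$order[parentBond]) else ""
    out <- paste0(out, .atom_token(mol, i, withMaps),
                  paste(ringAt[[i]], collapse = ""))
    kids <- treeChildren[[i]]
    if (length(kids)) {
      segs <- vapply(kids, function(k) emit(k[1], k[2]), character(1))
      if (length(segs) > 1) {
        out <- paste0(out,
                      paste0("(", segs[-length(segs)], ")", collapse = ""),
                      segs[length(segs)])
      } else {
        out <- paste0(out, segs)
      }
    }
    out
  }
  paste(vapply(roots, function(i) emit(i, 0L), character(1)), collapse = ".")
}
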