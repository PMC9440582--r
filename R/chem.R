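# Thin wrappers around OpenBabel (via ChemmineOB) for canonical SMILES and
# circular fingerprints.  These are the only places the package talks to the
# external cheminformatics toolkit.

.ob_quiet <- function(expr) {
  # OpenBabel writes parse warnings to stderr; keep package output clean
  msgs <- file(tempfile(), open = "w")
  on.exit({ sink(type = "message"); close(msgs) }, add = TRUE)
  sink(msgs, type = "message")
  force(expr)
}

.strip_atom_maps <- function(smiles) {
  gsub(":[0-9]+\\]", "]", smiles)
}

#' Canonicalize SMILES strings
#'
#' Converts SMILES to OpenBabel canonical form. Atom maps are stripped first,
#' so two differently written or differently mapped strings of the same
#' molecule canonicalize identically.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES, same length as the input.
#' @examples
#' canonicalSmiles(c("OCC", "CCO"))
#' @export
canonicalSmiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1)
  smiles <- .strip_atom_maps(smiles)
  one <- function(s) {
    out <- .ob_quiet(ChemmineOB::convertFormat("SMI", "CAN", source = s))
    out <- trimws(strsplit(out, "\n", fixed = TRUE)[[1]][1])
    if (is.na(out) || !nchar(out))
      stop("SMILES '", s, "' could not be parsed by the toolkit")
    out
  }
  batch <- .ob_quiet(ChemmineOB::convertFormat(
    "SMI", "CAN", source = paste(smiles, collapse = "\n")))
  lines <- trimws(strsplit(batch, "\n", fixed = TRUE)[[1]])
  lines <- lines[nzchar(lines)]
  if (length(lines) == length(smiles)) return(lines)
  # at least one molecule failed; redo one by one to name the offender
  vapply(smiles, one, character(1), USE.NAMES = FALSE)
}

.smiles_parses <- function(smiles) {
  ok <- try(.ob_quiet(ChemmineOB::convertFormat(
    "SMI", "CAN", source = .strip_atom_maps(smiles))), silent = TRUE)
  !(inherits(ok, "try-error") || !nzchar(trimws(ok)))
}

#' Compute a folded circular (ECFP/Morgan-style) fingerprint
#'
#' Delegates to OpenBabel's extended-connectivity fingerprints and OR-folds
#' the native 4096-bit vector down to the requested length. Following the
#' ECFP naming convention, \code{radius = 2} corresponds to ECFP4.
#'
#' @param smiles character vector of SMILES strings (one fingerprint per
#'   element).
#' @param length fingerprint length in bits; must divide the toolkit's native
#'   4096. Default 2048.
#' @param radius circular-environment radius (default 2, the ECFP4
#'   convention).
#' @return if \code{smiles} has one element, an integer 0/1 vector of
#'   \code{length} bits; otherwise a matrix with one fingerprint per row.
#' @examples
#' fp <- computeECFP("CCO")
#' sum(fp)
#' @export
computeECFP <- function(smiles, length = 2048L, radius = 2L) {
  stopifnot(is.character(smiles), length(smiles) >= 1)
  length <- as.integer(length)
  radius <- as.integer(radius)
  if (!radius %in% 0:5) stop("radius must be between 0 and 5")
  native <- 4096L
  if (length < 1L || native %% length != 0L)
    stop("fingerprint length must divide the toolkit's native ", native, " bits")
  fpName <- paste0("ECFP", 2L * radius)
  out <- matrix(0L, nrow = base::length(smiles), ncol = length)
  for (i in seq_along(smiles)) {
    s <- .strip_atom_maps(smiles[i])
    if (!.smiles_parses(s))
      stop("SMILES '", smiles[i], "' could not be parsed for fingerprinting")
    ref <- .ob_quiet(ChemmineOB::forEachMol("SMILES", s, identity, reduce = c))
    bits <- .ob_quiet(ChemmineOB::fingerprint_OB(list(ref), fpName))
    bits <- as.numeric(bits)
    if (base::length(bits) != native)
      stop("unexpected native fingerprint length ", base::length(bits))
    folded <- rowSums(matrix(bits, nrow = length)) > 0
    out[i, ] <- as.integer(folded)
  }
  if (nrow(out) == 1L) out[1L, ] else out
}
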