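# Product descriptors: character vocabulary, padded one-hot SMILES matrices
# and length filtering.  The fingerprint encoder lives in chem.R.

#' Build a character vocabulary from SMILES strings
#'
#' Collects the distinct characters over all input strings and sorts them in
#' a locale-independent (C radix) order, so the vocabulary is reproducible
#' and independent of input order.
#'
#' @param smiles character vector of SMILES strings (typically the training
#'   products).
#' @return a \linkS4class{TokenVocabulary}.
#' @examples
#' tokens(buildVocabulary(c("CCO", "CO")))
#' @export
buildVocabulary <- function(smiles) {
  if (!is.character(smiles) || length(smiles) == 0 || all(!nzchar(smiles)))
    stop("vocabulary input must be a non-empty character vector")
  chars <- unique(unlist(strsplit(smiles, "", fixed = TRUE)))
  new("TokenVocabulary", tokens = sort(chars, method = "radix"))
}

#' One-hot encode a SMILES string
#'
#' Row i of the result has a single 1 in the column of the i-th character;
#' rows past the string length are zero padding. Characters missing from the
#' vocabulary and strings longer than L are rejected (no silent truncation):
#' over-length products are removed beforehand with
#' \code{\link{filterByLength}}.
#'
#' @param smiles a single SMILES string (may be empty, giving an all-zero
#'   matrix).
#' @param vocab a \linkS4class{TokenVocabulary}.
#' @param L maximum sequence length (number of rows).
#' @return an \linkS4class{OneHotMatrix}.
#' @examples
#' oneHotEncode("CO", buildVocabulary("CO"), L = 4)
#' @export
oneHotEncode <- function(smiles, vocab, L) {
  stopifnot(is.character(smiles), length(smiles) == 1, is(vocab, "TokenVocabulary"))
  L <- as.integer(L)
  if (L < 1) stop("L must be >= 1")
  n <- nchar(smiles)
  if (n > L)
    stop("SMILES of length ", n, " exceeds L = ", L,
         "; over-length products must be filtered out, not truncated")
  m <- matrix(0L, nrow = L, ncol = length(vocab@tokens),
              dimnames = list(NULL, vocab@tokens))
  if (n > 0) {
    idx <- match(strsplit(smiles, "", fixed = TRUE)[[1]], vocab@tokens)
    if (anyNA(idx)) {
      bad <- substring(smiles, which(is.na(idx))[1], which(is.na(idx))[1])
      stop("character '", bad, "' is not in the vocabulary")
    }
    m[cbind(seq_len(n), idx)] <- 1L
  }
  new("OneHotMatrix", mat = m, trueLength = n)
}

#' Decode a one-hot matrix back to its SMILES string
#'
#' @param x an \linkS4class{OneHotMatrix}.
#' @param vocab the \linkS4class{TokenVocabulary} used for encoding.
#' @return the original string.
#' @export
decodeOneHot <- function(x, vocab) {
  stopifnot(is(x, "OneHotMatrix"), is(vocab, "TokenVocabulary"))
  if (x@trueLength == 0) return("")
  rows <- x@mat[seq_len(x@trueLength), , drop = FALSE]
  paste(vocab@tokens[max.col(rows)], collapse = "")
}

#' Drop samples whose product SMILES exceeds a length cap
#'
#' One-hot encoding pads every product to a common length L; products longer
#' than L are removed (train, validation and test alike) rather than
#' truncated. The number of removed samples is reported with a message.
#'
#' @param dataset a \linkS4class{LabeledDataset}.
#' @param L maximum product SMILES length.
#' @return the filtered \linkS4class{LabeledDataset}.
#' @export
filterByLength <- function(dataset, L) {
  stopifnot(is(dataset, "LabeledDataset"))
  L <- as.integer(L)
  if (L < 1) stop("L must be >= 1")
  keep <- nchar(dataset@products) <= L
  if (all(keep)) return(dataset)
  message("filterByLength: dropping ", sum(!keep), " of ", length(keep),
          " samples longer than ", L)
  if (!any(keep)) stop("no samples remain after length filtering")
  .make_dataset(dataset@products[keep], dataset@labels[keep],
                if (length(dataset@reactants)) dataset@reactants[keep]
                else list(),
                dataset@library)
}

#' Vocabulary sidecar files
#'
#' The vocabulary is persisted as a JSON array of tokens in order.
#'
#' @param vocab a \linkS4class{TokenVocabulary}.
#' @param path file path.
#' @name vocabulary-io
NULL

#' @rdname vocabulary-io
#' @export
writeVocabulary <- function(vocab, path) {
  stopifnot(is(vocab, "TokenVocabulary"))
  jsonlite::write_json(vocab@tokens, path)
  invisible(path)
}

#' @rdname vocabulary-io
#' @export
readVocabulary <- function(path) {
  new("TokenVocabulary", tokens = jsonlite::read_json(path, simplifyVector = TRUE))
}

# Batched encodings used by the trainer: products -> n x L x V one-hot array
# and n x Lfp x 1 fingerprint array.
.encode_onehot_batch <- function(products, vocab, L) {
  n <- length(products)
  V <- length(vocab@tokens)
  arr <- array(0, dim = c(n, L, V))
  for (i in seq_len(n)) {
    oh <- oneHotEncode(products[i], vocab, L)
    arr[i, , ] <- oh@mat
  }
  arr
}

.encode_fp_batch <- function(products, fpLength, fpRadius) {
  fp <- computeECFP(products, length = fpLength, radius = fpRadius)
  if (is.null(dim(fp))) fp <- matrix(fp, nrow = 1)
  array(fp, dim = c(nrow(fp), ncol(fp), 1L))
}
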