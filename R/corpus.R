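# Reaction corpus handling: reading reaction SMILES, multi-product
# splitting, template-library construction and dataset assembly.

#' Parse one reaction SMILES line
#'
#' Splits a reaction SMILES at its ">" separators into reactants, agents and
#' products, and each side at "." into molecules. Both the three-field
#' dialect \code{reactants>agents>products} and the agent-free
#' \code{reactants>>products} are accepted; atom maps are preserved verbatim.
#' Every molecular fragment is checked to parse.
#'
#' @param line a reaction SMILES string.
#' @param sourceId opaque identifier used in error messages.
#' @return a \linkS4class{RawReaction}.
#' @examples
#' parseReaction("CC(=O)O.OCC>>CC(=O)OCC", "r1")
#' @export
parseReaction <- function(line, sourceId = "") {
  stopifnot(is.character(line), length(line) == 1)
  line <- trimws(line)
  who <- if (nzchar(sourceId)) paste0(" (record ", sourceId, ")") else ""
  parts <- strsplit(line, ">", fixed = TRUE)[[1]]
  if (length(parts) != 3)
    stop("malformed reaction string", who,
         ": expected 'reactants>agents>products' or 'reactants>>products', got ",
         length(parts), " field(s)")
  splitSide <- function(s) {
    if (!nzchar(s)) return(character(0))
    frags <- strsplit(s, ".", fixed = TRUE)[[1]]
    frags[nzchar(frags)]
  }
  reactants <- splitSide(parts[1])
  agents <- splitSide(parts[2])
  prods <- splitSide(parts[3])
  if (length(reactants) == 0)
    stop("reaction has no reactants", who)
  if (length(prods) == 0)
    stop("reaction has no products", who)
  for (frag in c(reactants, agents, prods)) {
    ok <- try(.parse_smiles(frag), silent = TRUE)
    if (inherits(ok, "try-error"))
      stop("unparseable molecule '", frag, "'", who, ": ",
           attr(ok, "condition")$message)
  }
  new("RawReaction", reactantSmiles = reactants, agentSmiles = agents,
      productSmiles = prods, sourceId = as.character(sourceId))
}

#' Read a reaction SMILES file
#'
#' Accepts plain text (one reaction per line, optionally preceded by an id
#' column separated by a tab or comma) or a CSV with a header, in which case
#' the reaction column is detected as the one containing ">".
#'
#' @param path path to the input file.
#' @return a list of \linkS4class{RawReaction} objects.
#' @export
readReactions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (nrow(df) == 0) stop("no reactions in ", path)
    rxcol <- which(vapply(df, function(col)
      is.character(col) && any(grepl(">", col, fixed = TRUE)), logical(1)))[1]
    if (is.na(rxcol)) stop("no reaction SMILES column found in ", path)
    ids <- if ("id" %in% names(df)) as.character(df$id)
           else as.character(seq_len(nrow(df)))
    rx <- df[[rxcol]]
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
    if (length(lines) == 0) stop("no reactions in ", path)
    fields <- strsplit(lines, "[\t,]")
    rx <- character(length(lines)); ids <- character(length(lines))
    for (i in seq_along(fields)) {
      f <- fields[[i]]
      j <- which(grepl(">", f, fixed = TRUE))[1]
      if (is.na(j)) stop("line ", i, " of ", path, " has no reaction SMILES")
      rx[i] <- f[j]
      ids[i] <- if (j > 1) f[1] else as.character(i)
    }
  }
  mapply(parseReaction, rx, ids, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Split a multi-product reaction into single-product reactions
#'
#' Each product gives one reaction inheriting the full reactant and agent
#' lists; a single-product input comes back unchanged (as a 1-element list).
#'
#' @param raw a \linkS4class{RawReaction}.
#' @return list of single-product \linkS4class{RawReaction}s.
#' @export
splitMultiProduct <- function(raw) {
  stopifnot(is(raw, "RawReaction"))
  if (length(raw@productSmiles) == 0) stop("reaction has no products")
  lapply(seq_along(raw@productSmiles), function(i) {
    new("RawReaction",
        reactantSmiles = raw@reactantSmiles,
        agentSmiles = raw@agentSmiles,
        productSmiles = raw@productSmiles[i],
        sourceId = if (length(raw@productSmiles) == 1) raw@sourceId
                   else paste0(raw@sourceId, ".", i))
  })
}

#' Build a template library from extracted template strings
#'
#' Duplicates are removed and class labels 1..T are assigned in order of
#' first occurrence, so rebuilding from the same corpus reproduces identical
#' labels.
#'
#' @param templateStrings character vector of retro-template strings.
#' @return a \linkS4class{TemplateLibrary}.
#' @examples
#' lib <- buildTemplateLibrary(c("a>>b", "c>>d", "a>>b"))
#' labelOf(lib, "c>>d")
#' @export
buildTemplateLibrary <- function(templateStrings) {
  if (!is.character(templateStrings) || length(templateStrings) == 0)
    stop("template list must be a non-empty character vector")
  new("TemplateLibrary", templates = unique(templateStrings))
}

#' Preprocess raw reactions into labeled records and a template library
#'
#' The full preprocessing chain: multi-product reactions are split, a
#' retro-template is extracted from every single-product reaction at the
#' given environment radius, reactant/product SMILES are canonicalized (atom
#' maps stripped), templates are deduplicated into a
#' \linkS4class{TemplateLibrary} (labels by first occurrence) and each record
#' gets its class label. Records whose template extraction fails are dropped
#' with a message rather than aborting the run.
#'
#' @param raws list of \linkS4class{RawReaction} objects.
#' @param radius template environment radius (bonds around changed atoms).
#' @return list with \code{records} (list of \linkS4class{ReactionRecord}),
#'   \code{library} (\linkS4class{TemplateLibrary}) and \code{nDropped}.
#' @export
preprocessReactions <- function(raws, radius = 1L) {
  stopifnot(is.list(raws), length(raws) >= 1)
  singles <- unlist(lapply(raws, splitMultiProduct), recursive = FALSE)
  tmpl <- character(length(singles))
  keep <- logical(length(singles))
  for (i in seq_along(singles)) {
    tt <- try(extractTemplate(singles[[i]], radius = radius), silent = TRUE)
    if (inherits(tt, "try-error")) {
      keep[i] <- FALSE
    } else {
      tmpl[i] <- tt
      keep[i] <- TRUE
    }
  }
  nDropped <- sum(!keep)
  if (nDropped > 0)
    message("dropped ", nDropped,
            " reaction(s) with failed template extraction")
  if (!any(keep)) stop("template extraction failed for every reaction")
  singles <- singles[keep]
  tmpl <- tmpl[keep]
  library <- buildTemplateLibrary(tmpl)
  labels <- labelOf(library, tmpl)
  records <- vector("list", length(singles))
  for (i in seq_along(singles)) {
    records[[i]] <- new("ReactionRecord",
                        reactants = canonicalSmiles(singles[[i]]@reactantSmiles),
                        product = canonicalSmiles(singles[[i]]@productSmiles),
                        template = tmpl[i],
                        classLabel = labels[i])
  }
  list(records = records, library = library, nDropped = nDropped)
}

#' Assemble a labeled dataset from reaction records
#'
#' One (product, class label) sample per record, with per-class counts and a
#' product-length distribution in \code{datasetStats}.
#'
#' @param records list of \linkS4class{ReactionRecord}s.
#' @param library the \linkS4class{TemplateLibrary} the labels refer to.
#' @return a \linkS4class{LabeledDataset}.
#' @export
buildDataset <- function(records, library) {
  if (!is.list(records) || length(records) == 0)
    stop("record list must be non-empty")
  stopifnot(is(library, "TemplateLibrary"))
  for (i in seq_along(records)) {
    r <- records[[i]]
    lab <- labelOf(library, r@template)
    if (is.na(lab))
      stop("record ", i, " has a template unknown to the library: ",
           r@template)
    if (lab != r@classLabel)
      stop("record ", i, " carries label ", r@classLabel,
           " but the library assigns ", lab)
  }
  prods <- vapply(records, function(r) r@product, character(1))
  labels <- vapply(records, function(r) r@classLabel, integer(1))
  reacts <- lapply(records, function(r) r@reactants)
  .make_dataset(prods, labels, reacts, library)
}

.make_dataset <- function(products, labels, reactants, library) {
  cc <- table(factor(labels, levels = seq_len(length(library@templates))))
  stats <- list(classCounts = stats::setNames(as.integer(cc), names(cc)),
                lengthTable = table(nchar(products)))
  new("LabeledDataset", products = products, labels = as.integer(labels),
      reactants = reactants, library = library, stats = stats)
}

# ------------------------------------------------------------------- file IO

#' Dataset and template-library files
#'
#' The dataset is persisted as TSV with columns \code{product_smiles},
#' \code{class_label} and (when ground-truth reactants are retained)
#' \code{reactant_smiles} (dot-joined); the library as TSV with columns
#' \code{class_label}, \code{template_smarts}. Re-reading reproduces
#' identical samples and library.
#'
#' @param dataset a \linkS4class{LabeledDataset}.
#' @param library a \linkS4class{TemplateLibrary}.
#' @param path output/input file path.
#' @return the written path (writers) or the reconstructed object (readers).
#' @name dataset-io
NULL

#' @rdname dataset-io
#' @export
writeDataset <- function(dataset, path) {
  stopifnot(is(dataset, "LabeledDataset"))
  df <- data.frame(product_smiles = dataset@products,
                   class_label = dataset@labels,
                   stringsAsFactors = FALSE)
  if (length(dataset@reactants))
    df$reactant_smiles <- vapply(dataset@reactants, paste,
                                 character(1), collapse = ".")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname dataset-io
#' @export
readDataset <- function(path, library) {
  stopifnot(is(library, "TemplateLibrary"))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("product_smiles", "class_label") %in% names(df)))
    stop("not a dataset TSV: ", path)
  reacts <- if ("reactant_smiles" %in% names(df))
    strsplit(df$reactant_smiles, ".", fixed = TRUE) else list()
  .make_dataset(df$product_smiles, df$class_label, reacts, library)
}

#' @rdname dataset-io
#' @export
writeTemplateLibrary <- function(library, path) {
  stopifnot(is(library, "TemplateLibrary"))
  utils::write.table(
    data.frame(class_label = seq_along(library@templates),
               template_smarts = library@templates),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname dataset-io
#' @export
readTemplateLibrary <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("class_label", "template_smarts") %in% names(df)))
    stop("not a template library TSV: ", path)
  df <- df[order(df$class_label), ]
  if (!identical(as.integer(df$class_label), seq_len(nrow(df))))
    stop("library labels must be exactly 1..T")
  new("TemplateLibrary", templates = df$template_smarts)
}

.library_checksum <- function(library) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(library@templates, f)
  unname(tools::md5sum(f))
}
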