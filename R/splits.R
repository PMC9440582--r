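# Dataset splitting: the Plain uniform random 80/10/10 partition and the
# label-coverage ("Aug") variant that guarantees every template class occurs
# at least once in the training part.

.check_ratios <- function(ratios) {
  if (length(ratios) != 3 || any(ratios < 0) || abs(sum(ratios) - 1) > 1e-8)
    stop("ratios must be three non-negative fractions summing to 1")
}

.labels_of <- function(x) {
  if (is(x, "LabeledDataset")) x@labels
  else if (is.numeric(x)) as.integer(x)
  else stop("expected a LabeledDataset or an integer label vector")
}

#' Plain random split
#'
#' Uniformly random partition of the samples into train/validation/test by
#' the given ratios (validation and test sizes are floored, the remainder
#' goes to train). Reproducible from the seed. With many rare classes this
#' split leaves some labels absent from the training part — the imbalance the
#' coverage split repairs.
#'
#' @param x a \linkS4class{LabeledDataset}, an integer label vector, or a
#'   single integer sample count.
#' @param ratios target (train, val, test) fractions, summing to 1.
#' @param seed RNG seed.
#' @return a \linkS4class{SplitAssignment}.
#' @export
plainSplit <- function(x, ratios = c(0.8, 0.1, 0.1), seed = 1L) {
  .check_ratios(ratios)
  n <- if (is(x, "LabeledDataset")) length(x@products)
       else if (length(x) == 1 && is.numeric(x)) as.integer(x)
       else length(.labels_of(x))
  if (n < 1) stop("dataset is empty")
  set.seed(as.integer(seed))
  perm <- sample.int(n)
  nVal <- floor(n * ratios[2])
  nTest <- floor(n * ratios[3])
  test <- perm[seq_len(nTest)]
  val <- perm[nTest + seq_len(nVal)]
  train <- if (nTest + nVal > 0) perm[-seq_len(nTest + nVal)] else perm
  new("SplitAssignment", trainIdx = sort(as.integer(train)),
      valIdx = sort(as.integer(val)), testIdx = sort(as.integer(test)),
      ratios = as.numeric(ratios), seed = as.integer(seed),
      strategy = "plain")
}

#' Label-coverage ("Aug") split
#'
#' Guarantees that every class label appears at least once in the training
#' part: one uniformly chosen sample per class is reserved into train first,
#' and the remaining samples are partitioned randomly so the realized
#' fractions stay as close to the targets as the reservation permits
#' (validation and test sizes are floored against the full sample count).
#' Classes with a single sample end up in train; if every class is a
#' singleton, validation and test come out empty with a warning.
#'
#' @param x a \linkS4class{LabeledDataset} or an integer vector of class
#'   labels.
#' @inheritParams plainSplit
#' @return a \linkS4class{SplitAssignment}.
#' @export
augSplit <- function(x, ratios = c(0.8, 0.1, 0.1), seed = 1L) {
  .check_ratios(ratios)
  labels <- .labels_of(x)
  n <- length(labels)
  if (n < 1) stop("dataset is empty")
  set.seed(as.integer(seed))
  reserved <- vapply(split(seq_len(n), labels), function(ix)
    if (length(ix) == 1L) ix else sample(ix, 1L), integer(1))
  pool <- setdiff(seq_len(n), reserved)
  pool <- if (length(pool)) sample(pool) else integer(0)
  nVal <- min(floor(n * ratios[2]), length(pool))
  nTest <- min(floor(n * ratios[3]), max(0L, length(pool) - nVal))
  test <- pool[seq_len(nTest)]
  val <- pool[nTest + seq_len(nVal)]
  rest <- if (nTest + nVal > 0) pool[-seq_len(nTest + nVal)] else pool
  train <- c(reserved, rest)
  if (nVal == 0 || nTest == 0)
    warning("coverage reservation left the validation and/or test part empty")
  new("SplitAssignment", trainIdx = sort(unname(as.integer(train))),
      valIdx = sort(as.integer(val)), testIdx = sort(as.integer(test)),
      ratios = as.numeric(ratios), seed = as.integer(seed), strategy = "aug")
}

#' Split persistence
#'
#' Splits are stored as TSV of (sample_index, partition) with a comment
#' header recording strategy, ratios and seed, so every experiment can be
#' replayed.
#'
#' @param split a \linkS4class{SplitAssignment}.
#' @param path file path.
#' @name split-io
NULL

#' @rdname split-io
#' @export
writeSplit <- function(split, path) {
  stopifnot(is(split, "SplitAssignment"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# strategy=", split@strategy),
    paste0("# ratios=", paste(split@ratios, collapse = ",")),
    paste0("# seed=", split@seed),
    "sample_index\tpartition"), con)
  df <- rbind(data.frame(i = split@trainIdx, p = "train"),
              data.frame(i = split@valIdx, p = "val"),
              data.frame(i = split@testIdx, p = "test"))
  df <- df[order(df$i), ]
  writeLines(paste(df$i, df$p, sep = "\t"), con)
  invisible(path)
}

#' @rdname split-io
#' @export
readSplit <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  get <- function(key) sub(paste0("# ", key, "="), "",
                           hdr[startsWith(hdr, paste0("# ", key, "="))])
  body <- utils::read.delim(text = lines[!startsWith(lines, "#")],
                            stringsAsFactors = FALSE)
  new("SplitAssignment",
      trainIdx = sort(body$sample_index[body$partition == "train"]),
      valIdx = sort(body$sample_index[body$partition == "val"]),
      testIdx = sort(body$sample_index[body$partition == "test"]),
      ratios = as.numeric(strsplit(get("ratios"), ",")[[1]]),
      seed = as.integer(get("seed")), strategy = get("strategy"))
}
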