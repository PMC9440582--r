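# Top-k exact-match evaluation.  The primary mode scores template-class
# identity; the reactant mode applies the top-k predicted templates to the
# product and scores whether any proposed reactant set equals the ground
# truth (as canonical, unordered sets).

.topk_from_hits <- function(hitRank, ks, n, mode) {
  acc <- vapply(ks, function(k) mean(hitRank <= k, na.rm = FALSE), numeric(1))
  new("TopKResult", k = as.integer(ks), accuracy = acc,
      nEvaluated = as.integer(n), mode = mode)
}

#' Top-k exact-match accuracy on class labels
#'
#' For each k, the fraction of samples whose true class label occurs among
#' the k highest-probability predictions; ties were already broken by the
#' ranking's stored order. Accuracy is non-decreasing in k.
#'
#' @param ranking a \linkS4class{PredictionRanking} (or an integer matrix of
#'   ranked labels, one row per sample).
#' @param truths integer vector of true class labels.
#' @param ks the k values to evaluate (default 1, 3, 5, 10).
#' @return a \linkS4class{TopKResult}.
#' @export
topkAccuracy <- function(ranking, truths, ks = c(1L, 3L, 5L, 10L)) {
  labs <- if (is(ranking, "PredictionRanking")) ranking@labels
          else if (is.matrix(ranking)) ranking
          else stop("ranking must be a PredictionRanking or a label matrix")
  if (nrow(labs) != length(truths))
    stop("rankings (", nrow(labs), ") and truths (", length(truths),
         ") differ in length")
  ks <- sort(as.integer(ks))
  if (any(ks < 1)) stop("k values must be positive")
  hitRank <- vapply(seq_len(nrow(labs)), function(i) {
    r <- match(truths[i], labs[i, ])
    if (is.na(r)) Inf else as.numeric(r)
  }, numeric(1))
  .topk_from_hits(hitRank, ks, length(truths), "label")
}

#' Top-k accuracy after template application
#'
#' A sample is a hit at k if any of its k top-ranked templates, applied to
#' the product, proposes a reactant set whose canonical SMILES equal the
#' ground-truth reactants (unordered comparison). Two distinct templates
#' proposing the same reactants both count. Requires the dataset to retain
#' ground-truth reactants.
#'
#' @param ranking a \linkS4class{PredictionRanking} over the dataset's
#'   classes.
#' @param dataset a \linkS4class{LabeledDataset} with ground-truth reactants,
#'   aligned with the ranking rows (e.g. via its test indices).
#' @param ks the k values to evaluate.
#' @param maxK cap on how many ranked templates are applied per sample
#'   (defaults to max(ks)).
#' @return a \linkS4class{TopKResult}.
#' @export
reactantMatchAccuracy <- function(ranking, dataset, ks = c(1L, 3L, 5L, 10L),
                                  maxK = max(ks)) {
  stopifnot(is(ranking, "PredictionRanking"), is(dataset, "LabeledDataset"))
  if (!length(dataset@reactants))
    stop("dataset does not retain ground-truth reactants")
  labs <- ranking@labels
  if (nrow(labs) != length(dataset@products))
    stop("ranking rows must align with the dataset samples")
  ks <- sort(as.integer(ks))
  maxK <- min(as.integer(maxK), ncol(labs))
  lib <- dataset@library
  hitRank <- rep(Inf, nrow(labs))
  for (i in seq_len(nrow(labs))) {
    truth <- sort(canonicalSmiles(dataset@reactants[[i]]))
    for (r in seq_len(maxK)) {
      tmpl <- templateOf(lib, labs[i, r])
      cand <- tryCatch(applyTemplate(dataset@products[i], tmpl),
                       error = function(e) list())
      if (any(vapply(cand, function(s) identical(s, truth), logical(1)))) {
        hitRank[i] <- r
        break
      }
    }
  }
  .topk_from_hits(hitRank, ks, nrow(labs), "reactant")
}
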