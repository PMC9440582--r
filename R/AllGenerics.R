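# Generics and simple accessors.  Slot access from user code should go
# through these.

#' @rdname TemplateLibrary-class
#' @param object,x an object.
#' @export
setGeneric("templates", function(x) standardGeneric("templates"))

#' @rdname TemplateLibrary-class
#' @export
setMethod("templates", "TemplateLibrary", function(x) x@templates)

#' Label of a template / template of a label
#'
#' @param library a \linkS4class{TemplateLibrary}.
#' @param template character vector of template strings.
#' @param label integer vector of class labels.
#' @return \code{labelOf}: integer labels (NA for unknown templates);
#'   \code{templateOf}: template strings.
#' @export
labelOf <- function(library, template) {
  stopifnot(is(library, "TemplateLibrary"))
  match(template, library@templates)
}

#' @rdname labelOf
#' @export
templateOf <- function(library, label) {
  stopifnot(is(library, "TemplateLibrary"))
  label <- as.integer(label)
  if (any(is.na(label)) || any(label < 1L) ||
      any(label > length(library@templates)))
    stop("label out of range of the template library")
  library@templates[label]
}

#' @rdname LabeledDataset-class
#' @param x a \linkS4class{LabeledDataset}.
#' @export
setGeneric("products", function(x) standardGeneric("products"))

#' @rdname LabeledDataset-class
#' @export
setMethod("products", "LabeledDataset", function(x) x@products)

#' @rdname LabeledDataset-class
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname LabeledDataset-class
#' @export
setMethod("classLabels", "LabeledDataset", function(x) x@labels)

#' @rdname LabeledDataset-class
#' @export
setGeneric("templateLibrary", function(x) standardGeneric("templateLibrary"))

#' @rdname LabeledDataset-class
#' @export
setMethod("templateLibrary", "LabeledDataset", function(x) x@library)

#' @rdname LabeledDataset-class
#' @export
setGeneric("datasetStats", function(x) standardGeneric("datasetStats"))

#' @rdname LabeledDataset-class
#' @export
setMethod("datasetStats", "LabeledDataset", function(x) x@stats)

#' @rdname LabeledDataset-class
#' @export
setGeneric("groundTruthReactants", function(x)
  standardGeneric("groundTruthReactants"))

#' @rdname LabeledDataset-class
#' @export
setMethod("groundTruthReactants", "LabeledDataset", function(x) x@reactants)

#' @rdname TokenVocabulary-class
#' @param x a \linkS4class{TokenVocabulary}.
#' @export
setGeneric("tokens", function(x) standardGeneric("tokens"))

#' @rdname TokenVocabulary-class
#' @export
setMethod("tokens", "TokenVocabulary", function(x) x@tokens)

#' @rdname OneHotMatrix-class
#' @param x an \linkS4class{OneHotMatrix}.
#' @export
setGeneric("encodingMatrix", function(x) standardGeneric("encodingMatrix"))

#' @rdname OneHotMatrix-class
#' @export
setMethod("encodingMatrix", "OneHotMatrix", function(x) x@mat)

#' @rdname OneHotMatrix-class
#' @export
setGeneric("trueLength", function(x) standardGeneric("trueLength"))

#' @rdname OneHotMatrix-class
#' @export
setMethod("trueLength", "OneHotMatrix", function(x) x@trueLength)

#' @rdname FilterSchedule-class
#' @param x a \linkS4class{FilterSchedule}.
#' @export
setGeneric("filterSizes", function(x) standardGeneric("filterSizes"))

#' @rdname FilterSchedule-class
#' @export
setMethod("filterSizes", "FilterSchedule", function(x) x@sizes)

#' @rdname MultiScaleFeature-class
#' @param x a \linkS4class{MultiScaleFeature}.
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname MultiScaleFeature-class
#' @export
setMethod("featureValues", "MultiScaleFeature", function(x) x@values)

#' @rdname MultiScaleFeature-class
#' @export
setGeneric("groupOffsets", function(x) standardGeneric("groupOffsets"))

#' @rdname MultiScaleFeature-class
#' @export
setMethod("groupOffsets", "MultiScaleFeature", function(x) x@groupOffsets)

#' @rdname SplitAssignment-class
#' @param x a \linkS4class{SplitAssignment}.
#' @export
setGeneric("trainIdx", function(x) standardGeneric("trainIdx"))

#' @rdname SplitAssignment-class
#' @export
setMethod("trainIdx", "SplitAssignment", function(x) x@trainIdx)

#' @rdname SplitAssignment-class
#' @export
setGeneric("valIdx", function(x) standardGeneric("valIdx"))

#' @rdname SplitAssignment-class
#' @export
setMethod("valIdx", "SplitAssignment", function(x) x@valIdx)

#' @rdname SplitAssignment-class
#' @export
setGeneric("testIdx", function(x) standardGeneric("testIdx"))

#' @rdname SplitAssignment-class
#' @export
setMethod("testIdx", "SplitAssignment", function(x) x@testIdx)

#' @rdname PredictionRanking-class
#' @param x a \linkS4class{PredictionRanking}.
#' @export
setGeneric("rankedLabels", function(x) standardGeneric("rankedLabels"))

#' @rdname PredictionRanking-class
#' @export
setMethod("rankedLabels", "PredictionRanking", function(x) x@labels)

#' @rdname PredictionRanking-class
#' @export
setGeneric("rankedProbs", function(x) standardGeneric("rankedProbs"))

#' @rdname PredictionRanking-class
#' @export
setMethod("rankedProbs", "PredictionRanking", function(x) x@probs)

#' @rdname TopKResult-class
#' @param x a \linkS4class{TopKResult}.
#' @export
setGeneric("accuracies", function(x) standardGeneric("accuracies"))

#' @rdname TopKResult-class
#' @export
setMethod("accuracies", "TopKResult", function(x) {
  stats::setNames(x@accuracy, paste0("top", x@k))
})

#' @rdname MultiScaleClassifier-class
#' @param x a \linkS4class{MultiScaleClassifier}.
#' @export
setGeneric("modelConfigOf", function(x) standardGeneric("modelConfigOf"))

#' @rdname MultiScaleClassifier-class
#' @export
setMethod("modelConfigOf", "MultiScaleClassifier", function(x) x@config)

#' @rdname MultiScaleClassifier-class
#' @export
setGeneric("trainingHistory", function(x) standardGeneric("trainingHistory"))

#' @rdname MultiScaleClassifier-class
#' @export
setMethod("trainingHistory", "MultiScaleClassifier", function(x) x@history)

# ----------------------------------------------------------------- lengths

#' @describeIn TemplateLibrary-class number of templates (= number of classes).
#' @export
setMethod("length", "TemplateLibrary", function(x) length(x@templates))

#' @describeIn TokenVocabulary-class number of tokens.
#' @export
setMethod("length", "TokenVocabulary", function(x) length(x@tokens))

#' @describeIn FilterSchedule-class number of operation groups K.
#' @export
setMethod("length", "FilterSchedule", function(x) length(x@sizes))

#' @describeIn LabeledDataset-class number of samples.
#' @export
setMethod("length", "LabeledDataset", function(x) length(x@products))

# --------------------------------------------------------------------- show

setMethod("show", "TemplateLibrary", function(object) {
  cat("TemplateLibrary with", length(object@templates), "templates",
      "(labels 1..", length(object@templates), ")\n", sep = " ")
})

setMethod("show", "LabeledDataset", function(object) {
  cat("LabeledDataset:", length(object@products), "samples,",
      length(object@library@templates), "classes\n")
  lens <- nchar(object@products)
  cat("  product SMILES length: min", min(lens), "median",
      stats::median(lens), "max", max(lens), "\n")
  if (length(object@reactants))
    cat("  ground-truth reactants retained\n")
})

setMethod("show", "FilterSchedule", function(object) {
  k <- length(object@sizes)
  cat("FilterSchedule: K =", k, "sizes",
      if (k <= 8) paste(object@sizes, collapse = ", ")
      else paste0(paste(utils::head(object@sizes, 3), collapse = ", "),
                  ", ..., ", object@sizes[k]),
      "\n")
})

setMethod("show", "TokenVocabulary", function(object) {
  cat("TokenVocabulary with", length(object@tokens), "tokens:",
      paste(object@tokens, collapse = ""), "\n")
})

setMethod("show", "ModelConfig", function(object) {
  cat("ModelConfig\n")
  cat("  fingerprint branch: length", object@fpLength, "radius",
      object@fpRadius, "| schedule", object@fpSchedule@minSize, "/",
      object@fpSchedule@step, "/", object@fpSchedule@maxSize,
      "(K =", length(object@fpSchedule@sizes), ")\n")
  cat("  SMILES branch: L =", object@seqLength, "channels",
      object@seqChannels, "| schedule", object@seqSchedule@minSize, "/",
      object@seqSchedule@step, "/", object@seqSchedule@maxSize,
      "(K =", length(object@seqSchedule@sizes), ")\n")
  cat("  out channels", object@outChannels, "| pooling", object@pooling,
      "| classes", object@nClasses, "\n")
  cat("  training:", object@epochs, "epochs, batch", object@batchSize,
      ", lr", object@learningRate, ", seed", object@seed, "\n")
})

setMethod("show", "MultiScaleClassifier", function(object) {
  cat("MultiScaleClassifier (", object@type, ")\n", sep = "")
  cat("  classes:", object@config@nClasses, "\n")
  if (nrow(object@history)) {
    last <- object@history[nrow(object@history), ]
    cat("  final training loss:", signif(last$trainLoss, 5))
    if (!is.na(last$valLoss)) cat(", validation loss:", signif(last$valLoss, 5))
    cat("\n")
  }
})

setMethod("show", "SplitAssignment", function(object) {
  n <- length(object@trainIdx) + length(object@valIdx) + length(object@testIdx)
  cat("SplitAssignment (", object@strategy, "), seed ", object@seed, "\n",
      sep = "")
  cat("  train/val/test:", length(object@trainIdx), "/",
      length(object@valIdx), "/", length(object@testIdx),
      " of ", n, "\n")
})

setMethod("show", "TopKResult", function(object) {
  cat("TopKResult (", object@mode, " match, n = ", object@nEvaluated, ")\n",
      sep = "")
  for (i in seq_along(object@k))
    cat(sprintf("  top-%d: %.4f\n", object@k[i], object@accuracy[i]))
})

setMethod("show", "PredictionRanking", function(object) {
  cat("PredictionRanking:", nrow(object@labels), "samples, top",
      ncol(object@labels), "classes each\n")
})

setMethod("show", "RawReaction", function(object) {
  cat("RawReaction", object@sourceId, "\n")
  cat("  ", paste(object@reactantSmiles, collapse = "."), ">",
      paste(object@agentSmiles, collapse = "."), ">",
      paste(object@productSmiles, collapse = "."), "\n", sep = "")
})

setMethod("show", "ReactionRecord", function(object) {
  cat("ReactionRecord (class ", object@classLabel, ")\n", sep = "")
  cat("  ", paste(object@reactants, collapse = "."), ">>", object@product,
      "\n", sep = "")
  cat("  template: ", object@template, "\n", sep = "")
})
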