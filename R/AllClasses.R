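#' @import methods
NULL

# ---------------------------------------------------------------- reactions

#' RawReaction: one parsed reaction SMILES record
#'
#' Holds the reactant, agent and product SMILES of a single reaction exactly
#' as written in the source file (atom maps preserved).
#'
#' @slot reactantSmiles character vector of reactant SMILES (non-empty).
#' @slot agentSmiles character vector of agent SMILES (possibly empty;
#'   agents are parsed but not used downstream).
#' @slot productSmiles character vector of product SMILES (non-empty).
#' @slot sourceId opaque record identifier from the input file.
#' @export
setClass("RawReaction",
         representation(reactantSmiles = "character",
                        agentSmiles = "character",
                        productSmiles = "character",
                        sourceId = "character"),
         validity = function(object) {
           if (length(object@reactantSmiles) == 0)
             return("reactant list must be non-empty")
           if (length(object@productSmiles) == 0)
             return("product list must be non-empty")
           TRUE
         })

#' ReactionRecord: the canonical reaction quadruple
#'
#' A fully preprocessed single-product reaction: canonical reactant SMILES,
#' one canonical product SMILES, its retro-template and the positive-integer
#' class label of that template.
#'
#' @slot reactants character vector of canonical reactant SMILES.
#' @slot product a single canonical product SMILES.
#' @slot template the reaction-SMARTS retro-template (product side first).
#' @slot classLabel positive integer class label.
#' @export
setClass("ReactionRecord",
         representation(reactants = "character", product = "character",
                        template = "character", classLabel = "integer"),
         validity = function(object) {
           if (length(object@product) != 1) return("exactly one product required")
           if (length(object@reactants) < 1) return("at least one reactant required")
           if (!nzchar(object@template)) return("template must be non-empty")
           if (length(object@classLabel) != 1 || is.na(object@classLabel) ||
               object@classLabel < 1L)
             return("classLabel must be a positive integer")
           TRUE
         })

#' TemplateLibrary: bijection between templates and class labels
#'
#' Stores the deduplicated retro-templates in label order: the template at
#' position i carries class label i, so labels are exactly 1..T.
#'
#' @slot templates character vector of unique template strings.
#' @export
setClass("TemplateLibrary",
         representation(templates = "character"),
         validity = function(object) {
           if (length(object@templates) == 0)
             return("template library must be non-empty")
           if (anyDuplicated(object@templates))
             return("template strings must be unique")
           if (any(!nzchar(object@templates)))
             return("template strings must be non-empty")
           TRUE
         })

#' LabeledDataset: (product, class label) samples with their library
#'
#' The training corpus for template classification: one row per reaction with
#' the canonical product SMILES and the class label of its template, plus the
#' ground-truth reactants (for reactant-level evaluation), the template
#' library and summary statistics.
#'
#' @slot products character vector of canonical product SMILES.
#' @slot labels integer class labels, parallel to \code{products}.
#' @slot reactants list of character vectors of canonical reactant SMILES
#'   (may be empty when the dataset was read from a products-only file).
#' @slot library the \linkS4class{TemplateLibrary}.
#' @slot stats list with \code{classCounts} (named integer) and
#'   \code{lengthTable} (product SMILES length distribution).
#' @export
setClass("LabeledDataset",
         representation(products = "character", labels = "integer",
                        reactants = "list", library = "TemplateLibrary",
                        stats = "list"),
         validity = function(object) {
           n <- length(object@products)
           if (length(object@labels) != n)
             return("products and labels must have equal length")
           if (n == 0) return("dataset must contain at least one sample")
           Tn <- length(object@library@templates)
           if (any(object@labels < 1L) || any(object@labels > Tn))
             return("every label must exist in the template library")
           if (length(object@reactants) &&
               length(object@reactants) != n)
             return("reactants, when present, must parallel the samples")
           cc <- object@stats$classCounts
           if (!is.null(cc) && sum(cc) != n)
             return("class counts must sum to the number of samples")
           TRUE
         })

# ----------------------------------------------------------------- encoders

#' TokenVocabulary: character vocabulary of a SMILES corpus
#'
#' The distinct characters occurring in a set of SMILES strings, sorted in a
#' locale-independent order; column index of character \code{ch} in one-hot
#' matrices is \code{match(ch, tokens(vocab))}.
#'
#' @slot tokens character vector of distinct single characters.
#' @export
setClass("TokenVocabulary",
         representation(tokens = "character"),
         validity = function(object) {
           if (length(object@tokens) == 0) return("vocabulary must be non-empty")
           if (anyDuplicated(object@tokens)) return("tokens must be distinct")
           if (any(nchar(object@tokens) != 1))
             return("tokens must be single characters")
           TRUE
         })

#' OneHotMatrix: padded one-hot encoding of one SMILES string
#'
#' An L x |tokens| binary matrix: row i of the first \code{trueLength} rows
#' has a single 1 in the column of the i-th character; padding rows beyond
#' \code{trueLength} are all zero.
#'
#' @slot mat the binary matrix.
#' @slot trueLength number of non-padding rows.
#' @export
setClass("OneHotMatrix",
         representation(mat = "matrix", trueLength = "integer"),
         validity = function(object) {
           m <- object@mat
           tl <- object@trueLength
           if (tl < 0 || tl > nrow(m)) return("trueLength out of range")
           if (any(m != 0 & m != 1)) return("entries must be 0/1")
           if (tl > 0 && any(rowSums(m[seq_len(tl), , drop = FALSE]) != 1))
             return("each non-padding row must sum to exactly 1")
           if (tl < nrow(m) &&
               any(m[seq(tl + 1L, nrow(m)), , drop = FALSE] != 0))
             return("padding rows must be all zero")
           TRUE
         })

# ------------------------------------------------------------ multiscale net

#' FilterSchedule: arithmetic schedule of convolution filter sizes
#'
#' Filter sizes F_i = minSize + (i-1) * step, kept while F_i <= maxSize
#' (inclusive bound, the default) or F_i < maxSize (strict).
#'
#' @slot minSize,step,maxSize positive integers.
#' @slot inclusive logical; whether maxSize itself is admitted.
#' @slot sizes the enumerated, strictly increasing filter sizes.
#' @export
setClass("FilterSchedule",
         representation(minSize = "integer", step = "integer",
                        maxSize = "integer", inclusive = "logical",
                        sizes = "integer"),
         validity = function(object) {
           if (object@minSize < 1) return("minSize must be >= 1")
           if (object@step < 1) return("step must be >= 1")
           if (object@maxSize < object@minSize)
             return("maxSize must be >= minSize")
           if (length(object@sizes) < 1) return("schedule must be non-empty")
           if (any(diff(object@sizes) <= 0))
             return("sizes must be strictly increasing")
           expect <- object@minSize +
             (seq_along(object@sizes) - 1L) * object@step
           if (!identical(as.integer(expect), object@sizes))
             return("sizes must follow minSize + (i-1)*step")
           TRUE
         })

#' MultiScaleFeature: concatenated operation-group outputs
#'
#' @slot values numeric feature vector (all entries in [0,1] when the final
#'   nonlinearity is the sigmoid).
#' @slot groupOffsets 0-based start index of each group's segment within
#'   \code{values}.
#' @export
setClass("MultiScaleFeature",
         representation(values = "numeric", groupOffsets = "integer"),
         validity = function(object) {
           if (length(object@groupOffsets) == 0) return("no groups")
           if (object@groupOffsets[1] != 0L)
             return("first group offset must be 0")
           if (any(diff(object@groupOffsets) <= 0))
             return("group offsets must be increasing")
           if (max(object@groupOffsets) >= length(object@values))
             return("offsets exceed feature length")
           TRUE
         })

# -------------------------------------------------------------------- model

#' ModelConfig: run configuration of the two-branch classifier
#'
#' Defaults follow the reference training recipe: fingerprint branch schedule
#' 32/32/2048 on a 2048-bit ECFP, SMILES branch schedule 5/5/200 on length-300
#' one-hot input, Adam with learning rate 0.001, batch size 128, 20 epochs.
#'
#' @slot fpLength fingerprint length in bits.
#' @slot fpRadius circular fingerprint radius.
#' @slot fpSchedule,seqSchedule \linkS4class{FilterSchedule}s of the two
#'   branches.
#' @slot seqLength maximum SMILES length L for one-hot encoding.
#' @slot seqChannels one-hot channel count (vocabulary size); NA until a
#'   vocabulary is known.
#' @slot outChannels convolution output channels C per operation group.
#' @slot hiddenSizes integer vector of optional hidden layer sizes in the
#'   classifier head (empty = single fully connected layer).
#' @slot nClasses number of template classes M; NA until a library is known.
#' @slot pooling "global" or "window" max-pooling.
#' @slot poolWidth,poolStride window-pooling geometry (ignored for global).
#' @slot epochs,batchSize,learningRate,seed training hyperparameters.
#' @export
setClass("ModelConfig",
         representation(fpLength = "integer", fpRadius = "integer",
                        fpSchedule = "FilterSchedule",
                        seqSchedule = "FilterSchedule",
                        seqLength = "integer", seqChannels = "integer",
                        outChannels = "integer", hiddenSizes = "integer",
                        nClasses = "integer", pooling = "character",
                        poolWidth = "integer", poolStride = "integer",
                        epochs = "integer", batchSize = "integer",
                        learningRate = "numeric", seed = "integer"),
         validity = function(object) {
           if (object@fpLength < 1) return("fpLength must be positive")
           if (max(object@fpSchedule@sizes) > object@fpLength)
             return("fingerprint filter sizes exceed the fingerprint length")
           if (max(object@seqSchedule@sizes) > object@seqLength)
             return("SMILES filter sizes exceed the sequence length")
           if (object@outChannels < 1) return("outChannels must be >= 1")
           if (!object@pooling %in% c("global", "window"))
             return("pooling must be 'global' or 'window'")
           if (!is.na(object@nClasses) && object@nClasses < 2)
             return("nClasses must be >= 2")
           if (object@epochs < 1 || object@batchSize < 1)
             return("epochs and batchSize must be positive")
           if (object@learningRate <= 0) return("learningRate must be positive")
           TRUE
         })

#' MultiScaleClassifier: a trained template classifier
#'
#' Either the two-branch multi-scale CNN (\code{type = "cnn"}) or the
#' fingerprint-only three-layer MLP baseline (\code{type = "mlp"}).
#' Prediction is a pure function of the stored parameters, configuration and
#' vocabulary.
#'
#' @slot type "cnn" or "mlp".
#' @slot params opaque list of weight arrays.
#' @slot config the \linkS4class{ModelConfig} used for training.
#' @slot vocab the training \linkS4class{TokenVocabulary} (empty for "mlp").
#' @slot libraryChecksum md5 checksum of the template library the labels
#'   refer to.
#' @slot history per-epoch data.frame with training and validation loss.
#' @export
setClass("MultiScaleClassifier",
         representation(type = "character", params = "list",
                        config = "ModelConfig", vocab = "TokenVocabulary",
                        libraryChecksum = "character", history = "data.frame"),
         validity = function(object) {
           if (!object@type %in% c("cnn", "mlp"))
             return("type must be 'cnn' or 'mlp'")
           TRUE
         })

# -------------------------------------------------------------------- splits

#' SplitAssignment: train/validation/test partition of a dataset
#'
#' @slot trainIdx,valIdx,testIdx disjoint 1-based sample indices whose union
#'   covers the dataset exactly once.
#' @slot ratios target fractions (train, val, test), summing to 1.
#' @slot seed RNG seed used to draw the assignment.
#' @slot strategy "plain" or "aug".
#' @export
setClass("SplitAssignment",
         representation(trainIdx = "integer", valIdx = "integer",
                        testIdx = "integer", ratios = "numeric",
                        seed = "integer", strategy = "character"),
         validity = function(object) {
           all_ <- c(object@trainIdx, object@valIdx, object@testIdx)
           if (anyDuplicated(all_)) return("partitions must be disjoint")
           if (!setequal(all_, seq_along(all_)))
             return("partitions must cover 1..n exactly once")
           if (length(object@ratios) != 3 ||
               abs(sum(object@ratios) - 1) > 1e-8)
             return("ratios must be three fractions summing to 1")
           if (!object@strategy %in% c("plain", "aug"))
             return("strategy must be 'plain' or 'aug'")
           TRUE
         })

# ---------------------------------------------------------------- evaluation

#' PredictionRanking: class labels ranked by predicted probability
#'
#' One row per evaluated product; column j of \code{labels} holds the class
#' with the j-th highest softmax probability (ties broken by label order).
#'
#' @slot labels integer matrix of ranked class labels.
#' @slot probs numeric matrix of matching probabilities (non-increasing along
#'   each row).
#' @export
setClass("PredictionRanking",
         representation(labels = "matrix", probs = "matrix"),
         validity = function(object) {
           if (!all(dim(object@labels) == dim(object@probs)))
             return("labels and probs must have identical shape")
           if (any(object@probs < -1e-9)) return("probabilities must be >= 0")
           bad <- apply(object@probs, 1, function(p) any(diff(p) > 1e-9))
           if (any(bad)) return("probabilities must be non-increasing per row")
           TRUE
         })

#' TopKResult: top-k exact-match accuracies
#'
#' @slot k the evaluated k values.
#' @slot accuracy fraction of samples whose truth is in the top k, per k.
#' @slot nEvaluated number of evaluated samples.
#' @slot mode "label" (template-class match) or "reactant" (template applied
#'   to the product reproduces the ground-truth reactants).
#' @export
setClass("TopKResult",
         representation(k = "integer", accuracy = "numeric",
                        nEvaluated = "integer", mode = "character"),
         validity = function(object) {
           if (length(object@k) != length(object@accuracy))
             return("k and accuracy must be parallel")
           if (any(object@accuracy < 0 | object@accuracy > 1))
             return("accuracies must lie in [0,1]")
           if (is.unsorted(object@k)) return("k values must be increasing")
           if (any(diff(object@accuracy) < -1e-12))
             return("accuracy must be non-decreasing in k")
           TRUE
         })
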