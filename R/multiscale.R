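# The multi-scale feature extractor: K parallel operation groups
# (1-D convolution -> batch normalization -> sigmoid -> max-pooling) whose
# filter sizes follow an arithmetic schedule, concatenated into one feature
# vector.

#' Enumerate an arithmetic filter-size schedule
#'
#' Filter sizes are F_i = minSize + (i-1) * step. With the default inclusive
#' bound, sizes up to and including maxSize are kept — the convention that
#' makes the reference fingerprint schedule (32, 32, 2048) contain exactly 64
#' filters ending at 2048. \code{inclusive = FALSE} keeps strictly smaller
#' sizes only.
#'
#' @param minSize,step,maxSize positive integers, minSize <= maxSize.
#' @param inclusive admit maxSize itself (default TRUE).
#' @return a \linkS4class{FilterSchedule}.
#' @examples
#' length(makeFilterSchedule(32, 32, 2048))   # 64
#' filterSizes(makeFilterSchedule(5, 10, 37)) # 5 15 25 35
#' @export
makeFilterSchedule <- function(minSize, step, maxSize, inclusive = TRUE) {
  minSize <- as.integer(minSize); step <- as.integer(step)
  maxSize <- as.integer(maxSize)
  if (is.na(minSize) || minSize < 1) stop("minSize must be >= 1")
  if (is.na(step) || step < 1) stop("step must be >= 1")
  if (is.na(maxSize) || maxSize < minSize) stop("maxSize must be >= minSize")
  sizes <- seq.int(minSize, maxSize, by = step)
  if (!inclusive) sizes <- sizes[sizes < maxSize]
  if (length(sizes) == 0)
    stop("schedule is empty: no size ", minSize, " + i*", step,
         " lies strictly below ", maxSize)
  new("FilterSchedule", minSize = minSize, step = step, maxSize = maxSize,
      inclusive = inclusive, sizes = as.integer(sizes))
}

#' Random weights for one operation group
#'
#' Convenience initializer for inspecting the feature extractor outside a
#' trained model: weights are drawn N(0, 1/(F*d)).
#'
#' @param filterSize filter length F.
#' @param inChannels input channels d.
#' @param outChannels output channels C.
#' @return list with \code{W} (F x d x C array) and \code{b} (length C).
#' @export
randomGroupWeights <- function(filterSize, inChannels, outChannels) {
  sd <- sqrt(1 / (filterSize * inChannels))
  list(W = array(stats::rnorm(filterSize * inChannels * outChannels, sd = sd),
                 dim = c(filterSize, inChannels, outChannels)),
       b = numeric(outChannels))
}

# W as F x d x C array -> (F*d) x C matrix with row index (f-1)*d + k
.weight_matrix <- function(W) {
  stopifnot(length(dim(W)) == 3)
  matrix(aperm(W, c(2, 1, 3)), dim(W)[1] * dim(W)[2], dim(W)[3])
}

#' Apply one operation group to an input matrix
#'
#' One unit of the feature extractor: valid (no padding, stride 1) 1-D
#' cross-correlation with C filters of length F, normalization, element-wise
#' sigmoid into [0,1], then max-pooling. \code{normalization} is
#' \code{"identity"} (pass-through, the reference point for the sliding
#' window oracle), \code{"batch"} (statistics of the given input) or
#' \code{"running"} (frozen statistics from \code{normState}, as at
#' inference).
#'
#' @param x input matrix, l positions x d channels.
#' @param W filter weights, F x d x C array.
#' @param b per-channel bias, length C.
#' @param normalization one of "identity", "batch", "running".
#' @param normState for "running": list with \code{mean}, \code{var},
#'   \code{gamma}, \code{beta}, each length C.
#' @param pooling "global" (one max per channel) or "window".
#' @param poolWidth,poolStride window pooling geometry.
#' @return numeric vector of pooled features (length C under global pooling).
#' @examples
#' x <- matrix(rnorm(30), 10, 3)
#' w <- randomGroupWeights(3, 3, 2)
#' applyOperationGroup(x, w$W, w$b)
#' @export
applyOperationGroup <- function(x, W, b,
                                normalization = c("identity", "batch", "running"),
                                normState = NULL,
                                pooling = c("global", "window"),
                                poolWidth = 2L, poolStride = poolWidth) {
  normalization <- match.arg(normalization)
  pooling <- match.arg(pooling)
  stopifnot(is.matrix(x))
  dW <- dim(W)
  if (length(dW) != 3 || dW[2] != ncol(x))
    stop("weights must be an F x d x C array with d = ncol(x) = ", ncol(x))
  Fsize <- dW[1]; C <- dW[3]
  l <- nrow(x)
  if (l < Fsize)
    stop("operation group with filter size ", Fsize,
         " cannot be applied to input of length ", l)
  X <- array(x, dim = c(1L, l, ncol(x)))
  dims <- c(1L, l, ncol(x))
  Z <- .conv1d_forward_cpp(X, dims, .weight_matrix(W), b)
  out <- switch(normalization,
    identity = Z,
    batch = .bn_forward(Z, rep(1, C), numeric(C), numeric(C), rep(1, C),
                        mode = "train")$out,
    running = {
      if (is.null(normState))
        stop("normalization = 'running' needs normState")
      .bn_forward(Z, normState$gamma, normState$beta, normState$mean,
                  normState$var, mode = "eval")$out
    })
  A <- .sigmoid(out)
  P <- l - Fsize + 1L
  width <- if (pooling == "global") P else min(as.integer(poolWidth), P)
  stride <- if (pooling == "global") P else min(as.integer(poolStride), P)
  drop(.pool_max(A, 1L, P, width, stride)$out)
}

#' Extract the concatenated multi-scale feature vector
#'
#' Applies one operation group per schedule entry to the same input and
#' concatenates the pooled outputs in schedule order.
#'
#' @param x input matrix, l positions x d channels; l must be at least the
#'   largest filter size in the schedule.
#' @param schedule a \linkS4class{FilterSchedule}.
#' @param weights list with one \code{list(W, b)} per schedule entry (e.g.
#'   from \code{\link{randomGroupWeights}}).
#' @inheritParams applyOperationGroup
#' @return a \linkS4class{MultiScaleFeature}.
#' @export
extractMultiscaleFeatures <- function(x, schedule, weights,
                                      normalization = c("identity", "batch",
                                                        "running"),
                                      normState = NULL,
                                      pooling = c("global", "window"),
                                      poolWidth = 2L, poolStride = poolWidth) {
  stopifnot(is(schedule, "FilterSchedule"))
  sizes <- schedule@sizes
  if (length(weights) != length(sizes))
    stop("need one weight set per schedule entry (", length(sizes), ")")
  if (nrow(x) < max(sizes))
    stop("input length ", nrow(x), " is smaller than the largest filter ",
         max(sizes))
  segs <- vector("list", length(sizes))
  for (g in seq_along(sizes)) {
    segs[[g]] <- applyOperationGroup(
      x, weights[[g]]$W, weights[[g]]$b, normalization = normalization,
      normState = if (is.list(normState) && length(normState) == length(sizes))
        normState[[g]] else normState,
      pooling = pooling, poolWidth = poolWidth, poolStride = poolStride)
  }
  lens <- lengths(segs)
  new("MultiScaleFeature", values = unlist(segs, use.names = FALSE),
      groupOffsets = as.integer(cumsum(c(0L, lens[-length(lens)]))))
}
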