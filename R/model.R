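# The two-branch multi-scale classifier: assembly, training with Adam and
# cross-entropy, inference, parameter counting, persistence, and the
# fingerprint MLP baseline.

#' Construct a model configuration
#'
#' Defaults reproduce the reference recipe: fingerprint branch with schedule
#' 32/32/2048 over a 2048-bit radius-2 ECFP (input channel 1), SMILES branch
#' with schedule 5/5/200 over length-300 one-hot input, global max-pooling, a
#' single fully connected softmax head, Adam (learning rate 0.001), batch
#' size 128, 20 epochs. Scale the schedules, \code{outChannels}, and
#' \code{epochs} down for desk-size experiments.
#'
#' @param fpLength fingerprint length in bits (default 2048).
#' @param fpRadius fingerprint radius (default 2; ECFP4 convention).
#' @param fpSchedule fingerprint-branch \linkS4class{FilterSchedule}.
#' @param seqSchedule SMILES-branch \linkS4class{FilterSchedule}.
#' @param seqLength one-hot length L (default 300).
#' @param seqChannels vocabulary size; filled in at training time when NA.
#' @param outChannels convolution output channels per group (default 8).
#' @param hiddenSizes optional hidden layer sizes of the head (default none:
#'   one fully connected layer to the class logits).
#' @param nClasses number of classes; filled in at training time when NA.
#' @param pooling "global" (default) or "window".
#' @param poolWidth,poolStride window-pooling geometry.
#' @param epochs,batchSize,learningRate,seed training hyperparameters.
#' @return a \linkS4class{ModelConfig}.
#' @export
modelConfig <- function(fpLength = 2048L, fpRadius = 2L,
                        fpSchedule = makeFilterSchedule(32L, 32L, 2048L),
                        seqSchedule = makeFilterSchedule(5L, 5L, 200L),
                        seqLength = 300L, seqChannels = NA_integer_,
                        outChannels = 8L, hiddenSizes = integer(0),
                        nClasses = NA_integer_,
                        pooling = c("global", "window"),
                        poolWidth = 2L, poolStride = poolWidth,
                        epochs = 20L, batchSize = 128L,
                        learningRate = 0.001, seed = 1L) {
  new("ModelConfig", fpLength = as.integer(fpLength),
      fpRadius = as.integer(fpRadius), fpSchedule = fpSchedule,
      seqSchedule = seqSchedule, seqLength = as.integer(seqLength),
      seqChannels = as.integer(seqChannels),
      outChannels = as.integer(outChannels),
      hiddenSizes = as.integer(hiddenSizes), nClasses = as.integer(nClasses),
      pooling = match.arg(pooling), poolWidth = as.integer(poolWidth),
      poolStride = as.integer(poolStride), epochs = as.integer(epochs),
      batchSize = as.integer(batchSize),
      learningRate = as.numeric(learningRate), seed = as.integer(seed))
}

# pooled output width of one group on input length l
.group_out_width <- function(config, Fsize, l) {
  P <- l - Fsize + 1L
  if (config@pooling == "global") return(config@outChannels)
  width <- min(config@poolWidth, P)
  stride <- min(config@poolStride, P)
  config@outChannels * ((P - width) %/% stride + 1L)
}

.feature_dim <- function(config) {
  sum(vapply(config@fpSchedule@sizes, function(f)
    .group_out_width(config, f, config@fpLength), integer(1))) +
  sum(vapply(config@seqSchedule@sizes, function(f)
    .group_out_width(config, f, config@seqLength), integer(1)))
}

#' Count trainable parameters of the assembled model
#'
#' Convolution weights and biases, the per-channel scale and shift of each
#' batch normalization, and the classifier head. Running statistics are not
#' trainable and are excluded. The count decreases strictly as either
#' branch's \code{step} grows, since fewer operation groups remain.
#'
#' @param config a \linkS4class{ModelConfig} with \code{seqChannels} and
#'   \code{nClasses} set.
#' @return integer parameter count.
#' @export
countParameters <- function(config) {
  stopifnot(is(config, "ModelConfig"))
  if (is.na(config@seqChannels) || is.na(config@nClasses))
    stop("countParameters needs seqChannels and nClasses set in the config")
  C <- config@outChannels
  groups <- function(sizes, d) sum(sizes * d * C + C + 2L * C)
  conv <- groups(config@fpSchedule@sizes, 1L) +
          groups(config@seqSchedule@sizes, config@seqChannels)
  dims <- c(.feature_dim(config), config@hiddenSizes, config@nClasses)
  head <- sum(dims[-length(dims)] * dims[-1] + dims[-1])
  as.integer(conv + head)
}

#' Cross-entropy loss
#'
#' Mean negative log-probability of the true class:
#' loss = -(1/N) sum_i sum_c y_ic log(p_ic), with y the one-hot indicator of
#' the true label. Probabilities at the true class are clamped at 1e-12
#' before the log; clamping is reported with a message.
#'
#' @param probs N x M matrix of class probabilities (rows sum to 1).
#' @param truth integer vector of true labels in 1..M.
#' @return the scalar loss.
#' @examples
#' p <- rbind(c(0.7, 0.2, 0.1), c(0.1, 0.8, 0.1))
#' crossEntropyLoss(p, c(1, 2))   # -(log(0.7) + log(0.8)) / 2
#' @export
crossEntropyLoss <- function(probs, truth) {
  stopifnot(is.matrix(probs), nrow(probs) == length(truth))
  truth <- as.integer(truth)
  if (any(truth < 1L) || any(truth > ncol(probs)))
    stop("labels must lie in 1..", ncol(probs))
  rs <- rowSums(probs)
  if (any(abs(rs - 1) > 1e-6))
    stop("probability rows must sum to 1")
  p <- probs[cbind(seq_along(truth), truth)]
  if (any(p < 1e-12)) {
    message("crossEntropyLoss: clamped ", sum(p < 1e-12),
            " zero probability value(s) at the true class")
    p <- pmax(p, 1e-12)
  }
  -mean(log(p))
}

# --- model assembly ----------------------------------------------------------

.init_model <- function(config) {
  C <- config@outChannels
  fp <- lapply(config@fpSchedule@sizes, .init_group, d = 1L, C = C)
  sq <- lapply(config@seqSchedule@sizes, .init_group, d = config@seqChannels,
               C = C)
  dims <- c(.feature_dim(config), config@hiddenSizes, config@nClasses)
  head <- lapply(seq_len(length(dims) - 1L),
                 function(i) .init_fc(dims[i], dims[i + 1L]))
  list(fp = fp, seq = sq, head = head)
}

.pool_spec <- function(config)
  list(mode = config@pooling, width = config@poolWidth,
       stride = config@poolStride)

# Forward pass over one batch.  Xfp: n x fpLength x 1, Xseq: n x L x V.
# mode "train" uses batch statistics (and updates running ones in the
# returned params); "eval" uses running statistics.
.model_forward <- function(params, config, Xfp, Xseq, mode) {
  pool <- .pool_spec(config)
  n <- dim(Xfp)[1]
  branches <- list(
    list(key = "fp", X = Xfp, dims = as.integer(dim(Xfp)),
         sizes = config@fpSchedule@sizes),
    list(key = "seq", X = Xseq, dims = as.integer(dim(Xseq)),
         sizes = config@seqSchedule@sizes))
  feats <- list(); caches <- list(fp = list(), seq = list())
  for (br in branches) {
    for (g in seq_along(br$sizes)) {
      gf <- .group_forward(br$X, br$dims, params[[br$key]][[g]],
                           br$sizes[g], mode, pool)
      feats[[length(feats) + 1L]] <- gf$out
      caches[[br$key]][[g]] <- gf$cache
      if (mode == "train") {
        params[[br$key]][[g]]$rm <- gf$rm
        params[[br$key]][[g]]$rv <- gf$rv
      }
    }
  }
  feat <- do.call(cbind, feats)
  hcache <- list()
  a <- feat
  nl <- length(params$head)
  for (i in seq_len(nl)) {
    z <- sweep(a %*% params$head[[i]]$W, 2, params$head[[i]]$b, "+")
    hcache[[i]] <- list(input = a, z = z)
    a <- if (i < nl) .relu(z) else z
  }
  probs <- .softmax_rows(a)
  list(probs = probs, params = params,
       cache = list(branches = caches, head = hcache, feat = feat,
                    featWidths = vapply(feats, ncol, integer(1))))
}

.model_backward <- function(params, config, Xfp, Xseq, cache, probs, truth) {
  n <- nrow(probs)
  Y <- matrix(0, n, ncol(probs))
  Y[cbind(seq_len(n), truth)] <- 1
  dz <- (probs - Y) / n
  grads <- list(head = vector("list", length(params$head)))
  for (i in rev(seq_along(params$head))) {
    hc <- cache$head[[i]]
    grads$head[[i]] <- list(dW = crossprod(hc$input, dz), db = colSums(dz))
    if (i > 1L) {
      da <- dz %*% t(params$head[[i]]$W)
      dz <- da * (cache$head[[i - 1L]]$z > 0)     # ReLU'
    } else {
      dfeat <- dz %*% t(params$head[[i]]$W)
    }
  }
  widths <- cache$featWidths
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  kFp <- length(config@fpSchedule@sizes)
  grads$fp <- vector("list", kFp)
  grads$seq <- vector("list", length(config@seqSchedule@sizes))
  idx <- 0L
  for (g in seq_along(config@fpSchedule@sizes)) {
    idx <- idx + 1L
    dOut <- dfeat[, starts[idx]:ends[idx], drop = FALSE]
    grads$fp[[g]] <- .group_backward(dOut, cache$branches$fp[[g]], Xfp,
                                     as.integer(dim(Xfp)))
  }
  for (g in seq_along(config@seqSchedule@sizes)) {
    idx <- idx + 1L
    dOut <- dfeat[, starts[idx]:ends[idx], drop = FALSE]
    grads$seq[[g]] <- .group_backward(dOut, cache$branches$seq[[g]], Xseq,
                                      as.integer(dim(Xseq)))
  }
  grads
}

# Adam over the trainable leaves of the parameter tree
.trainable_keys <- list(group = c("W", "b", "gamma", "beta"),
                        head = c("W", "b"))

.adam_init_model <- function(params) {
  st <- list(fp = lapply(params$fp, function(g)
               lapply(g[.trainable_keys$group], .adam_new)),
             seq = lapply(params$seq, function(g)
               lapply(g[.trainable_keys$group], .adam_new)),
             head = lapply(params$head, function(h)
               lapply(h[.trainable_keys$head], .adam_new)))
  st
}

.adam_step_model <- function(params, grads, st, lr, t) {
  for (br in c("fp", "seq")) {
    for (g in seq_along(params[[br]])) {
      gg <- grads[[br]][[g]]
      glist <- list(W = gg$dW, b = gg$db, gamma = gg$dGamma, beta = gg$dBeta)
      for (k in .trainable_keys$group) {
        u <- .adam_upd(params[[br]][[g]][[k]], glist[[k]],
                       st[[br]][[g]][[k]], lr, t)
        params[[br]][[g]][[k]] <- u$param
        st[[br]][[g]][[k]] <- u$st
      }
    }
  }
  for (i in seq_along(params$head)) {
    glist <- list(W = grads$head[[i]]$dW, b = grads$head[[i]]$db)
    for (k in .trainable_keys$head) {
      u <- .adam_upd(params$head[[i]][[k]], glist[[k]], st$head[[i]][[k]],
                     lr, t)
      params$head[[i]][[k]] <- u$param
      st$head[[i]][[k]] <- u$st
    }
  }
  list(params = params, st = st)
}

# --- training ----------------------------------------------------------------

.check_lengths <- function(products, L) {
  over <- nchar(products) > L
  if (any(over))
    stop(sum(over), " product(s) exceed seqLength = ", L,
         "; apply filterByLength() first")
}

#' Train the two-branch multi-scale template classifier
#'
#' Builds the vocabulary from the training products, encodes fingerprints and
#' one-hot matrices, and minimizes the cross-entropy by mini-batch Adam for
#' the configured number of epochs. One integer seed (from the config)
#' controls weight initialization and shuffling, so a repeated run reproduces
#' the same model. Per-epoch training loss (and validation loss, when the
#' split has a validation part) is recorded in the training history.
#'
#' @param dataset a \linkS4class{LabeledDataset} whose products all fit the
#'   configured \code{seqLength}.
#' @param split optional \linkS4class{SplitAssignment}; its training part is
#'   used for fitting and its validation part for monitoring. Without a split
#'   the whole dataset is used for fitting.
#' @param config a \linkS4class{ModelConfig}.
#' @param verbose print per-epoch losses.
#' @return a \linkS4class{MultiScaleClassifier}.
#' @export
trainClassifier <- function(dataset, split = NULL, config = modelConfig(),
                            verbose = FALSE) {
  stopifnot(is(dataset, "LabeledDataset"), is(config, "ModelConfig"))
  trainIx <- if (is.null(split)) seq_along(dataset@products)
             else split@trainIdx
  valIx <- if (is.null(split)) integer(0) else split@valIdx
  if (length(trainIx) == 0) stop("training split is empty")

  prodsTr <- dataset@products[trainIx]
  labsTr <- dataset@labels[trainIx]
  .check_lengths(dataset@products, config@seqLength)

  vocab <- buildVocabulary(prodsTr)
  config@seqChannels <- length(vocab@tokens)
  config@nClasses <- length(dataset@library@templates)

  XfpTr <- .encode_fp_batch(prodsTr, config@fpLength, config@fpRadius)
  XsqTr <- .encode_onehot_batch(prodsTr, vocab, config@seqLength)
  if (length(valIx)) {
    XfpVa <- .encode_fp_batch(dataset@products[valIx], config@fpLength,
                              config@fpRadius)
    XsqVa <- .encode_onehot_batch(dataset@products[valIx], vocab,
                                  config@seqLength)
    labsVa <- dataset@labels[valIx]
  }

  set.seed(config@seed)
  params <- .init_model(config)
  st <- .adam_init_model(params)
  n <- length(trainIx)
  t <- 0L
  hist <- data.frame(epoch = integer(0), trainLoss = numeric(0),
                     valLoss = numeric(0))
  for (ep in seq_len(config@epochs)) {
    ord <- sample.int(n)
    lossSum <- 0
    for (b0 in seq(1L, n, by = config@batchSize)) {
      ix <- ord[b0:min(b0 + config@batchSize - 1L, n)]
      fw <- .model_forward(params, config,
                           XfpTr[ix, , , drop = FALSE],
                           XsqTr[ix, , , drop = FALSE], mode = "train")
      params <- fw$params
      p <- pmax(fw$probs[cbind(seq_along(ix), labsTr[ix])], 1e-12)
      lossSum <- lossSum - sum(log(p))
      grads <- .model_backward(params, config,
                               XfpTr[ix, , , drop = FALSE],
                               XsqTr[ix, , , drop = FALSE],
                               fw$cache, fw$probs, labsTr[ix])
      t <- t + 1L
      up <- .adam_step_model(params, grads, st, config@learningRate, t)
      params <- up$params
      st <- up$st
    }
    valLoss <- NA_real_
    if (length(valIx)) {
      pv <- .predict_probs(params, config, XfpVa, XsqVa)
      valLoss <- -mean(log(pmax(pv[cbind(seq_along(labsVa), labsVa)], 1e-12)))
    }
    hist <- rbind(hist, data.frame(epoch = ep, trainLoss = lossSum / n,
                                   valLoss = valLoss))
    if (verbose)
      message(sprintf("epoch %d: train loss %.4f%s", ep, lossSum / n,
                      if (is.na(valLoss)) ""
                      else sprintf(", val loss %.4f", valLoss)))
  }
  new("MultiScaleClassifier", type = "cnn", params = params, config = config,
      vocab = vocab, libraryChecksum = .library_checksum(dataset@library),
      history = hist)
}

.predict_probs <- function(params, config, Xfp, Xseq, chunk = 512L) {
  n <- dim(Xfp)[1]
  out <- NULL
  for (b0 in seq(1L, n, by = chunk)) {
    ix <- b0:min(b0 + chunk - 1L, n)
    fw <- .model_forward(params, config, Xfp[ix, , , drop = FALSE],
                         Xseq[ix, , , drop = FALSE], mode = "eval")
    out <- rbind(out, fw$probs)
  }
  out
}

# --- MLP baseline ------------------------------------------------------------

#' Train the fingerprint MLP baseline
#'
#' A three-layer perceptron — fingerprint input, one ReLU hidden layer,
#' softmax output — trained with the same loss and optimizer as the CNN.
#' Serves as the reference point the two-branch model is compared against.
#'
#' @inheritParams trainClassifier
#' @param hiddenSize width of the hidden layer (default 512).
#' @return a \linkS4class{MultiScaleClassifier} with \code{type = "mlp"}.
#' @export
trainMLPBaseline <- function(dataset, split = NULL, config = modelConfig(),
                             hiddenSize = 512L, verbose = FALSE) {
  stopifnot(is(dataset, "LabeledDataset"), is(config, "ModelConfig"))
  trainIx <- if (is.null(split)) seq_along(dataset@products)
             else split@trainIdx
  if (length(trainIx) == 0) stop("training split is empty")
  labsTr <- dataset@labels[trainIx]
  config@nClasses <- length(dataset@library@templates)
  config@hiddenSizes <- as.integer(hiddenSize)
  X <- .encode_fp_batch(dataset@products[trainIx], config@fpLength,
                        config@fpRadius)[, , 1]
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)

  set.seed(config@seed)
  params <- list(h1 = .init_fc(config@fpLength, hiddenSize),
                 h2 = .init_fc(hiddenSize, config@nClasses))
  st <- list(h1 = lapply(params$h1, .adam_new),
             h2 = lapply(params$h2, .adam_new))
  n <- length(trainIx); t <- 0L
  hist <- data.frame(epoch = integer(0), trainLoss = numeric(0),
                     valLoss = numeric(0))
  for (ep in seq_len(config@epochs)) {
    ord <- sample.int(n)
    lossSum <- 0
    for (b0 in seq(1L, n, by = config@batchSize)) {
      ix <- ord[b0:min(b0 + config@batchSize - 1L, n)]
      x <- X[ix, , drop = FALSE]
      z1 <- sweep(x %*% params$h1$W, 2, params$h1$b, "+")
      a1 <- .relu(z1)
      z2 <- sweep(a1 %*% params$h2$W, 2, params$h2$b, "+")
      probs <- .softmax_rows(z2)
      y <- labsTr[ix]
      p <- pmax(probs[cbind(seq_along(ix), y)], 1e-12)
      lossSum <- lossSum - sum(log(p))
      Y <- matrix(0, length(ix), config@nClasses)
      Y[cbind(seq_along(ix), y)] <- 1
      dz2 <- (probs - Y) / length(ix)
      g2 <- list(W = crossprod(a1, dz2), b = colSums(dz2))
      dz1 <- (dz2 %*% t(params$h2$W)) * (z1 > 0)
      g1 <- list(W = crossprod(x, dz1), b = colSums(dz1))
      t <- t + 1L
      for (nm in c("W", "b")) {
        u <- .adam_upd(params$h1[[nm]], g1[[nm]], st$h1[[nm]],
                       config@learningRate, t)
        params$h1[[nm]] <- u$param; st$h1[[nm]] <- u$st
        u <- .adam_upd(params$h2[[nm]], g2[[nm]], st$h2[[nm]],
                       config@learningRate, t)
        params$h2[[nm]] <- u$param; st$h2[[nm]] <- u$st
      }
    }
    hist <- rbind(hist, data.frame(epoch = ep, trainLoss = lossSum / n,
                                   valLoss = NA_real_))
    if (verbose) message(sprintf("epoch %d: train loss %.4f", ep, lossSum / n))
  }
  new("MultiScaleClassifier", type = "mlp", params = params, config = config,
      vocab = new("TokenVocabulary", tokens = "C"),
      libraryChecksum = .library_checksum(dataset@library), history = hist)
}

# --- inference ---------------------------------------------------------------

#' Rank template classes for products
#'
#' Encodes the products with the model's configuration and vocabulary, runs
#' the forward pass with frozen normalization statistics, and returns class
#' labels ordered by decreasing softmax probability. Inference is
#' deterministic: identical inputs give identical rankings.
#'
#' @param model a trained \linkS4class{MultiScaleClassifier}.
#' @param newProducts character vector of product SMILES.
#' @param topN keep only the first topN ranked classes (default: all).
#' @return a \linkS4class{PredictionRanking}.
#' @export
predictRanking <- function(model, newProducts, topN = NULL) {
  stopifnot(is(model, "MultiScaleClassifier"), is.character(newProducts),
            length(newProducts) >= 1)
  config <- model@config
  if (model@type == "cnn") {
    .check_lengths(newProducts, config@seqLength)
    Xfp <- .encode_fp_batch(newProducts, config@fpLength, config@fpRadius)
    Xsq <- .encode_onehot_batch(newProducts, model@vocab, config@seqLength)
    probs <- .predict_probs(model@params, config, Xfp, Xsq)
  } else {
    X <- .encode_fp_batch(newProducts, config@fpLength,
                          config@fpRadius)[, , 1]
    if (is.null(dim(X))) X <- matrix(X, nrow = 1)
    a1 <- .relu(sweep(X %*% model@params$h1$W, 2, model@params$h1$b, "+"))
    probs <- .softmax_rows(sweep(a1 %*% model@params$h2$W, 2,
                                 model@params$h2$b, "+"))
  }
  .ranking_from_probs(probs, topN)
}

.ranking_from_probs <- function(probs, topN = NULL) {
  M <- ncol(probs)
  k <- if (is.null(topN)) M else min(as.integer(topN), M)
  labs <- t(apply(probs, 1, function(p) order(p, decreasing = TRUE)))[,
            seq_len(k), drop = FALSE]
  ps <- t(vapply(seq_len(nrow(probs)),
                 function(i) probs[i, labs[i, ]], numeric(k)))
  if (k == 1) { labs <- matrix(labs, ncol = 1); ps <- matrix(ps, ncol = 1) }
  new("PredictionRanking", labels = matrix(as.integer(labs), nrow(probs), k),
      probs = matrix(ps, nrow(probs), k))
}

# --- persistence -------------------------------------------------------------

#' Save / load a trained classifier
#'
#' The checkpoint is an opaque serialized object; a JSON sidecar
#' (\code{<path>.json}) records the configuration, vocabulary, library
#' checksum and training history for provenance. Reloading reproduces
#' bit-identical predictions.
#'
#' @param model a \linkS4class{MultiScaleClassifier}.
#' @param path checkpoint path.
#' @name classifier-io
NULL

#' @rdname classifier-io
#' @export
saveClassifier <- function(model, path) {
  stopifnot(is(model, "MultiScaleClassifier"))
  saveRDS(model, path)
  cfg <- model@config
  sidecar <- list(
    type = model@type,
    fpLength = cfg@fpLength, fpRadius = cfg@fpRadius,
    fpSchedule = list(min = cfg@fpSchedule@minSize, step = cfg@fpSchedule@step,
                      max = cfg@fpSchedule@maxSize),
    seqSchedule = list(min = cfg@seqSchedule@minSize,
                       step = cfg@seqSchedule@step,
                       max = cfg@seqSchedule@maxSize),
    seqLength = cfg@seqLength, seqChannels = cfg@seqChannels,
    outChannels = cfg@outChannels, nClasses = cfg@nClasses,
    epochs = cfg@epochs, batchSize = cfg@batchSize,
    learningRate = cfg@learningRate, seed = cfg@seed,
    vocabulary = model@vocab@tokens,
    libraryChecksum = model@libraryChecksum,
    history = model@history)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname classifier-io
#' @export
loadClassifier <- function(path) {
  model <- readRDS(path)
  if (!is(model, "MultiScaleClassifier"))
    stop("not a classifier checkpoint: ", path)
  model
}
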