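# Loss closed forms, parameter counting, training behaviour, inference
# determinism and persistence.

test_that("cross-entropy matches its closed forms", {
  M <- 7
  perfect <- diag(M)[rep(1:M, 2), ]
  expect_equal(crossEntropyLoss(perfect, rep(1:M, 2)), 0)

  unif <- matrix(1 / M, 10, M)
  expect_equal(crossEntropyLoss(unif, sample(M, 10, replace = TRUE)), log(M))

  p <- rbind(c(0.7, 0.2, 0.1), c(0.1, 0.8, 0.1))
  expect_equal(crossEntropyLoss(p, c(1, 2)), -(log(0.7) + log(0.8)) / 2,
               tolerance = 1e-12)
  expect_equal(crossEntropyLoss(p, c(1, 2)), 0.28990, tolerance = 1e-4)

  expect_error(crossEntropyLoss(matrix(c(.5, .2), 1), 1L), "sum to 1")
  expect_error(crossEntropyLoss(unif, c(rep(1, 9), 9L)), "labels")
  z <- matrix(c(1, 0, 0, 1), 2, byrow = TRUE)
  expect_message(crossEntropyLoss(z, c(2, 1)), "clamped")
})

test_that("parameter count has a closed form and shrinks with step", {
  # single-group toy: F=3, d=2 (seq side suppressed by matching fp), C=1,
  # M=2, no hidden layer, global pooling; hand count:
  #  fp group (F=3,d=1):   3*1*1 + 1 + 2 = 6
  #  seq group (F=3,d=2):  3*2*1 + 1 + 2 = 9
  #  head: feat=2 -> M=2:  2*2 + 2     = 6
  cfg <- modelConfig(fpLength = 8L, fpSchedule = makeFilterSchedule(3, 5, 3),
                     seqSchedule = makeFilterSchedule(3, 5, 3),
                     seqLength = 8L, seqChannels = 2L, outChannels = 1L,
                     nClasses = 2L)
  expect_equal(countParameters(cfg), 6L + 9L + 6L)

  base <- modelConfig(seqChannels = 40L, nClasses = 100L)
  fpStep2 <- modelConfig(fpSchedule = makeFilterSchedule(32, 64, 2048),
                         seqChannels = 40L, nClasses = 100L)
  seqStep2 <- modelConfig(seqSchedule = makeFilterSchedule(5, 10, 200),
                          seqChannels = 40L, nClasses = 100L)
  expect_lt(countParameters(fpStep2), countParameters(base))
  expect_lt(countParameters(seqStep2), countParameters(base))

  # two configs differing only in M differ by the head delta
  c1 <- modelConfig(seqChannels = 40L, nClasses = 100L)
  c2 <- modelConfig(seqChannels = 40L, nClasses = 150L)
  D <- msRetro:::.feature_dim(c1)
  expect_equal(countParameters(c2) - countParameters(c1), 50L * (D + 1L))

  expect_error(countParameters(modelConfig()), "seqChannels")
})

test_that("training reduces the loss and is seed-reproducible", {
  fx <- tiny_model()
  h <- trainingHistory(fx$model)
  expect_lt(h$trainLoss[nrow(h)], h$trainLoss[1])

  again <- trainClassifier(fx$ds, fx$sp, fx$cfg)
  expect_identical(trainingHistory(again)$trainLoss,
                   trainingHistory(fx$model)$trainLoss)
})

test_that("predictions are proper softmax rankings and deterministic", {
  fx <- tiny_model()
  te <- testIdx(fx$sp)
  r <- predictRanking(fx$model, products(fx$ds)[te])
  pr <- rankedProbs(r)
  expect_true(all(abs(rowSums(pr) - 1) < 1e-6))
  expect_true(all(pr >= 0))
  labs <- rankedLabels(r)
  expect_true(all(apply(labs, 1, function(x) setequal(x, 1:6))))

  r2 <- predictRanking(fx$model, products(fx$ds)[te])
  expect_identical(rankedLabels(r2), labs)
  expect_identical(rankedProbs(r2), pr)

  top2 <- predictRanking(fx$model, products(fx$ds)[te][1], topN = 2)
  expect_equal(dim(rankedLabels(top2)), c(1L, 2L))
})

test_that("checkpoints reload to bit-identical predictions", {
  fx <- tiny_model()
  probe <- products(fx$ds)[testIdx(fx$sp)][1:5]
  f <- tempfile(fileext = ".rds")
  saveClassifier(fx$model, f)
  expect_true(file.exists(paste0(f, ".json")))
  m2 <- loadClassifier(f)
  expect_identical(rankedProbs(predictRanking(m2, probe)),
                   rankedProbs(predictRanking(fx$model, probe)))
})

test_that("a consistent label permutation permutes learned predictions", {
  fx <- tiny_model()
  ds <- fx$ds
  perm <- c(3L, 1L, 2L, 6L, 4L, 5L)
  lib2 <- buildTemplateLibrary(templates(templateLibrary(ds))[order(perm)])
  dsPerm <- msRetro:::.make_dataset(products(ds), perm[classLabels(ds)],
                                    groundTruthReactants(ds), lib2)
  mPerm <- trainClassifier(dsPerm, fx$sp, fx$cfg)
  te <- testIdx(fx$sp)
  truth <- classLabels(ds)[te]
  top1 <- rankedLabels(predictRanking(fx$model, products(ds)[te]))[, 1]
  top1Perm <- rankedLabels(predictRanking(mPerm, products(ds)[te]))[, 1]
  accBase <- mean(top1 == truth)
  accPerm <- mean(top1Perm == perm[truth])
  # label names carry no information: the relabeled task is learned equally
  # well, and wherever both models are right the predictions correspond
  # through the permutation
  expect_gt(accBase, 2 / 6)
  expect_gte(accPerm, accBase - 0.15)
  agree <- mean(perm[top1] == top1Perm)
  expect_gte(agree, accBase + accPerm - 1 - 1e-9)
})

test_that("the MLP baseline trains, beats chance and is reproducible", {
  fx <- tiny_model()
  mlp <- trainMLPBaseline(fx$ds, fx$sp, fx$cfg, hiddenSize = 64L)
  te <- testIdx(fx$sp)
  r <- topkAccuracy(predictRanking(mlp, products(fx$ds)[te]),
                    classLabels(fx$ds)[te], ks = 1)
  expect_gt(accuracies(r)[1], 1 / 6)
  mlp2 <- trainMLPBaseline(fx$ds, fx$sp, fx$cfg, hiddenSize = 64L)
  expect_identical(trainingHistory(mlp2)$trainLoss,
                   trainingHistory(mlp)$trainLoss)
})

test_that("training rejects empty splits and over-length products", {
  fx <- tiny_model()
  emptySplit <- new("SplitAssignment",
                    trainIdx = integer(0),
                    valIdx = seq_along(products(fx$ds)), testIdx = integer(0),
                    ratios = c(0, 1, 0), seed = 1L, strategy = "plain")
  expect_error(trainClassifier(fx$ds, emptySplit, fx$cfg), "empty")
  shortCfg <- modelConfig(fpLength = 256L,
                          fpSchedule = makeFilterSchedule(16, 16, 64),
                          seqSchedule = makeFilterSchedule(2, 2, 4),
                          seqLength = 5L, outChannels = 2L, epochs = 1L)
  expect_error(trainClassifier(fx$ds, fx$sp, shortCfg), "filterByLength")
})
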