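# Filter schedules and the operation-group feature extractor.

test_that("filter schedules enumerate min + (i-1)*step up to the bound", {
  s <- makeFilterSchedule(32, 32, 2048)
  expect_length(filterSizes(s), 64L)
  expect_equal(max(filterSizes(s)), 2048L)

  expect_equal(filterSizes(makeFilterSchedule(5, 5, 5)), 5L)
  expect_equal(filterSizes(makeFilterSchedule(5, 10, 37)), c(5L, 15L, 25L, 35L))

  # strict bound drops the endpoint
  expect_length(filterSizes(makeFilterSchedule(32, 32, 2048,
                                               inclusive = FALSE)), 63L)

  expect_error(makeFilterSchedule(0, 5, 10), "minSize")
  expect_error(makeFilterSchedule(5, 0, 10), "step")
  expect_error(makeFilterSchedule(10, 5, 5), "maxSize")
})

test_that("schedule length never grows when step grows", {
  for (minS in c(1, 5, 32)) {
    ks <- vapply(1:20, function(st)
      length(makeFilterSchedule(minS, st, 200)), integer(1))
    expect_true(all(diff(ks) <= 0))
  }
})

test_that("operation group matches the sliding-window oracle", {
  set.seed(77)
  for (trial in 1:8) {
    l <- sample(6:16, 1); d <- sample(1:8, 1)
    Fs <- sample(2:min(5, l), 1); C <- sample(1:3, 1)
    x <- matrix(rnorm(l * d), l, d)
    w <- randomGroupWeights(Fs, d, C)
    got <- applyOperationGroup(x, w$W, w$b, normalization = "identity")
    P <- l - Fs + 1
    oracle <- vapply(seq_len(C), function(c) {
      conv <- vapply(seq_len(P), function(p)
        sum(x[p:(p + Fs - 1), , drop = FALSE] * w$W[, , c]) + w$b[c],
        numeric(1))
      max(1 / (1 + exp(-conv)))
    }, numeric(1))
    expect_lt(max(abs(got - oracle)), 1e-6)
  }
})

test_that("activations stay in [0,1] and shape errors are caught", {
  set.seed(3)
  x <- matrix(rnorm(120, sd = 10), 30, 4)
  w <- randomGroupWeights(5, 4, 6)
  for (norm in c("identity", "batch")) {
    out <- applyOperationGroup(x, w$W, w$b, normalization = norm)
    expect_true(all(out >= 0 & out <= 1))
  }
  st <- list(mean = rnorm(6), var = runif(6) + .1, gamma = rep(1, 6),
             beta = rep(0, 6))
  out <- applyOperationGroup(x, w$W, w$b, normalization = "running",
                             normState = st)
  expect_true(all(out >= 0 & out <= 1))

  expect_error(applyOperationGroup(matrix(0, 3, 4), w$W, w$b), "filter size")
  expect_error(applyOperationGroup(matrix(0, 30, 2), w$W, w$b), "d = ncol")
})

test_that("multi-scale features concatenate in schedule order", {
  set.seed(11)
  x <- matrix(rnorm(40), 10, 4)
  sched <- makeFilterSchedule(3, 2, 5)       # sizes 3, 5
  ws <- list(randomGroupWeights(3, 4, 2), randomGroupWeights(5, 4, 2))
  ms <- extractMultiscaleFeatures(x, sched, ws)
  expect_length(featureValues(ms), 4L)       # K * C
  expect_equal(groupOffsets(ms), c(0L, 2L))

  # boundary: single window when F = l
  schedL <- makeFilterSchedule(10, 1, 10)
  wl <- list(randomGroupWeights(10, 4, 3))
  msl <- extractMultiscaleFeatures(x, schedL, wl)
  expect_length(featureValues(msl), 3L)

  # reversing the group order permutes the segments exactly
  seg1 <- featureValues(ms)[1:2]
  seg2 <- featureValues(ms)[3:4]
  msRev <- extractMultiscaleFeatures(x, makeFilterSchedule(5, 2, 5),
                                     ws[2])
  expect_equal(featureValues(msRev), seg2)

  expect_error(extractMultiscaleFeatures(matrix(0, 4, 4), sched, ws),
               "smaller than the largest")
  expect_error(extractMultiscaleFeatures(x, sched, ws[1]), "one weight set")
})

test_that("feature length formula holds across pooling modes", {
  set.seed(19)
  x <- matrix(rnorm(72), 18, 4)
  sched <- makeFilterSchedule(3, 4, 11)      # sizes 3, 7, 11
  ws <- lapply(filterSizes(sched), randomGroupWeights, inChannels = 4,
               outChannels = 2)
  for (pool in list(list(mode = "global", w = 1, s = 1),
                    list(mode = "window", w = 4, s = 4),
                    list(mode = "window", w = 3, s = 2))) {
    ms <- extractMultiscaleFeatures(x, sched, ws, pooling = pool$mode,
                                    poolWidth = pool$w, poolStride = pool$s)
    expLen <- sum(vapply(filterSizes(sched), function(f) {
      P <- 18 - f + 1
      if (pool$mode == "global") 2L
      else 2L * as.integer((P - min(pool$w, P)) %/% min(pool$s, P) + 1L)
    }, integer(1)))
    expect_length(featureValues(ms), expLen)
  }
})
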