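# Plain and label-coverage (Aug) splits.

test_that("plain split sizes follow the floor rounding rule", {
  s <- plainSplit(100L, seed = 4)
  expect_length(trainIdx(s), 80L)
  expect_length(valIdx(s), 10L)
  expect_length(testIdx(s), 10L)

  s10 <- plainSplit(10L, seed = 4)
  expect_equal(lengths(list(trainIdx(s10), valIdx(s10), testIdx(s10))),
               c(8L, 1L, 1L))

  expect_identical(plainSplit(57L, seed = 9), plainSplit(57L, seed = 9))
  expect_error(plainSplit(20L, ratios = c(0.5, 0.2, 0.2)), "ratios")
  expect_error(plainSplit(0L), "empty")
})

test_that("both strategies produce disjoint covering partitions", {
  set.seed(1)
  for (trial in 1:5) {
    n <- sample(20:200, 1)
    labels <- sample(5, n, replace = TRUE)
    for (s in list(plainSplit(n, seed = trial),
                   augSplit(labels, seed = trial))) {
      all_ <- c(trainIdx(s), valIdx(s), testIdx(s))
      expect_equal(sort(all_), seq_len(n))
    }
  }
})

test_that("aug split always covers every label in train", {
  lt <- longtail_dataset()
  labels <- lt$class_label
  expect_true(any(table(labels) == 1))        # singleton classes present
  for (seed in 1:5) {
    s <- augSplit(labels, seed = seed)
    expect_setequal(unique(labels[trainIdx(s)]), unique(labels))
  }
  # singletons always land in train
  single <- as.integer(names(which(table(labels) == 1)))
  s <- augSplit(labels, seed = 1)
  expect_true(all(which(labels %in% single) %in% trainIdx(s)))
})

test_that("aug split keeps ratios close and degenerates gracefully", {
  labels <- rep(1:50, each = 10)
  s <- augSplit(labels, seed = 21)
  expect_setequal(unique(labels[trainIdx(s)]), 1:50)
  frac <- length(trainIdx(s)) / length(labels)
  expect_lt(abs(frac - 0.8), 0.02)

  expect_warning(sAll <- augSplit(1:40, seed = 2), "empty")
  expect_length(trainIdx(sAll), 40L)
  expect_length(valIdx(sAll), 0L)
})

test_that("plain split misses rare labels where aug does not", {
  lt <- longtail_dataset()
  labels <- lt$class_label
  sPlain <- plainSplit(length(labels), seed = 5)
  missed <- setdiff(unique(labels), unique(labels[trainIdx(sPlain)]))
  expect_gt(length(missed), 0)
  sAug <- augSplit(labels, seed = 5)
  expect_length(setdiff(unique(labels), unique(labels[trainIdx(sAug)])), 0)
})

test_that("split files round-trip with their metadata", {
  labels <- rep(1:10, each = 6)
  s <- augSplit(labels, seed = 13)
  f <- tempfile(fileext = ".tsv")
  writeSplit(s, f)
  s2 <- readSplit(f)
  expect_identical(trainIdx(s2), trainIdx(s))
  expect_identical(valIdx(s2), valIdx(s))
  expect_identical(testIdx(s2), testIdx(s))
  expect_identical(s2@seed, s@seed)
  expect_identical(s2@strategy, "aug")
})
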