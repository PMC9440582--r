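# The synthetic reaction generator: determinism, validity, statistics and
# end-to-end class recovery.

test_that("generation is a deterministic function of the spec", {
  a <- generateSyntheticReactions(nClasses = 5, samplesPerClass = 4, seed = 7)
  b <- generateSyntheticReactions(nClasses = 5, samplesPerClass = 4, seed = 7)
  expect_identical(a, b)
  c <- generateSyntheticReactions(nClasses = 5, samplesPerClass = 4, seed = 8)
  expect_false(identical(a, c))

  f1 <- tempfile(); f2 <- tempfile()
  writeReactions(a, f1); writeReactions(b, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("corpus statistics match the spec exactly", {
  rx <- generateSyntheticReactions(nClasses = 8, samplesPerClass = 6,
                                   seed = 10)
  expect_equal(nrow(rx), 48L)
  expect_equal(as.integer(table(rx$class_label)), rep(6L, 8))

  lt <- generateSyntheticReactions(nClasses = 40, samplesPerClass = 3,
                                   seed = 10, distribution = "longtail")
  expect_equal(length(unique(lt$class_label)), 40L)
  expect_true(any(table(lt$class_label) == 1))   # singleton classes occur

  expect_error(generateSyntheticReactions(nClasses = 1), "between")
  expect_error(generateSyntheticReactions(nClasses = 99), "between")
})

test_that("every emitted product parses and is a single molecule", {
  rx <- generateSyntheticReactions(nClasses = 10, samplesPerClass = 3,
                                   seed = 12)
  prods <- vapply(strsplit(rx$reaction_smiles, ">>", fixed = TRUE), `[`,
                  character(1), 2)
  expect_false(any(grepl(".", prods, fixed = TRUE)))
  canon <- canonicalSmiles(prods)         # errors on unparseable input
  expect_true(all(nzchar(canon)))
})

test_that("preprocessing the corpus recovers the rule classes exactly", {
  fx <- small_corpus()
  expect_equal(length(fx$library), 6L)
  tab <- table(fx$rx$class_label, classLabels(fx$dataset))
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
})

test_that("the separable set is separable for a 1-NN fingerprint oracle", {
  ds <- generateSeparableSet(nClasses = 6, samplesPerClass = 8, seed = 5)
  expect_equal(length(ds), 48L)
  expect_equal(unname(datasetStats(ds)$classCounts), rep(8L, 6))

  fp <- computeECFP(products(ds), length = 1024L)
  lab <- classLabels(ds)
  d2 <- as.matrix(stats::dist(fp, method = "manhattan"))
  diag(d2) <- Inf
  pred <- lab[apply(d2, 1, which.min)]     # leave-one-out 1-NN
  expect_gte(mean(pred == lab), 0.95)
})
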