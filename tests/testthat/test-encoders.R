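# Fingerprint and one-hot encoders.

test_that("vocabulary is deduplicated, sorted and order-invariant", {
  v <- buildVocabulary(c("CCO", "CO"))
  expect_equal(tokens(v), c("C", "O"))
  expect_equal(length(v), 2L)

  strs <- c("CC(=O)OCC", "c1ccccc1", "ClCCBr", "N#CC")
  v1 <- buildVocabulary(strs)
  v2 <- buildVocabulary(rev(strs))
  expect_identical(tokens(v1), tokens(v2))
  expect_false(anyDuplicated(tokens(v1)) > 0)

  expect_error(buildVocabulary(character(0)), "non-empty")
})

test_that("one-hot matrices honour the shape and row-sum contract", {
  v <- buildVocabulary(c("CO"))
  oh <- oneHotEncode("CO", v, 4L)
  m <- encodingMatrix(oh)
  expect_equal(dim(m), c(4L, 2L))
  expect_equal(m[1, ], c(C = 1L, O = 0L))
  expect_equal(m[2, ], c(C = 0L, O = 1L))
  expect_true(all(m[3:4, ] == 0))
  expect_equal(trueLength(oh), 2L)

  empty <- oneHotEncode("", v, 4L)
  expect_equal(sum(encodingMatrix(empty)), 0)
  expect_equal(trueLength(empty), 0L)

  expect_error(oneHotEncode("CCCCC", v, 4L), "exceeds")
  expect_error(oneHotEncode("CX", v, 4L), "not in the vocabulary")
})

test_that("encode/decode round trip is exact on random corpus strings", {
  fx <- small_corpus()
  prods <- products(fx$dataset)
  v <- buildVocabulary(prods)
  L <- max(nchar(prods)) + 5L
  for (s in prods[seq_len(min(15, length(prods)))]) {
    oh <- oneHotEncode(s, v, L)
    expect_equal(sum(encodingMatrix(oh)), nchar(s))   # row-sum property
    expect_identical(decodeOneHot(oh, v), s)
  }
})

test_that("fingerprints are deterministic, canonical-invariant and sized", {
  f1 <- computeECFP("CCO")
  expect_length(f1, 2048L)
  expect_true(all(f1 %in% 0:1))
  expect_identical(f1, computeECFP("CCO"))        # determinism
  expect_identical(f1, computeECFP("OCC"))        # same molecule
  expect_length(computeECFP("CCO", length = 512L), 512L)
  expect_gt(sum(computeECFP("CC(=O)OCC")), 0)
  expect_error(computeECFP("CCO", length = 3000L), "divide")
  expect_error(computeECFP("notasmiles[["), "parsed")
  m <- computeECFP(c("CCO", "CCN"), length = 512L)
  expect_equal(dim(m), c(2L, 512L))
})

test_that("filterByLength drops over-length products only", {
  fx <- small_corpus()
  ds <- fx$dataset
  lens <- nchar(products(ds))
  cut <- sort(lens)[floor(length(lens) * 0.7)]
  expect_message(kept <- filterByLength(ds, cut), "dropping")
  expect_equal(length(kept), sum(lens <= cut))
  expect_true(all(nchar(products(kept)) <= cut))
  # identity when L exceeds everything
  expect_identical(products(filterByLength(ds, max(lens))), products(ds))
  expect_error(filterByLength(ds, 0L), "L must be")
})

test_that("vocabulary JSON sidecar round-trips", {
  v <- buildVocabulary(c("CC(=O)OCC", "ClC"))
  f <- tempfile(fileext = ".json")
  writeVocabulary(v, f)
  expect_identical(tokens(readVocabulary(f)), tokens(v))
})
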