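# Internal atom-mapped SMILES graph parser and writer (the substrate of
# template extraction).

parse <- function(s) msRetro:::.parse_smiles(s)
write_smi <- function(m, ...) msRetro:::.write_smiles(m, ...)

test_that("parser assigns implicit hydrogens by standard valences", {
  m <- parse("CC(=O)OCC")
  expect_equal(m$elem, c("C", "C", "O", "O", "C", "C"))
  expect_equal(m$nH, c(3L, 0L, 0L, 0L, 2L, 3L))

  m2 <- parse("N#CCBr")
  expect_equal(m2$nH, c(0L, 0L, 2L, 0L))
  expect_equal(m2$order[1], 3L)

  m3 <- parse("[NH4+]")
  expect_equal(m3$charge, 1L)
  expect_equal(m3$nH, 4L)
})

test_that("atom maps survive a parse/write round trip", {
  s <- "[CH3:1][CH2:2][OH:3]"
  expect_identical(write_smi(parse(s)), s)
  stripped <- write_smi(parse(s), withMaps = FALSE)
  expect_false(grepl(":", stripped, fixed = TRUE))
  expect_equal(canonicalSmiles(stripped), canonicalSmiles("CCO"))
})

test_that("writer output canonicalizes to the same molecule", {
  for (s in c("CC(C)C(=O)OCC", "ClCC(Br)CC#N", "C1CCCCC1", "CC1CC1CO",
              "O.CCO", "CS(=O)C")) {
    expect_equal(canonicalSmiles(write_smi(parse(s))), canonicalSmiles(s),
                 info = s)
  }
})

test_that("malformed SMILES are rejected with clear errors", {
  expect_error(parse("C(C"), "unbalanced")
  expect_error(parse("C1CC"), "unclosed ring")
  expect_error(parse("[C@H](N)C"), "stereo")
  expect_error(parse("C%1"), "%nn")
  expect_error(parse("Cx"), "not supported")
  expect_error(parse(""), "non-empty")
})
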