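# Reaction parsing, multi-product splitting, template extraction and
# dataset/library assembly.

test_that("parseReaction splits dialects correctly and preserves maps", {
  r <- parseReaction("CC(=O)O.OCC>>CC(=O)OCC", "r1")
  expect_equal(r@reactantSmiles, c("CC(=O)O", "OCC"))
  expect_equal(r@agentSmiles, character(0))
  expect_equal(r@productSmiles, "CC(=O)OCC")

  r2 <- parseReaction("[CH3:1][OH:2]>>[CH3:1][O:2]C")
  expect_equal(r2@reactantSmiles, "[CH3:1][OH:2]")
  expect_equal(r2@productSmiles, "[CH3:1][O:2]C")

  r3 <- parseReaction("CC(=O)O.OCC>O>CC(=O)OCC", "agents")
  expect_equal(r3@agentSmiles, "O")

  expect_error(parseReaction("CC>CC"), "field")
  expect_error(parseReaction("C(C>>CC", "bad"), "unparseable|unbalanced")
  expect_error(parseReaction(">>CC"), "no reactants")
})

test_that("splitMultiProduct conserves reactions one per product", {
  raw <- new("RawReaction", reactantSmiles = "CC", agentSmiles = character(0),
             productSmiles = c("CC", "CCC"), sourceId = "m")
  out <- splitMultiProduct(raw)
  expect_length(out, 2)
  expect_equal(vapply(out, function(x) x@productSmiles, character(1)),
               c("CC", "CCC"))
  expect_true(all(vapply(out, function(x)
    identical(x@reactantSmiles, "CC"), logical(1))))

  single <- parseReaction("CC>>CCO")
  expect_equal(splitMultiProduct(single)[[1]]@productSmiles, "CCO")
})

test_that("template library assigns first-occurrence labels 1..T", {
  lib <- buildTemplateLibrary(c("tA>>x", "tB>>y", "tA>>x"))
  expect_equal(length(lib), 2L)
  expect_equal(labelOf(lib, "tA>>x"), 1L)
  expect_equal(labelOf(lib, "tB>>y"), 2L)
  expect_equal(templateOf(lib, 2L), "tB>>y")

  lib1 <- buildTemplateLibrary("only>>one")
  expect_equal(length(lib1), 1L)

  many <- paste0("t", seq_len(500), ">>p")
  expect_equal(labelOf(buildTemplateLibrary(many), many), 1:500)

  expect_error(buildTemplateLibrary(character(0)), "non-empty")
})

test_that("extractTemplate is deterministic and flags degenerate input", {
  t1 <- extractTemplate(parseReaction(ESTER_RXN, "e1"))
  t2 <- extractTemplate(parseReaction(ESTER_RXN, "e2"))
  expect_identical(t1, t2)
  expect_identical(t1, ESTER_TEMPLATE)
  # the product pattern carries the ester carbonyl motif
  prodSide <- strsplit(t1, ">>", fixed = TRUE)[[1]][1]
  expect_match(prodSide, "(=\\[O;H0;\\+0:[0-9]+\\])", perl = TRUE)

  expect_error(extractTemplate(parseReaction("CC(=O)O.OCC>>CC(=O)OCC")),
               "atom map|mapped")
  expect_error(extractTemplate(parseReaction("[CH3:1][OH:2]>>[CH3:1][OH:2]")),
               "no changed atoms")
})

test_that("preprocessing builds consistent records and datasets", {
  fx <- small_corpus()
  expect_equal(length(fx$library), 6L)
  ds <- fx$dataset
  expect_equal(length(ds), nrow(fx$rx))
  expect_equal(sum(datasetStats(ds)$classCounts), length(ds))
  # recovered labels are a relabeling of the generator truth
  tab <- table(fx$rx$class_label, classLabels(ds))
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
  # constructed per-class mean
  expect_equal(mean(datasetStats(ds)$classCounts), 4)

  expect_error(buildDataset(list(), fx$library), "non-empty")
  alien <- fx$records[[1]]
  alien@template <- "not>>known"
  expect_error(buildDataset(c(fx$records, alien), fx$library), "unknown")
})

test_that("two preprocessing passes over one corpus give identical libraries", {
  fx <- small_corpus()
  pp2 <- preprocessReactions(fx$raws)
  expect_identical(templates(pp2$library), templates(fx$library))
})

test_that("dataset and library TSVs round-trip exactly", {
  fx <- small_corpus()
  dsFile <- tempfile(fileext = ".tsv")
  libFile <- tempfile(fileext = ".tsv")
  writeDataset(fx$dataset, dsFile)
  writeTemplateLibrary(fx$library, libFile)
  lib2 <- readTemplateLibrary(libFile)
  ds2 <- readDataset(dsFile, lib2)
  expect_identical(templates(lib2), templates(fx$library))
  expect_identical(products(ds2), products(fx$dataset))
  expect_identical(classLabels(ds2), classLabels(fx$dataset))
  expect_identical(groundTruthReactants(ds2),
                   groundTruthReactants(fx$dataset))
})

test_that("readReactions handles id columns and rejects empty files", {
  fx <- small_corpus()
  f <- tempfile(fileext = ".txt")
  writeReactions(fx$rx, f)
  raws <- readReactions(f)
  expect_length(raws, nrow(fx$rx))
  expect_equal(raws[[1]]@sourceId, fx$rx$id[1])

  empty <- tempfile()
  writeLines(character(0), empty)
  expect_error(readReactions(empty), "no reactions")
})
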