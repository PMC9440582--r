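# Top-k exact-match metrics and template application.

test_that("top-k accuracy matches hand enumeration", {
  rankings <- rbind(c(1L, 2L, 3L),
                    c(3L, 2L, 1L),
                    c(2L, 1L, 3L))
  truths <- c(1L, 2L, 3L)
  r <- topkAccuracy(rankings, truths, ks = c(1, 2))
  expect_equal(unname(accuracies(r)), c(1 / 3, 2 / 3))

  perfect <- topkAccuracy(rankings, rankings[, 1], ks = c(1, 2, 3))
  expect_equal(unname(accuracies(perfect)), c(1, 1, 1))

  # k >= M with full rankings is always a hit
  kBig <- topkAccuracy(rankings, truths, ks = 3)
  expect_equal(unname(accuracies(kBig)), 1)

  expect_error(topkAccuracy(rankings, 1:2), "differ in length")
  expect_error(topkAccuracy(rankings, truths, ks = 0), "positive")
})

test_that("accuracy is monotone in k and a random classifier scores k/M", {
  set.seed(42)
  M <- 50L; n <- 2000L
  rankings <- t(vapply(seq_len(n), function(i) sample.int(M), integer(M)))
  truths <- sample.int(M, n, replace = TRUE)
  r <- topkAccuracy(rankings, truths, ks = c(1, 3, 5, 10))
  acc <- unname(accuracies(r))
  expect_true(all(diff(acc) >= 0))
  for (j in seq_along(acc)) {
    p <- c(1, 3, 5, 10)[j] / M
    expect_lt(abs(acc[j] - p), 4 * sqrt(p * (1 - p) / n))
  }
})

test_that("applyTemplate reproduces the esterification reactants", {
  out <- applyTemplate("CCOC(C)=O", ESTER_TEMPLATE)
  expect_true(any(vapply(out, identical, logical(1),
                         y = sort(c("CC(=O)O", "CCO")))))
  # a template that does not embed returns the empty set
  expect_length(applyTemplate("C", ESTER_TEMPLATE), 0)
})

test_that("ground-truth templates round-trip the corpus reactants", {
  fx <- small_corpus()
  ds <- fx$dataset
  lib <- templateLibrary(ds)
  for (i in seq_len(length(ds))) {
    cand <- applyTemplate(products(ds)[i],
                          templateOf(lib, classLabels(ds)[i]))
    truth <- sort(groundTruthReactants(ds)[[i]])
    expect_true(any(vapply(cand, identical, logical(1), y = truth)),
                info = paste("sample", i))
  }
})

test_that("reactant-mode accuracy equals label mode on the round-trip corpus", {
  fx <- small_corpus()
  ds <- fx$dataset
  M <- length(templateLibrary(ds))
  n <- length(ds)
  set.seed(8)
  # synthetic rankings: half the samples get the right label on top,
  # the rest get it at rank 2
  labs <- matrix(0L, n, M)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(M), classLabels(ds)[i])
    labs[i, ] <- if (i %% 2 == 0) c(classLabels(ds)[i], others)
                 else c(others[1], classLabels(ds)[i], others[-1])
  }
  probs <- matrix(rep(seq(M, 1) / sum(seq_len(M)), each = n), n, M)
  ranking <- new("PredictionRanking", labels = labs, probs = probs)

  labelAcc <- accuracies(topkAccuracy(ranking, classLabels(ds), ks = c(1, 2)))
  reactAcc <- accuracies(reactantMatchAccuracy(ranking, ds, ks = c(1, 2)))
  expect_equal(unname(labelAcc), c(0.5, 1))
  # label correctness implies reactant correctness here, and a wrong label's
  # template either fails to apply or yields different reactants, so the two
  # modes coincide at k = 2; at k = 1 reactant mode can only be >= label mode
  expect_equal(unname(reactAcc)[2], 1)
  expect_gte(unname(reactAcc)[1], 0.5)
})

test_that("distinct templates with identical effect both count as hits", {
  # same chemistry, reactant fragments written in swapped order
  sides <- strsplit(ESTER_TEMPLATE, ">>", fixed = TRUE)[[1]]
  frags <- strsplit(sides[2], ".", fixed = TRUE)[[1]]
  twin <- paste0(sides[1], ">>", frags[2], ".", frags[1])
  expect_false(identical(twin, ESTER_TEMPLATE))

  lib <- buildTemplateLibrary(c(ESTER_TEMPLATE, twin))
  ds <- msRetro:::.make_dataset(products = "CCOC(C)=O", labels = 1L,
                                reactants = list(c("CC(=O)O", "CCO")),
                                library = lib)
  ranking <- new("PredictionRanking",
                 labels = matrix(c(2L, 1L), 1),      # twin ranked first
                 probs = matrix(c(0.6, 0.4), 1))
  acc <- accuracies(reactantMatchAccuracy(ranking, ds, ks = c(1, 2)))
  expect_equal(unname(acc), c(1, 1))                 # twin already hits at k=1
})
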