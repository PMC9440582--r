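# Shared fixtures, built in code and memoized per test run.

.fixture_env <- new.env(parent = emptyenv())

# a mapped esterification toy reaction and its frozen retro-template
# (computed once with extractTemplate at radius 1 and kept as a regression
# reference)
ESTER_RXN <- paste0("[CH3:1][C:2](=[O:3])[OH:4].[OH:5][CH2:6][CH3:7]",
                    ">>[CH3:1][C:2](=[O:3])[O:5][CH2:6][CH3:7]")
ESTER_TEMPLATE <- paste0(
  "[C;H3;+0:1]-[C;H0;+0:2](=[O;H0;+0:3])-[O;H0;+0:4]-[C;H2;+0:5]",
  ">>[C;H3;+0:1]-[C;H0;+0:2](=[O;H0;+0:3])-[O;H1;+0]",
  ".[O;H1;+0:4]-[C;H2;+0:5]")

# small preprocessed synthetic corpus: 6 rule classes x 4 reactions
small_corpus <- function() {
  if (is.null(.fixture_env$small)) {
    rx <- generateSyntheticReactions(nClasses = 6, samplesPerClass = 4,
                                     seed = 101)
    raws <- lapply(seq_len(nrow(rx)), function(i)
      parseReaction(rx$reaction_smiles[i], rx$id[i]))
    pp <- preprocessReactions(raws)
    .fixture_env$small <- list(rx = rx, raws = raws, records = pp$records,
                               library = pp$library,
                               dataset = buildDataset(pp$records, pp$library))
  }
  .fixture_env$small
}

# a tiny trained model on a separable set (6 classes), reused across tests
tiny_model <- function() {
  if (is.null(.fixture_env$model)) {
    ds <- generateSeparableSet(nClasses = 6, samplesPerClass = 20, seed = 202)
    sp <- plainSplit(ds, seed = 1)
    cfg <- modelConfig(fpLength = 256L,
                       fpSchedule = makeFilterSchedule(16L, 16L, 64L),
                       seqSchedule = makeFilterSchedule(3L, 3L, 9L),
                       seqLength = 40L, outChannels = 3L,
                       epochs = 10L, batchSize = 8L, learningRate = 0.01,
                       seed = 9L)
    .fixture_env$model <- list(ds = ds, sp = sp, cfg = cfg,
                               model = trainClassifier(ds, sp, cfg))
  }
  .fixture_env$model
}

# long-tail labels with singletons for split tests
longtail_dataset <- function() {
  if (is.null(.fixture_env$longtail)) {
    rx <- generateSyntheticReactions(nClasses = 30, samplesPerClass = 3,
                                     seed = 303, distribution = "longtail")
    .fixture_env$longtail <- rx
  }
  .fixture_env$longtail
}
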