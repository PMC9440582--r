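Package: msRetro
Title: Multi-Scale Convolutional Template Classification for Single-Step
    Retrosynthesis
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Template-based single-step retrosynthesis prediction cast as
    multi-class reaction-template classification. Atom-mapped reaction SMILES
    are preprocessed into (product, template-class) samples; a retro-template
    extractor derives reaction SMARTS at a configurable environment radius and
    assigns positive-integer class labels. Products are described by two
    descriptors, a folded circular (ECFP/Morgan-style) fingerprint and a padded
    one-hot SMILES character matrix, each fed to a branch of a multi-scale
    one-dimensional convolutional feature extractor whose parallel operation
    groups (convolution, batch normalization, sigmoid, max-pooling) use filter
    sizes on an arithmetic schedule. Branch features are concatenated and
    classified by a softmax head trained with cross-entropy. Includes Plain and
    label-coverage (Aug) dataset splits, top-k exact-match evaluation at the
    class-label and reactant level, a fingerprint MLP baseline, and a synthetic
    reaction-corpus generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite,
    ChemmineOB
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
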