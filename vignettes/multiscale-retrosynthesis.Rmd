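---
title: "Multi-scale convolutional template classification for single-step retrosynthesis"
author: "msRetro"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale convolutional template classification for single-step retrosynthesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msRetro)
```

## The problem and the model

Single-step retrosynthesis asks: given a product molecule, which reactants
could have produced it in one reaction? Template-based methods answer by
predicting a *reaction template* — a reaction-SMARTS pattern describing the
local bond changes — and applying it to the product to propose reactant sets.
When the templates extracted from a reaction corpus are deduplicated and each
assigned a positive-integer class label, retrosynthesis becomes multi-class
classification: learn $p(C \mid P, \theta)$, the probability that product $P$
belongs to template class $C$.

A reaction with $M$ reactants is represented by the quadruple
$(\{S_j\}_{j=1}^M,\; P,\; T,\; C)$: canonical reactant SMILES, one canonical
product SMILES, the retro-template and its class label. Training uses the
$(P, C)$ pairs only; the template library maps predictions back to chemistry.

The classifier in this package describes the product twice:

* an **ECFP fingerprint** — a folded binary vector (default 2048 bits,
  radius 2) whose bits flag circular substructures, computed by OpenBabel;
* a **one-hot SMILES matrix** — an $L \times |\mathrm{tokens}|$ binary matrix
  over the character vocabulary of the training corpus, zero-padded past the
  string length.

Each descriptor feeds one branch of a **multi-scale feature extractor**: $K$
parallel *operation groups*, each a valid (no padding, stride 1) 1-D
convolution with $C$ filters of length $F_i$, followed by batch
normalization, an element-wise sigmoid into $[0,1]$, and max-pooling. The
filter lengths follow an arithmetic schedule

$$F_i = \mathrm{min} + (i - 1)\,\mathrm{step}, \qquad F_i \le \mathrm{max},$$

so small filters see local motifs and large filters see long-range structure.
The defaults are 32/32/2048 for the fingerprint branch (64 groups, matching
its worked example, which includes the endpoint — hence the inclusive bound,
with a strict-bound flag available) and 5/5/200 for the SMILES branch. The
pooled group outputs are concatenated and a fully connected softmax head
produces class probabilities, trained with cross-entropy

$$\mathcal{L} = -\frac{1}{N}\sum_i \sum_{c=1}^{M} y_{ic} \log p_{ic}$$

by mini-batch Adam. The reference recipe (the `modelConfig()` defaults) is 20
epochs, batch size 128, learning rate 0.001. A three-layer fingerprint MLP
(`trainMLPBaseline()`) is the comparison baseline.

## Preprocessing and its conventions

`parseReaction()` slices a reaction SMILES at its `>` separators (both the
`reactants>agents>products` and `reactants>>products` dialects are accepted;
agents are parsed and ignored). Multi-product reactions are split into one
single-product reaction per product. `extractTemplate()` derives the
retro-template at a configurable environment radius (default 1 bond around
the changed atoms); `preprocessReactions()` chains these, canonicalizes all
stored SMILES (atom maps stripped), drops reactions whose extraction fails
(with a count) and assigns labels in first-occurrence order, which makes the
library reproducible.

Design choices in the extractor, made where conventions genuinely diverge:

* **Changed atoms** are mapped atoms whose bonds to mapped neighbours differ
  between sides, whose H count or formal charge changes, or that carry a bond
  to a non-surviving (leaving-group) atom. Unmapped reactant atoms within the
  radius of the reaction centre are kept on the reactant side.
* **Template atoms record element, H count and charge** — for environment
  atoms too, not only for changed ones. This is more specific than
  minimal-environment conventions: groups that differ one bond from the
  reaction centre (methyl vs ethyl ethers, acetates vs tert-butyl ethers)
  get distinct classes. The cost is generality — a template transfers to
  fewer off-corpus products; for a classification benchmark specificity is
  the safer side of the trade.
* **Atom maps are renumbered 1..k by rank** before serialization, so the
  template does not depend on the absolute map numbers of the source
  reaction.
* **Fragment and atom order** in the serialized SMARTS follow map order with
  a deterministic DFS, so identical reactions give byte-identical templates.

`applyTemplate()` embeds the product pattern in a molecule (non-induced
matching on element, aromaticity, and the recorded H/charge constraints,
bond orders exact) and rewrites matched bonds and atoms according to the
reactant pattern; every embedding yields a candidate reactant set,
canonicalized and compared as an unordered set. Both evaluation modes are
exposed: `topkAccuracy()` scores template-class identity (the primary metric,
matching the classification view), `reactantMatchAccuracy()` scores whether
any top-k template reproduces the ground-truth reactants — on corpora where
label correctness implies reactant correctness the two coincide.

## Encoders

Tokenization is character-level: the vocabulary is the set of distinct
characters in the training products, sorted in a locale-independent order.
Characters unseen in training raise an error at encoding time rather than
being mapped silently. Products longer than $L$ are *dropped* (never
truncated) by `filterByLength()`, applied identically to train, validation
and test; $L$ should cover the bulk of the length distribution (300 is the
default, matching patent-corpus products; 100 suits short metabolite
SMILES). The fingerprint encoder OR-folds OpenBabel's native 4096-bit ECFP
to the configured length; radius 2 (ECFP4) and 2048 bits are the defaults,
2048 also being the fingerprint branch's largest filter.

## Numerical choices

* Convolution is cross-correlation (no kernel flipping), stride 1, no
  padding: an input of length $l$ gives $l - F + 1$ positions.
* Batch normalization uses batch statistics during training and running
  statistics (momentum 0.1, $\varepsilon = 10^{-5}$) at inference; an
  identity mode exists so the operation group can be tested against a plain
  sliding-window oracle.
* Global max-pooling (one value per channel) is the default, the TextCNN
  convention; windowed pooling is available by configuration.
* Log-probabilities are clamped at $10^{-12}$ inside the loss.
* One integer seed controls weight initialization and shuffling; training
  twice with the same seed reproduces the history bit for bit. There is no
  early stopping and no learning-rate schedule.
* The classifier head is a single fully connected layer by default; hidden
  layers can be added by configuration.

The backward pass was verified against central-difference numerical
gradients on a small two-branch model (agreement to ~1e-10; the convolution
bias gradient is exactly zero under batch normalization, which is expected —
the shift is absorbed).

## The synthetic benchmark

Real benchmark corpora are large and external; the package instead ships a
generator whose ground truth is known by construction.
`generateSyntheticReactions()` emits atom-mapped nucleophilic substitutions
$R{-}CH_2{-}Br + H{-}Z \rightarrow R{-}CH_2{-}Z$ (classes 1–20, one per
nucleophile $Z$: hydroxyl, methoxy, ethoxy, amino, methylamino,
dimethylamino, sulfanyl, methylthio, cyano, ethynyl, acetoxy, ethylthio,
ethylamino, fluoro, chloro, iodo, isopropoxy, acetamido, acetylthio,
N-methyl-N-ethylamino) and the same substitutions at a secondary carbon
(classes 21–40). Scaffolds are random alkyl chains with the carbon adjacent
to the reaction centre fixed to CH$_2$, which makes each rule's template
scaffold-invariant; the $Z$ groups were chosen so the radius-1 templates are
pairwise distinct. Preprocessing the corpus therefore recovers exactly $T$
classes, bijective with the generator truth — the key integration property.

Defaults emulate the per-class abundance of patent reaction data (5 samples
per class on average; a long-tail option draws geometric class sizes, making
singleton classes common, the regime where the Plain split loses labels and
the coverage split matters). What the generator does *not* emulate: ring
chemistry, stereochemistry, aromatic systems, reagent/condition effects, and
the scale and noise of real corpora (tens of thousands of classes, mapping
errors, duplicate reactions). Passing the benchmark shows the pipeline and
the optimizer are correct and that the architecture can separate
template-determined product classes; it does not certify real-corpus
accuracy.

## Splits

`plainSplit()` partitions uniformly at random by the target ratios
(validation and test floored, remainder to train). `augSplit()` first
reserves one uniformly chosen sample per class into train — so every label
is trainable — then ratio-partitions the rest; the guarantee applies to
train only, and singleton classes end up entirely in train. Both splits are
persisted with their seed, strategy and ratios.

## Desk-scale configuration

The tests and the acceptance script train a scaled-down model on the
20-class, 50-samples-per-class benchmark: 512-bit fingerprints with schedule
32/32/256, SMILES length 60 with schedule 3/3/12, $C = 4$ output channels,
10 epochs, batch size 16, learning rate 0.01. The batch size and learning
rate follow from step-count arithmetic: 1000 samples at batch 16 for 10
epochs give ~630 optimizer steps, comparable (within an order of magnitude)
to the reference recipe's step count at full scale, whereas batch 128 at
this sample count would allow only ~70 steps — too few for Adam at any
reasonable rate. These sizes keep the full suite in minutes on one CPU.

## Known limitations

* The atom-mapped SMILES dialect handled by the internal graph parser covers
  the organic subset, brackets with H counts/charges/maps, branches, ring
  closures and bond orders `-`, `=`, `#`; stereo descriptors and isotopes
  are rejected with a clear error. Unmapped SMILES elsewhere in the package
  go through OpenBabel and are not limited this way.
* Atom mapping is assumed present (as in curated corpora); the package does
  not compute mappings.
* Implicit-hydrogen assignment for aromatic atoms in the internal parser is
  approximate (one bond equivalent); the synthetic generator emits aliphatic
  chemistry only.
* Aug coverage is guaranteed for train, not for validation/test.
* `countParameters()` reports the count for this package's assembly (single
  fully connected head unless configured otherwise); published parameter
  tables for architectures whose head/channel configuration is unspecified
  are not reproducible bit-exactly and are only tracked as a trend
  (count strictly decreasing in either branch's step).

## A compact example

```{r example, eval = FALSE}
rx <- generateSyntheticReactions(nClasses = 20, samplesPerClass = 50, seed = 1)
raws <- lapply(seq_len(nrow(rx)), function(i)
  parseReaction(rx$reaction_smiles[i], rx$id[i]))
pp <- preprocessReactions(raws)
ds <- buildDataset(pp$records, pp$library)

split <- plainSplit(ds, seed = 2)
cfg <- modelConfig(fpLength = 512L,
                   fpSchedule = makeFilterSchedule(32, 32, 256),
                   seqSchedule = makeFilterSchedule(3, 3, 12),
                   seqLength = 60L, outChannels = 4L,
                   epochs = 10L, batchSize = 16L, learningRate = 0.01)
model <- trainClassifier(ds, split, cfg)

te <- testIdx(split)
ranking <- predictRanking(model, products(ds)[te])
topkAccuracy(ranking, classLabels(ds)[te], ks = c(1, 3, 5, 10))
```

The numbers this prints on the study conditions are computed by
`scripts/acceptance.R` and by the test suite; the README shows one such run.
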