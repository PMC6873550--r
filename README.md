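# smilescape

Training and benchmarking tools for SMILES-based molecular generative
models, built around a question that matters whenever an RNN is asked to
propose molecules: **how much of a target chemical space does the trained
model actually cover, how evenly, and how cleanly?**

A molecule has one canonical SMILES string but many *randomized* ones —
rewritings from random atom orderings. Training on a fresh randomized
writing of every molecule each epoch is a data-augmentation scheme that
markedly improves how completely and uniformly a recurrent model covers its
target space. `smilescape` implements the full apparatus in R:

* canonical, restricted-randomized and unrestricted-randomized SMILES
  writers (the unrestricted string set is a strict superset of the
  restricted one), plus DeepSMILES conversion;
* the exact tokenizer (character-based; `Cl`, `Br`, `[...]` and `%NN` are
  single tokens; `^`/`$` markers, `$` doubling as padding);
* a stacked LSTM/GRU language model with teacher forcing, unmasked
  end-token-padded batches, uniform `(-sqrt(1/w), sqrt(1/w))` weight
  initialization and total-gradient-norm clipping at 1.0 — written in base
  R matrix algebra with hand-derived backpropagation through time;
* the evaluation mathematics, all in nats:

  - `phi(k, N) = 1 - (1 - 1/N)^k`, the expected unique fraction when an
    *ideal* uniform generator over an `N`-molecule space is sampled `k`
    times with replacement;
  - `completeness = ratio_unique / phi(k, N)`,
    `uniformity = ratio_unique / phi(|in|, N)`,
    `closedness = |in| / k`, and their product **UCC**;
  - **UC-JSD**, the Jensen–Shannon divergence (weights 1/3) of the
    sum-normalized NLL vectors of the training, validation and sampled
    sets — used both to drive learning-rate decay and to pick the best
    epoch (window-4 smoothed argmin);

* a fully enumerable synthetic target space (up to 10 heavy atoms over
  C/N/O, with decidable exclusion filters such as *no triple bonds* and
  *no rings smaller than 5*) standing in for a combinatorially enumerated
  database like GDB-13, so that membership, completeness and closedness
  are all exactly computable at desk scale.

## Worked example

```r
library(smilescape)

space <- enumerateToySpace(5, c("C", "N", "O"), toySpaceFilters())
#> ChemicalSpace of 1495 molecules (<= 5 heavy atoms; elements C,N,O)
#>   uniform NLL: 7.31 nats

split <- splitTrainValidation(space, nTrain = 150, nValid = 50, seed = 1)
phi(2e9, 9.75e8)
#> [1] 0.87143

vocab <- spaceVocabulary(space)
model <- smilesRNN(vocab, layers = 2, width = 48, seed = 1, maxLen = 40)
#> SmilesRNN: 2 x LSTM(48), embedding 48, dropout 0.00, vocab 17

cfg <- trainConfig(batchSize = 16, maxEpochs = 40, lrInit = 3e-3,
                   ucjsdSampleSize = 96, seed = 1)
run <- trainModel(model, split, variant = "randomized_restricted",
                  config = cfg)
#> TrainingRun (randomized_restricted): 40 epochs, best epoch 39
#>   (uc_jsd 0.01486)

samp <- sampleSmiles(bestModel(run), n = 10000, seed = 2)
ev <- evaluateSample(ifelse(samp$terminated, samp$smiles, NA), space)
#> SampleEvaluation: k = 10000 against a space of 1495 molecules
#>   valid 5138 (ratio 0.5138)   in-space 5018 (closedness 0.5018)
#>   unique members 1157 (ratio_unique 0.7739)
#>   completeness 0.7749   uniformity 0.8018   UCC 0.3118
```

Reading the result: a model trained on 150 of the 1,495 molecules (10% of
the space) with per-epoch randomized-SMILES augmentation generated valid
molecules about half the time, and those draws recovered 1,157 distinct
members — 77% of what the *ideal* uniform generator would be expected to
recover in the same 10,000 draws (`completeness 0.77`), spread fairly
evenly over the space (`uniformity 0.80`). The single-number summary UCC
multiplies completeness, uniformity and closedness so that a model weak on
any one axis scores poorly. `runBenchmark()` repeats this protocol for
canonical and randomized variants under identical budgets and returns a
comparison table; at every budget we tried, the randomized-restricted arm
recovers more of the space than the canonical arm, the qualitative effect
the package exists to measure.

A thin command-line wrapper over the same functions lives in
`inst/cli/smilescape.R` (subcommands `toyspace`, `augment`, `train`,
`sample`, `evaluate`, `benchmark`; every run writes a manifest with its
resolved configuration and seeds).

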