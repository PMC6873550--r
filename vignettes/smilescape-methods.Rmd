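---
title: "Randomized SMILES generative modeling and chemical-space coverage: methods"
author: "smilescape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Randomized SMILES generative modeling and chemical-space coverage: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smilescape)
```

## Overview

`smilescape` implements, end to end and at desk scale, the methodology of
training recurrent language models on different string representations of
the same molecules and measuring how well the generated chemical space
covers a finite, fully enumerable target space. The package contains five
cooperating layers:

1. **String machinery** — a SMILES parser, a canonical writer, and two
   randomized writers (restricted and unrestricted), plus DeepSMILES
   conversion.
2. **Tokenization** — the character-based tokenizer with the multi-character
   exceptions (`Cl`, `Br`, bracket atoms, `%NN` ring closures) and
   begin/end markers.
3. **The model** — an embedding, `l` stacked LSTM or GRU layers of width
   `w` with inter-layer dropout, a linear projection and a softmax, trained
   by teacher forcing.
4. **Metrics** — Shannon entropy, the Jensen–Shannon divergence, the
   UC-JSD training monitor, the ideal-sampler expectation `phi(k, N)`, and
   the completeness / uniformity / closedness / UCC coverage scores.
5. **A synthetic target space** — an exhaustively enumerated set of small
   molecules with exclusion filters, standing in for a combinatorial
   database like GDB-13 so that every claim is testable without external
   data.

## Randomized SMILES

A molecule admits many SMILES strings; canonical writers pick one by
ranking atoms with an invariant-refinement algorithm. Randomized SMILES are
produced here by drawing a uniformly random permutation of the atom indices
and writing the molecule depth-first following that permutation: the
permutation decides the starting atom and the order in which branches are
explored, never the grammar.

Two randomized dialects are provided:

* **Restricted** (`randomized_restricted`): the writer keeps its traversal
  fixes — every non-final child of an atom is parenthesised and the final
  child continues the chain, giving minimal-parenthesis strings.
* **Unrestricted** (`randomized_unrestricted`): the writer follows the
  permutation literally; when the final child of an atom has a lower
  permutation priority than its parent, it is written as a (redundant)
  branch. On a benzene ring this produces forms of the family
  `c1cc(c(cc1))` that the restricted writer can never emit. Because every
  restricted traversal corresponds to a permutation ranked in discovery
  order — for which the unrestricted writer adds no parentheses — the
  unrestricted string set is a strict superset of the restricted one; the
  test suite verifies this exhaustively molecule by molecule.

Randomization is uniform over *permutations*, not over distinct strings:
several permutations usually collapse to the same string (for ethanol, 6
permutations give 4 restricted strings), so strings are not equiprobable.
The molecule-level NLL aggregation (`moleculeNll`) therefore sums model
probabilities over distinct strings, exactly or over a sampled budget.

The canonical form produced by `canonicalizeSmiles()` is the package's own:
iterative refinement of (element, aromaticity, charge, hydrogen count,
isotope, degree, bond-order sum) followed by a lexicographic backtracking
tie-break. It is idempotent and invariant under atom relabeling — the two
properties everything else relies on — but it is an *internal molecule
key*, not a reproduction of any other toolkit's canonical order. Where an
independent view of "same molecule" is needed, the test suite calls
OpenBabel through `ChemmineOB` as an oracle.

The parser handles the organic subset plus bracket atoms (charge, explicit
hydrogens, isotopes), aromatic lowercase forms, ring closures including
`%NN`, and enforces standard lowest valences (C 4, N 3, O 2, adjusted by
charge). Chirality tags and directional bond characters are read but
dropped: the package works at constitution level throughout, which is
sufficient for the coverage questions it answers. Hypervalent nitrogen
forms (e.g. uncharged `N(=O)=O`) are rejected; the charged-separated
writing is the accepted one.

## Tokenization

Tokenization is character-based with exactly three multi-character cases:
`Cl`/`Br`, bracket expressions, and `%` followed by two digits. `^` is
prepended, `$` appended, and the `$` index doubles as the padding symbol.
Vocabularies are the lexicographically sorted distinct tokens of a corpus
(radix order, so index assignment is locale- and order-independent).
Encoding an unknown token is a hard error rather than a silent skip — a
skip would silently corrupt every downstream NLL comparison. Because
augmentation regenerates strings each epoch, `spaceVocabulary()` adds the
structural tokens any randomized writing can introduce (parentheses,
ring-closure digits), guaranteeing epoch files never fall outside the
vocabulary.

## Model and training protocol

The model is `smilesRNN(vocab, layers, width, embedding, dropout, cell)`.
Constraints and defaults follow the architecture it reimplements: the
embedding dimension must satisfy `m <= w` (default `m = w`, since only the
inequality is specified); dropout lives strictly *between* recurrent
layers; all weight matrices are initialized i.i.d. uniform on
`(-sqrt(1/w), sqrt(1/w))`.

Training (`trainModel`) follows the reference protocol:

* per epoch the training set is shuffled and cut into minibatches of size
  `b`, each a matrix of encoded rows right-padded with the end token;
* teacher forcing: the ground-truth token is always the next input;
* the loss is the *unmasked* mean NLL of the batch — padding positions are
  included, their target being the end token, which leaves training quality
  unaffected while avoiding masks;
* gradients are rescaled whenever their total norm exceeds `clipNorm`
  (default 1.0);
* with augmentation on, a fresh randomized writing of every training *and*
  validation molecule is generated each epoch (the reference protocol
  regenerates the training strings per epoch and is ambiguous about the
  validation set; both are regenerated here). With augmentation off, one randomized writing is frozen — the
  "no data augmentation" arm. Epoch files can also be pre-generated with
  `writeAugmentationEpochs()`; the default is on-the-fly regeneration,
  which has identical statistics and no disk footprint.

The *reporting* NLL of a sequence (`sequenceNll`) truncates at the first
end token inclusive: evaluation quantities concern whole molecule strings,
which end at `$`, while the training loss is unmasked. Both views coincide
when a row needs no padding, and the test suite pins each against
independent step-by-step oracles.

The optimizer is Adam with standard moments; the source protocol does not
name its optimizer, so this is configuration, not contract. Sampling is
plain autoregressive multinomial sampling at temperature 1 (temperature
scaling, beam search and top-k are deliberately out of scope); sequences
hitting `maxLen` (default 128; 40–64 in the tests, where strings are
short) without `$` are flagged non-terminated and counted invalid
downstream.

## UC-JSD and the learning-rate schedule

After each epoch, equal-length NLL vectors are collected for the training,
validation and freshly sampled sets (`ucjsdSampleSize` each; larger sets
are subsampled with a seeded stream). Each vector is divided by its sum —
element order preserved, no sorting — giving three discrete distributions
whose Jensen–Shannon divergence with weights 1/3 is the UC-JSD. It lives in
`[0, log 3]` and approaches 0 when the three NLL profiles are uniform and
matching, the signature of a complete, uniform generator. Two numerical
facts are worth noting and are asserted in tests: UC-JSD is invariant under
scaling any *one* vector (its normalized distribution is unchanged) but not
under a common shift of all NLLs; and constant vectors of any levels give
exactly 0. A `sorted = TRUE` mode exists for sensitivity analysis only.

The learning-rate schedule is driven by the same metric: a window-4
trailing moving average is applied to the UC-JSD history, and when the
smoothed value has not improved by more than `lrTolerance` (default 1e-4)
for `lrPatience` consecutive epochs (default 5), the rate is multiplied by
`lrDecayFactor` (default 0.7). The reference protocol states only that its
decay strategy is based on the per-epoch UC-JSD without fixing the exact
recipe; the defaults here are this package's own choices and fully
configurable. Best-epoch selection applies the same
window-4 smoothing and takes the argmin, ties to the earliest epoch.

## Coverage metrics

For a size-`k` sample with replacement against a target space of `N`
molecules:

* `ratio_valid = |valid| / k` — strings parsing to valid molecules, with
  repeats;
* `closedness = ratio_in = |in| / k` — valid strings whose canonical form
  is in the space, with repeats;
* `ratio_unique = |unique| / N` — distinct space members recovered;
* `phi(k, N) = 1 - (1 - 1/N)^k` — the expected unique fraction for the
  *ideal model* (uniform over exactly the space), evaluated in log space so
  that `k = 2e9`, `N = 9.75e8` is exact; the exact expectation is used, not
  the `exp(-k/N)` approximation, since exactness is free;
* `completeness = ratio_unique / phi(k, N)`;
* `uniformity = ratio_unique / phi(|in|, N)`;
* `UCC = completeness * uniformity * closedness`.

Completeness and uniformity are not clamped at 1: finite-sample
fluctuations slightly above 1 are possible for near-ideal generators and
are reported as-is. Non-terminated and unparseable strings count as
invalid; duplicates count toward every with-repeats quantity. All
entropies and NLLs are in nats.

## The synthetic target space

`enumerateToySpace()` grows molecular graphs breadth-first — add an atom,
or close a ring — over elements from {C, N, O}, deduplicating by canonical
string at every step. The default exclusion filters (no triple bonds, no
rings smaller than 5) are cheap, decidable analogues of the strained-ring
and unstable-functional-group exclusions of real enumerated databases.
Both are *monotone* under growth (a forbidden feature never disappears
when atoms or bonds are added), so they prune during enumeration without
losing any member; an independent isomorphism-class oracle built on
igraph's VF2 confirms the counts in the test suite. The defaults give
9,880 molecules at up to 6 heavy atoms — large enough that a sample of the
trained models cannot trivially saturate it, small enough to enumerate in
under a minute. Because triple bonds and small rings are valid chemistry
excluded by fiat, out-of-space valid molecules exist and closedness is a
meaningful quantity, exactly as with a real enumerated database.

What the toy space does *not* emulate: the size (9,880 versus 975 million),
the string length regime (8–12 tokens versus 20+), stereochemistry,
aromatic perception, and the specific filter chemistry of fragment-like
databases. Passing the scaled-down benchmark therefore demonstrates that
the machinery reproduces the *mechanism* — data augmentation by
representation resampling improving coverage — not the published headline
percentages, which require GPU-scale training on the real database.

## Study conditions of the scaled-down benchmark

The acceptance suite trains both arms (canonical versus restricted
randomized) under identical budgets: the 9,880-molecule space, 100
training and 100 validation molecules, a 2-layer LSTM of width 64,
batch size 16, 80 epochs, initial learning rate 3e-3, and a `2N`-draw
evaluation sample, repeated over five disjoint seed sets. The training
fraction (~1%) deliberately mirrors the data-sparse end of the published
benchmarks (1,000 molecules from 975 million), which is where the
augmentation effect is strongest and which a desk-scale budget can reach;
the win criterion (randomized beats canonical on UCC and on
unique-fraction in at least 4 of 5 replicates) matches the qualitative
ordering reported for every training-set size. The UC-JSD-as-selector
check trains six configurations (width 12/24/48, LSTM and GRU) on a
1,495-molecule space and requires a negative Spearman correlation between
best-epoch UC-JSD and UCC. Problem sizes throughout were chosen once, as a
balance between statistical resolution and an ordinary workstation run
time, and are stated here so they can be scaled up verbatim.

## Numerical choices and degenerate inputs

* Seeds: every stochastic call takes one integer seed; internal streams
  derive from it by fixed arithmetic on (seed, purpose tag, index), all
  below 2^31. Two calls with the same arguments are bitwise identical.
* Softmax rows are checked to sum to 1 within 1e-6 in tests; NLLs are
  accumulated in log space (`logSumExp`) wherever probabilities are summed.
* `phi(0, N) = 0`, `phi(k, 1) = 1` for `k >= 1`; empty spaces, zero-sum
  NLL vectors, all-invalid samples and unknown variants raise typed errors.
* Canonicalization returns `NA` (a failure value) for unparseable strings
  so samplers can score validity without exception handling.
* Ties: vocabulary order is radix-sorted; best-epoch ties break earliest;
  the canonical tie-break takes the lexicographically smallest writing.

## Known limitations

* The canonical form is package-internal; canonical strings must never be
  compared byte-for-byte against another toolkit's output (graph identity
  is the portable notion, and is what the tests assert via OpenBabel).
* No stereochemistry, no aromaticity *perception* (aromatic flags are
  preserved as written, with pragmatic valence rules), no hypervalent
  nitrogen/sulfur forms beyond charge adjustment.
* The RNN is plain base-R matrix algebra: perfectly adequate at toy scale
  (a full benchmark replicate is ~90 s on one core) but not a vehicle for
  million-molecule corpora.
* The reference learning-rate recipe and optimizer are not fixed by the
  protocol;
  the schedule here is UC-JSD-driven with documented defaults, so
  epoch-by-epoch trajectories are not expected to match the original runs.
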