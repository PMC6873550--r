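#' Token vocabulary for SMILES language models
#'
#' A bijection between string tokens and contiguous integer indices. The
#' begin-of-sequence token `"^"` and end-of-sequence token `"$"` are always
#' present; the end token doubles as the padding symbol when sequences are
#' batched to a common length.
#'
#' @slot tokens character vector of distinct tokens; the index of a token is
#'   its position in this vector.
#' @export
setClass("TokenVocabulary", representation(tokens = "character"),
         validity = function(object) {
  msg <- NULL
  if (anyDuplicated(object@tokens)) msg <- c(msg, "tokens must be distinct")
  if (!all(c("^", "$") %in% object@tokens))
    msg <- c(msg, "begin '^' and end '$' tokens must be present")
  if (is.null(msg)) TRUE else msg
})

#' A finite, fully enumerable target chemical space
#'
#' Holds the complete set of member molecules as canonical SMILES strings,
#' standing in for a combinatorially enumerated database such as GDB-13:
#' membership of an arbitrary molecule is decidable by canonical-string
#' lookup, and the negative log-likelihood of the ideal uniform generator over
#' the space is `log(size)` nats.
#'
#' @slot members sorted character vector of distinct canonical SMILES.
#' @slot maxHeavyAtoms integer enumeration bound used to build the space.
#' @slot elements character vector of allowed elements.
#' @slot filters list describing the exclusion filters applied.
#' @export
setClass("ChemicalSpace",
         representation(members = "character", maxHeavyAtoms = "integer",
                        elements = "character", filters = "list"),
         validity = function(object) {
  msg <- NULL
  if (length(object@members) == 0L) msg <- c(msg, "degenerate space")
  if (anyDuplicated(object@members))
    msg <- c(msg, "members must be pairwise distinct")
  if (!identical(object@members, sort(object@members, method = "radix")))
    msg <- c(msg, "members must be stored sorted (radix order)")
  if (is.null(msg)) TRUE else msg
})

#' Disjoint training/validation split of a chemical space
#'
#' @slot training canonical SMILES used for model fitting.
#' @slot validation held-out canonical SMILES from the same space.
#' @slot seed integer seed the split was drawn with.
#' @export
setClass("SpaceSplit",
         representation(training = "character", validation = "character",
                        seed = "integer"),
         validity = function(object) {
  if (length(intersect(object@training, object@validation)) > 0L)
    "training and validation sets must be disjoint" else TRUE
})

#' Recurrent SMILES language model
#'
#' Embedding -> stacked LSTM/GRU (inter-layer dropout) -> linear -> softmax,
#' trained by teacher forcing on tokenized SMILES strings.
#'
#' @slot hparams list of hyperparameters (`layers`, `width`, `embedding`,
#'   `dropout`, `cell`, `vocabSize`, `maxLen`).
#' @slot params named list of weight matrices.
#' @slot vocab the [TokenVocabulary-class] the model was built against.
#' @export
setClass("SmilesRNN",
         representation(hparams = "list", params = "list",
                        vocab = "TokenVocabulary"))

#' Coverage evaluation of a sample against a chemical space
#'
#' Counts and ratios for a size-`k` sample with replacement: validity,
#' in-space fraction (closedness), unique in-space recovery, and the
#' completeness/uniformity/UCC composites relative to the ideal uniform
#' sampler expectation phi.
#'
#' @slot k sample size (with repeats).
#' @slot nValid number of sampled strings parsing to a valid molecule.
#' @slot nIn number of valid sampled strings inside the space (with repeats).
#' @slot nUnique number of distinct space members recovered.
#' @slot spaceSize size N of the target space.
#' @slot ratioValid,ratioIn,ratioUnique the three ratios.
#' @slot completeness,uniformity,closedness,ucc composite scores.
#' @slot phiK,phiIn ideal-model expectations phi(k,N) and phi(nIn,N).
#' @export
setClass("SampleEvaluation",
         representation(k = "numeric", nValid = "numeric", nIn = "numeric",
                        nUnique = "numeric", spaceSize = "numeric",
                        ratioValid = "numeric", ratioIn = "numeric",
                        ratioUnique = "numeric", completeness = "numeric",
                        uniformity = "numeric", closedness = "numeric",
                        ucc = "numeric", phiK = "numeric", phiIn = "numeric"),
         validity = function(object) {
  msg <- NULL
  if (!(object@nUnique <= object@nIn && object@nIn <= object@nValid &&
        object@nValid <= object@k))
    msg <- c(msg, "count chain nUnique <= nIn <= nValid <= k violated")
  if (is.null(msg)) TRUE else msg
})

#' Result of a training run
#'
#' @slot records data.frame with one row per epoch (`epoch`, `uc_jsd`,
#'   `learning_rate`, `mean_train_nll`, `mean_valid_nll`).
#' @slot bestEpoch epoch index minimising the window-4 smoothed UC-JSD.
#' @slot model the model after the final epoch.
#' @slot bestModel the model restored at `bestEpoch`.
#' @slot config resolved training configuration.
#' @export
setClass("TrainingRun",
         representation(records = "data.frame", bestEpoch = "integer",
                        model = "SmilesRNN", bestModel = "SmilesRNN",
                        config = "list"))
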