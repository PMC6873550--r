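# Training orchestration: per-epoch randomized-SMILES regeneration (data
# augmentation), shuffling, minibatching with end-token padding, teacher
# forcing, Adam updates with total-gradient-norm clipping, per-epoch UC-JSD
# monitoring, UC-JSD-driven learning-rate decay and best-epoch selection.

#' Training configuration
#'
#' @param batchSize minibatch size `b`.
#' @param maxEpochs number of epochs.
#' @param lrInit initial learning rate.
#' @param lrDecayFactor multiplicative decay in `(0, 1)` applied when the
#'   smoothed UC-JSD stalls.
#' @param lrPatience epochs without smoothed-UC-JSD improvement before a
#'   decay fires.
#' @param lrTolerance absolute improvement below which an epoch counts as a
#'   stall.
#' @param clipNorm total gradient norm cap (gradients are rescaled so the
#'   norm never exceeds this; default 1.0).
#' @param ucjsdSampleSize size of the equal-length NLL vectors (training,
#'   validation, sampled) used for the per-epoch UC-JSD.
#' @param seed integer master seed; all epoch-level randomness (shuffles,
#'   augmentation, dropout, monitoring subsamples) derives from it.
#' @param augmentation regenerate randomized SMILES for the training *and*
#'   validation sets each epoch; with `FALSE` a single randomized writing is
#'   drawn once and reused (the "no data augmentation" arm). Ignored for the
#'   canonical variant, whose writing is unique.
#' @param sampleMaxLen length cap for monitoring samples; defaults to the
#'   model's `maxLen`.
#' @return a list of class `"trainConfig"`.
#' @export
trainConfig <- function(batchSize = 64L, maxEpochs = 30L, lrInit = 1e-3,
                        lrDecayFactor = 0.7, lrPatience = 5L,
                        lrTolerance = 1e-4, clipNorm = 1.0,
                        ucjsdSampleSize = 512L, seed = 1L,
                        augmentation = TRUE, sampleMaxLen = NULL) {
  stopifnot(batchSize >= 1L, maxEpochs >= 1L, clipNorm > 0,
            lrDecayFactor > 0, lrDecayFactor < 1, lrPatience >= 1L)
  structure(list(batchSize = as.integer(batchSize),
                 maxEpochs = as.integer(maxEpochs), lrInit = lrInit,
                 lrDecayFactor = lrDecayFactor,
                 lrPatience = as.integer(lrPatience),
                 lrTolerance = lrTolerance, clipNorm = clipNorm,
                 ucjsdSampleSize = as.integer(ucjsdSampleSize),
                 seed = as.integer(seed), augmentation = isTRUE(augmentation),
                 sampleMaxLen = sampleMaxLen),
            class = "trainConfig")
}

# number of decay events implied by a UC-JSD history (window-4 smoothing,
# stall counting with an absolute improvement tolerance)
.lrDecayCount <- function(ucjsd, patience, tolerance) {
  if (length(ucjsd) == 0L) return(0L)
  sm <- trailingMean(ucjsd, 4L)
  best <- Inf; stall <- 0L; decays <- 0L
  for (s in sm) {
    if (s < best - tolerance) { best <- s; stall <- 0L }
    else { stall <- stall + 1L
           if (stall %% patience == 0L) decays <- decays + 1L }
  }
  decays
}

#' UC-JSD-driven learning-rate step
#'
#' Applies a window-4 trailing moving average to the per-epoch UC-JSD
#' history; if the smoothed value has not improved (by more than
#' `lrTolerance`) for `lrPatience` consecutive epochs, the learning rate is
#' multiplied by `lrDecayFactor`, otherwise returned unchanged. The rate
#' never increases, and after `e` decay events equals
#' `lrInit * lrDecayFactor^e`.
#'
#' @param history numeric vector of per-epoch UC-JSD values (oldest first).
#' @param currentLr the learning rate in force.
#' @param config a [trainConfig()].
#' @return the learning rate for the next epoch.
#' @export
adaptiveLrStep <- function(history, currentLr, config) {
  stopifnot(length(history) >= 1L)
  now <- .lrDecayCount(history, config$lrPatience, config$lrTolerance)
  before <- .lrDecayCount(history[-length(history)], config$lrPatience,
                          config$lrTolerance)
  if (now > before) currentLr * config$lrDecayFactor else currentLr
}

#' Best-epoch selection from a UC-JSD series
#'
#' Smooths the series with a trailing moving average of window 4 (shorter
#' prefix windows use the available history) and returns the index of the
#' minimum; ties break to the earliest epoch.
#'
#' @param ucjsd numeric vector of per-epoch UC-JSD values.
#' @return integer epoch index (1-based).
#' @export
selectBestEpoch <- function(ucjsd) {
  stopifnot(length(ucjsd) >= 1L)
  which.min(trailingMean(ucjsd, 4L))
}

# per-epoch strings for a variant: canonical strings, one frozen randomized
# writing, or a fresh randomized writing per molecule
.epochStrings <- function(graphs, canonical, variant, augmentation, seed,
                          epoch, tag) {
  if (variant == "canonical") return(canonical)
  restricted <- variant == "randomized_restricted"
  e <- if (augmentation) epoch else 0L
  withSeed(deriveSeed(seed, paste0("aug-", tag), e), {
    vapply(graphs, function(g) {
      writeSmilesGraph(g, sample.int(length(g$elem)),
                       restricted = restricted)
    }, character(1))
  })
}

#' Train a SMILES RNN
#'
#' One epoch: (re)generate the epoch's strings (for randomized variants with
#' augmentation a fresh writing of every training and validation molecule),
#' shuffle, split into minibatches padded with the end token, take an Adam
#' step per batch on the unmasked teacher-forced loss with the total
#' gradient norm clipped at `clipNorm`; then compute the epoch's UC-JSD from
#' equal-length NLL vectors of the training, validation and freshly sampled
#' sets, and apply the adaptive learning-rate step. The vocabulary must
#' cover every string any epoch can produce; an out-of-vocabulary token is a
#' hard error.
#'
#' @param model a freshly initialized [SmilesRNN-class].
#' @param split a [SpaceSplit-class] (canonical training/validation
#'   molecules).
#' @param variant `"canonical"`, `"randomized_restricted"` or
#'   `"randomized_unrestricted"`.
#' @param config a [trainConfig()].
#' @param verbose print one line per epoch.
#' @return a [TrainingRun-class].
#' @export
trainModel <- function(model, split, variant = "randomized_restricted",
                       config = trainConfig(), verbose = FALSE) {
  .checkVariant(variant, c("canonical", "randomized_restricted",
                           "randomized_unrestricted"))
  hp <- model@hparams
  params <- model@params
  vocab <- model@vocab
  cfg <- config
  trainGraphs <- lapply(split@training, parseSmiles)
  validGraphs <- lapply(split@validation, parseSmiles)
  nTrain <- length(trainGraphs)
  if (nTrain == 0L) stop("empty training set")

  adamM <- lapply(params, function(p) p * 0)
  adamV <- lapply(params, function(p) p * 0)
  adamT <- 0L
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  lr <- cfg$lrInit

  records <- data.frame(epoch = integer(0), uc_jsd = numeric(0),
                        learning_rate = numeric(0),
                        mean_train_nll = numeric(0),
                        mean_valid_nll = numeric(0))
  snapshots <- vector("list", cfg$maxEpochs)
  maxClipNorm <- 0

  for (e in seq_len(cfg$maxEpochs)) {
    trainStrs <- .epochStrings(trainGraphs, split@training, variant,
                               cfg$augmentation, cfg$seed, e, "train")
    validStrs <- .epochStrings(validGraphs, split@validation, variant,
                               cfg$augmentation, cfg$seed, e, "valid")
    trainToks <- lapply(trainStrs, tokenizeSmiles)
    ord <- withSeed(deriveSeed(cfg$seed, "shuffle", e), sample.int(nTrain))
    lossSum <- 0; lossRows <- 0L
    batchStarts <- seq(1L, nTrain, by = cfg$batchSize)
    dropRng <- deriveSeed(cfg$seed, "dropout", e)
    withSeed(dropRng, {
      for (bs in batchStarts) {
        rows <- ord[bs:min(bs + cfg$batchSize - 1L, nTrain)]
        X <- encodeBatch(trainToks[rows], vocab)
        lg <- .lossAndGrads(params, hp, X)
        # total-norm clip
        nrm <- sqrt(sum(vapply(lg$grads, function(g) sum(g^2), numeric(1))))
        if (nrm > cfg$clipNorm) {
          sc <- cfg$clipNorm / nrm
          lg$grads <- lapply(lg$grads, function(g) g * sc)
          maxClipNorm <- max(maxClipNorm, cfg$clipNorm)
        } else maxClipNorm <- max(maxClipNorm, nrm)
        adamT <- adamT + 1L
        corr1 <- 1 - beta1^adamT; corr2 <- 1 - beta2^adamT
        for (nm in names(params)) {
          adamM[[nm]] <- beta1 * adamM[[nm]] + (1 - beta1) * lg$grads[[nm]]
          adamV[[nm]] <- beta2 * adamV[[nm]] +
            (1 - beta2) * lg$grads[[nm]]^2
          params[[nm]] <- params[[nm]] -
            lr * (adamM[[nm]] / corr1) / (sqrt(adamV[[nm]] / corr2) + eps)
        }
        lossSum <- lossSum + lg$loss * length(rows)
        lossRows <- lossRows + length(rows)
      }
    })
    meanTrainNll <- lossSum / lossRows

    epModel <- new("SmilesRNN", hparams = hp, params = params, vocab = vocab)
    # equal-size NLL vectors for UC-JSD: subsample the string sets first so
    # only the monitored strings are scored
    nS <- cfg$ucjsdSampleSize
    maxLen <- if (is.null(cfg$sampleMaxLen)) hp$maxLen else cfg$sampleMaxLen
    samp <- sampleSmiles(epModel, nS, maxLen = maxLen,
                         seed = deriveSeed(cfg$seed, "ucjsd-sample", e))
    sub <- function(strs, tag) {
      if (length(strs) == nS) return(strs)
      strs[withSeed(deriveSeed(cfg$seed, tag, e),
                    sample.int(length(strs), nS,
                               replace = length(strs) < nS))]
    }
    trainNlls <- sequenceNllMany(epModel, sub(trainStrs, "sub-train"))
    # degenerate no-validation runs monitor the training strings twice
    monValid <- if (length(validStrs) > 0L) validStrs else trainStrs
    validNlls <- sequenceNllMany(epModel, sub(monValid, "sub-valid"))
    meanValidNll <- mean(validNlls)
    uc <- ucJsd(trainNlls, validNlls, samp$nll)

    records <- rbind(records,
                     data.frame(epoch = e, uc_jsd = uc, learning_rate = lr,
                                mean_train_nll = meanTrainNll,
                                mean_valid_nll = meanValidNll))
    snapshots[[e]] <- params
    lr <- adaptiveLrStep(records$uc_jsd, lr, cfg)
    if (verbose)
      message(sprintf(
        "epoch %3d  uc_jsd %.5f  lr %.2e  train %.3f  valid %.3f",
        e, uc, lr, meanTrainNll, meanValidNll))
  }

  best <- selectBestEpoch(records$uc_jsd)
  run <- new("TrainingRun", records = records, bestEpoch = as.integer(best),
             model = new("SmilesRNN", hparams = hp, params = params,
                         vocab = vocab),
             bestModel = new("SmilesRNN", hparams = hp,
                             params = snapshots[[best]], vocab = vocab),
             config = c(unclass(cfg), list(variant = variant,
                                           maxClipNorm = maxClipNorm)))
  run
}

#' @describeIn trainModel per-epoch records of a [TrainingRun-class].
#' @param run a [TrainingRun-class].
#' @export
epochRecords <- function(run) run@records

#' @describeIn trainModel the epoch selected by the smoothed UC-JSD.
#' @export
bestEpoch <- function(run) run@bestEpoch

#' @describeIn trainModel the model restored at the best epoch.
#' @export
bestModel <- function(run) run@bestModel

#' @export
setMethod("show", "TrainingRun", function(object) {
  cat("TrainingRun (", object@config$variant, "): ",
      nrow(object@records), " epochs, best epoch ", object@bestEpoch,
      " (uc_jsd ", round(object@records$uc_jsd[object@bestEpoch], 5), ")\n",
      sep = "")
})

#' Write the per-epoch training log as CSV
#'
#' Header `epoch,uc_jsd,learning_rate,mean_train_nll,mean_valid_nll`, one
#' row per epoch, reals formatted to 6 decimal places.
#'
#' @param run a [TrainingRun-class].
#' @param path output path.
#' @export
writeEpochLog <- function(run, path) {
  r <- run@records
  lines <- c("epoch,uc_jsd,learning_rate,mean_train_nll,mean_valid_nll",
             sprintf("%d,%s,%s,%s,%s", r$epoch, fmt6(r$uc_jsd),
                     fmt6(r$learning_rate), fmt6(r$mean_train_nll),
                     fmt6(r$mean_valid_nll)))
  writeLines(lines, path)
  invisible(path)
}

#' Augmentation plan for pre-generated epoch files
#'
#' @param variant a string variant.
#' @param epochs number of epoch files.
#' @param baseSeed integer seed; the seed of epoch `e` derives from it.
#' @param regenerateEachEpoch draw a fresh randomized writing per epoch
#'   (ignored for the canonical variant).
#' @return list of class `"augmentationPlan"`.
#' @export
augmentationPlan <- function(variant = "randomized_restricted", epochs = 1L,
                             baseSeed = 1L, regenerateEachEpoch = TRUE) {
  .checkVariant(variant, c("canonical", "randomized_restricted",
                           "randomized_unrestricted"))
  stopifnot(epochs >= 1L)
  structure(list(variant = variant, epochs = as.integer(epochs),
                 baseSeed = as.integer(baseSeed),
                 regenerateEachEpoch = isTRUE(regenerateEachEpoch)),
            class = "augmentationPlan")
}

#' Write per-epoch augmentation files
#'
#' For each epoch writes one `.smi` file (`epoch_0001.smi`, ...) containing
#' one freshly randomized writing per molecule; the molecule multiset of
#' every file is identical, only the strings differ. For the canonical
#' variant all epoch files are identical.
#'
#' @param smiles character vector of molecules (any valid writings).
#' @param plan an [augmentationPlan()].
#' @param outDir output directory (created if needed).
#' @return character vector of file paths.
#' @export
writeAugmentationEpochs <- function(smiles, plan, outDir) {
  stopifnot(length(smiles) > 0L, inherits(plan, "augmentationPlan"))
  if (!dir.exists(outDir))
    if (!dir.create(outDir, recursive = TRUE))
      stop("cannot create directory ", outDir)
  graphs <- lapply(smiles, parseSmiles)
  canonical <- vapply(graphs, .canonicalFromGraph, character(1))
  paths <- character(plan$epochs)
  for (e in seq_len(plan$epochs)) {
    strs <- .epochStrings(graphs, canonical, plan$variant,
                          plan$regenerateEachEpoch, plan$baseSeed, e,
                          "file")
    paths[e] <- file.path(outDir, sprintf("epoch_%04d.smi", e))
    writeLines(strs, paths[e])
  }
  paths
}

#' Benchmark SMILES variants on a toy chemical space
#'
#' Reproduces the benchmark protocol at desk scale: for each variant a model
#' is initialized with the same seed and hyperparameters, trained under the
#' same budget, the best epoch is selected by smoothed UC-JSD, a size-`k`
#' sample with replacement is drawn from that epoch, and the sample is
#' scored against the target space.
#'
#' @param space the target [ChemicalSpace-class].
#' @param split a [SpaceSplit-class].
#' @param variants character vector of variants to compare.
#' @param k sample size for the evaluation.
#' @param config a [trainConfig()].
#' @param layers,width,embedding,dropout,cell,maxLen model hyperparameters.
#' @param seed integer seed for model init and sampling.
#' @param verbose print per-epoch progress.
#' @return a data.frame with one row per variant (ratios, UCC, best epoch,
#'   best UC-JSD); the full [SampleEvaluation-class] objects and
#'   [TrainingRun-class]s are attached as attributes `"evaluations"` and
#'   `"runs"`.
#' @export
runBenchmark <- function(space, split,
                         variants = c("canonical", "randomized_restricted"),
                         k = 10L * spaceSize(space),
                         config = trainConfig(), layers = 2L, width = 64L,
                         embedding = NULL, dropout = 0, cell = "LSTM",
                         maxLen = 64L, seed = 1L, verbose = FALSE) {
  vocab <- spaceVocabulary(space)
  rows <- list(); evals <- list(); runs <- list()
  for (variant in variants) {
    model <- smilesRNN(vocab, layers = layers, width = width,
                       embedding = embedding, dropout = dropout,
                       cell = cell, maxLen = maxLen,
                       seed = deriveSeed(seed, "init-model"))
    run <- trainModel(model, split, variant = variant, config = config,
                      verbose = verbose)
    samp <- sampleSmiles(bestModel(run), k,
                         seed = deriveSeed(seed, paste0("bench-", variant)))
    strs <- ifelse(samp$terminated, samp$smiles, NA_character_)
    ev <- evaluateSample(strs, space)
    rows[[variant]] <- data.frame(
      variant = variant, best_epoch = bestEpoch(run),
      uc_jsd = run@records$uc_jsd[bestEpoch(run)],
      ratio_valid = ev@ratioValid, ratio_in = ev@ratioIn,
      ratio_unique = ev@ratioUnique, completeness = ev@completeness,
      uniformity = ev@uniformity, closedness = ev@closedness, ucc = ev@ucc)
    evals[[variant]] <- ev
    runs[[variant]] <- run
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "evaluations") <- evals
  attr(out, "runs") <- runs
  out
}

#' Vocabulary covering every SMILES variant writable on a space
#'
#' Builds the vocabulary from the canonical strings of all members plus the
#' structural tokens any randomized writing can introduce (branch
#' parentheses, ring-closure digits, bond symbols for the bond orders
#' present), so per-epoch augmentation can never produce an
#' out-of-vocabulary token.
#'
#' @param space a [ChemicalSpace-class] (or character vector of molecules).
#' @return a [TokenVocabulary-class].
#' @export
spaceVocabulary <- function(space) {
  members <- if (is(space, "ChemicalSpace")) space@members else space
  extras <- c("(", ")", as.character(1:9))
  buildVocabulary(members, extraTokens = extras)
}
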