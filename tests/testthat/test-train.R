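tinyConfig <- function(...) {
  trainConfig(batchSize = 8, maxEpochs = 3, lrInit = 5e-3,
              ucjsdSampleSize = 32, seed = 7, ...)
}

test_that("learning-rate decay follows the smoothed UC-JSD stall rule", {
  cfg <- trainConfig(lrDecayFactor = 0.5, lrPatience = 3, lrTolerance = 1e-4)
  # strictly improving history: unchanged
  expect_equal(adaptiveLrStep(c(5, 4, 3, 2, 1), 0.01, cfg), 0.01)
  # flat for patience + 1 epochs: exactly one decay
  lr <- 0.01
  hist <- 1
  decays <- 0L
  for (e in 2:4) {
    hist <- c(hist, 1)
    newLr <- adaptiveLrStep(hist, lr, cfg)
    if (newLr < lr) decays <- decays + 1L
    lr <- newLr
  }
  expect_equal(decays, 1L)
  expect_equal(lr, 0.005)
  # closed form: after e decay events lr = init * factor^e
  lr <- 0.01; hist <- numeric(0); nDecay <- 0L
  for (e in 1:20) {
    hist <- c(hist, 1)
    newLr <- adaptiveLrStep(hist, lr, cfg)
    if (newLr < lr) nDecay <- nDecay + 1L
    lr <- newLr
  }
  expect_equal(lr, 0.01 * 0.5^nDecay)
  expect_gt(nDecay, 1L)
  # never increases
  set.seed(41)
  lr <- 0.01; hist <- numeric(0)
  for (e in 1:30) {
    hist <- c(hist, runif(1))
    newLr <- adaptiveLrStep(hist, lr, cfg)
    expect_lte(newLr, lr)
    lr <- newLr
  }
})

test_that("best-epoch selection uses the window-4 smoothed argmin with earliest ties", {
  expect_equal(selectBestEpoch(c(5, 4, 3, 2, 1)), 5L)
  expect_equal(selectBestEpoch(c(1, 1, 1, 1, 1)), 1L)
  set.seed(13)
  for (i in 1:20) {
    x <- round(runif(sample(4:15, 1)), 2)
    expect_equal(selectBestEpoch(x), oracleSmoothedArgmin(x))
  }
  expect_equal(selectBestEpoch(c(3, 1, 3, 3, 3, 3)),
               oracleSmoothedArgmin(c(3, 1, 3, 3, 3, 3)))
})

test_that("training learns past the uniform baseline and is reproducible", {
  alk <- spaceAlkanes(3)                      # {C, CC, CCC}
  split <- new("SpaceSplit", training = spaceMembers(alk),
               validation = character(0), seed = 1L)
  vocab <- spaceVocabulary(alk)
  m <- smilesRNN(vocab, layers = 1, width = 16, seed = 2, maxLen = 10)
  cfg <- trainConfig(batchSize = 3, maxEpochs = 30, lrInit = 1e-2,
                     ucjsdSampleSize = 16, seed = 5)
  run <- trainModel(m, split, "canonical", cfg)
  v <- vocabSize(vocab)
  # mean payload length 2 -> uniform baseline (L+1) log v
  expect_lt(tail(epochRecords(run)$mean_train_nll, 1), 3 * log(v))
  expect_true(all(epochRecords(run)$uc_jsd >= 0))
  expect_true(all(epochRecords(run)$uc_jsd <= log(3)))
  # determinism without augmentation
  run2 <- trainModel(m, split, "canonical", cfg)
  expect_identical(epochRecords(run), epochRecords(run2))
  # recorded gradient norms never exceed the clip
  expect_lte(run@config$maxClipNorm, cfg$clipNorm + 1e-6)
})

test_that("an overfit canonical run memorizes its ten training molecules", {
  sp <- spaceMedium()
  split <- splitTrainValidation(sp, 10, 10, seed = 42)
  vocab <- spaceVocabulary(sp)
  m <- smilesRNN(vocab, layers = 1, width = 32, seed = 4, maxLen = 40)
  cfg <- trainConfig(batchSize = 2, maxEpochs = 150, lrInit = 1e-2,
                     ucjsdSampleSize = 32, seed = 7)
  run <- trainModel(m, split, "canonical", cfg)
  samp <- sampleSmiles(run@model, 1000, seed = 9)
  recovered <- canonicalizeSmiles(ifelse(samp$terminated, samp$smiles, NA))
  expect_gte(sum(split@training %in% recovered), 9L)
})

test_that("augmentation regenerates strings per epoch; canonical is unaffected", {
  sp <- spaceMedium()
  split <- splitTrainValidation(sp, 30, 10, seed = 3)
  graphs <- lapply(split@training, smilescape:::parseSmiles)
  epochs <- lapply(1:5, function(e)
    smilescape:::.epochStrings(graphs, split@training,
                               "randomized_restricted", TRUE, 11L, e,
                               "train"))
  # consecutive epochs differ in at least one line
  differs <- vapply(1:4, function(e)
    any(epochs[[e]] != epochs[[e + 1L]]), logical(1))
  expect_true(all(differs))
  # every epoch writes the same molecule multiset
  for (e in 1:5) {
    expect_setequal(canonicalizeSmiles(epochs[[e]]), split@training)
  }
  # augmentation off: frozen randomized strings
  frozen1 <- smilescape:::.epochStrings(graphs, split@training,
                                        "randomized_restricted", FALSE, 11L,
                                        1L, "train")
  frozen2 <- smilescape:::.epochStrings(graphs, split@training,
                                        "randomized_restricted", FALSE, 11L,
                                        2L, "train")
  expect_identical(frozen1, frozen2)
  # canonical variant ignores augmentation entirely
  expect_identical(smilescape:::.epochStrings(graphs, split@training,
                                              "canonical", TRUE, 11L, 1L,
                                              "train"),
                   split@training)
})

test_that("epoch augmentation files have the stated layout and contents", {
  d <- file.path(tempdir(), "augtest")
  paths <- writeAugmentationEpochs("C", augmentationPlan(epochs = 5), d)
  expect_equal(basename(paths),
               sprintf("epoch_%04d.smi", 1:5))
  for (p in paths) expect_equal(readLines(p), "C")
  # multi-molecule randomized epochs canonicalize back to the input set,
  # and total distinct strings stay below epochs x molecules
  mols <- sample(spaceMembers(spaceMedium()), 50)
  paths <- writeAugmentationEpochs(
    mols, augmentationPlan("randomized_restricted", 20, baseSeed = 9), d)
  allLines <- unlist(lapply(paths, readLines))
  expect_true(all(canonicalizeSmiles(allLines) %in% mols))
  expect_lt(length(unique(allLines)), 20 * 50)
  # canonical plan: identical files
  paths <- writeAugmentationEpochs(mols, augmentationPlan("canonical", 3), d)
  expect_identical(readLines(paths[1]), readLines(paths[3]))
})

test_that("an out-of-vocabulary validation token is a hard error", {
  vocab <- buildVocabulary(c("CC", "CCO"))   # no "N"
  m <- smilesRNN(vocab, layers = 1, width = 8, seed = 1, maxLen = 10)
  split <- new("SpaceSplit", training = c("CC", "CCO"), validation = "CN",
               seed = 1L)
  expect_error(trainModel(m, split, "canonical", tinyConfig()),
               "out-of-vocabulary")
})

test_that("the epoch log CSV matches the records to six decimals", {
  alk <- spaceAlkanes(4)
  split <- splitTrainValidation(alk, 4, 1, seed = 2)
  m <- smilesRNN(spaceVocabulary(alk), layers = 1, width = 8, seed = 3,
                 maxLen = 12)
  run <- trainModel(m, split, "canonical", tinyConfig())
  f <- tempfile(fileext = ".csv")
  writeEpochLog(run, f)
  lines <- readLines(f)
  expect_equal(lines[1],
               "epoch,uc_jsd,learning_rate,mean_train_nll,mean_valid_nll")
  expect_length(lines, nrow(epochRecords(run)) + 1L)
  got <- read.csv(f)
  expect_equal(got$uc_jsd, round(epochRecords(run)$uc_jsd, 6),
               tolerance = 1e-9)
})
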