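smallVocab <- function() buildVocabulary(c("CCO", "C=O", "CNC", "OCO"))

test_that("initialization is uniform in (-sqrt(1/w), sqrt(1/w)) and reproducible", {
  v <- smallVocab()
  m <- smilesRNN(v, layers = 2, width = 4, seed = 3)
  bound <- sqrt(1 / 4)
  for (p in m@params) expect_true(all(abs(p) < bound))
  m2 <- smilesRNN(v, layers = 2, width = 4, seed = 3)
  expect_identical(m@params, m2@params)
  expect_false(identical(m@params,
                         smilesRNN(v, layers = 2, width = 4, seed = 4)@params))
  # empirical mean of >= 1e5 entries within 3 standard errors of 0
  big <- smilesRNN(v, layers = 2, width = 128, seed = 9)
  entries <- unlist(big@params)
  expect_gte(length(entries), 1e5)
  s <- sqrt(1 / 128)
  se <- (s / sqrt(3)) / sqrt(length(entries))
  expect_lt(abs(mean(entries)), 3 * se)
  expect_error(smilesRNN(v, width = 8, embedding = 16), "must not exceed")
})

test_that("forward step yields normalized, deterministic distributions", {
  v <- smallVocab()
  for (cell in c("LSTM", "GRU")) {
    m <- smilesRNN(v, layers = 2, width = 10, cell = cell, seed = 5)
    fs <- forwardStep(m, c(1L, 2L, 3L))
    expect_equal(rowSums(fs$probs), rep(1, 3), tolerance = 1e-6)
    expect_true(all(fs$probs >= 0))
    fs2 <- forwardStep(m, c(1L, 2L, 3L))
    expect_identical(fs$probs, fs2$probs)
    # zero weights -> exactly uniform
    mu <- uniformModel(v, layers = 1, width = 6, cell = cell)
    expect_equal(as.numeric(forwardStep(mu, 1L)$probs),
                 rep(1 / vocabSize(v), vocabSize(v)))
    expect_error(forwardStep(m, 999L), "out of range")
    badState <- forwardStep(m, c(1L, 2L))$state
    expect_error(forwardStep(m, c(1L, 2L, 3L), badState), "state shape")
  }
})

test_that("uniform-model sequence NLL equals the (L+1) log v closed form", {
  v <- smallVocab()
  nv <- vocabSize(v)
  for (cell in c("LSTM", "GRU")) {
    mu <- uniformModel(v, layers = 2, width = 7, cell = cell)
    for (L in c(1, 2, 5, 11, 20)) {
      s <- paste(rep("C", L), collapse = "")
      expect_equal(sequenceNll(mu, s), (L + 1) * log(nv), tolerance = 1e-9)
    }
  }
})

test_that("sequence NLL matches a step-by-step forward oracle and is non-negative", {
  v <- smallVocab()
  m <- smilesRNN(v, layers = 2, width = 12, seed = 8)
  set.seed(31)
  for (i in 1:100) {
    L <- sample(1:8, 1)
    toks <- c("^", sample(c("C", "N", "O", "="), L, replace = TRUE), "$")
    enc <- tryCatch(encodeTokens(toks, v), error = function(e) NULL)
    if (is.null(enc)) next
    nll <- sequenceNll(m, enc)
    expect_gte(nll, 0)
    st <- NULL; acc <- 0
    for (t in seq_len(length(enc) - 1L)) {
      fs <- forwardStep(m, enc[t], st)
      acc <- acc - log(fs$probs[1, enc[t + 1L]])
      st <- fs$state
    }
    expect_equal(nll, acc, tolerance = 1e-5 * max(1, acc))
  }
  expect_error(sequenceNll(m, encodeTokens(c("^", "C"), v)), "no end token")
})

test_that("batch loss is the unmasked mean including padding targets", {
  v <- smallVocab()
  m <- smilesRNN(v, layers = 1, width = 9, seed = 2)
  # identical rows: batch loss equals the single-row unmasked NLL
  X <- encodeBatch(lapply(c("CCO", "CCO", "CCO"), tokenizeSmiles), v)
  expect_equal(batchLoss(m, X), batchLoss(m, X[1, , drop = FALSE]),
               tolerance = 1e-12)
  # permutation invariance
  X2 <- encodeBatch(lapply(c("CCO", "C=O", "CNC"), tokenizeSmiles), v)
  expect_equal(batchLoss(m, X2), batchLoss(m, X2[c(3, 1, 2), ]),
               tolerance = 1e-12)
  # no padding needed -> coincides with the truncated sequence NLL
  X3 <- encodeBatch(list(tokenizeSmiles("CCO")), v)
  expect_equal(batchLoss(m, X3), sequenceNll(m, "CCO"), tolerance = 1e-12)
  # with padding, the unmasked loss exceeds the truncated NLL
  Xp <- encodeBatch(lapply(c("C", "CCO"), tokenizeSmiles), v)
  expect_gt(batchLoss(m, Xp),
            mean(sequenceNllMany(m, c("C", "CCO"))))
})

test_that("analytic gradients agree with finite differences for both cells", {
  v <- smallVocab()
  X <- encodeBatch(lapply(c("CCO", "C=O", "CNC"), tokenizeSmiles), v)
  for (cell in c("LSTM", "GRU")) {
    m <- smilesRNN(v, layers = 2, width = 6, embedding = 4, cell = cell,
                   seed = 3)
    lg <- smilescape:::.lossAndGrads(m@params, m@hparams, X)
    eps <- 1e-6
    set.seed(77)
    for (nm in names(m@params)) {
      for (ii in sample(length(m@params[[nm]]),
                        min(4, length(m@params[[nm]])))) {
        p2 <- m@params
        p2[[nm]][ii] <- p2[[nm]][ii] + eps
        up <- smilescape:::.lossAndGrads(p2, m@hparams, X)$loss
        p2[[nm]][ii] <- p2[[nm]][ii] - 2 * eps
        dn <- smilescape:::.lossAndGrads(p2, m@hparams, X)$loss
        num <- (up - dn) / (2 * eps)
        expect_equal(lg$grads[[nm]][ii], num,
                     tolerance = 1e-4 * max(1, abs(num)))
      }
    }
  }
})

test_that("sampling is seeded, self-consistent, and honours the length cap", {
  v <- smallVocab()
  m <- smilesRNN(v, layers = 2, width = 16, seed = 7)
  s <- sampleSmiles(m, 60, maxLen = 20, seed = 5)
  expect_identical(s, sampleSmiles(m, 60, maxLen = 20, seed = 5))
  expect_false(identical(s$smiles, sampleSmiles(m, 60, maxLen = 20,
                                                seed = 6)$smiles))
  for (i in which(s$terminated)) {
    expect_equal(sequenceNll(m, s$smiles[i]), s$nll[i], tolerance = 1e-9)
  }
  # uniform model: P(first token = "$") = 1/v within 3 sigma
  vt <- buildVocabulary("C")   # {"$", "C", "^"}
  mu <- uniformModel(vt, layers = 1, width = 5, maxLen = 30)
  draw <- sampleSmiles(mu, 10000, seed = 11)
  pEmpty <- mean(draw$terminated & draw$smiles == "")
  p0 <- 1 / 3
  expect_lt(abs(pEmpty - p0), 3 * sqrt(p0 * (1 - p0) / 10000))
})

test_that("the autoregressive factorization sums to unit probability", {
  # tiny model, v = 4, max_len = 4: enumerate every token sequence and
  # check that terminated strings plus live prefixes carry total mass 1
  vt <- buildVocabulary("CN")
  m <- smilesRNN(vt, layers = 1, width = 5, seed = 13, maxLen = 4)
  endIx <- match("$", vocabTokens(vt))
  beginIx <- match("^", vocabTokens(vt))
  total <- 0
  recurse <- function(prefix, state, p, depth) {
    fs <- forwardStep(m, prefix, state)
    for (tok in seq_len(vocabSize(vt))) {
      pt <- p * fs$probs[1, tok]
      if (tok == endIx || depth == 4L) total <<- total + pt
      else recurse(tok, fs$state, pt, depth + 1L)
    }
  }
  recurse(beginIx, NULL, 1, 1L)
  expect_equal(total, 1, tolerance = 1e-5)
})

test_that("checkpoints restore the model bit-for-bit", {
  v <- smallVocab()
  m <- smilesRNN(v, layers = 2, width = 8, seed = 4)
  f <- tempfile(fileext = ".ckpt")
  saveSmilesRNN(m, f, epoch = 7L)
  m2 <- loadSmilesRNN(f)
  expect_identical(m2@params, m@params)
  expect_identical(sequenceNll(m2, "CCO"), sequenceNll(m, "CCO"))
  saveRDS(list(format = "other"), f)
  expect_error(loadSmilesRNN(f), "not a smilescape checkpoint")
})
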