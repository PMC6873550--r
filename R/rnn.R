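# Recurrent SMILES language model: token embedding -> l stacked LSTM/GRU
# layers of width w (inter-layer dropout) -> linear projection to the
# vocabulary -> softmax. Written in base R matrix algebra; gradients are
# hand-derived backpropagation-through-time, checked against finite
# differences in the test suite.
#
# Gate layouts (column blocks of the packed weight matrices):
#   LSTM: [input | forget | candidate | output], candidate through tanh.
#   GRU:  [reset | update | new], PyTorch-style new gate
#         n = tanh(Wn x + bn + r * (Un h)).

.sigmoid <- function(x) 1 / (1 + exp(-x))

.nGates <- function(cell) if (cell == "LSTM") 4L else 3L

#' Construct and initialize a SMILES RNN
#'
#' Every weight matrix (embeddings, recurrent weights, biases, output
#' projection) is initialized i.i.d. uniform on `(-sqrt(1/w), sqrt(1/w))`.
#' The embedding dimension must not exceed the recurrent width (`m <= w`),
#' so the encoded input is never squeezed; dropout layers exist only
#' *between* recurrent layers (none after the last).
#'
#' @param vocab a [TokenVocabulary-class].
#' @param layers number of recurrent layers `l >= 1`.
#' @param width recurrent cell size `w`.
#' @param embedding embedding dimension `m <= w`; defaults to `w`.
#' @param dropout inter-layer dropout fraction in `[0, 1)`.
#' @param cell `"LSTM"` or `"GRU"`.
#' @param maxLen sampling length cap (tokens).
#' @param seed integer seed; fixed seed gives bitwise-identical parameters.
#' @return a [SmilesRNN-class].
#' @export
smilesRNN <- function(vocab, layers = 2L, width = 64L, embedding = NULL,
                      dropout = 0, cell = c("LSTM", "GRU"), maxLen = 128L,
                      seed = 1L) {
  cell <- match.arg(cell)
  if (is.null(embedding)) embedding <- width
  if (embedding > width)
    stop("embedding dimension m = ", embedding,
         " must not exceed the cell width w = ", width)
  stopifnot(layers >= 1L, width >= 1L, dropout >= 0, dropout < 1,
            maxLen >= 2L)
  v <- vocabSize(vocab)
  s <- sqrt(1 / width)
  G <- .nGates(cell)
  params <- withSeed(deriveSeed(seed, "init"), {
    p <- list(E = matrix(runif(v * embedding, -s, s), v, embedding),
              V = matrix(runif(width * v, -s, s), width, v),
              cOut = runif(v, -s, s))
    for (l in seq_len(layers)) {
      din <- if (l == 1L) embedding else width
      p[[paste0("W", l)]] <- matrix(runif(din * G * width, -s, s),
                                    din, G * width)
      p[[paste0("U", l)]] <- matrix(runif(width * G * width, -s, s),
                                    width, G * width)
      p[[paste0("b", l)]] <- runif(G * width, -s, s)
    }
    p
  })
  new("SmilesRNN",
      hparams = list(layers = as.integer(layers), width = as.integer(width),
                     embedding = as.integer(embedding), dropout = dropout,
                     cell = cell, vocabSize = v, maxLen = as.integer(maxLen)),
      params = params, vocab = vocab)
}

#' @describeIn smilesRNN the hyperparameter list.
#' @param model a [SmilesRNN-class].
#' @export
hyperParams <- function(model) model@hparams

#' @describeIn smilesRNN the model's [TokenVocabulary-class].
#' @export
modelVocabulary <- function(model) model@vocab

#' @export
setMethod("show", "SmilesRNN", function(object) {
  hp <- object@hparams
  cat(sprintf("SmilesRNN: %d x %s(%d), embedding %d, dropout %.2f, vocab %d\n",
              hp$layers, hp$cell, hp$width, hp$embedding, hp$dropout,
              hp$vocabSize))
})

.initState <- function(hp, b) {
  lapply(seq_len(hp$layers), function(l)
    list(h = matrix(0, b, hp$width), c = matrix(0, b, hp$width)))
}

# one recurrent step through all layers; returns probabilities, new state
# and (optionally) the caches needed for backprop
.stepCore <- function(params, hp, xidx, state, dropMasks = NULL,
                      keepCache = FALSE) {
  b <- length(xidx)
  w <- hp$width
  inp <- params$E[xidx, , drop = FALSE]
  caches <- if (keepCache) vector("list", hp$layers)
  newState <- vector("list", hp$layers)
  for (l in seq_len(hp$layers)) {
    h <- state[[l]]$h
    gates <- inp %*% params[[paste0("W", l)]] +
      matrix(params[[paste0("b", l)]], b, .nGates(hp$cell) * w, byrow = TRUE)
    if (hp$cell == "LSTM") {
      gates <- gates + h %*% params[[paste0("U", l)]]
      i <- .sigmoid(gates[, 1:w, drop = FALSE])
      f <- .sigmoid(gates[, w + 1:w, drop = FALSE])
      g <- tanh(gates[, 2 * w + 1:w, drop = FALSE])
      o <- .sigmoid(gates[, 3 * w + 1:w, drop = FALSE])
      cNew <- f * state[[l]]$c + i * g
      tc <- tanh(cNew)
      hNew <- o * tc
      if (keepCache)
        caches[[l]] <- list(x = inp, hPrev = h, cPrev = state[[l]]$c,
                            i = i, f = f, g = g, o = o, tc = tc)
      newState[[l]] <- list(h = hNew, c = cNew)
    } else {
      gh <- h %*% params[[paste0("U", l)]]
      r <- .sigmoid(gates[, 1:w, drop = FALSE] + gh[, 1:w, drop = FALSE])
      z <- .sigmoid(gates[, w + 1:w, drop = FALSE] +
                      gh[, w + 1:w, drop = FALSE])
      ghn <- gh[, 2 * w + 1:w, drop = FALSE]
      n <- tanh(gates[, 2 * w + 1:w, drop = FALSE] + r * ghn)
      hNew <- (1 - z) * n + z * h
      if (keepCache)
        caches[[l]] <- list(x = inp, hPrev = h, r = r, z = z, n = n,
                            ghn = ghn)
      newState[[l]] <- list(h = hNew, c = state[[l]]$c)
    }
    inp <- newState[[l]]$h
    if (!is.null(dropMasks) && l < hp$layers) {
      inp <- inp * dropMasks[[l]]
      if (keepCache) caches[[l]]$outMask <- dropMasks[[l]]
    }
  }
  logits <- inp %*% params$V +
    matrix(params$cOut, b, hp$vocabSize, byrow = TRUE)
  mx <- apply(logits, 1, max)
  ex <- exp(logits - mx)
  probs <- ex / rowSums(ex)
  list(probs = probs, state = newState, topIn = inp,
       caches = caches)
}

#' Single forward step of the RNN
#'
#' Feeds one token per batch row and returns the next-token probability
#' distribution together with the updated hidden state. Dropout is disabled
#' (evaluation mode), so the step is deterministic.
#'
#' @param model a [SmilesRNN-class].
#' @param inputs integer vector of token indices (one per batch row).
#' @param state a state as returned by a previous call, or `NULL` for the
#'   zero initial state.
#' @return list with `probs` (rows sum to 1) and `state`.
#' @export
forwardStep <- function(model, inputs, state = NULL) {
  hp <- model@hparams
  if (any(inputs < 1L | inputs > hp$vocabSize))
    stop("token index out of range")
  if (is.null(state)) state <- .initState(hp, length(inputs))
  if (length(state) != hp$layers ||
      nrow(state[[1]]$h) != length(inputs) ||
      ncol(state[[1]]$h) != hp$width)
    stop("state shape mismatch")
  res <- .stepCore(model@params, hp, inputs, state)
  list(probs = res$probs, state = res$state)
}

# encoded-rows helper: first end-token position per row (NA if absent)
.firstEnd <- function(X, endIdx) {
  apply(X, 1, function(r) {
    p <- which(r == endIdx)
    if (length(p) == 0L) NA_integer_ else p[1]
  })
}

# teacher-forced forward over an encoded batch.
# Returns per-row, per-position NLL matrix (positions = target columns
# 2..ncol(X)) plus caches when training = TRUE.
.forwardBatch <- function(params, hp, X, training = FALSE, dropSeed = NULL) {
  b <- nrow(X); Tt <- ncol(X)
  state <- .initState(hp, b)
  nllMat <- matrix(0, b, Tt - 1L)
  steps <- if (training) vector("list", Tt - 1L)
  masks <- NULL
  for (t in seq_len(Tt - 1L)) {
    if (training && hp$dropout > 0 && hp$layers > 1L) {
      masks <- lapply(seq_len(hp$layers - 1L), function(l)
        matrix(rbinom(b * hp$width, 1L, 1 - hp$dropout), b, hp$width) /
          (1 - hp$dropout))
    }
    res <- .stepCore(params, hp, X[, t], state, dropMasks = masks,
                     keepCache = training)
    tgt <- X[, t + 1L]
    pTgt <- res$probs[cbind(seq_len(b), tgt)]
    nllMat[, t] <- -log(pTgt)
    if (training)
      steps[[t]] <- list(xidx = X[, t], tgt = tgt, probs = res$probs,
                         caches = res$caches, topIn = res$topIn)
    state <- res$state
  }
  list(nllMat = nllMat, steps = steps)
}

#' Teacher-forced negative log-likelihood of one sequence
#'
#' Sums `-log P(next token)` from the step after the begin token through the
#' *first* end token inclusive. This is the reporting NLL of a string: the
#' probability of the whole molecule string ending exactly at `"$"`.
#'
#' @param model a [SmilesRNN-class].
#' @param x a SMILES string, a token character vector (with markers), or an
#'   encoded integer vector.
#' @return NLL in nats (non-negative).
#' @export
sequenceNll <- function(model, x) {
  vocab <- model@vocab
  enc <- if (is.character(x) && length(x) == 1L)
    encodeTokens(tokenizeSmiles(x), vocab)
  else if (is.character(x)) encodeTokens(x, vocab)
  else as.integer(x)
  if (enc[1] != beginIndex(vocab))
    stop("sequence must start with the begin token")
  if (!endIndex(vocab) %in% enc) stop("sequence has no end token")
  sequenceNllMany(model, list(enc))[1]
}

#' Batched truncated sequence NLLs
#'
#' @param model a [SmilesRNN-class].
#' @param xs character vector of SMILES strings, or a list of encoded
#'   integer vectors.
#' @param batchSize forward-pass batch size.
#' @return numeric vector of per-sequence NLLs (nats), truncated at the
#'   first end token.
#' @export
sequenceNllMany <- function(model, xs, batchSize = 256L) {
  vocab <- model@vocab
  encs <- if (is.character(xs))
    lapply(xs, function(s) encodeTokens(tokenizeSmiles(s), vocab))
  else xs
  endIdx <- endIndex(vocab)
  out <- numeric(length(encs))
  for (start in seq(1L, length(encs), by = batchSize)) {
    idx <- start:min(start + batchSize - 1L, length(encs))
    chunk <- encs[idx]
    width <- max(lengths(chunk))
    X <- matrix(endIdx, length(chunk), width)
    for (i in seq_along(chunk)) X[i, seq_along(chunk[[i]])] <- chunk[[i]]
    fb <- .forwardBatch(model@params, model@hparams, X, training = FALSE)
    fe <- .firstEnd(X, endIdx)
    for (i in seq_along(chunk)) {
      out[idx[i]] <- sum(fb$nllMat[i, seq_len(fe[i] - 1L)])
    }
  }
  out
}

#' Unmasked mean batch loss
#'
#' The training loss: the mean over batch rows of the *unmasked* per-row
#' NLL, i.e. including post-end padding positions, whose target is the
#' end/padding token itself. No mask is applied to already-finished
#' sequences; because the padding token equals the end token this does not
#' affect training quality, and when a row needs no padding the unmasked
#' loss coincides with its truncated sequence NLL.
#'
#' @param model a [SmilesRNN-class].
#' @param batch integer matrix of encoded rows (right-padded with the
#'   end-token index), or a character vector of SMILES to encode as one
#'   batch.
#' @return mean NLL in nats.
#' @export
batchLoss <- function(model, batch) {
  if (is.character(batch))
    batch <- encodeBatch(lapply(batch, tokenizeSmiles), model@vocab)
  stopifnot(nrow(batch) >= 1L)
  fb <- .forwardBatch(model@params, model@hparams, batch, training = FALSE)
  mean(rowSums(fb$nllMat))
}

# loss + gradients for a training step (teacher forcing, unmasked).
.lossAndGrads <- function(params, hp, X) {
  b <- nrow(X); w <- hp$width; G <- .nGates(hp$cell)
  fb <- .forwardBatch(params, hp, X, training = TRUE)
  loss <- mean(rowSums(fb$nllMat))
  grads <- lapply(params, function(p) if (is.matrix(p)) p * 0 else p * 0)
  scale <- 1 / b
  dhTime <- lapply(seq_len(hp$layers), function(l) matrix(0, b, w))
  dcTime <- lapply(seq_len(hp$layers), function(l) matrix(0, b, w))
  for (t in rev(seq_along(fb$steps))) {
    st <- fb$steps[[t]]
    dlogits <- st$probs
    dlogits[cbind(seq_len(b), st$tgt)] <-
      dlogits[cbind(seq_len(b), st$tgt)] - 1
    dlogits <- dlogits * scale
    grads$V <- grads$V + crossprod(st$topIn, dlogits)
    grads$cOut <- grads$cOut + colSums(dlogits)
    dAbove <- tcrossprod(dlogits, params$V)   # grad wrt top layer output
    for (l in rev(seq_len(hp$layers))) {
      cache <- st$caches[[l]]
      dh <- dAbove
      if (!is.null(cache$outMask)) dh <- dh * cache$outMask
      dh <- dh + dhTime[[l]]
      Wl <- paste0("W", l); Ul <- paste0("U", l); bl <- paste0("b", l)
      if (hp$cell == "LSTM") {
        dcell <- dh * cache$o * (1 - cache$tc^2) + dcTime[[l]]
        dG <- cbind((dcell * cache$g) * cache$i * (1 - cache$i),
                    (dcell * cache$cPrev) * cache$f * (1 - cache$f),
                    (dcell * cache$i) * (1 - cache$g^2),
                    (dh * cache$tc) * cache$o * (1 - cache$o))
        grads[[Wl]] <- grads[[Wl]] + crossprod(cache$x, dG)
        grads[[Ul]] <- grads[[Ul]] + crossprod(cache$hPrev, dG)
        grads[[bl]] <- grads[[bl]] + colSums(dG)
        dAbove <- tcrossprod(dG, params[[Wl]])
        dhTime[[l]] <- tcrossprod(dG, params[[Ul]])
        dcTime[[l]] <- dcell * cache$f
      } else {
        dn <- dh * (1 - cache$z)
        dz <- dh * (cache$hPrev - cache$n)
        dhPrev <- dh * cache$z
        dan <- dn * (1 - cache$n^2)
        dr <- dan * cache$ghn
        dar <- dr * cache$r * (1 - cache$r)
        daz <- dz * cache$z * (1 - cache$z)
        Un <- params[[Ul]][, 2 * w + 1:w, drop = FALSE]
        Ur <- params[[Ul]][, 1:w, drop = FALSE]
        Uz <- params[[Ul]][, w + 1:w, drop = FALSE]
        dhPrev <- dhPrev + tcrossprod(dan * cache$r, Un) +
          tcrossprod(dar, Ur) + tcrossprod(daz, Uz)
        dG <- cbind(dar, daz, dan)
        grads[[Wl]] <- grads[[Wl]] + crossprod(cache$x, dG)
        grads[[bl]] <- grads[[bl]] + colSums(dG)
        dUG <- cbind(dar, daz, dan * cache$r)
        grads[[Ul]] <- grads[[Ul]] + crossprod(cache$hPrev, dUG)
        dAbove <- tcrossprod(dG, params[[Wl]])
        dhTime[[l]] <- dhPrev
      }
    }
    # dAbove is now the gradient wrt the embedded input at step t
    agg <- rowsum(dAbove, group = st$xidx)
    rows <- as.integer(rownames(agg))
    grads$E[rows, ] <- grads$E[rows, , drop = FALSE] + agg
  }
  list(loss = loss, grads = grads)
}

#' Sample strings from the model
#'
#' Autoregressive multinomial sampling at temperature 1: starting from the
#' begin token and the zero state, tokens are drawn from the softmax
#' distribution until the end token or `maxLen` tokens. The reported NLL of
#' each sequence is the sum of `-log p` of the drawn tokens through the end
#' token, and equals `sequenceNll()` recomputed on the re-encoded string.
#' Sequences that hit `maxLen` without an end token are flagged
#' non-terminated (and should be counted invalid downstream).
#'
#' @param model a [SmilesRNN-class].
#' @param n number of sequences.
#' @param maxLen length cap; defaults to the model's `maxLen`.
#' @param seed integer seed.
#' @param batchSize rows sampled per forward sweep.
#' @return data.frame with columns `smiles`, `nll`, `terminated`.
#' @export
sampleSmiles <- function(model, n, maxLen = NULL, seed = 1L,
                         batchSize = 1024L) {
  hp <- model@hparams
  if (is.null(maxLen)) maxLen <- hp$maxLen
  stopifnot(n >= 1L, maxLen >= 2L)
  vocab <- model@vocab
  bIdx <- beginIndex(vocab); eIdx <- endIndex(vocab)
  v <- hp$vocabSize
  cum <- upper.tri(matrix(0, v, v), diag = TRUE)  # for row-wise cumsum
  allS <- character(0); allN <- numeric(0); allT <- logical(0)
  chunkSeed <- deriveSeed(seed, "sample")
  nChunks <- ceiling(n / batchSize)
  for (ch in seq_len(nChunks)) {
    b <- min(batchSize, n - (ch - 1L) * batchSize)
    res <- withSeed(deriveSeed(chunkSeed, "chunk", ch), {
      state <- .initState(hp, b)
      cur <- rep(bIdx, b)
      active <- rep(TRUE, b)
      nll <- numeric(b)
      toks <- matrix(NA_integer_, b, maxLen)
      tUsed <- 0L
      for (t in seq_len(maxLen)) {
        stp <- .stepCore(model@params, hp, cur, state)
        state <- stp$state
        u <- runif(b)
        cdf <- stp$probs %*% cum
        pick <- max.col(cdf >= u, ties.method = "first")
        p <- stp$probs[cbind(seq_len(b), pick)]
        nll[active] <- nll[active] - log(p[active])
        toks[, t] <- ifelse(active, pick, NA_integer_)
        tUsed <- t
        active <- active & pick != eIdx
        if (!any(active)) break
        cur <- ifelse(active, pick, eIdx)
      }
      terminated <- !active
      smiles <- vapply(seq_len(b), function(i) {
        seqToks <- toks[i, !is.na(toks[i, ])]
        stopAt <- match(eIdx, seqToks)
        if (!is.na(stopAt)) seqToks <- seqToks[seq_len(stopAt - 1L)]
        paste(vocab@tokens[seqToks], collapse = "")
      }, character(1))
      list(smiles = smiles, nll = nll, terminated = terminated)
    })
    allS <- c(allS, res$smiles); allN <- c(allN, res$nll)
    allT <- c(allT, res$terminated)
  }
  data.frame(smiles = allS, nll = allN, terminated = allT)
}

#' Save / load a model checkpoint
#'
#' The checkpoint stores a format tag, the hyperparameters, all parameter
#' matrices, the vocabulary and optional epoch metadata; loading reproduces
#' `sequenceNll` bit-for-bit on the saving platform.
#'
#' @param model a [SmilesRNN-class].
#' @param path checkpoint file path.
#' @param epoch optional epoch metadata.
#' @export
saveSmilesRNN <- function(model, path, epoch = NA_integer_) {
  saveRDS(list(format = "smilescape-ckpt-1", hparams = model@hparams,
               params = model@params, tokens = model@vocab@tokens,
               epoch = epoch), path)
  invisible(path)
}

#' @rdname saveSmilesRNN
#' @export
loadSmilesRNN <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "smilescape-ckpt-1"))
    stop("not a smilescape checkpoint: ", path)
  new("SmilesRNN", hparams = ck$hparams, params = ck$params,
      vocab = new("TokenVocabulary", tokens = ck$tokens))
}
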