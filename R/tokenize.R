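#' Tokenize a SMILES string
#'
#' Splits a SMILES (or DeepSMILES) string into model tokens. Tokenization is
#' character-based with three exceptions: the two-letter halogens `"Cl"` and
#' `"Br"` are single tokens, a bracket expression such as `"[nH]"` or
#' `"[O-]"` is a single token, and `"%"` followed by exactly two digits (a
#' ring-closure number above 9) is a single token. The begin token `"^"` is
#' prepended and the end token `"$"` appended.
#'
#' Validity of the molecule is not checked here; any SMILES-like text can be
#' tokenized as long as brackets and `%` escapes are well formed.
#'
#' @param smiles a single string.
#' @param markers prepend/append the begin and end tokens (default `TRUE`).
#' @return character vector of tokens.
#' @examples
#' tokenizeSmiles("Clc1ccccc1Br")
#' @export
tokenizeSmiles <- function(smiles, markers = TRUE) {
  stopifnot(is.character(smiles), length(smiles) == 1L, !is.na(smiles))
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n <- length(chars)
  out <- character(0)
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unterminated bracket expression in '", smiles, "'")
      out <- c(out, paste(chars[i:j], collapse = ""))
      i <- j + 1L
    } else if (ch == "%") {
      if (i + 2L > n || !all(grepl("[0-9]", chars[(i + 1L):(i + 2L)])))
        stop("'%' must be followed by exactly two digits in '", smiles, "'")
      out <- c(out, paste(chars[i:(i + 2L)], collapse = ""))
      i <- i + 3L
    } else if (ch == "C" && i < n && chars[i + 1L] == "l") {
      out <- c(out, "Cl"); i <- i + 2L
    } else if (ch == "B" && i < n && chars[i + 1L] == "r") {
      out <- c(out, "Br"); i <- i + 2L
    } else {
      out <- c(out, ch); i <- i + 1L
    }
  }
  if (markers) c("^", out, "$") else out
}

#' Reassemble a SMILES string from tokens
#'
#' Concatenates the tokens strictly between the begin token and the *first*
#' end token; everything after the first `"$"` (padding) is ignored.
#' `detokenizeSmiles(tokenizeSmiles(s))` is the identity for any tokenizable
#' `s`.
#'
#' @param tokens character vector starting with `"^"`.
#' @return a single string.
#' @export
detokenizeSmiles <- function(tokens) {
  if (length(tokens) == 0L || tokens[1] != "^")
    stop("token sequence must start with the begin token '^'")
  body <- tokens[-1]
  stopAt <- match("$", body)
  if (!is.na(stopAt)) body <- body[seq_len(stopAt - 1L)]
  paste(body, collapse = "")
}

#' Build a token vocabulary from a corpus
#'
#' Tokenizes every string and collects the distinct tokens, always including
#' the begin and end markers. Tokens are ordered lexicographically (radix
#' sort, locale-independent) so that the index assignment is reproducible
#' regardless of corpus line order.
#'
#' @param corpus character vector of SMILES strings.
#' @param extraTokens tokens to force into the vocabulary even if absent from
#'   the corpus (used to make augmented corpora encodable: randomized
#'   writings may use ring-closure digits or bond/branch tokens that the
#'   canonical strings do not).
#' @return a [TokenVocabulary-class].
#' @export
buildVocabulary <- function(corpus, extraTokens = character(0)) {
  stopifnot(length(corpus) > 0L)
  toks <- lapply(seq_along(corpus), function(i) {
    tryCatch(tokenizeSmiles(corpus[i]),
             error = function(e) stop("line ", i, ": ", conditionMessage(e),
                                      call. = FALSE))
  })
  new("TokenVocabulary",
      tokens = sortC(unique(c("^", "$", unlist(toks), extraTokens))))
}

#' @describeIn buildVocabulary number of tokens `v` in the vocabulary.
#' @param vocab a [TokenVocabulary-class].
#' @export
vocabSize <- function(vocab) length(vocab@tokens)

#' @describeIn buildVocabulary the token character vector (position = index).
#' @export
vocabTokens <- function(vocab) vocab@tokens

endIndex <- function(vocab) match("$", vocab@tokens)
beginIndex <- function(vocab) match("^", vocab@tokens)

#' Encode tokens as integer indices
#'
#' Indices are 1-based positions in the vocabulary. An out-of-vocabulary
#' token is a hard error (a silent skip would corrupt downstream NLL
#' comparisons between training, validation and sampled sets).
#'
#' @param tokens character vector of tokens.
#' @param vocab a [TokenVocabulary-class].
#' @return integer vector.
#' @export
encodeTokens <- function(tokens, vocab) {
  idx <- match(tokens, vocab@tokens)
  if (anyNA(idx))
    stop("out-of-vocabulary token(s): ",
         paste(unique(tokens[is.na(idx)]), collapse = ", "))
  idx
}

#' @rdname encodeTokens
#' @param indices integer vector of token indices.
#' @export
decodeIndices <- function(indices, vocab) {
  if (any(indices < 1L | indices > length(vocab@tokens)))
    stop("token index out of range")
  vocab@tokens[indices]
}

# Encode a list of token vectors into a right-padded integer matrix
# (rows = sequences, columns = longest sequence in the batch, padding = the
# end-token index, mirroring end-token padding without masks).
encodeBatch <- function(tokenList, vocab) {
  stopifnot(length(tokenList) > 0L)
  enc <- lapply(tokenList, encodeTokens, vocab = vocab)
  width <- max(lengths(enc))
  pad <- endIndex(vocab)
  mat <- matrix(pad, nrow = length(enc), ncol = width)
  for (i in seq_along(enc)) mat[i, seq_along(enc[[i]])] <- enc[[i]]
  mat
}

#' Serialize / load a vocabulary as plain text
#'
#' One token per line; the line number is the token index. Loading is
#' bit-exact.
#'
#' @param vocab a [TokenVocabulary-class].
#' @param path file path.
#' @export
writeVocabulary <- function(vocab, path) {
  writeLines(vocab@tokens, path)
  invisible(path)
}

#' @rdname writeVocabulary
#' @export
readVocabulary <- function(path) {
  new("TokenVocabulary", tokens = readLines(path))
}

#' @export
setMethod("show", "TokenVocabulary", function(object) {
  cat("TokenVocabulary with", length(object@tokens), "tokens\n")
  cat(" ", paste(object@tokens, collapse = " "), "\n")
})
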