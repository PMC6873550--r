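#' @importFrom methods new validObject is slot
#' @importFrom stats runif rbinom
#' @importFrom utils head tail
NULL

# Deterministic child-seed derivation: every source of randomness in the
# package flows from one integer seed plus a purpose tag, so that fixtures,
# epoch augmentation and sampling are reproducible call by call.
# Arithmetic kept in doubles below 2^31 (R integers are 32-bit).
deriveSeed <- function(seed, tag, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- 0
  for (ch in utf8ToInt(as.character(tag))) h <- (h * 31 + ch) %% 2147483647
  val <- (abs(seed) * 48271 + h * 16807 + index * 69621 + 1) %% 2147483647
  as.integer(val)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is left untouched.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# locale-independent lexicographic sort
sortC <- function(x) sort(x, method = "radix")

trailingMean <- function(x, window) {
  vapply(seq_along(x), function(i) {
    lo <- max(1L, i - window + 1L)
    mean(x[lo:i])
  }, numeric(1))
}

logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

fmt6 <- function(x) formatC(x, digits = 6, format = "f")
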