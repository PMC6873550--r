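# Evaluation mathematics: Shannon entropy, Jensen-Shannon divergence,
# UC-JSD, the ideal-sampler recovery expectation phi(k), and the
# completeness / uniformity / closedness / UCC coverage scores.
# All entropies and NLLs are in natural log units (nats).

#' Shannon entropy of a probability vector (nats)
#'
#' @param p numeric vector of probabilities, non-negative and summing to 1
#'   (within 1e-9); `0 * log(0)` is taken as 0.
#' @return entropy in `[0, log(length(p))]`.
#' @export
shannonEntropy <- function(p) {
  if (any(p < 0)) stop("probabilities must be non-negative")
  if (abs(sum(p) - 1) > 1e-9) stop("probabilities must sum to 1")
  nz <- p > 0
  -sum(p[nz] * log(p[nz]))
}

#' Jensen-Shannon divergence between distributions (nats)
#'
#' `JSD = H(sum_i alpha_i d_i) - sum_i alpha_i H(d_i)`: the entropy of the
#' weighted mixture minus the weighted mean entropy. Zero iff all
#' distributions are identical; bounded above by the entropy of the weight
#' vector.
#'
#' @param distributions a matrix with one distribution per row (or a list of
#'   equal-length probability vectors).
#' @param weights positive weights summing to 1; default uniform.
#' @return JSD in nats.
#' @export
jsd <- function(distributions, weights = NULL) {
  if (is.list(distributions)) {
    if (length(unique(lengths(distributions))) != 1L)
      stop("distributions must have a common support dimension")
    distributions <- do.call(rbind, distributions)
  }
  m <- nrow(distributions)
  if (is.null(weights)) weights <- rep(1 / m, m)
  if (length(weights) != m || any(weights <= 0) ||
      abs(sum(weights) - 1) > 1e-9)
    stop("weights must be positive and sum to 1")
  mixture <- colSums(distributions * weights)
  shannonEntropy(mixture) -
    sum(weights * apply(distributions, 1, shannonEntropy))
}

#' Uniformity-Completeness JSD of three NLL vectors
#'
#' Each of the training, validation and sampled NLL vectors (equal length,
#' element order preserved -- no sorting) is divided by its sum, turning it
#' into a probability distribution with one value per molecule; the JSD of
#' the three distributions with weights 1/3 is returned. The value lies in
#' `[0, log(3)]` and approaches 0 when the three sets have near-uniform,
#' matching NLL profiles -- the signature of a complete, uniform generator.
#' Note the per-vector normalization: scaling *one* vector by a positive
#' constant leaves UC-JSD unchanged, but UC-JSD is not invariant under a
#' common shift of all NLLs.
#'
#' @param training,validation,sampled equal-length numeric NLL vectors
#'   (nats, non-negative, strictly positive sums).
#' @param sorted sort each vector before normalization (sensitivity-analysis
#'   mode; the standard metric leaves element order untouched).
#' @return UC-JSD in nats.
#' @export
ucJsd <- function(training, validation, sampled, sorted = FALSE) {
  lens <- c(length(training), length(validation), length(sampled))
  if (length(unique(lens)) != 1L)
    stop("the three NLL vectors must have the same length")
  vecs <- list(training, validation, sampled)
  if (sorted) vecs <- lapply(vecs, sort)
  sums <- vapply(vecs, sum, numeric(1))
  if (any(sums <= 0)) stop("NLL vectors must have strictly positive sums")
  if (any(vapply(vecs, function(v) any(v < 0), logical(1))))
    stop("NLL vectors must be non-negative")
  dists <- do.call(rbind, Map(`/`, vecs, sums))
  jsd(dists, weights = rep(1 / 3, 3))
}

#' Expected unique fraction under ideal sampling with replacement
#'
#' `phi(k, N) = 1 - (1 - 1/N)^k`: the expected fraction of a size-N space
#' recovered by k uniform draws with replacement from the ideal model.
#' Evaluated in log space (`-expm1(k * log1p(-1/N))`) so that astronomically
#' large `k` and `N` (e.g. k = 2e9 draws from a 9.75e8-molecule database)
#' are handled without underflow. `phi(0, N) = 0`; strictly increasing in
#' `k`; tends to 1 as `k` grows.
#'
#' @param k number of draws (non-negative, may be fractional/huge).
#' @param N space size (>= 1).
#' @return expected unique fraction in `[0, 1]`.
#' @examples
#' phi(2e9, 9.75e8)  # ~0.871
#' @export
phi <- function(k, N) {
  stopifnot(all(k >= 0), all(N >= 1))
  ifelse(N == 1, as.numeric(k >= 1), -expm1(k * log1p(-1 / N)))
}

#' Evaluate a generated sample against a target chemical space
#'
#' Computes the coverage statistics of a size-`k` sample with replacement:
#' `valid` counts strings that parse to a valid molecule, `in` counts valid
#' strings whose canonical form lies in the space (both with repeats), and
#' `unique` counts the distinct space members recovered. The ratios and
#' composites follow:
#' `ratio_valid = |valid|/k`, `closedness = ratio_in = |in|/k`,
#' `ratio_unique = |unique|/N`, `completeness = ratio_unique / phi(k, N)`,
#' `uniformity = ratio_unique / phi(|in|, N)`, and
#' `UCC = completeness * uniformity * closedness`.
#' Completeness and uniformity are not clamped at 1: finite-sample
#' fluctuation slightly above 1 is possible and reported as-is.
#'
#' @param sampled character vector of sampled SMILES (with repeats); `NA`
#'   entries (e.g. non-terminated sequences) count as invalid.
#' @param space the target [ChemicalSpace-class].
#' @return a [SampleEvaluation-class].
#' @export
evaluateSample <- function(sampled, space) {
  stopifnot(length(sampled) > 0L)
  if (spaceSize(space) == 0L) stop("empty space")
  k <- length(sampled)
  N <- spaceSize(space)
  # canonicalize each distinct string once; repeats share the result
  tab <- table(sampled, useNA = "no")
  uniq <- names(tab)
  counts <- as.numeric(tab)
  canon <- canonicalizeSmiles(uniq)
  valid <- !is.na(canon)
  inSpace <- valid & canon %in% space@members
  nValid <- sum(counts[valid])
  nIn <- sum(counts[inSpace])
  nUnique <- length(unique(canon[inSpace]))
  phiK <- phi(k, N)
  phiIn <- phi(nIn, N)
  ratioUnique <- nUnique / N
  completeness <- ratioUnique / phiK
  uniformity <- if (nIn == 0) 0 else ratioUnique / phiIn
  closedness <- nIn / k
  new("SampleEvaluation", k = k, nValid = nValid, nIn = nIn,
      nUnique = nUnique, spaceSize = N,
      ratioValid = nValid / k, ratioIn = closedness,
      ratioUnique = ratioUnique, completeness = completeness,
      uniformity = uniformity, closedness = closedness,
      ucc = completeness * uniformity * closedness,
      phiK = phiK, phiIn = phiIn)
}

#' Unified coverage score UCC
#'
#' The product `completeness x uniformity x closedness`: a single score that
#' heavily penalizes a model that is weak on any one component.
#'
#' @param completeness either a [SampleEvaluation-class] or the completeness
#'   value.
#' @param uniformity,closedness component scores (ignored when a
#'   [SampleEvaluation-class] is given).
#' @return the three-way product.
#' @examples
#' ucc(0.836, 0.879, 0.861)  # 0.633
#' @export
ucc <- function(completeness, uniformity = NULL, closedness = NULL) {
  if (is(completeness, "SampleEvaluation"))
    return(completeness@completeness * completeness@uniformity *
             completeness@closedness)
  completeness * uniformity * closedness
}

#' @export
setMethod("show", "SampleEvaluation", function(object) {
  cat("SampleEvaluation: k =", object@k, "against a space of",
      object@spaceSize, "molecules\n")
  cat(sprintf("  valid %d (ratio %.4f)   in-space %d (closedness %.4f)\n",
              object@nValid, object@ratioValid, object@nIn,
              object@closedness))
  cat(sprintf("  unique members %d (ratio_unique %.4f)\n",
              object@nUnique, object@ratioUnique))
  cat(sprintf("  completeness %.4f   uniformity %.4f   UCC %.4f\n",
              object@completeness, object@uniformity, object@ucc))
})

#' Serialize a sample evaluation as report JSON
#'
#' @param ev a [SampleEvaluation-class].
#' @param path output path.
#' @export
writeEvaluationReport <- function(ev, path) {
  rep <- list(k = ev@k, n_valid = ev@nValid, n_in = ev@nIn,
              n_unique = ev@nUnique,
              ratio_valid = round(ev@ratioValid, 6),
              ratio_in = round(ev@ratioIn, 6),
              ratio_unique = round(ev@ratioUnique, 6),
              completeness = round(ev@completeness, 6),
              uniformity = round(ev@uniformity, 6),
              closedness = round(ev@closedness, 6),
              ucc = round(ev@ucc, 6),
              space_size = ev@spaceSize,
              phi_k = round(ev@phiK, 6), phi_in = round(ev@phiIn, 6))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Molecule-level negative log-likelihood under a model
#'
#' The probability of a *molecule* is the sum of the probabilities of all
#' its distinct SMILES writings of the given variant; the molecule NLL is
#' `-log` of that sum. In `"exact"` mode all writings are enumerated
#' (guarded by `maxHeavyAtoms`); in `"estimate"` mode the sum runs over the
#' distinct strings found in `budget` randomized draws, a lower bound on the
#' probability and hence an upper bound on the molecule NLL. For the
#' canonical variant the molecule NLL is simply the NLL of the canonical
#' string.
#'
#' @param model a [SmilesRNN-class].
#' @param smiles the molecule (any valid writing).
#' @param variant `"canonical"` or a randomized kind.
#' @param mode `"exact"` or `"estimate"`.
#' @param budget number of randomized draws in estimate mode.
#' @param seed integer seed for estimate mode.
#' @param maxHeavyAtoms exhaustive-mode guard.
#' @return molecule NLL in nats.
#' @export
moleculeNll <- function(model, smiles, variant = "randomized_restricted",
                        mode = c("exact", "estimate"), budget = 1000L,
                        seed = 1L, maxHeavyAtoms = 8L) {
  mode <- match.arg(mode)
  .checkVariant(variant, c("canonical", "randomized_restricted",
                           "randomized_unrestricted"))
  if (variant == "canonical") {
    return(sequenceNll(model, canonicalizeSmiles(smiles)))
  }
  if (mode == "exact") {
    strs <- enumerateRandomSmiles(smiles, variant, maxHeavyAtoms)
  } else {
    if (budget < 1L) stop("budget must be >= 1")
    g <- parseSmiles(smiles)
    n <- .nAtoms(g)
    restricted <- variant == "randomized_restricted"
    strs <- unique(withSeed(deriveSeed(seed, "moleculeNll"), {
      vapply(seq_len(budget), function(i) {
        writeSmilesGraph(g, sample.int(n), restricted = restricted)
      }, character(1))
    }))
  }
  nlls <- vapply(strs, function(s) sequenceNll(model, s), numeric(1))
  -logSumExp(-nlls)
}
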