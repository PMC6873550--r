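# SMILES writers: depth-first graph traversal driven by an atom priority
# vector. The same machinery implements the canonical writer (priorities =
# canonical ranks from iterative invariant refinement with backtracking
# tie-break) and the two randomized writers (priorities = a random atom
# permutation). The "restricted" writer emits minimal-parenthesis strings;
# the "unrestricted" writer follows the permutation literally and may wrap
# the final child of an atom in a redundant branch (yielding strings such as
# c1cc(c(cc1)) on a benzene ring) -- making its output set a strict superset
# of the restricted one.

.VARIANTS <- c("canonical", "randomized_restricted", "randomized_unrestricted",
               "deepsmiles_rings", "deepsmiles_branches", "deepsmiles_both")

.checkVariant <- function(variant, allowed = .VARIANTS) {
  if (length(variant) != 1L || !variant %in% allowed)
    stop("unknown variant '", paste(variant, collapse = ","),
         "'; expected one of: ", paste(allowed, collapse = ", "))
  variant
}

.adjacency <- function(g) {
  n <- .nAtoms(g)
  adj <- replicate(n, integer(0), simplify = FALSE)
  bnd <- replicate(n, integer(0), simplify = FALSE)
  if (nrow(g$bonds) > 0) {
    for (b in seq_len(nrow(g$bonds))) {
      i <- g$bonds[b, 1]; j <- g$bonds[b, 2]
      adj[[i]] <- c(adj[[i]], j); bnd[[i]] <- c(bnd[[i]], b)
      adj[[j]] <- c(adj[[j]], i); bnd[[j]] <- c(bnd[[j]], b)
    }
  }
  list(adj = adj, bnd = bnd)
}

.atomSymbol <- function(g, a) {
  elem <- g$elem[a]
  sym <- if (g$arom[a]) tolower(elem) else elem
  plain <- elem %in% .ORGANIC_SUBSET && g$charge[a] == 0L &&
    is.na(g$isotope[a]) && is.na(g$hcount[a])
  if (plain) return(sym)
  h <- g$hcount[a]
  hstr <- if (is.na(h) || h == 0L) "" else if (h == 1L) "H" else paste0("H", h)
  ch <- g$charge[a]
  cstr <- if (ch == 0L) "" else if (ch == 1L) "+" else if (ch == -1L) "-"
          else if (ch > 0L) paste0("+", ch) else paste0("-", -ch)
  istr <- if (is.na(g$isotope[a])) "" else g$isotope[a]
  paste0("[", istr, sym, hstr, cstr, "]")
}

.bondSymbol <- function(g, b) {
  if (g$baro[b]) return("")
  o <- g$bonds[b, 3]
  if (o == 2L) return("=")
  if (o == 3L) return("#")
  # explicit single between two aromatic atoms (e.g. biphenyl)
  if (g$arom[g$bonds[b, 1]] && g$arom[g$bonds[b, 2]]) return("-")
  ""
}

# Write a molgraph as SMILES following atom priorities `ranks` (lower value =
# visited earlier; the start atom is the global minimum).
writeSmilesGraph <- function(g, ranks, restricted = TRUE) {
  n <- .nAtoms(g)
  stopifnot(length(ranks) == n)
  if (n == 1L) return(.atomSymbol(g, 1L))
  ad <- .adjacency(g)

  visited <- logical(n)
  visitIdx <- integer(n)
  parent <- integer(n)
  children <- replicate(n, integer(0), simplify = FALSE)
  ringAt <- replicate(n, integer(0), simplify = FALSE)  # bond ids per atom
  edgeSeen <- logical(nrow(g$bonds))
  counter <- 0L

  dfs <- function(a) {
    visited[a] <<- TRUE
    counter <<- counter + 1L
    visitIdx[a] <<- counter
    nbrs <- ad$adj[[a]][order(ranks[ad$adj[[a]]])]
    bnds <- ad$bnd[[a]][order(ranks[ad$adj[[a]]])]
    for (k in seq_along(nbrs)) {
      nb <- nbrs[k]; be <- bnds[k]
      if (edgeSeen[be]) next
      if (visited[nb]) {
        edgeSeen[be] <<- TRUE
        ringAt[[a]] <<- c(ringAt[[a]], be)
        ringAt[[nb]] <<- c(ringAt[[nb]], be)
      } else {
        edgeSeen[be] <<- TRUE
        parent[nb] <<- a
        children[[a]] <<- c(children[[a]], nb)
        dfs(nb)
      }
    }
  }
  start <- which.min(ranks)
  dfs(start)
  if (counter < n) stop("molecular graph is disconnected")

  # ring-closure digit assignment in output (visit) order
  ringBonds <- unique(unlist(ringAt))
  digitOf <- integer(nrow(g$bonds))
  openDigits <- character(0)
  inUse <- logical(99)
  order_ <- order(visitIdx)
  closeStrs <- character(n); openStrs <- character(n)
  for (a in order_) {
    bs <- ringAt[[a]]
    if (length(bs) == 0L) next
    other <- vapply(bs, function(b) {
      ij <- g$bonds[b, 1:2]; if (ij[1] == a) ij[2] else ij[1]
    }, integer(1))
    closing <- bs[visitIdx[other] < visitIdx[a]]
    opening <- bs[visitIdx[other] > visitIdx[a]]
    # closings sorted by assigned digit, then free
    if (length(closing) > 0L) {
      dg <- digitOf[closing]
      closing <- closing[order(dg)]
      closeStrs[a] <- paste(vapply(closing, function(b) {
        d <- digitOf[b]; inUse[d] <<- FALSE
        paste0(if (d > 9L) paste0("%", d) else d)
      }, character(1)), collapse = "")
    }
    # openings sorted by partner visit order; smallest free digit each
    if (length(opening) > 0L) {
      otherO <- other[visitIdx[other] > visitIdx[a]]
      opening <- opening[order(visitIdx[otherO])]
      openStrs[a] <- paste(vapply(opening, function(b) {
        d <- which(!inUse)[1]
        inUse[d] <<- TRUE
        digitOf[b] <<- d
        paste0(.bondSymbol(g, b), if (d > 9L) paste0("%", d) else d)
      }, character(1)), collapse = "")
    }
  }

  bondOf <- function(a, c) ad$bnd[[a]][match(c, ad$adj[[a]])]
  render <- function(a) {
    out <- paste0(.atomSymbol(g, a), closeStrs[a], openStrs[a])
    ch <- children[[a]]
    m <- length(ch)
    if (m == 0L) return(out)
    for (k in seq_len(m)) {
      c <- ch[k]
      piece <- paste0(.bondSymbol(g, bondOf(a, c)), render(c))
      lastPlain <- k == m &&
        (restricted || ranks[c] > ranks[a])
      out <- paste0(out, if (lastPlain) piece else paste0("(", piece, ")"))
    }
    out
  }
  render(start)
}

# --- canonical ranking -------------------------------------------------------
# Invariants are packed into doubles (exact below 2^53) rather than pasted
# strings: canonicalization sits on the hot path of space enumeration.

.initialInvariant <- function(g) {
  n <- .nAtoms(g)
  deg <- integer(n); bsum <- integer(n)
  if (nrow(g$bonds) > 0) {
    for (b in seq_len(nrow(g$bonds))) {
      i <- g$bonds[b, 1]; j <- g$bonds[b, 2]
      deg[i] <- deg[i] + 1L; deg[j] <- deg[j] + 1L
      o <- if (g$baro[b]) 3L else 2L * g$bonds[b, 3]
      bsum[i] <- bsum[i] + o; bsum[j] <- bsum[j] + o
    }
  }
  paste(g$elem, g$arom, g$charge,
        ifelse(is.na(g$hcount), -1L, g$hcount),
        ifelse(is.na(g$isotope), 0L, g$isotope), deg, bsum, sep = "|")
}

.refineRanks <- function(g, ranks, ad) {
  n <- .nAtoms(g)
  bcode <- ifelse(g$baro, 4L, g$bonds[, 3])
  base <- 5 * n + 6
  dmax <- max(1L, max(lengths(ad$adj)))
  shift <- base^dmax
  repeat {
    sig <- numeric(n)
    for (a in seq_len(n)) {
      nb <- ad$adj[[a]]
      s <- 0
      if (length(nb) > 0L) {
        codes <- sort(ranks[nb] * 5 + bcode[ad$bnd[[a]]])
        for (cd in codes) s <- s * base + cd
      }
      sig[a] <- ranks[a] * shift + s
    }
    newRanks <- match(sig, sort(unique(sig)))
    if (identical(newRanks, ranks)) return(ranks)
    ranks <- newRanks
  }
}

.canonStringFromRanks <- function(g, ranks, ad) {
  ranks <- .refineRanks(g, ranks, ad)
  tab <- tabulate(ranks)
  tied <- which(tab > 1L)
  if (length(tied) == 0L) return(writeSmilesGraph(g, ranks, restricted = TRUE))
  cell <- min(tied)
  cand <- vapply(which(ranks == cell), function(a) {
    r2 <- ranks * 2L
    r2[a] <- r2[a] - 1L
    .canonStringFromRanks(g, match(r2, sortC(unique(r2))), ad)
  }, character(1))
  sortC(cand)[1]
}

.canonicalFromGraph <- function(g) {
  if (.nAtoms(g) == 1L) return(.atomSymbol(g, 1L))
  ad <- .adjacency(g)
  inv <- .initialInvariant(g)
  ranks <- match(inv, sortC(unique(inv)))
  .canonStringFromRanks(g, ranks, ad)
}

#' Canonicalize SMILES strings
#'
#' Computes the package's canonical SMILES form: atoms are ranked by
#' iterative invariant refinement (element, aromaticity, charge, hydrogen
#' count, isotope, degree, bond-order sum, then neighbourhood ranks) with a
#' lexicographic backtracking tie-break, and the molecule is written
#' depth-first from the top-ranked atom. The canonical form is an internally
#' consistent molecule key: `canonicalizeSmiles` is idempotent and invariant
#' under atom reordering, but is not intended to match any other toolkit's
#' canonical strings byte-for-byte.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES; `NA` where the input does
#'   not parse to a valid molecule (a failure value rather than an error, so
#'   that sampler output can be scored for validity).
#' @examples
#' canonicalizeSmiles(c("OCC", "C1CC"))  # "CCO", NA
#' @export
canonicalizeSmiles <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s)) return(NA_character_)
    g <- tryCatch(parseSmiles(s), error = function(e) NULL)
    if (is.null(g)) return(NA_character_)
    .canonicalFromGraph(g)
  }, character(1), USE.NAMES = FALSE)
}

#' Write a randomized SMILES string
#'
#' Draws a uniformly random permutation of the atom indices and writes the
#' molecule depth-first following that permutation. The
#' `"randomized_restricted"` variant applies the writer's traversal fixes
#' (minimal parenthesisation), the `"randomized_unrestricted"` variant
#' follows the permutation literally and may emit redundant ring-into-branch
#' forms; its output set is a strict superset of the restricted one.
#' Randomization is uniform over atom permutations, not over distinct
#' strings: several permutations can map to the same string, so strings are
#' not drawn uniformly.
#'
#' @param smiles a valid SMILES string (any writing; it is parsed, not
#'   canonicalized first).
#' @param variant `"randomized_restricted"` or `"randomized_unrestricted"`.
#' @param seed integer seed; fixed seed gives a fixed output.
#' @return a SMILES string of the same molecule;
#'   `canonicalizeSmiles(randomizeSmiles(s)) == canonicalizeSmiles(s)` always.
#' @export
randomizeSmiles <- function(smiles,
                            variant = "randomized_restricted",
                            seed = sample.int(2147483646L, 1L)) {
  .checkVariant(variant, c("randomized_restricted",
                           "randomized_unrestricted"))
  g <- parseSmiles(smiles)
  perm <- withSeed(seed, sample.int(.nAtoms(g)))
  writeSmilesGraph(g, perm, restricted = variant == "randomized_restricted")
}

.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Exhaustively enumerate the randomized SMILES of a molecule
#'
#' Writes the molecule once from every permutation of its atom order and
#' returns the deduplicated set of strings. At most `n!` strings exist for a
#' molecule with `n` heavy atoms; the realized number is usually far lower
#' because many permutations produce the same string.
#'
#' @param smiles a valid SMILES string.
#' @param variant one of the two randomized kinds (or `"canonical"`, giving
#'   the single canonical string).
#' @param maxHeavyAtoms guard on exhaustive mode (default 8).
#' @return character vector of distinct SMILES strings.
#' @export
enumerateRandomSmiles <- function(smiles, variant = "randomized_restricted",
                                  maxHeavyAtoms = 8L) {
  .checkVariant(variant, c("canonical", "randomized_restricted",
                           "randomized_unrestricted"))
  g <- parseSmiles(smiles)
  if (variant == "canonical") return(.canonicalFromGraph(g))
  n <- .nAtoms(g)
  if (n > maxHeavyAtoms)
    stop("molecule has ", n, " heavy atoms (> ", maxHeavyAtoms,
         "); use countRandomSmiles() for a sampled estimate")
  perms <- .permutations(n)
  restricted <- variant == "randomized_restricted"
  unique(vapply(seq_len(nrow(perms)), function(i) {
    writeSmilesGraph(g, perms[i, ], restricted = restricted)
  }, character(1)))
}

#' Estimate the number of distinct randomized SMILES by sampling
#'
#' Draws `nDraws` randomized writings and counts the distinct strings
#' observed: a lower bound on the true count, monotone non-decreasing in
#' `nDraws` in expectation.
#'
#' @inheritParams enumerateRandomSmiles
#' @param nDraws number of randomized writings to draw.
#' @param seed integer seed.
#' @return integer count of distinct strings observed.
#' @export
countRandomSmiles <- function(smiles, variant = "randomized_restricted",
                              nDraws = 1000L, seed = 1L) {
  .checkVariant(variant, c("randomized_restricted",
                           "randomized_unrestricted"))
  stopifnot(nDraws >= 1L)
  g <- parseSmiles(smiles)
  n <- .nAtoms(g)
  restricted <- variant == "randomized_restricted"
  strs <- withSeed(deriveSeed(seed, "countRandomSmiles"), {
    vapply(seq_len(nDraws), function(i) {
      writeSmilesGraph(g, sample.int(n), restricted = restricted)
    }, character(1))
  })
  length(unique(strs))
}
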