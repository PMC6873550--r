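# Synthetic enumerable chemical space: a desk-scale stand-in for a
# combinatorially enumerated database (GDB-13 style). Molecules over a small
# element set are grown breadth-first -- add an atom, or close a ring --
# with canonical-string deduplication at every step; exclusion filters
# (no triple bonds, no rings below a minimum size) are monotone under
# growth, so they can prune during enumeration without losing any member.

.VALENCE_TOY <- c(C = 4L, N = 3L, O = 2L)

#' Exclusion-filter configuration for the toy chemical space
#'
#' The defaults exclude triple bonds and rings smaller than 5 atoms -- cheap,
#' decidable analogues of the strained-ring / unstable-functional-group
#' exclusions applied by real enumerated databases. They guarantee that
#' valid molecules *outside* the space exist (e.g. `"C#C"` or `"C1CC1"`),
#' which the closedness metric needs.
#'
#' @param noTripleBonds exclude any molecule containing a triple bond.
#' @param minRingSize exclude molecules with a ring smaller than this
#'   (`NULL` disables the filter).
#' @param maxBondOrder highest bond order enumerated (1 = saturated only).
#' @param acyclic if `TRUE`, exclude all rings.
#' @return a list with class `"toySpaceFilters"`.
#' @export
toySpaceFilters <- function(noTripleBonds = TRUE, minRingSize = 5L,
                            maxBondOrder = 3L, acyclic = FALSE) {
  stopifnot(maxBondOrder %in% 1:3)
  structure(list(noTripleBonds = isTRUE(noTripleBonds),
                 minRingSize = if (is.null(minRingSize)) NULL
                               else as.integer(minRingSize),
                 maxBondOrder = as.integer(maxBondOrder),
                 acyclic = isTRUE(acyclic)),
            class = "toySpaceFilters")
}

# shortest path length (edges) between i and j in adjacency matrix, Inf if
# disconnected; used for the ring-size-at-closure check
.spLength <- function(adj, i, j) {
  n <- nrow(adj)
  dist <- rep(Inf, n)
  dist[i] <- 0
  frontier <- i
  d <- 0
  while (length(frontier) > 0L) {
    d <- d + 1
    nxt <- integer(0)
    for (a in frontier) {
      nbs <- which(adj[a, ] > 0L)
      for (b in nbs) if (dist[b] == Inf) { dist[b] <- d; nxt <- c(nxt, b) }
    }
    if (dist[j] < Inf) return(dist[j])
    frontier <- nxt
  }
  Inf
}

.toyGraphToMolgraph <- function(elems, adj) {
  n <- length(elems)
  g <- .emptyGraph()
  for (a in seq_len(n)) g <- .addAtom(g, elems[a])
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (adj[i, j] > 0L) g <- .addBond(g, i, j, adj[i, j])
    }
  }
  g
}

.spaceCache <- new.env(parent = emptyenv())

#' Enumerate a toy chemical space
#'
#' Exhaustively enumerates every connected molecule with up to
#' `maxHeavyAtoms` heavy atoms over the given elements that passes the
#' exclusion filters, by breadth-first molecular-graph growth (atom addition
#' and ring closure) with canonical-SMILES deduplication at each step. The
#' result is deterministic for fixed arguments and membership of any
#' molecule is decidable by canonical-string lookup.
#'
#' @param maxHeavyAtoms maximum number of heavy atoms (1-10).
#' @param elements subset of `c("C", "N", "O")`.
#' @param filters a [toySpaceFilters()] configuration.
#' @param cache reuse a previously enumerated space with identical arguments
#'   from an in-session cache (default `TRUE`; enumeration is pure).
#' @return a [ChemicalSpace-class].
#' @examples
#' sp <- enumerateToySpace(3, "C", toySpaceFilters(maxBondOrder = 1, acyclic = TRUE))
#' spaceMembers(sp)  # "C" "CC" "CCC"
#' @export
enumerateToySpace <- function(maxHeavyAtoms = 6L,
                              elements = c("C", "N", "O"),
                              filters = toySpaceFilters(),
                              cache = TRUE) {
  stopifnot(maxHeavyAtoms >= 1L, maxHeavyAtoms <= 10L)
  if (!all(elements %in% names(.VALENCE_TOY)))
    stop("unsupported element(s): ",
         paste(setdiff(elements, names(.VALENCE_TOY)), collapse = ", "))
  if (!inherits(filters, "toySpaceFilters"))
    stop("filters must be created with toySpaceFilters()")
  key <- paste(maxHeavyAtoms, paste(sortC(elements), collapse = ","),
               paste(unlist(filters), collapse = ","), sep = ";")
  if (cache && !is.null(.spaceCache[[key]])) return(.spaceCache[[key]])

  maxOrder <- filters$maxBondOrder
  if (filters$noTripleBonds) maxOrder <- min(maxOrder, 2L)
  minRing <- if (filters$acyclic) Inf
             else if (is.null(filters$minRingSize)) 3L
             else max(3L, filters$minRingSize)

  seen <- new.env(parent = emptyenv(), hash = TRUE)
  members <- character(0)
  queue <- list()
  for (el in unique(elements)) {
    adj <- matrix(0L, 1, 1)
    key1 <- .canonicalFromGraph(.toyGraphToMolgraph(el, adj))
    seen[[key1]] <- TRUE
    members <- c(members, key1)
    queue[[length(queue) + 1L]] <- list(elems = el, adj = adj)
  }

  consider <- function(elems, adj) {
    cs <- .canonicalFromGraph(.toyGraphToMolgraph(elems, adj))
    if (is.null(seen[[cs]])) {
      seen[[cs]] <- TRUE
      members <<- c(members, cs)
      queue[[length(queue) + 1L]] <<- list(elems = elems, adj = adj)
    }
  }

  head <- 1L
  while (head <= length(queue)) {
    gr <- queue[[head]]; head <- head + 1L
    n <- length(gr$elems)
    free <- .VALENCE_TOY[gr$elems] - rowSums(gr$adj)
    # ring closures between existing atoms
    if (!is.infinite(minRing) && n >= minRing) {
      for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        if (gr$adj[i, j] > 0L) next
        if (free[i] < 1L || free[j] < 1L) next
        if (.spLength(gr$adj, i, j) < minRing - 1L) next
        for (o in seq_len(min(maxOrder, free[i], free[j]))) {
          adj2 <- gr$adj; adj2[i, j] <- o; adj2[j, i] <- o
          consider(gr$elems, adj2)
        }
      }
    }
    # atom additions
    if (n < maxHeavyAtoms) {
      for (i in seq_len(n)) {
        if (free[i] < 1L) next
        for (el in unique(elements)) {
          vnew <- .VALENCE_TOY[[el]]
          for (o in seq_len(min(maxOrder, free[i], vnew))) {
            adj2 <- rbind(cbind(gr$adj, 0L), 0L)
            adj2[i, n + 1L] <- o; adj2[n + 1L, i] <- o
            consider(c(gr$elems, el), adj2)
          }
        }
      }
    }
  }

  if (length(members) == 0L) stop("degenerate space")
  sp <- new("ChemicalSpace", members = sortC(members),
            maxHeavyAtoms = as.integer(maxHeavyAtoms),
            elements = sortC(unique(elements)),
            filters = unclass(filters))
  if (cache) .spaceCache[[key]] <- sp
  sp
}

#' Construct a chemical space from explicit molecules
#'
#' Canonicalizes and deduplicates the given SMILES; unparseable strings are
#' an error.
#'
#' @param smiles character vector of SMILES strings.
#' @return a [ChemicalSpace-class].
#' @export
chemicalSpace <- function(smiles) {
  canon <- canonicalizeSmiles(smiles)
  if (anyNA(canon))
    stop("invalid SMILES at line(s): ",
         paste(head(which(is.na(canon)), 5), collapse = ", "))
  new("ChemicalSpace", members = sortC(unique(canon)),
      maxHeavyAtoms = NA_integer_, elements = character(0), filters = list())
}

#' @describeIn enumerateToySpace the sorted canonical members.
#' @param space a [ChemicalSpace-class].
#' @export
spaceMembers <- function(space) space@members

#' @describeIn enumerateToySpace number of molecules N in the space.
#' @export
spaceSize <- function(space) length(space@members)

#' @describeIn enumerateToySpace negative log-likelihood `log(N)` (nats) that
#'   an ideal uniform generator assigns to each member.
#' @export
uniformNll <- function(space) log(length(space@members))

#' @describeIn enumerateToySpace decidable membership: is each (canonicalized)
#'   string a member of the space?
#' @param smiles character vector of SMILES strings.
#' @export
containsMolecule <- function(space, smiles) {
  canonicalizeSmiles(smiles) %in% space@members
}

#' @export
setMethod("show", "ChemicalSpace", function(object) {
  cat("ChemicalSpace of", length(object@members), "molecules",
      if (!is.na(object@maxHeavyAtoms))
        paste0("(<= ", object@maxHeavyAtoms, " heavy atoms; elements ",
               paste(object@elements, collapse = ","), ")"), "\n")
  cat("  uniform NLL:", round(uniformNll(object), 4), "nats\n")
  cat("  e.g.:", paste(head(object@members, 6), collapse = " "), "...\n")
})

#' Split a chemical space into training and validation sets
#'
#' Draws two disjoint uniform random subsets without replacement.
#' Reproducible for a fixed seed.
#'
#' @param space a [ChemicalSpace-class].
#' @param nTrain,nValid subset sizes; their sum must not exceed the space
#'   size.
#' @param seed integer seed.
#' @return a [SpaceSplit-class].
#' @export
splitTrainValidation <- function(space, nTrain, nValid, seed = 1L) {
  N <- spaceSize(space)
  if (nTrain + nValid > N)
    stop("nTrain + nValid (", nTrain + nValid, ") exceeds space size ", N)
  idx <- withSeed(deriveSeed(seed, "split"),
                  sample.int(N, nTrain + nValid))
  new("SpaceSplit",
      training = space@members[idx[seq_len(nTrain)]],
      validation = space@members[idx[nTrain + seq_len(nValid)]],
      seed = as.integer(seed))
}

#' @export
setMethod("show", "SpaceSplit", function(object) {
  cat("SpaceSplit: ", length(object@training), " training / ",
      length(object@validation), " validation molecules (seed ",
      object@seed, ")\n", sep = "")
})

#' Sample from the ideal uniform generator of a space
#'
#' Draws `k` molecules independently, uniformly and with replacement from
#' the space members: the hypothetical generator with uniform probability
#' over exactly the target space, against which trained models are compared.
#'
#' @param space a [ChemicalSpace-class].
#' @param k sample size.
#' @param seed integer seed.
#' @return character vector of `k` canonical SMILES (with repeats).
#' @export
idealSample <- function(space, k, seed = 1L) {
  stopifnot(k >= 1L)
  if (spaceSize(space) == 0L) stop("empty space")
  withSeed(deriveSeed(seed, "idealSample"),
           sample(space@members, k, replace = TRUE))
}

#' Read / write SMILES line files
#'
#' The `.smi` dialect: one record per line, first whitespace-separated field
#' is the SMILES, optional second field an identifier; blank lines are
#' skipped.
#'
#' @param path file path.
#' @return `readSmilesFile`: a data.frame with columns `smiles` and `id`
#'   (`NA` where absent).
#' @export
readSmilesFile <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  if (length(lines) == 0L)
    return(data.frame(smiles = character(0), id = character(0)))
  parts <- strsplit(trimws(lines), "[ \t]+")
  data.frame(
    smiles = vapply(parts, `[`, character(1), 1L),
    id = vapply(parts, function(p) if (length(p) > 1L) p[2] else NA_character_,
                character(1)))
}

#' @rdname readSmilesFile
#' @param smiles character vector (or data.frame with columns `smiles`,`id`).
#' @export
writeSmilesFile <- function(smiles, path) {
  if (is.data.frame(smiles)) {
    lines <- ifelse(is.na(smiles$id), smiles$smiles,
                    paste(smiles$smiles, smiles$id))
  } else lines <- smiles
  writeLines(lines, path)
  invisible(path)
}

#' @rdname readSmilesFile
#' @param space a [ChemicalSpace-class]; written as its sorted member list
#'   (content-deterministic).
#' @export
writeChemicalSpace <- function(space, path) {
  writeLines(space@members, path)
  invisible(path)
}

#' @rdname readSmilesFile
#' @export
readChemicalSpace <- function(path) {
  members <- readSmilesFile(path)$smiles
  new("ChemicalSpace", members = sortC(unique(members)),
      maxHeavyAtoms = NA_integer_, elements = character(0), filters = list())
}
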