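# Shared fixtures and independent oracles. Spaces come from the in-session
# enumeration cache, so each is built once per test run.

spaceAlkanes <- function(maxAtoms = 4L) {
  enumerateToySpace(maxAtoms, "C",
                    toySpaceFilters(maxBondOrder = 1, acyclic = TRUE))
}

spaceSmall <- function() enumerateToySpace(4L, c("C", "N", "O"),
                                           toySpaceFilters())
spaceMedium <- function() enumerateToySpace(5L, c("C", "N", "O"),
                                            toySpaceFilters())
spaceLarge <- function() enumerateToySpace(6L, c("C", "N", "O"),
                                           toySpaceFilters())

# Independent brute-force enumeration oracle: iterates over every labeled
# multigraph (element assignment x bond-order assignment per atom pair),
# keeps connected, valence-correct graphs passing the filters, and counts
# isomorphism classes with igraph's VF2 (vertex colors = elements, edge
# colors = bond orders). Completely separate from the package's growth +
# canonical-string path.
oracleCountMolecules <- function(maxAtoms, elements, maxOrder = 2L,
                                 minRing = 5L) {
  valence <- c(C = 4L, N = 3L, O = 2L)
  total <- 0L
  for (n in seq_len(maxAtoms)) {
    if (n == 1L) { total <- total + length(elements); next }
    pairs <- utils::combn(n, 2L)
    np <- ncol(pairs)
    orderGrid <- as.matrix(expand.grid(rep(list(0:maxOrder), np)))
    elemGrid <- as.matrix(expand.grid(rep(list(elements), n),
                                      stringsAsFactors = FALSE))
    reps <- list()
    for (oi in seq_len(nrow(orderGrid))) {
      ords <- orderGrid[oi, ]
      if (all(ords == 0L)) next
      edges <- pairs[, ords > 0L, drop = FALSE]
      eords <- ords[ords > 0L]
      gi <- igraph::graph_from_edgelist(t(edges), directed = FALSE)
      if (igraph::vcount(gi) < n)
        gi <- igraph::add_vertices(gi, n - igraph::vcount(gi))
      if (!igraph::is_connected(gi)) next
      gr <- igraph::girth(gi)$girth
      if (is.finite(gr) && gr > 0 && gr < minRing) next
      bsum <- integer(n)
      for (e in seq_along(eords)) {
        bsum[edges[1, e]] <- bsum[edges[1, e]] + eords[e]
        bsum[edges[2, e]] <- bsum[edges[2, e]] + eords[e]
      }
      for (ei in seq_len(nrow(elemGrid))) {
        els <- elemGrid[ei, ]
        if (any(bsum > valence[els])) next
        g2 <- igraph::set_vertex_attr(gi, "color",
                                      value = match(els, names(valence)))
        g2 <- igraph::set_edge_attr(g2, "color", value = eords)
        key <- paste(n, paste(sort(table(factor(els, names(valence)))),
                              collapse = ","),
                     paste(sort(bsum), collapse = ","),
                     paste(sort(eords), collapse = ","), sep = "|")
        found <- FALSE
        for (cand in reps[[key]]) {
          if (igraph::isomorphic(cand, g2, method = "vf2")) {
            found <- TRUE; break
          }
        }
        if (!found) {
          reps[[key]] <- c(reps[[key]], list(g2))
          total <- total + 1L
        }
      }
    }
  }
  total
}

# independent trailing moving average (window 4) for best-epoch checks
oracleSmoothedArgmin <- function(x, window = 4L) {
  sm <- numeric(length(x))
  for (i in seq_along(x)) sm[i] <- sum(x[max(1, i - window + 1):i]) /
      length(max(1, i - window + 1):i)
  which(sm == min(sm))[1]
}

# independent evaluation of the divergence formula on explicit vectors
oracleJsd <- function(dists, alpha) {
  H <- function(p) { nz <- p > 0; -sum(p[nz] * log(p[nz])) }
  mix <- Reduce(`+`, Map(`*`, dists, alpha))
  H(mix) - sum(unlist(Map(function(a, d) a * H(d), alpha, dists)))
}

# zero-weight copy of a model: every step distribution is uniform
uniformModel <- function(vocab, ...) {
  m <- smilesRNN(vocab, ...)
  m@params <- lapply(m@params, function(p) p * 0)
  m
}

obCanonical <- function(smiles) {
  out <- ChemmineOB::convertFormat("SMI", "CAN",
                                   paste0(paste(smiles, collapse = "\n"),
                                          "\n"))
  trimws(strsplit(out, "\n")[[1]])
}
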