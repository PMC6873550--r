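# SMILES -> molecular graph parser.
#
# The graph is a plain list ("molgraph"):
#   elem    character, element symbols (capitalized, e.g. "C", "Cl")
#   arom    logical, aromatic flag (written lowercase)
#   charge  integer formal charge
#   hcount  integer explicit hydrogen count from a bracket atom, NA = implicit
#   isotope integer isotope label, NA = unspecified
#   bonds   k x 3 integer matrix (a1, a2, order 1..3)
#   baro    logical length k, aromatic bond flag
#
# Stereo bond characters "/" and "\" are read as single bonds and chirality
# tags inside brackets are dropped: molecules are handled at constitution
# level, which is all the enumeration, randomization and coverage machinery
# requires.

.ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
.AROMATIC_SYMBOLS <- c("b", "c", "n", "o", "p", "s")

.emptyGraph <- function() {
  list(elem = character(0), arom = logical(0), charge = integer(0),
       hcount = integer(0), isotope = integer(0),
       bonds = matrix(integer(0), ncol = 3), baro = logical(0))
}

.addAtom <- function(g, elem, arom = FALSE, charge = 0L, hcount = NA_integer_,
                     isotope = NA_integer_) {
  g$elem <- c(g$elem, elem)
  g$arom <- c(g$arom, arom)
  g$charge <- c(g$charge, charge)
  g$hcount <- c(g$hcount, hcount)
  g$isotope <- c(g$isotope, isotope)
  g
}

.addBond <- function(g, a1, a2, order, aromatic = FALSE) {
  g$bonds <- rbind(g$bonds, c(a1, a2, order))
  g$baro <- c(g$baro, aromatic)
  g
}

.nAtoms <- function(g) length(g$elem)

.parseBracket <- function(token) {
  m <- regexec(
    "^\\[([0-9]+)?([A-Z][a-z]?|[a-z]|\\*)(@+|@TH[12])?(H([0-9]*))?(\\+([0-9]*)|-([0-9]*)|\\++|-+)?(:[0-9]+)?\\]$",
    token)[[1]]
  if (m[1] == -1) stop("malformed bracket atom '", token, "'")
  parts <- regmatches(token, regexec(
    "^\\[([0-9]+)?([A-Z][a-z]?|[a-z]|\\*)(@+|@TH[12])?(H([0-9]*))?(\\+([0-9]*)|-([0-9]*)|\\++|-+)?(:[0-9]+)?\\]$",
    token))[[1]]
  iso <- if (nzchar(parts[2])) as.integer(parts[2]) else NA_integer_
  sym <- parts[3]
  arom <- sym %in% c(.AROMATIC_SYMBOLS, "as", "se")
  elem <- if (arom) paste0(toupper(substr(sym, 1, 1)), substring(sym, 2)) else sym
  h <- if (nzchar(parts[5])) {
    if (nzchar(parts[6])) as.integer(parts[6]) else 1L
  } else 0L
  chargeStr <- parts[7]
  charge <- 0L
  if (nzchar(chargeStr)) {
    sign <- if (substr(chargeStr, 1, 1) == "+") 1L else -1L
    digits <- gsub("[+-]", "", chargeStr)
    charge <- if (nzchar(digits)) sign * as.integer(digits)
              else sign * nchar(chargeStr)
  }
  list(elem = elem, arom = arom, charge = charge, hcount = h, isotope = iso)
}

# Parse a single SMILES string into a molgraph. Throws an error (with an
# informative message) on syntactically invalid or valence-violating input;
# see canonicalizeSmiles()/isValidSmiles() for the non-throwing wrappers.
parseSmiles <- function(smiles, checkValence = TRUE) {
  tokens <- tokenizeSmiles(smiles, markers = FALSE)
  g <- .emptyGraph()
  prev <- 0L                  # current attachment atom (0 = none)
  stack <- integer(0)         # open branch attachment points
  pending <- NULL             # explicit bond symbol awaiting next atom/ring
  rings <- list()             # open ring closures: number -> list(atom, sym)

  bondFor <- function(a1, a2, sym) {
    if (is.null(sym)) {
      if (g$arom[a1] && g$arom[a2]) list(order = 1L, aromatic = TRUE)
      else list(order = 1L, aromatic = FALSE)
    } else if (sym == ":") {
      list(order = 1L, aromatic = TRUE)
    } else {
      list(order = c("-" = 1L, "/" = 1L, "\\" = 1L, "=" = 2L, "#" = 3L)[[sym]],
           aromatic = FALSE)
    }
  }

  placeAtom <- function(spec) {
    g <<- .addAtom(g, spec$elem, spec$arom, spec$charge, spec$hcount,
                   spec$isotope)
    a <- .nAtoms(g)
    if (prev > 0L) {
      b <- bondFor(prev, a, pending)
      g <<- .addBond(g, prev, a, b$order, b$aromatic)
    } else if (!is.null(pending)) {
      stop("bond symbol with no preceding atom")
    }
    pending <<- NULL
    prev <<- a
  }

  for (tk in tokens) {
    if (tk %in% .ORGANIC_SUBSET) {
      placeAtom(list(elem = tk, arom = FALSE, charge = 0L,
                     hcount = NA_integer_, isotope = NA_integer_))
    } else if (tk %in% .AROMATIC_SYMBOLS) {
      placeAtom(list(elem = toupper(tk), arom = TRUE, charge = 0L,
                     hcount = NA_integer_, isotope = NA_integer_))
    } else if (startsWith(tk, "[")) {
      placeAtom(.parseBracket(tk))
    } else if (tk %in% c("-", "=", "#", ":", "/", "\\")) {
      if (!is.null(pending)) stop("two consecutive bond symbols")
      pending <- tk
    } else if (tk == "(") {
      if (prev == 0L) stop("branch opened before any atom")
      stack <- c(stack, prev)
    } else if (tk == ")") {
      if (length(stack) == 0L) stop("unmatched closing parenthesis")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pending <- NULL
    } else if (grepl("^[0-9]$", tk) || startsWith(tk, "%")) {
      if (prev == 0L) stop("ring closure before any atom")
      num <- if (startsWith(tk, "%")) substring(tk, 2) else tk
      open <- rings[[num]]
      if (is.null(open)) {
        rings[[num]] <- list(atom = prev, sym = pending)
        pending <- NULL
      } else {
        if (open$atom == prev) stop("ring closure to the same atom")
        sym <- open$sym
        if (!is.null(sym) && !is.null(pending) && sym != pending)
          stop("conflicting ring-closure bond symbols")
        if (is.null(sym)) sym <- pending
        b <- bondFor(open$atom, prev, sym)
        g <- .addBond(g, open$atom, prev, b$order, b$aromatic)
        rings[[num]] <- NULL
        pending <- NULL
      }
    } else if (tk == ".") {
      stop("disconnected structures are not supported")
    } else {
      stop("unrecognized token '", tk, "'")
    }
  }
  if (length(stack) > 0L) stop("unclosed branch")
  if (length(rings) > 0L) stop("unclosed ring bond")
  if (!is.null(pending)) stop("dangling bond symbol")
  if (.nAtoms(g) == 0L) stop("empty molecule")
  dup <- paste(pmin(g$bonds[, 1], g$bonds[, 2]),
               pmax(g$bonds[, 1], g$bonds[, 2]))
  if (anyDuplicated(dup)) stop("duplicate bond between the same atom pair")
  if (checkValence) .checkGraph(g)
  g
}

.allowedValence <- function(elem, charge) {
  base <- c(B = 3, C = 4, N = 3, O = 2, P = 5, S = 6,
            F = 1, Cl = 1, Br = 1, I = 1, H = 1)
  if (!elem %in% names(base)) return(Inf)   # wildcard / exotic: not checked
  if (elem %in% c("C", "B")) base[[elem]] - abs(charge)
  else base[[elem]] + charge
}

# Valence / aromaticity sanity of a parsed graph; throws on violation.
.checkGraph <- function(g) {
  n <- .nAtoms(g)
  nonarom <- numeric(n)
  naro <- integer(n)
  if (nrow(g$bonds) > 0) {
    for (b in seq_len(nrow(g$bonds))) {
      i <- g$bonds[b, 1]; j <- g$bonds[b, 2]
      if (g$baro[b]) {
        naro[i] <- naro[i] + 1L; naro[j] <- naro[j] + 1L
        if (!(g$arom[i] && g$arom[j]))
          stop("aromatic bond between non-aromatic atoms")
      } else {
        o <- g$bonds[b, 3]
        nonarom[i] <- nonarom[i] + o; nonarom[j] <- nonarom[j] + o
      }
    }
  }
  for (a in seq_len(n)) {
    allowed <- .allowedValence(g$elem[a], g$charge[a])
    if (g$arom[a]) {
      if (!naro[a] %in% c(2L, 3L))
        stop("aromatic atom ", a, " must have 2 or 3 aromatic bonds")
      contrib <- naro[a] + if (g$elem[a] == "C") 1L else 0L
    } else {
      if (naro[a] > 0L) stop("aromatic bond on aliphatic atom ", a)
      contrib <- 0
    }
    h <- if (is.na(g$hcount[a])) 0L else g$hcount[a]
    if (nonarom[a] + contrib + h > allowed)
      stop("valence of atom ", a, " (", g$elem[a], ") exceeded")
  }
  invisible(TRUE)
}

#' Number of heavy (non-hydrogen) atoms in a SMILES string
#'
#' @param smiles character vector of SMILES strings.
#' @return integer vector; `NA` where the string does not parse.
#' @export
heavyAtomCount <- function(smiles) {
  vapply(smiles, function(s) {
    g <- tryCatch(parseSmiles(s), error = function(e) NULL)
    if (is.null(g)) NA_integer_ else sum(g$elem != "H")
  }, integer(1), USE.NAMES = FALSE)
}

#' Is a SMILES string a valid molecule?
#'
#' Checks SMILES syntax (balanced branches, closed rings, well-formed
#' brackets), connectivity and valence. Strings that fail for any reason
#' return `FALSE` rather than raising, so that sampler output can be scored.
#'
#' @param smiles character vector.
#' @return logical vector.
#' @export
isValidSmiles <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(s)) return(FALSE)
    !is.null(tryCatch(parseSmiles(s), error = function(e) NULL))
  }, logical(1), USE.NAMES = FALSE)
}
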