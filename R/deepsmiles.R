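# DeepSMILES syntax conversion.
#
# Ring syntax: the paired ring-closure digits of SMILES are replaced by a
# single number at the closing site equal to the ring size (the opening
# digit disappears), e.g. c1ccccc1 -> cccccc6.
# Branch syntax: opening parentheses disappear and each closing parenthesis
# becomes a run of ")" characters, one per atom that must be popped to
# return to the branching atom, e.g. C(C(C)O)N -> CCC)O))N.
#
# Conversion requires every ring closure to connect an atom to one of its
# ancestors on the current chain, which holds for any string produced by a
# depth-first writer (all writers in this package).

.isAtomToken <- function(tk) {
  startsWith(tk, "[") | tk %in% c(.ORGANIC_SUBSET, .AROMATIC_SYMBOLS)
}

.deepModes <- c("deepsmiles_rings", "deepsmiles_branches", "deepsmiles_both")

.toDeepOne <- function(smiles, doRings, doBranches) {
  tokens <- tokenizeSmiles(smiles, markers = FALSE)
  out <- character(0)
  anc <- integer(0)            # atom ids along the current chain
  frames <- list()             # per '(': list(depth, atomsInFrame)
  openRings <- list()          # digit -> list(atom, depth, sym)
  atomId <- 0L
  pendingSym <- ""

  for (tk in tokens) {
    if (.isAtomToken(tk)) {
      atomId <- atomId + 1L
      anc <- c(anc, atomId)
      if (length(frames) > 0L)
        frames[[length(frames)]]$count <- frames[[length(frames)]]$count + 1L
      out <- c(out, pendingSym, tk)
      pendingSym <- ""
    } else if (tk %in% c("-", "=", "#", ":", "/", "\\")) {
      pendingSym <- tk
    } else if (tk == "(") {
      frames[[length(frames) + 1L]] <- list(depth = length(anc), count = 0L)
      if (!doBranches) out <- c(out, "(")
    } else if (tk == ")") {
      if (length(frames) == 0L) stop("unmatched ')'")
      fr <- frames[[length(frames)]]
      frames[[length(frames)]] <- NULL
      anc <- anc[seq_len(fr$depth)]
      out <- c(out, if (doBranches) strrep(")", fr$count) else ")")
    } else if (grepl("^[0-9]$", tk) || startsWith(tk, "%")) {
      num <- if (startsWith(tk, "%")) substring(tk, 2) else tk
      if (!doRings) {
        out <- c(out, pendingSym, tk); pendingSym <- ""
      } else if (is.null(openRings[[num]])) {
        openRings[[num]] <- list(atom = anc[length(anc)], sym = pendingSym)
        pendingSym <- ""
      } else {
        op <- openRings[[num]]
        openRings[[num]] <- NULL
        pos <- match(op$atom, anc)
        if (is.na(pos))
          stop("ring closure partner is not an ancestor on the current chain")
        size <- length(anc) - pos + 1L
        sym <- if (nzchar(pendingSym)) pendingSym else op$sym
        out <- c(out, sym,
                 if (size > 9L) sprintf("%%%02d", size) else as.character(size))
        pendingSym <- ""
      }
    } else {
      stop("unsupported token '", tk, "' in DeepSMILES conversion")
    }
  }
  if (length(openRings) > 0L) stop("unclosed ring bond")
  paste(out, collapse = "")
}

#' Convert SMILES to DeepSMILES
#'
#' Applies the DeepSMILES grammar changes: `"deepsmiles_rings"` replaces
#' paired ring-closure digits with a single ring-size number at the closing
#' site, `"deepsmiles_branches"` replaces parenthesis pairs with runs of
#' `")"`, and `"deepsmiles_both"` applies both.
#'
#' @param smiles character vector of SMILES strings.
#' @param mode one of `"deepsmiles_rings"`, `"deepsmiles_branches"`,
#'   `"deepsmiles_both"`.
#' @return character vector of converted strings; `NA` where conversion
#'   fails (a failure value, counted as invalid downstream).
#' @examples
#' toDeepSmiles("c1ccccc1", "deepsmiles_rings")     # "cccccc6"
#' toDeepSmiles("C(C(C)O)N", "deepsmiles_branches") # "CCC)O))N"
#' @export
toDeepSmiles <- function(smiles, mode = "deepsmiles_both") {
  .checkVariant(mode, .deepModes)
  doRings <- mode %in% c("deepsmiles_rings", "deepsmiles_both")
  doBranches <- mode %in% c("deepsmiles_branches", "deepsmiles_both")
  vapply(smiles, function(s) {
    if (is.na(s)) return(NA_character_)
    tryCatch(.toDeepOne(s, doRings, doBranches),
             error = function(e) NA_character_)
  }, character(1), USE.NAMES = FALSE)
}

.fromDeepOne <- function(text, doRings, doBranches) {
  tokens <- tokenizeSmiles(text, markers = FALSE)
  g <- .emptyGraph()
  anc <- integer(0)
  frames <- integer(0)
  openRings <- list()
  pendingSym <- NULL

  bondFor <- function(a1, a2, sym) {
    if (is.null(sym)) {
      if (g$arom[a1] && g$arom[a2]) list(order = 1L, aromatic = TRUE)
      else list(order = 1L, aromatic = FALSE)
    } else if (sym == ":") list(order = 1L, aromatic = TRUE)
    else list(order = c("-" = 1L, "/" = 1L, "\\" = 1L,
                        "=" = 2L, "#" = 3L)[[sym]], aromatic = FALSE)
  }

  for (tk in tokens) {
    if (.isAtomToken(tk)) {
      spec <- if (startsWith(tk, "[")) .parseBracket(tk)
              else if (tk %in% .AROMATIC_SYMBOLS)
                list(elem = toupper(tk), arom = TRUE, charge = 0L,
                     hcount = NA_integer_, isotope = NA_integer_)
              else list(elem = tk, arom = FALSE, charge = 0L,
                        hcount = NA_integer_, isotope = NA_integer_)
      g <- .addAtom(g, spec$elem, spec$arom, spec$charge, spec$hcount,
                    spec$isotope)
      a <- .nAtoms(g)
      if (length(anc) > 0L) {
        b <- bondFor(anc[length(anc)], a, pendingSym)
        g <- .addBond(g, anc[length(anc)], a, b$order, b$aromatic)
      }
      anc <- c(anc, a)
      pendingSym <- NULL
    } else if (tk %in% c("-", "=", "#", ":", "/", "\\")) {
      pendingSym <- tk
    } else if (tk == "(") {
      if (doBranches) stop("'(' is not valid in DeepSMILES branch syntax")
      frames <- c(frames, length(anc))
    } else if (tk == ")") {
      if (doBranches) {
        if (length(anc) <= 1L) stop("popped past the chain root")
        anc <- anc[-length(anc)]
      } else {
        if (length(frames) == 0L) stop("unmatched ')'")
        anc <- anc[seq_len(frames[length(frames)])]
        frames <- frames[-length(frames)]
      }
    } else if (grepl("^[0-9]$", tk) || startsWith(tk, "%")) {
      num <- if (startsWith(tk, "%")) substring(tk, 2) else tk
      if (doRings) {
        size <- as.integer(num)
        pos <- length(anc) - (size - 1L)
        if (size < 3L || pos < 1L) stop("invalid ring size ", size)
        cur <- anc[length(anc)]
        b <- bondFor(anc[pos], cur, pendingSym)
        g <- .addBond(g, anc[pos], cur, b$order, b$aromatic)
        pendingSym <- NULL
      } else {
        cur <- anc[length(anc)]
        if (is.null(openRings[[num]])) {
          openRings[[num]] <- list(atom = cur, sym = pendingSym)
        } else {
          op <- openRings[[num]]
          openRings[[num]] <- NULL
          sym <- if (!is.null(pendingSym)) pendingSym else op$sym
          b <- bondFor(op$atom, cur, sym)
          g <- .addBond(g, op$atom, cur, b$order, b$aromatic)
        }
        pendingSym <- NULL
      }
    } else {
      stop("unsupported token '", tk, "'")
    }
  }
  if (length(openRings) > 0L) stop("unclosed ring bond")
  .checkGraph(g)
  .canonicalFromGraph(g)
}

#' @rdname toDeepSmiles
#' @param text character vector of DeepSMILES strings in the given `mode`.
#' @return `fromDeepSmiles` returns the canonical SMILES of the decoded
#'   molecule (`NA` on failure).
#' @export
fromDeepSmiles <- function(text, mode = "deepsmiles_both") {
  .checkVariant(mode, .deepModes)
  doRings <- mode %in% c("deepsmiles_rings", "deepsmiles_both")
  doBranches <- mode %in% c("deepsmiles_branches", "deepsmiles_both")
  vapply(text, function(s) {
    if (is.na(s)) return(NA_character_)
    tryCatch(.fromDeepOne(s, doRings, doBranches),
             error = function(e) NA_character_)
  }, character(1), USE.NAMES = FALSE)
}
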