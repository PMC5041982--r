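## Hashed linear-path 2D fingerprints and Tanimoto screening.
##
## Every linear (non-branching) bond path of 1..maxPathBonds bonds over the
## heavy atoms is tokenised -- atoms by (element, aromaticity, formal
## charge), bonds by order with aromatic bonds their own type -- read in its
## lexicographically smaller direction, and hashed with 32-bit FNV-1a modulo
## nbits. The scheme is deterministic and independent of atom input order.

.FNV_OFFSET <- 2166136261
.FNV_PRIME <- 16777619
.TWO32 <- 2^32

.fnv1a32 <- function(s) {
  bytes <- utf8ToInt(s)
  h <- .FNV_OFFSET
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), b)
    l16 <- h %% 65536
    h <- (l16 * .FNV_PRIME +
          ((((h - l16) / 65536) * .FNV_PRIME) %% 65536) * 65536) %% .TWO32
  }
  h
}

.atomToken <- function(atoms, i) {
  paste0(atoms$element[i],
         ifelse(atoms$aromatic[i], "~", ""),
         ifelse(atoms$charge[i] != 0,
                sprintf("%+d", atoms$charge[i]), ""))
}

.bondToken <- function(bonds, k) {
  ifelse(bonds$aromatic[k], "a", as.character(bonds$order[k]))
}

## enumerate canonical token strings of all simple linear paths with
## 1..maxPathBonds bonds over heavy atoms
.pathTokens <- function(graph, maxPathBonds) {
  atoms <- graph$atoms
  bonds <- graph$bonds
  heavy <- which(!atoms$isH)
  if (length(heavy) < 2L || nrow(bonds) == 0L) return(character(0))
  keep <- !atoms$isH[bonds$a1] & !atoms$isH[bonds$a2]
  bonds <- bonds[keep, , drop = FALSE]
  if (nrow(bonds) == 0L) return(character(0))
  atok <- vapply(seq_len(nrow(atoms)), function(i) .atomToken(atoms, i),
                 character(1))
  nb <- lapply(seq_len(nrow(atoms)), function(i) integer(0))
  for (k in seq_len(nrow(bonds))) {
    a <- bonds$a1[k]; b <- bonds$a2[k]
    nb[[a]] <- c(nb[[a]], k)
    nb[[b]] <- c(nb[[b]], k)
  }
  btok <- vapply(seq_len(nrow(bonds)), function(k) .bondToken(bonds, k),
                 character(1))
  other <- function(k, i) if (bonds$a1[k] == i) bonds$a2[k] else bonds$a1[k]
  found <- new.env(parent = emptyenv())
  walk <- function(i, visited, tokens) {
    if ((length(tokens) - 1L) / 2L >= maxPathBonds) return()
    for (k in nb[[i]]) {
      j <- other(k, i)
      if (visited[j]) next
      tok <- c(tokens, btok[k], atok[j])
      fwd <- paste(tok, collapse = "!")
      rev <- paste(base::rev(tok), collapse = "!")
      assign(if (fwd <= rev) fwd else rev, TRUE, envir = found)
      visited[j] <- TRUE
      walk(j, visited, tok)
      visited[j] <- FALSE
    }
  }
  visited <- rep(FALSE, nrow(atoms))
  for (i in heavy) {
    visited[i] <- TRUE
    walk(i, visited, atok[i])
    visited[i] <- FALSE
  }
  ls(found)
}

#' 2D hashed-path fingerprint
#'
#' @param cpd a \linkS4class{Compound} (must carry a parsed molecular graph).
#' @param maxPathBonds longest path length in bonds (default 7).
#' @param nbits fingerprint length (default 2048).
#' @return a \linkS4class{Fingerprint2D}. A molecule with a single heavy atom
#'   (no heavy-atom bonds) yields the empty bit set.
#' @examples
#' fp <- fingerprint2d(compound("etoh", "CCO"))
#' fp
#' @export
fingerprint2d <- function(cpd, maxPathBonds = 7L, nbits = 2048L) {
  stopifnot(is(cpd, "Compound"))
  if (is.null(cpd@graph))
    stop("compound '", cpd@id, "' has no parsed molecular graph")
  toks <- .pathTokens(cpd@graph, as.integer(maxPathBonds))
  bits <- if (length(toks))
    sort(unique(as.integer(vapply(toks, .fnv1a32, numeric(1)) %%
                           as.integer(nbits))))
  else integer(0)
  methods::new("Fingerprint2D", bits = bits, nbits = as.integer(nbits))
}

#' Tanimoto similarity of two bit fingerprints
#'
#' \code{|A intersect B| / |A union B|}; defined as 1 when both bit sets are
#' empty.
#'
#' @param a,b \linkS4class{Fingerprint2D} objects of equal length.
#' @return similarity in \code{[0, 1]}.
#' @export
tanimoto <- function(a, b) {
  stopifnot(is(a, "Fingerprint2D"), is(b, "Fingerprint2D"))
  if (a@nbits != b@nbits)
    stop("fingerprints have different lengths (", a@nbits, " vs ", b@nbits,
         ")")
  ni <- length(intersect(a@bits, b@bits))
  nu <- length(union(a@bits, b@bits))
  if (nu == 0L) return(1)
  ni / nu
}

#' Screen a library against a reference compound
#'
#' In \code{containment} mode a candidate is a hit iff every reference bit is
#' present in the candidate fingerprint (the scaffold reading of "100 percent
#' similarity": elaborated analogs retain all reference paths). In
#' \code{tanimoto} mode a candidate is a hit iff its Tanimoto similarity to
#' the reference is \code{>= cutoff}.
#'
#' @param library a \linkS4class{CompoundLibrary}.
#' @param reference a \linkS4class{Compound}.
#' @param mode \code{"containment"} (default) or \code{"tanimoto"}.
#' @param cutoff Tanimoto cutoff in \code{[0, 1]} (tanimoto mode).
#' @param maxPathBonds,nbits fingerprint parameters.
#' @return data.frame \code{(compound_id, tanimoto, passes)} sorted by
#'   descending similarity, ties broken by id.
#' @export
screenLibrary <- function(library, reference,
                          mode = c("containment", "tanimoto"), cutoff = 1.0,
                          maxPathBonds = 7L, nbits = 2048L) {
  mode <- match.arg(mode)
  stopifnot(is(library, "CompoundLibrary"))
  if (length(library) == 0L) stop("empty library")
  if (cutoff < 0 || cutoff > 1) stop("cutoff must lie in [0, 1]")
  ref <- fingerprint2d(reference, maxPathBonds, nbits)
  sim <- numeric(length(library))
  pass <- logical(length(library))
  for (i in seq_len(length(library))) {
    fp <- fingerprint2d(library[[i]], maxPathBonds, nbits)
    sim[i] <- tanimoto(ref, fp)
    pass[i] <- if (mode == "containment") all(ref@bits %in% fp@bits)
               else sim[i] >= cutoff
  }
  ids <- libraryIds(library)
  out <- data.frame(compound_id = ids, tanimoto = sim, passes = pass,
                    stringsAsFactors = FALSE)
  out[order(-out$tanimoto, out$compound_id), , drop = FALSE]
}
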