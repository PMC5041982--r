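## 3D pharmacophore perception, distance-bin fingerprints and 0-100 scoring.
##
## Six feature types: D (H-bond donor), A (acceptor), H (hydrophobe),
## R (aromatic ring), N (negative ionizable), P (positive ionizable).
## Feature rules are an editable named list of predicate functions over the
## molecular graph + conformer; the shipped defaults are documented in
## defaultFeatureRules(). Fingerprints count unordered feature pairs into
## Euclidean distance bins; similarity is the count-vector (min/max)
## Tanimoto scaled to 0-100.

.FEATURE_TYPES <- c("D", "A", "H", "R", "N", "P")

## perception context: atoms, bonds, neighbour lists, per-atom coordinates
.featureContext <- function(cpd) {
  if (is.null(cpd@conformer))
    stop("compound '", cpd@id, "' has no conformer; ",
         "supply 3D coordinates or run embedConformers()")
  if (is.null(cpd@graph))
    stop("compound '", cpd@id, "' has no molecular graph")
  atoms <- cpd@graph$atoms
  cf <- cpd@conformer
  n <- nrow(atoms)
  coords <- matrix(NA_real_, n, 3)
  if (nrow(cf) == n) {
    coords[] <- as.matrix(cf[, c("x", "y", "z")])
  } else if (nrow(cf) == sum(!atoms$isH)) {
    coords[!atoms$isH, ] <- as.matrix(cf[, c("x", "y", "z")])
  } else {
    stop("conformer atom count does not match the molecular graph for '",
         cpd@id, "'")
  }
  bonds <- cpd@graph$bonds
  nbr <- lapply(seq_len(n), function(i) integer(0))
  for (k in seq_len(nrow(bonds))) {
    nbr[[bonds$a1[k]]] <- c(nbr[[bonds$a1[k]]], bonds$a2[k])
    nbr[[bonds$a2[k]]] <- c(nbr[[bonds$a2[k]]], bonds$a1[k])
  }
  list(atoms = atoms, bonds = bonds, nbr = nbr, coords = coords,
       aromaticRings = cpd@graph$aromaticRings)
}

.centroid <- function(coords, idx) colMeans(coords[idx, , drop = FALSE])

## does heavy atom i carry a double bond to oxygen?
.hasCarbonylO <- function(ctx, i) {
  b <- ctx$bonds
  k <- which((b$a1 == i | b$a2 == i) & b$order == 2L)
  any(ctx$atoms$element[ifelse(b$a1[k] == i, b$a2[k], b$a1[k])] == "O")
}

#' Default pharmacophore feature rules
#'
#' Returns the shipped rule set: a named list (one entry per feature type)
#' of functions mapping a perception context to feature centroids. Replace
#' or drop entries to customise perception. The defaults:
#' \describe{
#'   \item{D}{N or O with at least one (implicit or explicit) hydrogen and
#'     no negative formal charge; centroid at the heavy atom.}
#'   \item{A}{O with non-positive charge, or N with non-positive charge that
#'     is not an aromatic N bearing three heavy neighbours; centroid at the
#'     atom.}
#'   \item{H}{connected components of two or more hydrophobic atoms
#'     (non-aromatic carbon with only C/H neighbours, or Cl/Br/I); centroid
#'     of the component.}
#'   \item{R}{one feature per aromatic ring, at the ring centroid.}
#'   \item{N}{carboxylic/carboxylate groups (C doubly bonded to one O with a
#'     second O carrying H or a negative charge; centroid of the three
#'     atoms) plus any other atom with negative formal charge.}
#'   \item{P}{atoms with positive formal charge, plus aliphatic amine N
#'     (at least one H, not aromatic, no neighbouring carbonyl carbon or
#'     sulfonyl sulfur).}
#' }
#' @return named list of rule functions.
#' @export
defaultFeatureRules <- function() {
  list(
    D = function(ctx) {
      a <- ctx$atoms
      idx <- which(!a$isH & a$element %in% c("N", "O") & a$nH >= 1L &
                   a$charge >= 0L)
      ctx$coords[idx, , drop = FALSE]
    },
    A = function(ctx) {
      a <- ctx$atoms
      nHeavy <- vapply(ctx$nbr, function(v) sum(!a$isH[v]), integer(1))
      keep <- which(!a$isH & a$charge <= 0L &
                    (a$element == "O" |
                     (a$element == "N" & !(a$aromatic & nHeavy >= 3L))))
      ctx$coords[keep, , drop = FALSE]
    },
    H = function(ctx) {
      a <- ctx$atoms
      hydroC <- !a$isH & a$element == "C" & !a$aromatic &
        vapply(seq_along(ctx$nbr), function(i)
          all(a$element[ctx$nbr[[i]]] %in% c("C", "H")), logical(1))
      hydro <- which(hydroC | a$element %in% c("Cl", "Br", "I"))
      if (!length(hydro)) return(matrix(numeric(0), 0, 3))
      ## connected components within the hydrophobic atom set
      comp <- stats::setNames(seq_along(hydro), hydro)
      repeat {
        changed <- FALSE
        for (i in hydro) for (j in ctx$nbr[[i]]) {
          if (!j %in% hydro) next
          ci <- comp[as.character(i)]; cj <- comp[as.character(j)]
          if (ci != cj) { comp[comp == cj] <- ci; changed <- TRUE }
        }
        if (!changed) break
      }
      out <- lapply(unique(comp), function(cc) {
        idx <- as.integer(names(comp)[comp == cc])
        if (length(idx) < 2L) return(NULL)
        matrix(.centroid(ctx$coords, idx), 1, 3)
      })
      do.call(rbind, c(out, list(matrix(numeric(0), 0, 3))))
    },
    R = function(ctx) {
      if (!length(ctx$aromaticRings)) return(matrix(numeric(0), 0, 3))
      do.call(rbind, lapply(ctx$aromaticRings, function(idx)
        matrix(.centroid(ctx$coords, idx), 1, 3)))
    },
    N = function(ctx) {
      a <- ctx$atoms
      used <- integer(0)
      out <- list()
      for (i in which(a$element == "C" & !a$isH)) {
        nb <- ctx$nbr[[i]]
        os <- nb[a$element[nb] == "O"]
        if (length(os) < 2L) next
        b <- ctx$bonds
        dbl <- vapply(os, function(o) any(
          ((b$a1 == i & b$a2 == o) | (b$a2 == i & b$a1 == o)) &
            b$order == 2L), logical(1))
        acid <- vapply(os, function(o) a$nH[o] >= 1L | a$charge[o] < 0L,
                       logical(1))
        if (any(dbl) && any(acid & !dbl)) {
          grp <- c(i, os)
          used <- c(used, grp)
          out[[length(out) + 1L]] <- matrix(.centroid(ctx$coords, grp), 1, 3)
        }
      }
      lone <- which(a$charge < 0L & !a$isH & !(seq_len(nrow(a)) %in% used))
      if (length(lone))
        out[[length(out) + 1L]] <- ctx$coords[lone, , drop = FALSE]
      do.call(rbind, c(out, list(matrix(numeric(0), 0, 3))))
    },
    P = function(ctx) {
      a <- ctx$atoms
      pos <- which(a$charge > 0L & !a$isH)
      amine <- which(a$element == "N" & !a$aromatic & a$nH >= 1L &
                     a$charge == 0L)
      amine <- amine[vapply(amine, function(i) {
        nb <- ctx$nbr[[i]]
        !any(vapply(nb, function(j)
          (a$element[j] == "C" && .hasCarbonylO(ctx, j)) ||
          (a$element[j] == "S" && .hasCarbonylO(ctx, j)), logical(1)))
      }, logical(1))]
      ctx$coords[union(pos, amine), , drop = FALSE]
    })
}

#' Perceive pharmacophore features of a 3D compound
#'
#' @param cpd a \linkS4class{Compound} with a conformer.
#' @param rules named list of feature rules; see
#'   \code{\link{defaultFeatureRules}}.
#' @return data.frame \code{(ftype, x, y, z)}, one row per feature, centroid
#'   coordinates in Angstrom. Deterministic for a given conformer and rule
#'   set.
#' @export
perceiveFeatures <- function(cpd, rules = defaultFeatureRules()) {
  ctx <- .featureContext(cpd)
  out <- lapply(names(rules), function(tt) {
    m <- rules[[tt]](ctx)
    m <- matrix(as.numeric(m), ncol = 3)
    m <- m[stats::complete.cases(m), , drop = FALSE]
    if (!nrow(m)) return(NULL)
    data.frame(ftype = tt, x = m[, 1], y = m[, 2], z = m[, 3],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(out, list(
    data.frame(ftype = character(), x = numeric(), y = numeric(),
               z = numeric(), stringsAsFactors = FALSE))))
  rownames(out) <- NULL
  out
}

#' Pharmacophore distance-bin fingerprint
#'
#' Every unordered feature pair is assigned to the distance bin \code{b}
#' with \code{edges[b] <= d < edges[b+1]}; distances at or beyond the last
#' edge fall into one overflow bin. The total count equals
#' \code{choose(n_features, 2)}.
#'
#' @param features data.frame \code{(ftype, x, y, z)} from
#'   \code{\link{perceiveFeatures}}.
#' @param binEdges strictly increasing bin edges in Angstrom, starting at 0.
#' @return a \linkS4class{PharmFingerprint}.
#' @export
pharmFingerprint <- function(features, binEdges = c(0, 2, 4, 6, 8, 10, 12)) {
  if (length(binEdges) < 2L || binEdges[1] != 0 || any(diff(binEdges) <= 0))
    stop("binEdges must be strictly increasing and start at 0")
  n <- nrow(features)
  keys <- character(0)
  if (n >= 2L) {
    co <- as.matrix(features[, c("x", "y", "z")])
    pr <- utils::combn(n, 2)
    d <- sqrt(rowSums((co[pr[1, ], , drop = FALSE] -
                       co[pr[2, ], , drop = FALSE])^2))
    bin <- findInterval(d, binEdges)
    t1 <- features$ftype[pr[1, ]]
    t2 <- features$ftype[pr[2, ]]
    keys <- paste(pmin(t1, t2), pmax(t1, t2), bin, sep = "|")
  }
  tab <- table(keys)
  counts <- stats::setNames(as.integer(tab), names(tab))
  methods::new("PharmFingerprint", counts = counts,
               binEdges = as.numeric(binEdges))
}

#' Pharmacophore similarity score (0-100)
#'
#' Count-vector Tanimoto over the union of keys, scaled to 0-100:
#' \code{100 * sum(min(a, b)) / sum(max(a, b))}. Two empty fingerprints
#' score 100; exactly one empty scores 0.
#'
#' @param a,b \linkS4class{PharmFingerprint} objects on the same bin edges.
#' @return score in \code{[0, 100]}.
#' @export
pharmSimilarity <- function(a, b) {
  stopifnot(is(a, "PharmFingerprint"), is(b, "PharmFingerprint"))
  if (!isTRUE(all.equal(a@binEdges, b@binEdges)))
    stop("fingerprints use different bin edges")
  if (!length(a@counts) && !length(b@counts)) return(100)
  if (!length(a@counts) || !length(b@counts)) return(0)
  keys <- union(names(a@counts), names(b@counts))
  av <- ifelse(keys %in% names(a@counts), a@counts[keys], 0L)
  bv <- ifelse(keys %in% names(b@counts), b@counts[keys], 0L)
  100 * sum(pmin(av, bv)) / sum(pmax(av, bv))
}

#' Pool reference fingerprints
#'
#' Combines several fingerprints into one by taking, per key, the maximum
#' count (for screening against a family of actives rather than a single
#' reference).
#'
#' @param fps list of \linkS4class{PharmFingerprint} objects on identical
#'   bin edges.
#' @return a \linkS4class{PharmFingerprint}.
#' @export
poolPharmFingerprints <- function(fps) {
  stopifnot(length(fps) >= 1L)
  edges <- fps[[1]]@binEdges
  for (f in fps) if (!isTRUE(all.equal(f@binEdges, edges)))
    stop("fingerprints use different bin edges")
  keys <- unique(unlist(lapply(fps, function(f) names(f@counts))))
  counts <- vapply(keys, function(k)
    max(vapply(fps, function(f)
      if (k %in% names(f@counts)) f@counts[[k]] else 0L, integer(1))),
    integer(1))
  methods::new("PharmFingerprint", counts = counts, binEdges = edges)
}

#' Rank a 3D library by pharmacophore similarity and select hits
#'
#' Scores every library member against the reference fingerprint, ranks in
#' decreasing score order (ties broken by compound id) and selects scores
#' strictly greater than the threshold.
#'
#' @param library a \linkS4class{CompoundLibrary} whose members carry
#'   conformers, or a named list of precomputed feature tables
#'   (data.frames \code{ftype, x, y, z}).
#' @param reference a \linkS4class{Compound} with a conformer, a feature
#'   table, or a precomputed \linkS4class{PharmFingerprint}.
#' @param threshold selection threshold; strictly-greater comparison
#'   (default 70).
#' @param binEdges distance-bin edges, Angstrom.
#' @param rules feature rule set.
#' @return list with \code{ranking} (data.frame \code{compound_id, score,
#'   selected}) and \code{selected} (ids passing the threshold).
#' @export
rankAndSelect <- function(library, reference, threshold = 70,
                          binEdges = c(0, 2, 4, 6, 8, 10, 12),
                          rules = defaultFeatureRules()) {
  if (is(library, "CompoundLibrary")) {
    if (length(library) == 0L) stop("empty library")
    ids <- libraryIds(library)
    fps <- lapply(library@compounds, function(cp)
      pharmFingerprint(perceiveFeatures(cp, rules), binEdges))
  } else if (is.list(library) && length(library) &&
             all(vapply(library, is.data.frame, logical(1)))) {
    ids <- names(library) %||% sprintf("F%04d", seq_along(library))
    fps <- lapply(library, pharmFingerprint, binEdges = binEdges)
  } else stop("library must be a CompoundLibrary or a list of feature tables")
  refFp <- if (is(reference, "PharmFingerprint")) reference
    else if (is.data.frame(reference))
      pharmFingerprint(reference, binEdges)
    else pharmFingerprint(perceiveFeatures(reference, rules), binEdges)
  score <- vapply(fps, function(f) pharmSimilarity(refFp, f), numeric(1))
  rk <- data.frame(compound_id = ids, score = unname(score),
                   stringsAsFactors = FALSE)
  rk <- rk[order(-rk$score, rk$compound_id), , drop = FALSE]
  rk$selected <- rk$score > threshold
  rownames(rk) <- NULL
  list(ranking = rk, selected = rk$compound_id[rk$selected])
}

#' Generate 3D conformers with OpenBabel
#'
#' Deterministic 3D embedding (\code{obabel --gen3d}) for compounds lacking
#' conformers; embedding provenance is recorded in each compound's
#' \code{props} as \code{conformer_source = "obabel --gen3d"}.
#'
#' @param library a \linkS4class{CompoundLibrary}.
#' @return the library with conformers attached.
#' @export
embedConformers <- function(library) {
  stopifnot(is(library, "CompoundLibrary"))
  need <- which(vapply(library@compounds,
                       function(cp) is.null(cp@conformer), logical(1)))
  if (!length(need)) return(library)
  smi <- tempfile(fileext = ".smi")
  sdf <- tempfile(fileext = ".sdf")
  on.exit(unlink(c(smi, sdf)), add = TRUE)
  writeLines(vapply(library@compounds[need],
                    function(cp) paste(cp@smiles, cp@id, sep = "\t"),
                    character(1)), smi)
  status <- system2("obabel", c(smi, "-osdf", "--gen3d", "-O", sdf),
                    stdout = FALSE, stderr = FALSE)
  if (!identical(status, 0L) || !file.exists(sdf))
    stop("obabel --gen3d failed")
  emb <- readLibrary(sdf, format = "sdf")
  embIds <- libraryIds(emb)
  for (i in need) {
    j <- match(library@compounds[[i]]@id, embIds)
    if (is.na(j)) next
    library@compounds[[i]]@conformer <- emb@compounds[[j]]@conformer
    library@compounds[[i]]@graph <- emb@compounds[[j]]@graph
    library@compounds[[i]]@props$conformer_source <- "obabel --gen3d"
  }
  library
}
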