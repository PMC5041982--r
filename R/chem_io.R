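## Compound construction and library I/O.
##
## Parsing of SMILES and SDF V2000 is delegated to ChemmineR/ChemmineOB
## (OpenBabel); on top of the parsed atom/bond blocks this file builds the
## internal molecular-graph representation (elements, formal charges,
## aromaticity, implicit hydrogen counts) that the fingerprint, pharmacophore
## and field code consumes.

.MDL_CHARGE <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
                 `5` = -1L, `6` = -2L, `7` = -3L)

## default valences used for implicit-H assignment; effective valence is
## adjusted by formal charge (N+ binds 4, O- binds 1, C+/- binds 3)
.DEFAULT_VALENCE <- c(H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4,
                      P = 3, S = 2, Cl = 1, Se = 2, Br = 1, I = 1)

.parseOneSmiles <- function(smiles, id) {
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles, id))),
    error = function(e) NULL)
  if (is.null(sdf) || length(sdf) == 0L) return(NULL)
  sdf[[1]]
}

## molecular graph from a single ChemmineR::SDF object
.sdfToGraph <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  element <- sub("_.*$", "", rownames(ab))
  n <- nrow(ab)
  ## V2000 atom-line fields after x,y,z + element: ChemmineR labels the
  ## mass-difference column "C5" and the MDL charge code column "C6"
  chargeCode <- if ("C6" %in% colnames(ab)) as.character(ab[, "C6"]) else
    rep("0", n)
  charge <- unname(.MDL_CHARGE[chargeCode])
  charge[is.na(charge)] <- 0L
  bb <- if (is.null(bb)) matrix(integer(0), 0, 3) else as.matrix(bb)
  if (nrow(bb) && is.null(dim(ChemmineR::bondblock(sdf))))
    bb <- matrix(bb, nrow = 1)
  if (nrow(bb) == 0L || ncol(bb) < 3L) {
    bonds <- data.frame(a1 = integer(), a2 = integer(), order = integer(),
                        aromatic = logical())
  } else {
    bonds <- data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
                        order = as.integer(bb[, 3]), aromatic = FALSE)
    bonds <- bonds[bonds$a1 > 0L & bonds$a2 > 0L, , drop = FALSE]
  }
  aromaticAtom <- rep(FALSE, n)
  aromaticRings <- list()
  if (nrow(bonds) && n >= 3L) {
    rr <- tryCatch(
      suppressWarnings(ChemmineR::rings(sdf, type = "all", arom = TRUE)),
      error = function(e) NULL)
    if (!is.null(rr) && length(rr$RINGS)) {
      bondKey <- paste(pmin(bonds$a1, bonds$a2), pmax(bonds$a1, bonds$a2))
      for (k in seq_along(rr$RINGS)) {
        if (!isTRUE(rr$AROMATIC[[k]])) next
        idx <- as.integer(sub("^.*_", "", rr$RINGS[[k]]))
        aromaticRings[[length(aromaticRings) + 1L]] <- idx
        aromaticAtom[idx] <- TRUE
        cyc <- cbind(idx, c(idx[-1], idx[1]))
        key <- paste(pmin(cyc[, 1], cyc[, 2]), pmax(cyc[, 1], cyc[, 2]))
        bonds$aromatic[bondKey %in% key] <- TRUE
      }
    }
  }
  ## implicit hydrogens from default valences (kekulized bond orders)
  orderSum <- rep(0, n)
  if (nrow(bonds)) {
    tab <- tapply(c(bonds$order, bonds$order), c(bonds$a1, bonds$a2), sum)
    orderSum[as.integer(names(tab))] <- tab
  }
  defv <- .DEFAULT_VALENCE[element]
  defv[is.na(defv)] <- 0
  effv <- ifelse(element %in% c("N", "P"), defv + charge,
          ifelse(element %in% c("O", "S", "Se"), defv + charge,
          ifelse(element == "C", defv - abs(charge), defv)))
  nH <- pmax(0, round(effv - orderSum))
  nH[element == "H"] <- 0
  ## count explicit H neighbours too
  explicitH <- rep(0L, n)
  if (nrow(bonds)) {
    isH <- element == "H"
    hb <- bonds[isH[bonds$a1] | isH[bonds$a2], , drop = FALSE]
    if (nrow(hb)) {
      heavyEnd <- ifelse(isH[hb$a1], hb$a2, hb$a1)
      tb <- table(heavyEnd)
      explicitH[as.integer(names(tb))] <- as.integer(tb)
    }
  }
  list(atoms = data.frame(element = element, charge = charge,
                          aromatic = aromaticAtom,
                          nH = as.integer(nH) + explicitH,
                          isH = element == "H",
                          stringsAsFactors = FALSE),
       bonds = bonds,
       aromaticRings = aromaticRings)
}

.sdfCoords <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  data.frame(element = sub("_.*$", "", rownames(ab)),
             x = ab[, 1], y = ab[, 2], z = ab[, 3],
             stringsAsFactors = FALSE)
}

.sdfIs3D <- function(sdf) {
  hdr <- ChemmineR::header(sdf)
  if (any(grepl("3D", hdr))) return(TRUE)
  any(abs(ChemmineR::atomblock(sdf)[, 3]) > 1e-6)
}

#' Construct a Compound
#'
#' Parses the SMILES with OpenBabel (via ChemmineR) and caches the molecular
#' graph. If a conformer is supplied its heavy-atom count must agree with the
#' molecular graph parsed from the SMILES.
#'
#' @param id compound identifier.
#' @param smiles SMILES string; \code{NA} allowed for conformer-only
#'   pseudo-compounds (synthetic generators), in which case no graph is built.
#' @param conformer \code{NULL} or data.frame with columns
#'   \code{element, x, y, z} (Angstrom).
#' @param props named list of string properties.
#' @return a \linkS4class{Compound}.
#' @examples
#' compound("etoh", "CCO")
#' @export
compound <- function(id, smiles, conformer = NULL, props = list()) {
  smiles <- as.character(smiles)
  graph <- NULL
  if (!is.na(smiles)) {
    sdf <- .parseOneSmiles(smiles, id)
    if (is.null(sdf))
      stop("unparseable SMILES for compound '", id, "': ", smiles)
    graph <- .sdfToGraph(sdf)
  }
  if (!is.null(conformer)) {
    conformer <- as.data.frame(conformer)
    if (!is.null(graph)) {
      nHeavyConf <- sum(conformer$element != "H")
      nHeavyGraph <- sum(!graph$atoms$isH)
      if (nHeavyConf != nHeavyGraph)
        stop("conformer heavy-atom count (", nHeavyConf,
             ") inconsistent with molecular graph (", nHeavyGraph,
             ") for compound '", id, "'")
    }
  }
  methods::new("Compound", id = id, smiles = smiles, conformer = conformer,
               props = props, graph = graph)
}

.newLibrary <- function(compounds, nSkipped = 0L) {
  methods::new("CompoundLibrary", compounds = compounds,
               nSkipped = as.integer(nSkipped))
}

#' Read a compound library
#'
#' Reads a SMILES file (whitespace-separated \code{"smiles id"}, one record
#' per line, lines starting with \code{#} ignored) or an SDF V2000 file.
#' Records that fail to parse are skipped and counted in
#' \code{\link{nSkipped}}. Conformers are populated only from SDF blocks with
#' 3D coordinates.
#'
#' @param path input file.
#' @param format \code{"smiles"}, \code{"sdf"}, or \code{"auto"} (by file
#'   extension).
#' @return a \linkS4class{CompoundLibrary}, in file order.
#' @export
readLibrary <- function(path, format = c("auto", "smiles", "sdf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read library file: ", path)
  if (format == "auto")
    format <- if (grepl("\\.sdf$", path, ignore.case = TRUE)) "sdf"
              else "smiles"
  if (format == "smiles") {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    comps <- list(); skipped <- 0L
    for (i in seq_along(lines)) {
      tok <- strsplit(lines[i], "[[:space:]]+")[[1]]
      smi <- tok[1]
      id <- if (length(tok) >= 2L) tok[2] else sprintf("C%04d", i)
      cp <- tryCatch(compound(id, smi), error = function(e) NULL)
      if (is.null(cp)) skipped <- skipped + 1L
      else comps[[length(comps) + 1L]] <- cp
    }
  } else {
    sdfset <- tryCatch(ChemmineR::read.SDFset(path),
                       error = function(e) stop("cannot parse SDF: ", path))
    ok <- ChemmineR::validSDF(sdfset)
    skipped <- sum(!ok)
    sdfset <- sdfset[ok]
    comps <- vector("list", length(sdfset))
    for (i in seq_along(sdfset)) {
      sdf <- sdfset[[i]]
      id <- ChemmineR::sdfid(sdfset[i])
      if (!nzchar(id) || is.na(id)) id <- sprintf("C%04d", i)
      smi <- tryCatch(
        as.character(suppressWarnings(ChemmineR::sdf2smiles(sdfset[i]))),
        error = function(e) NA_character_)
      conf <- if (.sdfIs3D(sdf)) .sdfCoords(sdf) else NULL
      cp <- methods::new("Compound", id = id,
                         smiles = if (length(smi)) smi else NA_character_,
                         conformer = conf, props = list(),
                         graph = .sdfToGraph(sdf))
      comps[[i]] <- cp
    }
  }
  if (length(comps) == 0L)
    stop("no parseable records in ", path)
  .newLibrary(comps, skipped)
}

#' Write a compound library
#'
#' @param library a \linkS4class{CompoundLibrary}.
#' @param path output file.
#' @param format \code{"smiles"} writes \code{"smiles<TAB>id"} lines.
#' @return invisibly, \code{path}.
#' @export
writeLibrary <- function(library, path, format = c("smiles")) {
  format <- match.arg(format)
  stopifnot(is(library, "CompoundLibrary"))
  lines <- vapply(library@compounds,
                  function(cp) paste(cp@smiles, cp@id, sep = "\t"),
                  character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Canonical SMILES via OpenBabel
#'
#' @param smiles character vector of SMILES.
#' @return canonical SMILES strings.
#' @export
canonicalSmiles <- function(smiles) {
  vapply(smiles, function(s) {
    out <- ChemmineOB::convertFormat("SMI", "CAN", s)
    strsplit(trimws(out), "[[:space:]]+")[[1]][1]
  }, character(1), USE.NAMES = FALSE)
}

#' Read an activity table
#'
#' CSV with header columns \code{compound_id, ic50_molar, assay}; every
#' \code{ic50_molar} must parse as a positive number (row-level validation).
#'
#' @param path CSV file.
#' @return data.frame with one activity record per row, file order preserved.
#' @export
readActivityTable <- function(path) {
  if (!file.exists(path)) stop("cannot read activity table: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("compound_id", "ic50_molar", "assay")
  if (!all(need %in% names(tab)))
    stop("activity table needs columns: ", paste(need, collapse = ", "))
  ic50 <- suppressWarnings(as.numeric(tab$ic50_molar))
  bad <- which(is.na(ic50) | ic50 <= 0)
  if (length(bad))
    stop("invalid ic50_molar (must be a positive number) in row(s): ",
         paste(bad, collapse = ", "))
  dup <- duplicated(tab[, c("compound_id", "assay")])
  if (any(dup))
    stop("duplicate (compound_id, assay) in row(s): ",
         paste(which(dup), collapse = ", "))
  data.frame(compound_id = tab$compound_id, ic50_molar = ic50,
             assay = tab$assay, stringsAsFactors = FALSE)
}
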