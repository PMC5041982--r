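#' @import methods
NULL

setClassUnion("DataFrameOrNULL", c("data.frame", "NULL"))

#' Compound: a small molecule with optional 3D conformer
#'
#' Canonical in-memory representation of one library member: identifier,
#' SMILES, an optional conformer (one row per atom, coordinates in Angstrom),
#' free-form string properties, and a cached molecular graph used by the
#' fingerprint and pharmacophore machinery.
#'
#' @slot id single non-empty compound identifier.
#' @slot smiles SMILES string (may be \code{NA} for site-table
#'   pseudo-compounds emitted by the synthetic generators).
#' @slot conformer \code{NULL} or a data.frame with columns
#'   \code{element, x, y, z}; coordinates are Angstrom, right-handed, as
#'   stored in SDF.
#' @slot props named list of string properties.
#' @slot graph \code{NULL} or the internal molecular-graph list (atoms,
#'   bonds, aromaticity, implicit hydrogen counts) built at parse time.
#'
#' @examples
#' cpd <- compound("benz", "c1ccccc1")
#' compoundId(cpd)
#' @exportClass Compound
#' @aliases Compound-class
setClass("Compound",
  representation(id = "character", smiles = "character",
                 conformer = "DataFrameOrNULL", props = "list",
                 graph = "ANY"))

setValidity("Compound", function(object) {
  msg <- character()
  if (length(object@id) != 1L || is.na(object@id) || !nzchar(object@id))
    msg <- c(msg, "'id' must be a single non-empty string")
  if (length(object@smiles) != 1L)
    msg <- c(msg, "'smiles' must be a single string (possibly NA)")
  if (!is.null(object@conformer)) {
    cf <- object@conformer
    if (!all(c("element", "x", "y", "z") %in% names(cf)))
      msg <- c(msg, "conformer needs columns element, x, y, z")
    else if (nrow(cf) < 1L)
      msg <- c(msg, "conformer must contain at least one atom")
    else if (!all(is.finite(as.matrix(cf[, c("x", "y", "z")]))))
      msg <- c(msg, "conformer coordinates must be finite")
  }
  if (length(msg)) msg else TRUE
})

#' CompoundLibrary: an ordered collection of compounds
#'
#' Thin ordered container over \linkS4class{Compound} objects with a count of
#' records that failed to parse on input.
#'
#' @slot compounds list of \linkS4class{Compound}.
#' @slot nSkipped number of unparseable records skipped while reading.
#' @exportClass CompoundLibrary
#' @aliases CompoundLibrary-class
setClass("CompoundLibrary",
  representation(compounds = "list", nSkipped = "integer"))

setValidity("CompoundLibrary", function(object) {
  if (!all(vapply(object@compounds, is, logical(1), "Compound")))
    return("all elements must be Compound objects")
  ids <- vapply(object@compounds, function(x) x@id, character(1))
  if (anyDuplicated(ids))
    return("compound ids must be unique within a library")
  TRUE
})

#' Fingerprint2D: hashed linear-path 2D fingerprint
#'
#' Bit-set fingerprint over linear heavy-atom bond paths, hashed with 32-bit
#' FNV-1a modulo \code{nbits}.
#'
#' @slot bits sorted integer bit indices in \code{[0, nbits)}.
#' @slot nbits fingerprint length.
#' @exportClass Fingerprint2D
#' @aliases Fingerprint2D-class
setClass("Fingerprint2D",
  representation(bits = "integer", nbits = "integer"))

setValidity("Fingerprint2D", function(object) {
  if (length(object@nbits) != 1L || object@nbits < 1L)
    return("'nbits' must be a positive integer")
  if (length(object@bits) &&
      (min(object@bits) < 0L || max(object@bits) >= object@nbits))
    return("bit indices must lie in [0, nbits)")
  if (is.unsorted(object@bits, strictly = TRUE) && length(object@bits) > 1L)
    return("bits must be sorted and unique")
  TRUE
})

#' PharmFingerprint: pharmacophore distance-bin count fingerprint
#'
#' Count map over (ordered feature-type pair, distance bin) keys. Keys are
#' strings \code{"t1|t2|bin"} with \code{t1 <= t2} lexicographically; the bin
#' index is 1-based with one overflow bin past the last edge.
#'
#' @slot counts named non-negative integer vector.
#' @slot binEdges strictly increasing distance-bin edges in Angstrom,
#'   starting at 0.
#' @exportClass PharmFingerprint
#' @aliases PharmFingerprint-class
setClass("PharmFingerprint",
  representation(counts = "integer", binEdges = "numeric"))

setValidity("PharmFingerprint", function(object) {
  if (length(object@counts) && is.null(names(object@counts)))
    return("counts must be named")
  if (length(object@counts) && any(object@counts < 0L))
    return("counts must be non-negative")
  e <- object@binEdges
  if (length(e) < 2L || e[1] != 0 || any(diff(e) <= 0))
    return("binEdges must be strictly increasing and start at 0")
  TRUE
})

#' PLSModel: NIPALS partial least squares regression model
#'
#' Latent-factor regression of pIC50 on field descriptors, with coefficients
#' back-transformed to the original descriptor space and standard training
#' statistics.
#'
#' @slot nFactors number of latent factors.
#' @slot coefficients regression weights for the kept descriptor columns,
#'   original (unscaled) units.
#' @slot intercept model intercept.
#' @slot r2 training coefficient of determination.
#' @slot fstat regression F statistic, \code{(r2/k)/((1-r2)/(n-k-1))} with
#'   \code{k} the number of latent factors.
#' @slot rmse training root-mean-square error, \code{sqrt(SSres/n)}.
#' @slot see standard error of estimate, \code{sqrt(SSres/(n-k-1))}.
#' @slot keptColumns indices of descriptor columns surviving the variance
#'   filter.
#' @slot nSamples,nColumns training dimensions.
#' @slot gridSpec \code{NULL} or the field-grid specification the
#'   descriptors were computed on (used by \code{\link{fieldMaps}}).
#' @slot channels descriptor channel names when fitted on field grids.
#' @exportClass PLSModel
#' @aliases PLSModel-class
setClass("PLSModel",
  representation(nFactors = "integer", coefficients = "numeric",
                 intercept = "numeric", r2 = "numeric", fstat = "numeric",
                 rmse = "numeric", see = "numeric", keptColumns = "integer",
                 nSamples = "integer", nColumns = "integer",
                 gridSpec = "ANY", channels = "character"))

setValidity("PLSModel", function(object) {
  if (object@nFactors < 1L)
    return("nFactors must be >= 1")
  if (length(object@coefficients) != length(object@keptColumns))
    return("one coefficient per kept column required")
  if (!is.na(object@r2) && (object@r2 < -1e-8 || object@r2 > 1 + 1e-8))
    return("r2 out of [0, 1]")
  if (object@rmse < 0)
    return("rmse must be non-negative")
  TRUE
})

#' FourPLFit: four-parameter logistic dose-response fit
#'
#' @slot ic50 fitted half-maximal inhibitory concentration, molar.
#' @slot hill fitted hill slope.
#' @slot top,bottom fitted plateaus, percent of control.
#' @slot rss residual sum of squares.
#' @slot converged did the optimizer converge.
#' @slot diagnostics list with optimizer details (message, starts tried).
#' @exportClass FourPLFit
#' @aliases FourPLFit-class
setClass("FourPLFit",
  representation(ic50 = "numeric", hill = "numeric", top = "numeric",
                 bottom = "numeric", rss = "numeric", converged = "logical",
                 diagnostics = "list"))

setValidity("FourPLFit", function(object) {
  if (length(object@ic50) != 1L || is.na(object@ic50) || object@ic50 <= 0)
    return("ic50 must be a single positive number")
  TRUE
})

#' BindingFit: law-of-mass-action binding fit
#'
#' Quadratic mass-action fit of an F_norm titration at fixed labeled-target
#' concentration.
#'
#' @slot kd fitted dissociation constant, molar.
#' @slot baseline,amplitude F_norm baseline and transition amplitude.
#' @slot targetConc fixed labeled-target concentration, molar.
#' @slot rss residual sum of squares.
#' @slot converged did the optimizer converge.
#' @exportClass BindingFit
#' @aliases BindingFit-class
setClass("BindingFit",
  representation(kd = "numeric", baseline = "numeric", amplitude = "numeric",
                 targetConc = "numeric", rss = "numeric",
                 converged = "logical"))

setValidity("BindingFit", function(object) {
  if (object@kd <= 0) return("kd must be positive")
  if (object@targetConc <= 0) return("targetConc must be positive")
  TRUE
})

#' CrosstabSummary: regulation cross-tabulation of a DE gene table
#'
#' Counts by (direction, prior STAT3 regulation, prior STAT1 regulation) and
#' the named derived fractions, each with numerator and denominator recorded.
#'
#' @slot counts data.frame with columns \code{direction, stat3, stat1, n}.
#' @slot fractions data.frame with columns
#'   \code{name, numerator, denominator, value} (value \code{NA} when the
#'   denominator is zero: undefined, not 0).
#' @slot nDown,nUp input list sizes.
#' @exportClass CrosstabSummary
#' @aliases CrosstabSummary-class
setClass("CrosstabSummary",
  representation(counts = "data.frame", fractions = "data.frame",
                 nDown = "integer", nUp = "integer"))

setValidity("CrosstabSummary", function(object) {
  if (sum(object@counts$n) != object@nDown + object@nUp)
    return("cell counts must partition the input genes")
  fr <- object@fractions
  if (nrow(fr) && any(fr$numerator > fr$denominator))
    return("every fraction numerator must be <= its denominator")
  TRUE
})
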