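#' @rdname Compound-class
#' @param object,x an object.
#' @export
setGeneric("compoundId", function(x) standardGeneric("compoundId"))
#' @rdname Compound-class
#' @export
setGeneric("compoundSmiles", function(x) standardGeneric("compoundSmiles"))
#' @rdname Compound-class
#' @export
setGeneric("conformer", function(x) standardGeneric("conformer"))
#' @rdname CompoundLibrary-class
#' @param x a \linkS4class{CompoundLibrary}.
#' @export
setGeneric("compounds", function(x) standardGeneric("compounds"))
#' @rdname CompoundLibrary-class
#' @export
setGeneric("nSkipped", function(x) standardGeneric("nSkipped"))
#' @rdname Fingerprint2D-class
#' @param x a fingerprint.
#' @export
setGeneric("fpBits", function(x) standardGeneric("fpBits"))
#' @rdname Fingerprint2D-class
#' @export
setGeneric("fpLength", function(x) standardGeneric("fpLength"))
#' @rdname PharmFingerprint-class
#' @param x a fingerprint.
#' @export
setGeneric("fpCounts", function(x) standardGeneric("fpCounts"))
#' @rdname PharmFingerprint-class
#' @export
setGeneric("binEdges", function(x) standardGeneric("binEdges"))

setMethod("compoundId", "Compound", function(x) x@id)
setMethod("compoundSmiles", "Compound", function(x) x@smiles)
setMethod("conformer", "Compound", function(x) x@conformer)
setMethod("compounds", "CompoundLibrary", function(x) x@compounds)
setMethod("nSkipped", "CompoundLibrary", function(x) x@nSkipped)
setMethod("fpBits", "Fingerprint2D", function(x) x@bits)
setMethod("fpLength", "Fingerprint2D", function(x) x@nbits)
setMethod("fpCounts", "PharmFingerprint", function(x) x@counts)
setMethod("binEdges", "PharmFingerprint", function(x) x@binEdges)

#' @rdname CompoundLibrary-class
#' @export
setMethod("length", "CompoundLibrary", function(x) length(x@compounds))

#' @rdname CompoundLibrary-class
#' @param i index or compound id.
#' @param j,...,drop ignored.
#' @export
setMethod("[[", "CompoundLibrary", function(x, i, j, ...) {
  if (is.character(i)) {
    k <- match(i, libraryIds(x))
    if (is.na(k)) stop("no compound with id '", i, "'")
    i <- k
  }
  x@compounds[[i]]
})

#' @rdname CompoundLibrary-class
#' @export
setMethod("[", "CompoundLibrary", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, libraryIds(x))
  initialize(x, compounds = x@compounds[i])
})

#' Compound ids of a library
#' @param x a \linkS4class{CompoundLibrary}.
#' @return character vector of ids, in library order.
#' @export
libraryIds <- function(x) {
  stopifnot(is(x, "CompoundLibrary"))
  vapply(x@compounds, function(cp) cp@id, character(1))
}

setMethod("show", "Compound", function(object) {
  cat("Compound '", object@id, "'\n  SMILES: ", object@smiles, "\n", sep = "")
  if (!is.null(object@conformer))
    cat("  conformer: ", nrow(object@conformer), " atoms (3D)\n", sep = "")
})

setMethod("show", "CompoundLibrary", function(object) {
  cat("CompoundLibrary with ", length(object), " compounds",
      if (object@nSkipped > 0L)
        paste0(" (", object@nSkipped, " unparseable records skipped)"),
      "\n", sep = "")
  n <- min(length(object), 5L)
  for (i in seq_len(n))
    cat("  ", object@compounds[[i]]@id, ": ",
        object@compounds[[i]]@smiles, "\n", sep = "")
  if (length(object) > n) cat("  ...\n")
})

setMethod("show", "Fingerprint2D", function(object) {
  cat("Fingerprint2D: ", length(object@bits), " of ", object@nbits,
      " bits set\n", sep = "")
})

setMethod("show", "PharmFingerprint", function(object) {
  cat("PharmFingerprint: ", length(object@counts), " (type pair, bin) keys, ",
      sum(object@counts), " pairs; edges [",
      paste(object@binEdges, collapse = ", "), "] A\n", sep = "")
})

setMethod("show", "PLSModel", function(object) {
  cat("PLSModel: ", object@nFactors, " factors, n = ", object@nSamples,
      ", p = ", object@nColumns, " (", length(object@keptColumns),
      " kept)\n", sep = "")
  cat(sprintf("  r2 = %.4f  F = %.2f  rmse = %.4f  see = %.4f\n",
              object@r2, object@fstat, object@rmse, object@see))
})

setMethod("show", "FourPLFit", function(object) {
  cat(sprintf(
    "FourPLFit: IC50 = %.4g M, hill = %.3f, top = %.1f, bottom = %.1f%s\n",
    object@ic50, object@hill, object@top, object@bottom,
    if (object@converged) "" else "  [NOT CONVERGED]"))
})

setMethod("show", "BindingFit", function(object) {
  cat(sprintf(
    "BindingFit: KD = %.4g M (target %.3g M), baseline = %.4g, amplitude = %.4g%s\n",
    object@kd, object@targetConc, object@baseline, object@amplitude,
    if (object@converged) "" else "  [NOT CONVERGED]"))
})

setMethod("show", "CrosstabSummary", function(object) {
  cat("CrosstabSummary: ", object@nDown, " down, ", object@nUp,
      " up genes\n", sep = "")
  fr <- object@fractions
  for (i in seq_len(nrow(fr)))
    cat(sprintf("  %-28s %3d / %3d%s\n", fr$name[i], fr$numerator[i],
                fr$denominator[i],
                if (is.na(fr$value[i])) "  (undefined)"
                else sprintf("  = %.1f%%", 100 * fr$value[i])))
})
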