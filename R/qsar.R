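## Field-based 3D-QSAR: rigid common-scaffold alignment, Gaussian-kernel
## field grids in four channels, NIPALS partial least squares on pIC50,
## training statistics, repeated leave-k-out cross-validation (q2),
## prediction and favourable/disfavoured coefficient maps.

#' AlignedSet: compounds superposed into a common frame
#'
#' @slot library the aligned \linkS4class{CompoundLibrary}.
#' @slot rmsd per-compound RMSD (Angstrom) over the mapped scaffold atoms
#'   after superposition.
#' @slot transforms per-compound list with rotation matrix \code{R} and
#'   translation \code{t} (applied as \code{x R + t}).
#' @exportClass AlignedSet
#' @aliases AlignedSet-class
setClass("AlignedSet",
  representation(library = "CompoundLibrary", rmsd = "numeric",
                 transforms = "list"))

setMethod("show", "AlignedSet", function(object) {
  cat("AlignedSet: ", length(object@library), " compounds, scaffold RMSD ",
      sprintf("%.3f", mean(object@rmsd)), " A (mean)\n", sep = "")
})

.FIELD_CHANNELS <- c("donor", "hydrophobic", "electron_withdrawing",
                     "negative_ionic")

#' pIC50 from a molar IC50
#'
#' @param ic50 IC50 values in molar units; must be positive.
#' @return \code{-log10(ic50)}.
#' @examples
#' pic50(1e-6)    # 6
#' pic50(2.5e-6)  # 5.602
#' @export
pic50 <- function(ic50) {
  if (any(!is.finite(ic50)) || any(ic50 <= 0))
    stop("ic50 must be positive (molar)")
  -log10(ic50)
}

#' Regression F statistic of a latent-factor model
#'
#' The standard regression F with the latent-factor count as model degrees
#' of freedom: \code{F = (r2 / k) / ((1 - r2) / (n - k - 1))}.
#'
#' @param r2 training coefficient of determination.
#' @param k number of latent factors.
#' @param n number of training samples.
#' @return the F statistic.
#' @examples
#' plsFstatistic(0.94, 4, 39)
#' @export
plsFstatistic <- function(r2, k, n) {
  if (n - k - 1 <= 0) return(NA_real_)
  (r2 / k) / ((1 - r2) / (n - k - 1))
}

## least-squares proper rotation (Kabsch); maps P onto Q as P %*% R + t
.kabsch <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  A <- t(sweep(P, 2, cp)) %*% sweep(Q, 2, cq)
  s <- svd(A)
  if (sum(s$d > max(s$d) * 1e-8) < 2L)
    warning("degenerate (collinear) scaffold atoms; ",
            "superposition is not unique")
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  t <- cq - cp %*% R
  list(R = R, t = as.numeric(t))
}

#' Rigid common-scaffold superposition
#'
#' Superposes each compound's mapped scaffold atoms onto the reference by
#' the least-squares rigid (proper rotation + translation, Kabsch)
#' transform and applies that transform to the whole conformer.
#'
#' @param library a \linkS4class{CompoundLibrary} with conformers.
#' @param reference a \linkS4class{Compound} with a conformer.
#' @param scaffoldMap a two-column integer matrix (compound atom row,
#'   reference atom row), or a list of such matrices, one per compound.
#'   At least 3 mapped atoms are required.
#' @return an \linkS4class{AlignedSet}.
#' @export
alignRigid <- function(library, reference, scaffoldMap) {
  stopifnot(is(library, "CompoundLibrary"))
  if (is.null(reference@conformer)) stop("reference has no conformer")
  refXYZ <- as.matrix(reference@conformer[, c("x", "y", "z")])
  if (!is.list(scaffoldMap))
    scaffoldMap <- rep(list(scaffoldMap), length(library))
  if (length(scaffoldMap) != length(library))
    stop("need one scaffold map per compound")
  rmsd <- numeric(length(library))
  transforms <- vector("list", length(library))
  for (i in seq_len(length(library))) {
    cp <- library@compounds[[i]]
    if (is.null(cp@conformer))
      stop("compound '", cp@id, "' has no conformer")
    m <- as.matrix(scaffoldMap[[i]])
    if (nrow(m) < 3L)
      stop("alignment of '", cp@id, "' needs at least 3 mapped atoms")
    X <- as.matrix(cp@conformer[, c("x", "y", "z")])
    tr <- .kabsch(X[m[, 1], , drop = FALSE], refXYZ[m[, 2], , drop = FALSE])
    Xnew <- X %*% tr$R + matrix(tr$t, nrow(X), 3, byrow = TRUE)
    rmsd[i] <- sqrt(mean(rowSums(
      (Xnew[m[, 1], , drop = FALSE] - refXYZ[m[, 2], , drop = FALSE])^2)))
    cp@conformer[, c("x", "y", "z")] <- Xnew
    library@compounds[[i]] <- cp
    transforms[[i]] <- tr
  }
  names(rmsd) <- libraryIds(library)
  methods::new("AlignedSet", library = library, rmsd = rmsd,
               transforms = transforms)
}

## channel site tables (position + weight) for one compound
.fieldSites <- function(cpd, rules = defaultFeatureRules()) {
  if (is.data.frame(cpd)) {
    ## pseudo-compound: a ready site table (x, y, z, channel, weight)
    need <- c("x", "y", "z", "channel", "weight")
    if (!all(need %in% names(cpd)))
      stop("site table needs columns ", paste(need, collapse = ", "))
    if (!all(cpd$channel %in% .FIELD_CHANNELS))
      stop("unknown field channel in site table")
    return(lapply(stats::setNames(.FIELD_CHANNELS, .FIELD_CHANNELS),
                  function(ch) {
      s <- cpd[cpd$channel == ch, , drop = FALSE]
      list(xyz = as.matrix(s[, c("x", "y", "z")]), w = s$weight)
    }))
  }
  ctx <- .featureContext(cpd)
  atoms <- ctx$atoms
  ## donor sites: explicit H on N/O when present, else the heavy donor atom
  donorHeavy <- which(!atoms$isH & atoms$element %in% c("N", "O") &
                      atoms$nH >= 1L & atoms$charge >= 0L)
  dxyz <- matrix(numeric(0), 0, 3)
  for (i in donorHeavy) {
    hs <- ctx$nbr[[i]][atoms$isH[ctx$nbr[[i]]]]
    hs <- hs[!is.na(ctx$coords[hs, 1])]
    dxyz <- rbind(dxyz, if (length(hs)) ctx$coords[hs, , drop = FALSE]
                        else ctx$coords[i, , drop = FALSE])
  }
  hydro <- which((!atoms$isH & atoms$element == "C" & !atoms$aromatic &
                  vapply(seq_along(ctx$nbr), function(i)
                    all(atoms$element[ctx$nbr[[i]]] %in% c("C", "H")),
                    logical(1))) |
                 atoms$element %in% c("Cl", "Br", "I"))
  q <- gasteigerCharges(cpd)
  heavyIdx <- which(!atoms$isH)
  negQ <- which(q < 0)
  nion <- rules$N(ctx)
  nion <- matrix(as.numeric(nion), ncol = 3)
  nion <- nion[stats::complete.cases(nion), , drop = FALSE]
  list(
    donor = list(xyz = dxyz, w = rep(1, nrow(dxyz))),
    hydrophobic = list(xyz = ctx$coords[hydro, , drop = FALSE],
                       w = rep(1, length(hydro))),
    electron_withdrawing = list(
      xyz = ctx$coords[heavyIdx[negQ], , drop = FALSE], w = abs(q[negQ])),
    negative_ionic = list(xyz = nion, w = rep(1, nrow(nion))))
}

#' Build a field-grid specification
#'
#' @param origin grid origin (Angstrom).
#' @param spacing grid spacing (Angstrom, default 1).
#' @param dims integer grid dimensions \code{c(nx, ny, nz)}.
#' @return a grid-spec list.
#' @export
fieldGridSpec <- function(origin, spacing = 1, dims) {
  stopifnot(length(origin) == 3L, length(dims) == 3L, spacing > 0)
  list(origin = as.numeric(origin), spacing = as.numeric(spacing),
       dims = as.integer(dims))
}

.gridPoints <- function(spec) {
  ax <- lapply(1:3, function(k)
    spec$origin[k] + spec$spacing * (seq_len(spec$dims[k]) - 1L))
  as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
}

#' Compute four-channel Gaussian field descriptors
#'
#' At each grid point \code{g} the channel value is
#' \code{sum_s w_s exp(-alpha r(s, g)^2)} over the channel's sites:
#' H-bond donor sites (weight 1), hydrophobic atoms (weight 1), atoms with
#' negative Gasteiger partial charge (weight |q|), and negative-ionizable
#' group centroids (weight 1).
#'
#' @param x an \linkS4class{AlignedSet}, a \linkS4class{CompoundLibrary}, or
#'   a list of \linkS4class{Compound} objects / site tables (data.frames
#'   with columns \code{x, y, z, channel, weight}).
#' @param gridSpec a grid spec from \code{\link{fieldGridSpec}}, or
#'   \code{NULL} to enclose all sites with \code{margin} Angstrom on every
#'   side. When an explicit grid is supplied, sites outside it raise a
#'   grid-bounds error.
#' @param spacing,margin grid construction parameters, Angstrom.
#' @param alpha Gaussian decay, 1/Angstrom^2 (default 0.5).
#' @param ids row names for the descriptor matrix.
#' @return a \code{FieldGridSet}: list with the descriptor matrix \code{X}
#'   (one row per compound, channels concatenated channel-major), the
#'   \code{gridSpec}, \code{channels} and \code{alpha}.
#' @export
computeFields <- function(x, gridSpec = NULL, spacing = 1, margin = 3,
                          alpha = 0.5, ids = NULL) {
  items <- if (is(x, "AlignedSet")) x@library@compounds
    else if (is(x, "CompoundLibrary")) x@compounds
    else if (is.list(x)) x
    else stop("unsupported input for computeFields()")
  if (is.null(ids))
    ids <- vapply(seq_along(items), function(i) {
      it <- items[[i]]
      if (is(it, "Compound")) it@id else sprintf("S%04d", i)
    }, character(1))
  sites <- lapply(items, .fieldSites)
  allXYZ <- do.call(rbind, lapply(sites, function(s)
    do.call(rbind, lapply(s, `[[`, "xyz"))))
  if (is.null(gridSpec)) {
    if (!nrow(allXYZ)) stop("no field sites found; cannot size a grid")
    lo <- apply(allXYZ, 2, min) - margin
    hi <- apply(allXYZ, 2, max) + margin
    gridSpec <- fieldGridSpec(lo, spacing,
                              pmax(2L, ceiling((hi - lo) / spacing) + 1L))
  } else if (nrow(allXYZ)) {
    lo <- gridSpec$origin
    hi <- gridSpec$origin + gridSpec$spacing * (gridSpec$dims - 1L)
    if (any(sweep(allXYZ, 2, lo) < 0) || any(sweep(allXYZ, 2, hi) > 0))
      stop("grid-bounds error: sites lie outside the supplied field grid")
  }
  G <- .gridPoints(gridSpec)
  m <- nrow(G)
  X <- matrix(0, length(items), 4L * m,
              dimnames = list(ids, paste(rep(.FIELD_CHANNELS, each = m),
                                         rep(seq_len(m), 4L), sep = ".")))
  for (i in seq_along(items)) {
    for (ci in seq_along(.FIELD_CHANNELS)) {
      s <- sites[[i]][[.FIELD_CHANNELS[ci]]]
      if (!nrow(s$xyz)) next
      d2 <- outer(rowSums(G^2), rowSums(s$xyz^2), "+") -
        2 * G %*% t(s$xyz)
      X[i, (ci - 1L) * m + seq_len(m)] <-
        exp(-alpha * pmax(d2, 0)) %*% s$w
    }
  }
  structure(list(X = X, gridSpec = gridSpec, channels = .FIELD_CHANNELS,
                 alpha = alpha), class = "FieldGridSet")
}

#' @export
print.FieldGridSet <- function(x, ...) {
  cat("FieldGridSet: ", nrow(x$X), " compounds x ", ncol(x$X),
      " descriptors (", paste(x$gridSpec$dims, collapse = "x"),
      " grid, spacing ", x$gridSpec$spacing, " A, alpha ", x$alpha,
      ")\n", sep = "")
  invisible(x)
}

.descriptorMatrix <- function(X) {
  if (inherits(X, "FieldGridSet")) X$X else as.matrix(X)
}

#' Fit a NIPALS partial least squares QSAR model
#'
#' Columns with variance below \code{varTol} are dropped, the rest centred
#' and scaled to unit variance; NIPALS extracts \code{nFactors} latent
#' variables and the coefficients are returned in the original descriptor
#' space. Training statistics: \code{r2 = 1 - SSres/SStot},
#' \code{rmse = sqrt(SSres/n)}, standard error of estimate
#' \code{sqrt(SSres/(n-k-1))} and \code{F = (r2/k)/((1-r2)/(n-k-1))} with
#' \code{k = nFactors}.
#'
#' @param X descriptor matrix or \code{FieldGridSet}.
#' @param y response (pIC50) vector.
#' @param nFactors number of latent factors (default 4).
#' @param varTol variance filter threshold (default 1e-8).
#' @return a \linkS4class{PLSModel}.
#' @export
fitPLS <- function(X, y, nFactors = 4L, varTol = 1e-8) {
  gridSpec <- if (inherits(X, "FieldGridSet")) X$gridSpec else NULL
  channels <- if (inherits(X, "FieldGridSet")) X$channels else character(0)
  X <- .descriptorMatrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (length(y) != n) stop("length(y) must match nrow(X)")
  nFactors <- as.integer(nFactors)
  if (n < nFactors + 2L)
    stop("under-determined: need at least nFactors + 2 samples")
  if (stats::var(y) < 1e-16)
    stop("degenerate response: y has zero variance")
  colVar <- apply(X, 2, stats::var)
  kept <- which(colVar >= varTol)
  if (!length(kept)) stop("no descriptor column survives the variance filter")
  if (nFactors > min(n - 1L, length(kept)))
    stop("nFactors exceeds min(n_samples - 1, n_descriptors)")
  Xk <- X[, kept, drop = FALSE]
  mu <- colMeans(Xk)
  sdv <- sqrt(colVar[kept])
  Xs <- sweep(sweep(Xk, 2, mu), 2, sdv, "/")
  ybar <- mean(y)
  f <- y - ybar
  E <- Xs
  p <- ncol(Xs)
  W <- matrix(0, p, nFactors); P <- matrix(0, p, nFactors)
  qv <- numeric(nFactors)
  for (a in seq_len(nFactors)) {
    w <- drop(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14) { nFactors <- a - 1L; break }
    w <- w / nw
    tt <- drop(E %*% w)
    tt2 <- sum(tt^2)
    pp <- drop(crossprod(E, tt)) / tt2
    qq <- sum(f * tt) / tt2
    E <- E - tcrossprod(tt, pp)
    f <- f - qq * tt
    W[, a] <- w; P[, a] <- pp; qv[a] <- qq
  }
  if (nFactors < 1L) stop("response is orthogonal to all descriptors")
  W <- W[, seq_len(nFactors), drop = FALSE]
  P <- P[, seq_len(nFactors), drop = FALSE]
  qv <- qv[seq_len(nFactors)]
  Bs <- W %*% solve(crossprod(P, W), qv)
  beta <- drop(Bs) / sdv
  intercept <- ybar - sum(beta * mu)
  fitted <- intercept + drop(Xk %*% beta)
  ssRes <- sum((y - fitted)^2)
  ssTot <- sum((y - ybar)^2)
  r2 <- 1 - ssRes / ssTot
  k <- nFactors
  fstat <- plsFstatistic(r2, k, n)
  methods::new("PLSModel", nFactors = nFactors, coefficients = unname(beta),
               intercept = intercept, r2 = r2, fstat = fstat,
               rmse = sqrt(ssRes / n),
               see = if (n - k - 1L > 0L) sqrt(ssRes / (n - k - 1L))
                     else NA_real_,
               keptColumns = as.integer(kept), nSamples = as.integer(n),
               nColumns = ncol(X), gridSpec = gridSpec, channels = channels)
}

#' Predict pIC50 from a fitted PLS model
#'
#' @param object a \linkS4class{PLSModel}.
#' @param newdata descriptor matrix, single descriptor vector, or
#'   \code{FieldGridSet} (must match the model's grid specification).
#' @param ... ignored.
#' @return predicted pIC50 values.
#' @export
setMethod("predict", "PLSModel", function(object, newdata, ...) {
  if (inherits(newdata, "FieldGridSet") && !is.null(object@gridSpec) &&
      !isTRUE(all.equal(newdata$gridSpec, object@gridSpec)))
    stop("field grid of 'newdata' does not match the model grid")
  if (is.numeric(newdata) && is.null(dim(newdata)))
    newdata <- matrix(newdata, nrow = 1)
  X <- .descriptorMatrix(newdata)
  if (ncol(X) != object@nColumns)
    stop("descriptor count mismatch: model expects ", object@nColumns)
  drop(object@intercept +
       X[, object@keptColumns, drop = FALSE] %*% object@coefficients)
})

#' Repeated leave-k-out cross-validation (q2)
#'
#' Each repeat draws a seeded random partition of the samples into folds of
#' size \code{k}; each fold is predicted from a model fitted on the
#' remainder. \code{q2 = 1 - PRESS / sum((y - mean(y))^2)} with PRESS summed
#' over all folds of a repeat; the reported \code{q2} is the mean over
#' repeats.
#'
#' @param X descriptor matrix or \code{FieldGridSet}.
#' @param y response vector.
#' @param k fold size (leave-k-out, default 5).
#' @param nRepeats number of repeated partitions (default 5).
#' @param nFactors PLS factors (default 4).
#' @param seed RNG seed for the partitions (default 20160325).
#' @param varTol variance filter threshold passed to \code{\link{fitPLS}}.
#' @return a \code{CVReport} list: \code{scheme, k, nRepeats, nFactors,
#'   seed, q2, q2PerRepeat, trainR2PerRepeat, press, residuals}.
#' @export
crossValidate <- function(X, y, k = 5L, nRepeats = 5L, nFactors = 4L,
                          seed = 20160325L, varTol = 1e-8) {
  X <- .descriptorMatrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (k >= n) stop("fold size k must be smaller than the number of samples")
  ssTot <- sum((y - mean(y))^2)
  res <- NULL
  q2rep <- numeric(nRepeats); pressRep <- numeric(nRepeats)
  trainR2 <- numeric(nRepeats)
  withr::with_seed(as.integer(seed), {
    for (r in seq_len(nRepeats)) {
      perm <- sample.int(n)
      foldId <- ceiling(seq_len(n) / k)[order(perm)]  # folds of size k
      press <- 0; tr2 <- numeric(0)
      for (fold in unique(foldId)) {
        test <- which(foldId == fold)
        fit <- fitPLS(X[-test, , drop = FALSE], y[-test],
                      nFactors = nFactors, varTol = varTol)
        pred <- predict(fit, X[test, , drop = FALSE])
        press <- press + sum((y[test] - pred)^2)
        tr2 <- c(tr2, fit@r2)
        res <- rbind(res, data.frame(repeatId = r, fold = fold,
                                     index = test, observed = y[test],
                                     predicted = pred))
      }
      pressRep[r] <- press
      q2rep[r] <- 1 - press / ssTot
      trainR2[r] <- mean(tr2)
    }
  })
  structure(list(scheme = "leave-k-out", k = as.integer(k),
                 nRepeats = as.integer(nRepeats),
                 nFactors = as.integer(nFactors), seed = as.integer(seed),
                 q2 = mean(q2rep), q2PerRepeat = q2rep,
                 trainR2PerRepeat = trainR2, press = pressRep,
                 residuals = res),
            class = "CVReport")
}

#' @export
print.CVReport <- function(x, ...) {
  cat("CVReport: leave-", x$k, "-out x ", x$nRepeats, " repeats, ",
      x$nFactors, " factors (seed ", x$seed, ")\n", sep = "")
  cat(sprintf("  q2 = %.4f (per repeat: %s)\n", x$q2,
              paste(sprintf("%.3f", x$q2PerRepeat), collapse = ", ")))
  invisible(x)
}

#' Favourable/disfavoured field coefficient maps
#'
#' Reshapes the model coefficients back onto the field grid, one signed
#' value per (grid point, channel): positive favourable, negative
#' disfavoured; dropped (constant-field) points carry 0.
#'
#' @param model a \linkS4class{PLSModel} fitted on a \code{FieldGridSet}.
#' @return data.frame \code{(x, y, z, channel, coefficient)} with
#'   \code{4 * nx * ny * nz} rows.
#' @export
fieldMaps <- function(model) {
  stopifnot(is(model, "PLSModel"))
  if (is.null(model@gridSpec))
    stop("model was not fitted on field-grid descriptors")
  G <- .gridPoints(model@gridSpec)
  m <- nrow(G)
  coefs <- numeric(model@nColumns)
  coefs[model@keptColumns] <- model@coefficients
  data.frame(x = rep(G[, 1], 4L), y = rep(G[, 2], 4L), z = rep(G[, 3], 4L),
             channel = rep(model@channels, each = m),
             coefficient = coefs, stringsAsFactors = FALSE)
}
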