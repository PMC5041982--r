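## Seeded synthetic-data generators. Every generator is a pure function of
## (seed, parameters) and returns its ground truth alongside the data so
## the analysis modules can be tested closed-loop. Each generator draws
## from its own stream: the effective seed is derived from the user seed
## and the generator name by FNV-1a hashing (modulo 2^31 - 1), so adding
## parameters or calling generators in a different order never perturbs
## unrelated draws.

.deriveSeed <- function(seed, stream) {
  as.integer((as.numeric(seed) + .fnv1a32(stream)) %% (2^31 - 1))
}

.C188_SCAFFOLD <- "O=S(=O)(Nc1cccc2ccccc12)c1ccccc1"

.ANALOG_SUBSTITUENTS <- c("C", "CC", "CCC", "C(C)C", "CCO", "OC", "Cl",
                          "Br", "N", "CCN", "C#N", "c2ccc(O)cc2")

.DECOY_FRAGMENTS <- c("C", "O", "N", "CC", "CO", "CN", "CCO", "C(C)",
                      "C(=O)O", "CCN", "CCC")
.DECOY_STARTERS <- c("", "", "c1ccncc1", "C1CCCCC1", "c1ccoc1")

#' Generate a screening library with planted scaffold analogs
#'
#' Analogs are the reference scaffold elaborated with a substituent at the
#' para position of its benzenesulfonyl ring, so every reference bond path
#' survives and 2D containment screening is guaranteed to retain them.
#' Decoys are scaffold-free molecules assembled from a small fragment
#' grammar (chains, esters, amines, single heterocycles).
#'
#' @param seed integer seed.
#' @param nDecoys,nAnalogs library composition.
#' @param referenceSmiles reference scaffold; the default is an
#'   N-naphth-1-yl benzenesulfonamide.
#' @param analogTemplate \code{sprintf} template placing a substituent on
#'   the reference scaffold.
#' @return list with \code{library} (a \linkS4class{CompoundLibrary}),
#'   \code{reference} (a \linkS4class{Compound}), and \code{truth}
#'   (data.frame \code{id, is_analog}).
#' @export
genLibrary <- function(seed, nDecoys = 100L, nAnalogs = 5L,
                       referenceSmiles = .C188_SCAFFOLD,
                       analogTemplate =
                         "O=S(=O)(Nc1cccc2ccccc12)c1ccc(%s)cc1") {
  stopifnot(nDecoys >= 0L, nAnalogs >= 0L)
  reference <- compound("REF", referenceSmiles)  # errors if unparseable
  withr::with_seed(.deriveSeed(seed, "library"), {
    subs <- sample(.ANALOG_SUBSTITUENTS,
                   nAnalogs, replace = nAnalogs > length(.ANALOG_SUBSTITUENTS))
    analogs <- lapply(seq_len(nAnalogs), function(i)
      compound(sprintf("A%03d", i), sprintf(analogTemplate, subs[i])))
    decoys <- list()
    while (length(decoys) < nDecoys) {
      smi <- paste0(sample(.DECOY_STARTERS, 1),
                    paste(sample(.DECOY_FRAGMENTS,
                                 sample(3:6, 1), replace = TRUE),
                          collapse = ""))
      cp <- tryCatch(compound(sprintf("D%03d", length(decoys) + 1L), smi),
                     error = function(e) NULL)
      if (!is.null(cp)) decoys[[length(decoys) + 1L]] <- cp
    }
    comps <- c(analogs, decoys)
    ord <- sample(seq_along(comps))
    lib <- .newLibrary(comps[ord])
  })
  truth <- data.frame(id = libraryIds(lib),
                      is_analog = startsWith(libraryIds(lib), "A"),
                      stringsAsFactors = FALSE)
  list(library = lib, reference = reference, truth = truth)
}

#' Generate a field-QSAR training set with a planted linear rule
#'
#' Each pseudo-compound is a site table (random feature placements inside
#' the grid box, one set per field channel); descriptors are computed with
#' \code{\link{computeFields}} on a fixed grid and the response is
#' \code{y = X beta + N(0, noiseSd)} with a sparse planted \code{beta}.
#'
#' @param seed integer seed.
#' @param nCompounds training-set size (default 40, the study's set size).
#' @param gridSpec field grid (default 2 x 2 x 2, spacing 3 Angstrom: a
#'   coarse pooled-field descriptor space, keeping the descriptor count
#'   below the 40-compound sample size so the planted linear rule is
#'   identifiable).
#' @param nSites sites per channel per compound.
#' @param nActive number of non-zero planted coefficients.
#' @param noiseSd Gaussian noise SD on y; overridden by \code{targetR2}.
#' @param targetR2 if given, noise is calibrated so the true signal
#'   fraction \code{var(signal)/(var(signal)+noiseSd^2)} equals it.
#' @param alpha Gaussian field decay.
#' @return list with \code{fields} (FieldGridSet), \code{y}, \code{yClean},
#'   \code{beta}, \code{noiseSd}, \code{siteTables}.
#' @export
genQsar <- function(seed, nCompounds = 40L,
                    gridSpec = fieldGridSpec(c(0, 0, 0), 3, c(2, 2, 2)),
                    nSites = 3L, nActive = 8L, noiseSd = 0,
                    targetR2 = NULL, alpha = 0.5) {
  lo <- gridSpec$origin
  hi <- gridSpec$origin + gridSpec$spacing * (gridSpec$dims - 1L)
  withr::with_seed(.deriveSeed(seed, "qsar"), {
    siteTables <- lapply(seq_len(nCompounds), function(i) {
      do.call(rbind, lapply(.FIELD_CHANNELS, function(ch) {
        data.frame(x = stats::runif(nSites, lo[1], hi[1]),
                   y = stats::runif(nSites, lo[2], hi[2]),
                   z = stats::runif(nSites, lo[3], hi[3]),
                   channel = ch,
                   weight = if (ch == "electron_withdrawing")
                     stats::runif(nSites, 0.1, 1) else 1,
                   stringsAsFactors = FALSE)
      }))
    })
    fields <- computeFields(siteTables, gridSpec = gridSpec, alpha = alpha,
                            ids = sprintf("Q%03d", seq_len(nCompounds)))
    p <- ncol(fields$X)
    beta <- numeric(p)
    active <- sample.int(p, nActive)
    beta[active] <- sample(c(-1, 1), nActive, replace = TRUE) *
      stats::runif(nActive, 0.5, 1.5)
    yClean <- drop(fields$X %*% beta) + 5  # around typical pIC50 magnitude
    if (!is.null(targetR2)) {
      stopifnot(targetR2 > 0, targetR2 < 1)
      noiseSd <- stats::sd(yClean) * sqrt((1 - targetR2) / targetR2)
    }
    y <- yClean + stats::rnorm(nCompounds, 0, noiseSd)
  })
  list(fields = fields, y = y, yClean = yClean, beta = beta,
       noiseSd = noiseSd, siteTables = siteTables, gridSpec = gridSpec)
}

#' Generate a 4PL dose-response data set
#'
#' Exact four-parameter logistic values on the given dose ladder plus
#' multiplicative Gaussian noise.
#'
#' @param seed integer seed.
#' @param ic50 planted IC50, molar (default 3.7e-6, the lead compound's
#'   pSTAT3 Luminex IC50).
#' @param hill,top,bottom planted curve parameters.
#' @param doseLadder molar doses; default the assay ladder
#'   0.1/0.3/1/3/10/100 micromolar.
#' @param noiseFrac multiplicative noise fraction.
#' @param nReplicates replicate curves.
#' @return list with \code{data} (data.frame \code{dose_molar, response,
#'   replicate}) and \code{truth}.
#' @export
genDoseResponse <- function(seed, ic50 = 3.7e-6, hill = 1, top = 100,
                            bottom = 0,
                            doseLadder = c(0.1, 0.3, 1, 3, 10, 100) * 1e-6,
                            noiseFrac = 0, nReplicates = 1L) {
  clean <- .fourPL(doseLadder, log10(ic50), hill, top, bottom)
  withr::with_seed(.deriveSeed(seed, "dose"), {
    dat <- do.call(rbind, lapply(seq_len(nReplicates), function(r)
      data.frame(dose_molar = doseLadder,
                 response = clean *
                   (1 + noiseFrac * stats::rnorm(length(doseLadder))),
                 replicate = r)))
  })
  list(data = dat,
       truth = list(ic50 = ic50, hill = hill, top = top, bottom = bottom,
                    responseClean = clean))
}

#' Generate a thermophoresis titration
#'
#' A 1:2 serial dilution (default 16 points from 10,000 nM, reaching
#' 0.305 nM) of titrant against a fixed labeled-target concentration;
#' F_norm follows the quadratic mass-action solution scaled by an
#' amplitude on a baseline, with additive Gaussian noise whose standard
#' deviation is \code{noiseFrac} of the transition amplitude (instrument
#' precision is naturally expressed relative to the binding-induced
#' F_norm change).
#'
#' @param seed integer seed.
#' @param kd planted dissociation constant, molar (default 4.7 nM).
#' @param targetConc labeled-target concentration, molar (default 80 nM).
#' @param topConc top titrant concentration, molar (default 10 micromolar).
#' @param nPoints,dilution dilution-series geometry.
#' @param baseline,amplitude F_norm baseline and transition amplitude.
#' @param noiseFrac noise SD as a fraction of \code{abs(amplitude)}.
#' @return list with \code{data} (data.frame \code{titrant_molar, fnorm})
#'   and \code{truth}.
#' @export
genMst <- function(seed, kd = 4.7e-9, targetConc = 80e-9, topConc = 1e-5,
                   nPoints = 16L, dilution = 2, baseline = 0.85,
                   amplitude = 0.15, noiseFrac = 0) {
  L <- topConc / dilution^(seq_len(nPoints) - 1L)
  clean <- baseline + amplitude * fractionBound(L, targetConc, kd)
  withr::with_seed(.deriveSeed(seed, "mst"), {
    fnorm <- clean +
      noiseFrac * abs(amplitude) * stats::rnorm(nPoints)
  })
  list(data = data.frame(titrant_molar = L, fnorm = fnorm),
       truth = list(kd = kd, targetConc = targetConc, baseline = baseline,
                    amplitude = amplitude, fnormClean = clean))
}

## Table 3 cell composition (direction, stat3 prior, stat1 prior, count)
.TABLE3_CELLS <- data.frame(
  direction = c(rep("down", 4), rep("up", 4)),
  stat3 = c("Pos", "Pos", "Neg", "None", "Neg", "Neg", "Pos", "None"),
  stat1 = c("None", "Pos", "Pos", "Pos", "None", "Neg", "None", "Pos"),
  n = c(8L, 16L, 14L, 10L, 36L, 1L, 1L, 4L),
  stringsAsFactors = FALSE)

#' Generate a gene-regulation table with planted cell counts
#'
#' Genes are allocated to (direction, stat3_prior, stat1_prior) cells at
#' the requested proportions (largest-remainder rounding, deterministic);
#' fold changes are drawn beyond the magnitude threshold with the sign of
#' the direction and fdr values strictly below the significance threshold,
#' so the generated table passes \code{\link{filterDE}} unchanged and
#' \code{\link{geneCrosstab}} recovers the planted composition exactly.
#'
#' @param seed integer seed.
#' @param nGenes number of genes (default 90, the fixture's size).
#' @param cellProportions data.frame \code{(direction, stat3, stat1, n)};
#'   counts are rescaled to \code{nGenes}. Default: the fixture's cells.
#' @param fcRange fold-change magnitude range (min must be >= the intended
#'   threshold).
#' @param fdrMax upper bound (exclusive) for generated fdr values.
#' @return list with \code{table} (a gene data.frame) and \code{truth}
#'   (the realised cell counts).
#' @export
genGeneTable <- function(seed, nGenes = 90L, cellProportions = .TABLE3_CELLS,
                         fcRange = c(1.5, 6), fdrMax = 0.01) {
  stopifnot(nGenes >= 0L, fcRange[1] >= 1)
  props <- cellProportions$n / sum(cellProportions$n)
  raw <- props * nGenes
  n <- floor(raw)
  rem <- nGenes - sum(n)
  if (rem > 0) {
    extra <- order(raw - n, decreasing = TRUE)[seq_len(rem)]
    n[extra] <- n[extra] + 1L
  }
  cells <- cellProportions
  cells$n <- as.integer(n)
  withr::with_seed(.deriveSeed(seed, "genes"), {
    rows <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
      if (cells$n[i] == 0L) return(NULL)
      sgn <- if (cells$direction[i] == "down") -1 else 1
      data.frame(
        fold_change = sgn * stats::runif(cells$n[i], fcRange[1], fcRange[2]),
        fdr = stats::runif(cells$n[i], 0, fdrMax * 0.99),
        stat3_prior = cells$stat3[i], stat1_prior = cells$stat1[i],
        stringsAsFactors = FALSE)
    }))
    if (is.null(rows))
      rows <- data.frame(fold_change = numeric(), fdr = numeric(),
                         stat3_prior = character(),
                         stat1_prior = character())
    if (nrow(rows)) rows <- rows[sample.int(nrow(rows)), , drop = FALSE]
  })
  tab <- data.frame(gene = sprintf("G%04d", seq_len(nrow(rows))),
                    refseq = sprintf("NM_%06d", seq_len(nrow(rows))),
                    rows, stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  list(table = tab, truth = cells)
}
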