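## Pipeline driver: screen -> pharmacophore rank -> QSAR -> pharmacology
## -> crosstab as one configured, seeded, logged run. The configuration is
## a YAML file (or equivalent list); every stage's parameters and output
## row counts are echoed into a machine-readable JSON manifest. Stage
## failures abort the run with a stage-named error; referenced input files
## are validated before any stage executes.

.stageLog <- function(stage, ...) {
  message("[", stage, "] ", ...)
}

.pipelineStages <- function() {
  list(
    screen = function(par, outdir, seed) {
      lib <- readLibrary(par$library)
      ref <- if (!is.null(par$reference_smiles))
        compound("REF", par$reference_smiles)
      else readLibrary(par$reference)[[1]]
      hits <- screenLibrary(lib, ref,
                            mode = par$mode %||% "containment",
                            cutoff = par$cutoff %||% 1.0)
      out <- file.path(outdir, "hits.csv")
      utils::write.csv(hits, out, row.names = FALSE)
      list(outputs = out, rows = nrow(hits), nHits = sum(hits$passes))
    },
    pharm = function(par, outdir, seed) {
      lib <- readLibrary(par$library)
      ref <- readLibrary(par$reference)[[1]]
      edges <- as.numeric(par$bin_edges %||% c(0, 2, 4, 6, 8, 10, 12))
      rk <- rankAndSelect(lib, ref, threshold = par$threshold %||% 70,
                          binEdges = edges)
      out <- file.path(outdir, "ranked.csv")
      utils::write.csv(rk$ranking, out, row.names = FALSE)
      list(outputs = out, rows = nrow(rk$ranking),
           nSelected = length(rk$selected))
    },
    qsar = function(par, outdir, seed) {
      lib <- readLibrary(par$library)
      act <- readActivityTable(par$activities)
      ids <- libraryIds(lib)
      act <- act[match(ids, act$compound_id), , drop = FALSE]
      if (any(is.na(act$ic50_molar)))
        stop("activities missing for: ",
             paste(ids[is.na(act$ic50_molar)], collapse = ", "))
      fg <- computeFields(lib, spacing = par$spacing %||% 1,
                          alpha = par$alpha %||% 0.5)
      y <- pic50(act$ic50_molar)
      fit <- fitPLS(fg, y, nFactors = par$factors %||% 4)
      cv <- crossValidate(fg$X, y, k = par$cv_k %||% 5,
                          nRepeats = par$cv_repeats %||% 5,
                          nFactors = par$factors %||% 4,
                          seed = par$cv_seed %||% seed)
      modelOut <- file.path(outdir, "model.json")
      jsonlite::write_json(list(
        n_factors = fit@nFactors, r2 = fit@r2, f = fit@fstat,
        rmse = fit@rmse, see = fit@see, q2 = cv$q2,
        q2_per_repeat = cv$q2PerRepeat, intercept = fit@intercept,
        kept_columns = fit@keptColumns, coefficients = fit@coefficients),
        modelOut, auto_unbox = TRUE, digits = NA)
      mapOut <- file.path(outdir, "field_maps.csv")
      utils::write.csv(fieldMaps(fit), mapOut, row.names = FALSE)
      list(outputs = c(modelOut, mapOut), rows = length(y),
           r2 = fit@r2, q2 = cv$q2)
    },
    ic50 = function(par, outdir, seed) {
      dat <- utils::read.csv(par$doses)
      fit <- fit4PL(dat$dose_molar, dat$response,
                    top = par$top, bottom = par$bottom)
      out <- file.path(outdir, "ic50.json")
      jsonlite::write_json(list(ic50_molar = fit@ic50, hill = fit@hill,
                                top = fit@top, bottom = fit@bottom,
                                converged = fit@converged),
                           out, auto_unbox = TRUE, digits = NA)
      list(outputs = out, rows = nrow(dat), ic50_molar = fit@ic50)
    },
    kd = function(par, outdir, seed) {
      dat <- utils::read.csv(par$titration)
      fit <- fitKd(dat$titrant_molar, dat$fnorm,
                   targetConc = par$target_conc %||% 80e-9)
      out <- file.path(outdir, "kd.json")
      jsonlite::write_json(list(kd_molar = fit@kd, baseline = fit@baseline,
                                amplitude = fit@amplitude,
                                converged = fit@converged),
                           out, auto_unbox = TRUE, digits = NA)
      list(outputs = out, rows = nrow(dat), kd_molar = fit@kd)
    },
    ki = function(par, outdir, seed) {
      ki <- chengPrusoffKi(par$ic50, par$target_conc, par$kd_probe)
      out <- file.path(outdir, "ki.json")
      jsonlite::write_json(list(ki_molar = ki), out, auto_unbox = TRUE,
                           digits = NA)
      list(outputs = out, rows = 1L, ki_molar = ki)
    },
    crosstab = function(par, outdir, seed) {
      genes <- readGeneTable(par$genes)
      de <- filterDE(genes, fdrMax = par$fdr %||% 0.01,
                     fcMin = par$fc %||% 1.5)
      ct <- geneCrosstab(de$down, de$up)
      out <- file.path(outdir, "crosstab.json")
      jsonlite::write_json(list(
        n_down = ct@nDown, n_up = ct@nUp,
        counts = ct@counts, fractions = ct@fractions),
        out, auto_unbox = TRUE, digits = NA)
      list(outputs = out, rows = nrow(genes),
           n_down = ct@nDown, n_up = ct@nUp)
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.FILE_PARAMS <- c("library", "reference", "activities", "doses",
                  "titration", "genes")

#' Run the configured hit-to-lead pipeline
#'
#' Executes the enabled stages in configuration order; each stage reads its
#' declared inputs, writes its outputs under \code{outdir} and contributes
#' a manifest entry (parameters, outputs, row counts). The manifest carries
#' no timestamps, so a rerun of the same configuration is byte-identical.
#'
#' @param config YAML file path or an equivalent named list with fields
#'   \code{seed}, \code{outdir} and \code{stages} (a named list; stage
#'   names among \code{screen, pharm, qsar, ic50, kd, ki, crosstab}).
#' @param quiet suppress stage log messages.
#' @return invisibly, the manifest list (also written to
#'   \code{outdir/manifest.json}).
#' @export
runPipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$stages))
  outdir <- config$outdir %||% "."
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  handlers <- .pipelineStages()
  unknown <- setdiff(names(config$stages), names(handlers))
  if (length(unknown))
    stop("unknown pipeline stage(s): ", paste(unknown, collapse = ", "))
  ## validate referenced inputs before running anything
  for (nm in names(config$stages)) {
    par <- config$stages[[nm]]
    for (f in intersect(names(par), .FILE_PARAMS)) {
      if (!file.exists(par[[f]]))
        stop("stage '", nm, "': input file not found: ", par[[f]])
    }
  }
  manifest <- list(package = "hitlead",
                   version = as.character(utils::packageVersion("hitlead")),
                   seed = seed, stages = list())
  for (nm in names(config$stages)) {
    if (!quiet) .stageLog(nm, "running")
    res <- tryCatch(handlers[[nm]](config$stages[[nm]], outdir, seed),
                    error = function(e)
                      stop("stage '", nm, "' failed: ",
                           conditionMessage(e), call. = FALSE))
    res$outputs <- basename(res$outputs)  # keep the manifest path-free
    par <- config$stages[[nm]]
    for (f in intersect(names(par), .FILE_PARAMS))
      par[[f]] <- basename(par[[f]])
    manifest$stages[[nm]] <- c(list(params = par), res)
    if (!quiet) .stageLog(nm, "done (", res$rows, " rows)")
  }
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
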