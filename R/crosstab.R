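## Differential-expression filtering and cross-tabulation against prior
## STAT3/STAT1 regulation annotations.
##
## Gene tables are TSV with columns gene, refseq, fold_change, fdr,
## stat3_prior, stat1_prior. Fold changes are signed linear ratios
## (negative = downregulated); priors are Pos / Neg / None ("-" accepted
## for None). The packaged fixture extdata/table3.tsv carries the 48 down-
## and 42 up-regulated genes with prior STAT3/STAT1 annotations from the
## xenograft study; its fdr column is 0 for every row because the printed
## table lists only genes already past fdr < 0.01.

.PRIORS <- c("Pos", "Neg", "None")

#' Read a gene regulation table
#'
#' @param path TSV file with header columns \code{gene, refseq,
#'   fold_change, fdr, stat3_prior, stat1_prior}.
#' @return validated data.frame; \code{"-"} priors become \code{"None"}.
#' @export
readGeneTable <- function(path) {
  if (!file.exists(path)) stop("cannot read gene table: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "fold_change", "fdr", "stat3_prior", "stat1_prior")
  if (!all(need %in% names(tab)))
    stop("gene table needs columns: ", paste(need, collapse = ", "))
  for (col in c("stat3_prior", "stat1_prior")) {
    tab[[col]][tab[[col]] %in% c("-", "")] <- "None"
    bad <- !tab[[col]] %in% .PRIORS
    if (any(bad))
      stop("invalid ", col, " value(s): ",
           paste(unique(tab[[col]][bad]), collapse = ", "))
  }
  if (any(!is.finite(tab$fdr)) || any(tab$fdr < 0 | tab$fdr > 1))
    stop("fdr values must lie in [0, 1]")
  if (any(!is.finite(tab$fold_change)))
    stop("fold_change values must be finite")
  tab
}

#' Path to the packaged xenograft gene-regulation fixture
#'
#' The 48 downregulated and 42 upregulated genes (fdr < 0.01, |fold change|
#' >= 1.5) with their prior STAT3 and IFN/STAT1 regulation annotations, as
#' printed in the source study's summary table.
#'
#' @return file path of the TSV.
#' @export
table3Path <- function() {
  system.file("extdata", "table3.tsv", package = "hitlead",
              mustWork = TRUE)
}

#' Filter a gene table at the study's differential-expression thresholds
#'
#' Down: \code{fdr < fdrMax} and \code{fold_change <= -fcMin}; up:
#' \code{fdr < fdrMax} and \code{fold_change >= +fcMin}. The fdr comparison
#' is strict, the fold-change magnitude inclusive, mirroring the printed
#' thresholds "fdr < 0.01, fold change >= 1.5".
#'
#' @param genes data.frame from \code{\link{readGeneTable}}.
#' @param fdrMax fdr threshold (default 0.01, strict \code{<}).
#' @param fcMin minimum linear fold-change magnitude (default 1.5,
#'   inclusive; must be >= 1).
#' @param log2Input if \code{TRUE}, \code{fold_change} is log2 and is
#'   converted to a signed linear ratio before thresholding.
#' @return list with \code{down} and \code{up} data.frames.
#' @export
filterDE <- function(genes, fdrMax = 0.01, fcMin = 1.5, log2Input = FALSE) {
  if (fcMin < 1) stop("fcMin must be >= 1 (linear fold change)")
  fc <- genes$fold_change
  if (log2Input) fc <- sign(fc) * 2^abs(fc)
  sig <- genes$fdr < fdrMax
  list(down = genes[sig & fc <= -fcMin, , drop = FALSE],
       up = genes[sig & fc >= fcMin, , drop = FALSE])
}

.fraction <- function(name, num, den) {
  data.frame(name = name, numerator = as.integer(num),
             denominator = as.integer(den),
             value = if (den > 0) num / den else NA_real_,
             stringsAsFactors = FALSE)
}

#' Cross-tabulate regulated genes against prior STAT3/STAT1 annotations
#'
#' Counts every (direction, stat3_prior, stat1_prior) cell and derives the
#' summary fractions: the share of downregulated genes previously shown to
#' be positively regulated by STAT1, the STAT3/STAT1 co-regulated
#' downregulated genes, the STAT3-annotated totals by direction, and the
#' Pos/Neg split of STAT3-annotated downregulated genes.
#'
#' @param down,up disjoint data.frames from \code{\link{filterDE}}.
#' @return a \linkS4class{CrosstabSummary}.
#' @export
geneCrosstab <- function(down, up) {
  if (length(intersect(down$gene, up$gene)))
    stop("down and up gene lists overlap: ",
         paste(intersect(down$gene, up$gene), collapse = ", "))
  cells <- expand.grid(direction = c("down", "up"), stat3 = .PRIORS,
                       stat1 = .PRIORS, stringsAsFactors = FALSE)
  tally <- function(df, s3, s1)
    sum(df$stat3_prior == s3 & df$stat1_prior == s1)
  cells$n <- mapply(function(dir, s3, s1)
    tally(if (dir == "down") down else up, s3, s1),
    cells$direction, cells$stat3, cells$stat1)
  nDown <- nrow(down); nUp <- nrow(up)
  s3ann <- function(df) sum(df$stat3_prior != "None")
  fr <- rbind(
    .fraction("down_stat1_pos", sum(down$stat1_prior == "Pos"), nDown),
    .fraction("down_coregulated_pos_pos",
              tally(down, "Pos", "Pos"), nDown),
    .fraction("stat3_annotated_down", s3ann(down), s3ann(down) + s3ann(up)),
    .fraction("stat3_annotated_up", s3ann(up), s3ann(down) + s3ann(up)),
    .fraction("stat3_down_pos", sum(down$stat3_prior == "Pos"), s3ann(down)),
    .fraction("stat3_down_neg", sum(down$stat3_prior == "Neg"), s3ann(down)),
    .fraction("down_stat3_none_stat1_pos",
              sum(down$stat3_prior == "None" & down$stat1_prior == "Pos"),
              nDown))
  methods::new("CrosstabSummary", counts = cells, fractions = fr,
               nDown = as.integer(nDown), nUp = as.integer(nUp))
}

#' Extract one summary quantity from a cross-tabulation
#'
#' @param summary a \linkS4class{CrosstabSummary}.
#' @param name fraction name as listed in \code{summary@fractions$name}.
#' @param what \code{"value"}, \code{"numerator"} or \code{"denominator"}.
#' @return the requested number.
#' @export
crosstabStat <- function(summary, name,
                         what = c("value", "numerator", "denominator")) {
  what <- match.arg(what)
  fr <- summary@fractions
  i <- match(name, fr$name)
  if (is.na(i)) stop("unknown summary quantity: ", name)
  fr[[what]][i]
}
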