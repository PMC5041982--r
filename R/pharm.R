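## Quantitative pharmacology: percent-of-control normalisation, 4PL
## dose-response IC50 fitting, thermophoresis F_norm extraction,
## law-of-mass-action KD fitting, Cheng-Prusoff Ki and tumour-volume
## formulas. Nonlinear fits use Levenberg-Marquardt least squares
## (minpack.lm) with a deterministic multi-start grid.

#' Percent-of-control normalisation
#'
#' \code{value * 100 / control}: the SPR, Luminex/phosphoflow and MTT
#' readouts are all expressed as percent of the untreated control.
#'
#' @param values numeric readouts.
#' @param control untreated-control readout; must be positive.
#' @return values as percent of control.
#' @examples
#' percentOfControl(c(50, 25), 50)  # 100, 50
#' @export
percentOfControl <- function(values, control) {
  if (length(control) != 1L || !is.finite(control) || control <= 0)
    stop("control must be a single positive number")
  values * 100 / control
}

.fourPL <- function(dose, logIC50, hill, top, bottom) {
  bottom + (top - bottom) / (1 + 10^(hill * (log10(dose) - logIC50)))
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of
#' \code{response = bottom + (top - bottom) / (1 + 10^(hill * (log10(dose)
#' - log10(IC50))))} in log10 dose. Zero-dose rows are excluded from the
#' log-dose fit (they only serve to define the control). Initialisation is
#' a deterministic multi-start grid over log IC50 and hill; the best
#' converged start by residual sum of squares wins. Non-convergence is
#' flagged, never silent.
#'
#' @param dose molar concentrations (zero allowed, dropped from the fit).
#' @param response percent-of-control responses.
#' @param top,bottom optional fixed plateaus (e.g. \code{top = 100},
#'   \code{bottom = 0}); \code{NULL} fits them.
#' @return a \linkS4class{FourPLFit}.
#' @export
fit4PL <- function(dose, response, top = NULL, bottom = NULL) {
  stopifnot(length(dose) == length(response))
  keep <- dose > 0
  dose <- dose[keep]; response <- response[keep]
  if (!all(is.finite(dose)) || !all(is.finite(response)))
    stop("doses and responses must be finite")
  if (length(unique(dose)) < 4L)
    stop("need at least 4 distinct positive doses")
  ld <- log10(dose)
  fixTop <- !is.null(top); fixBottom <- !is.null(bottom)
  starts <- expand.grid(
    logIC50 = stats::quantile(ld, c(0.1, 0.3, 0.5, 0.7, 0.9), names = FALSE),
    hill = c(0.5, 1, 2))
  best <- NULL; tried <- 0L
  for (s in seq_len(nrow(starts))) {
    st <- list(logIC50 = starts$logIC50[s], hill = starts$hill[s])
    if (!fixTop) st$top <- max(response)
    if (!fixBottom) st$bottom <- min(response)
    form <- response ~ bottom + (top - bottom) /
      (1 + 10^(hill * (ld - logIC50)))
    dat <- data.frame(response = response, ld = ld)
    if (fixTop) dat$top <- top
    if (fixBottom) dat$bottom <- bottom
    fit <- tryCatch(
      minpack.lm::nlsLM(form, data = dat, start = st,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    tried <- tried + 1L
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    ## flagged non-convergent fit carrying the midpoint guess
    return(methods::new("FourPLFit", ic50 = 10^stats::median(ld), hill = NA_real_,
                        top = if (fixTop) top else max(response),
                        bottom = if (fixBottom) bottom else min(response),
                        rss = Inf, converged = FALSE,
                        diagnostics = list(message = "no start converged",
                                           startsTried = tried)))
  }
  cf <- stats::coef(best$fit)
  methods::new("FourPLFit",
               ic50 = 10^unname(cf["logIC50"]), hill = unname(cf["hill"]),
               top = if (fixTop) top else unname(cf["top"]),
               bottom = if (fixBottom) bottom else unname(cf["bottom"]),
               rss = best$rss, converged = TRUE,
               diagnostics = list(startsTried = tried))
}

#' Thermophoresis F_norm from a fluorescence time trace
#'
#' \code{F_cold} is the mean fluorescence over the cold window before the
#' IR laser switches on; \code{F_hot} the mean over a 1-s window centred at
#' \code{laserOn + hotTime}; \code{F_norm = F_hot / F_cold}.
#'
#' @param times seconds, strictly increasing.
#' @param fluorescence positive fluorescence values.
#' @param laserOn laser switch-on time, seconds.
#' @param coldWindow two-element window (seconds) entirely before
#'   \code{laserOn}; default the 5 s preceding laser-on.
#' @param hotTime seconds after laser-on at which the hot state is read
#'   (default 30).
#' @param hotWidth width of the hot averaging window, seconds (default 1).
#' @return \code{F_norm}.
#' @export
mstFnorm <- function(times, fluorescence, laserOn,
                     coldWindow = c(laserOn - 5, laserOn), hotTime = 30,
                     hotWidth = 1) {
  stopifnot(length(times) == length(fluorescence))
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (coldWindow[2] > laserOn)
    stop("cold window must lie entirely before laser-on")
  hotWin <- laserOn + hotTime + c(-hotWidth, hotWidth) / 2
  if (coldWindow[1] < times[1] || hotWin[2] > times[length(times)])
    stop("averaging windows fall outside the trace")
  cold <- fluorescence[times >= coldWindow[1] & times <= coldWindow[2]]
  hot <- fluorescence[times >= hotWin[1] & times <= hotWin[2]]
  if (!length(cold) || !length(hot))
    stop("averaging windows contain no samples")
  mean(hot) / mean(cold)
}

#' Fraction of target bound at equilibrium
#'
#' Exact solution of the 1:1 law of mass action at fixed total target
#' concentration \code{T} and total titrant \code{L}:
#' \code{FB = ((L + T + KD) - sqrt((L + T + KD)^2 - 4 L T)) / (2 T)}.
#'
#' @param L total titrant concentration(s), molar.
#' @param targetConc total target concentration, molar.
#' @param kd dissociation constant, molar.
#' @return fraction bound in \code{[0, 1]}.
#' @examples
#' fractionBound(1e-9, 1e-9, 1e-9)  # (3 - sqrt(5)) / 2
#' @export
fractionBound <- function(L, targetConc, kd) {
  if (targetConc <= 0 || kd <= 0) stop("targetConc and kd must be positive")
  if (any(L < 0)) stop("titrant concentrations must be non-negative")
  s <- L + targetConc + kd
  (s - sqrt(s^2 - 4 * L * targetConc)) / (2 * targetConc)
}

#' Fit KD from an F_norm titration (law of mass action)
#'
#' Fits \code{F_norm(L) = baseline + amplitude * FB(L; T, KD)} by
#' Levenberg-Marquardt least squares with a deterministic multi-start over
#' log KD.
#'
#' @param titrantConc molar titrant concentrations (>= 6 points spanning
#'   the transition).
#' @param fnorm measured F_norm values.
#' @param targetConc fixed labeled-target concentration, molar (default
#'   80 nM).
#' @return a \linkS4class{BindingFit}.
#' @export
fitKd <- function(titrantConc, fnorm, targetConc = 80e-9) {
  stopifnot(length(titrantConc) == length(fnorm))
  if (any(titrantConc < 0)) stop("titrant concentrations must be non-negative")
  if (targetConc <= 0) stop("targetConc must be positive")
  if (length(unique(titrantConc)) < 6L)
    stop("need at least 6 titrant concentrations")
  ord <- order(titrantConc)
  lo <- mean(fnorm[ord][seq_len(2)])
  hi <- mean(fnorm[ord][length(fnorm) - 0:1])
  pos <- titrantConc[titrantConc > 0]
  startKd <- exp(seq(log(min(pos)), log(max(pos)), length.out = 7))
  best <- NULL
  for (k0 in startKd) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        fnorm ~ baseline + amplitude *
          fractionBound(titrantConc, targetConc, exp(logKd)),
        data = data.frame(fnorm = fnorm, titrantConc = titrantConc),
        start = list(baseline = lo, amplitude = hi - lo, logKd = log(k0)),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    return(methods::new("BindingFit", kd = stats::median(pos), baseline = lo,
                        amplitude = hi - lo, targetConc = targetConc,
                        rss = Inf, converged = FALSE))
  cf <- stats::coef(best$fit)
  methods::new("BindingFit", kd = exp(unname(cf["logKd"])),
               baseline = unname(cf["baseline"]),
               amplitude = unname(cf["amplitude"]),
               targetConc = targetConc, rss = best$rss, converged = TRUE)
}

#' Cheng-Prusoff conversion of a competitive IC50 to Ki
#'
#' \code{Ki = IC50 / (1 + targetConc / kdProbe)}: corrects a competition
#' IC50 for the occupancy of the probe (here the labeled pY-peptide bound
#' to STAT3 at known KD).
#'
#' @param ic50 competition IC50, molar.
#' @param targetConc competing-target concentration, molar.
#' @param kdProbe probe dissociation constant, molar.
#' @return Ki in molar units.
#' @examples
#' chengPrusoffKi(2500e-9, 200e-9, 1.1e-9) * 1e9  # 13.67 nM
#' chengPrusoffKi(2500e-9, 200e-9, 1.0e-9) * 1e9  # 12.44 nM
#' @export
chengPrusoffKi <- function(ic50, targetConc, kdProbe) {
  if (any(c(ic50, targetConc, kdProbe) <= 0))
    stop("all inputs must be positive")
  ic50 / (1 + targetConc / kdProbe)
}

#' Ellipsoid tumour volume from caliper dimensions
#'
#' Two printed conventions are supported: \code{0.5 * L * S^2} (the
#' ellipsoid convention, default) and \code{(6 / pi) * L * S^2}.
#'
#' @param longMm,shortMm caliper long and short dimensions, mm
#'   (\code{longMm >= shortMm > 0}).
#' @param variant \code{"half"} (default) or \code{"six_over_pi"}.
#' @return volume in cubic millimetres.
#' @examples
#' tumorVolume(5, 2)  # 10 mm^3
#' @export
tumorVolume <- function(longMm, shortMm, variant = c("half", "six_over_pi")) {
  variant <- match.arg(variant)
  if (any(longMm <= 0) || any(shortMm <= 0))
    stop("dimensions must be positive")
  if (any(shortMm > longMm))
    stop("short dimension must not exceed the long dimension")
  pre <- if (variant == "half") 0.5 else 6 / pi
  pre * longMm * shortMm^2
}
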