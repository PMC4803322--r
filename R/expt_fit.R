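## Mapping fluorescence-intensity distributions to model induction rates:
## background subtraction by the mode of the zero-induction condition, then a
## maximally constrained least-squares fit of cumulative distributions with
## one alpha_k per condition and a single global intensity-per-molecule
## conversion factor X.

#' Construct a FluorescenceSample
#'
#' @param intensities Nonnegative intensities (arbitrary units, one per cell).
#' @param conditionLabel Condition label; use `"0"` for the zero-induction
#'   (background) condition.
#' @param circuitLabel Circuit carried by the strain.
#' @return A [FluorescenceSample-class].
#' @export
fluorescenceSample <- function(intensities, conditionLabel,
                               circuitLabel = "native") {
  new("FluorescenceSample", intensities = as.numeric(intensities),
      conditionLabel = as.character(conditionLabel),
      circuitLabel = circuitLabel)
}

#' @rdname FluorescenceSample-class
#' @param object A `FluorescenceSample`.
#' @export
setMethod("show", "FluorescenceSample", function(object) {
  cat(sprintf("FluorescenceSample '%s' (%s): %d cells, median %.3g a.u.\n",
              object@conditionLabel, object@circuitLabel,
              length(object@intensities), median(object@intensities)))
})

## Histogram mode with Freedman-Diaconis binning and parabolic refinement of
## the modal bin.
.histogramMode <- function(x) {
  n <- length(x)
  iqr <- IQR(x)
  h <- if (iqr > 0) 2 * iqr / n^(1 / 3) else diff(range(x)) / max(10, sqrt(n))
  if (h <= 0) return(x[1])
  breaks <- seq(min(x) - h / 2, max(x) + h, by = h)
  cnt <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE),
                  nbins = length(breaks) - 1)
  i <- which.max(cnt)
  center <- (breaks[i] + breaks[i + 1]) / 2
  if (i > 1 && i < length(cnt)) {
    cl <- cnt[i - 1]; c0 <- cnt[i]; cr <- cnt[i + 1]
    den <- cl - 2 * c0 + cr
    if (den < 0) center <- center + 0.5 * h * (cl - cr) / den
  }
  center
}

#' Subtract the background fluorescence
#'
#' Estimates the background as the mode of the zero-induction condition's
#' intensity histogram (Freedman-Diaconis binning, parabolic refinement of the
#' modal bin) and subtracts it from every intensity in every sample.
#'
#' @param samples List of [FluorescenceSample-class] objects, at least one of
#'   which has `conditionLabel == "0"`.
#' @param clip Clip negative post-subtraction intensities to zero (default
#'   TRUE: molecule counts are nonnegative).
#' @return List with `samples` (corrected) and `backgroundMode`.
#' @export
subtractBackground <- function(samples, clip = TRUE) {
  labs <- vapply(samples, function(s) s@conditionLabel, character(1))
  zero <- which(suppressWarnings(as.numeric(labs)) == 0)
  if (!length(zero)) stop("no zero-induction (label '0') sample present")
  b <- .histogramMode(unlist(lapply(samples[zero],
                                    function(s) s@intensities)))
  out <- lapply(samples, function(s) {
    v <- s@intensities - b
    if (clip) v <- pmax(v, 0)
    initialize(s, intensities = v)
  })
  list(samples = out, backgroundMode = b)
}

## CDF of X*n for a model marginal pn (P(n <= k) = C[k+1]) evaluated at x.
.modelCDF <- function(cumPn, X, x) {
  k <- floor(x / X)
  k <- pmin(pmax(k, -1), length(cumPn) - 1)
  ifelse(k < 0, 0, cumPn[k + 1])
}

## Mean squared CDF error for one sample at given alpha-marginal and X.
## evalPoints = "lattice": evaluate at the midpoints X*(n + 1/2) of the model's
## intensity lattice, spanning the sample range.  The model CDF is exact there
## and an atom smeared by sub-molecule background noise is counted in full, so
## the objective stays unbiased for background widths below X/2.
## evalPoints = "deciles": evaluate at the nine empirical deciles; unbiased
## only when the data sit exactly on the lattice.
.cdfObjective <- function(intens, cumPn, X, probs,
                          evalPoints = c("lattice", "deciles")) {
  evalPoints <- match.arg(evalPoints)
  if (evalPoints == "deciles") {
    d <- quantile(intens, probs = probs, names = FALSE, type = 7)
  } else {
    K <- max(1, ceiling(quantile(intens, 0.995, names = FALSE) / X))
    d <- X * ((0:K) + 0.5)
  }
  Femp <- vapply(d, function(x) mean(intens <= x), numeric(1))
  Fmod <- .modelCDF(cumPn, X, d)
  mean((Femp - Fmod)^2)
}

#' Profile error bars from an objective profile
#'
#' Reads off the `alpha_k` values at which the sum-of-squares profile crosses
#' `level` times its minimum, by linear interpolation between grid points.
#' Errors if the minimum sits at a grid edge; flags one-sided bars when a
#' crossing lies outside the grid.
#'
#' @param alpha Grid of induction rates (increasing).
#' @param S Objective values on the grid.
#' @param level Multiple of the minimum defining the bar (default 1.25).
#' @return List with `alphaLo`, `alphaHi` (NA when unbounded on that side),
#'   `bounded` (logical), `sMin`, `alphaHat`.
#' @export
errorBars <- function(alpha, S, level = 1.25) {
  stopifnot(length(alpha) == length(S), all(diff(alpha) > 0))
  i <- which.min(S)
  if (i == 1L || i == length(S))
    stop("objective minimum at a grid edge; widen the alpha grid")
  sMin <- S[i]
  # parabolic refinement of the minimum in log alpha
  la <- log(alpha[(i - 1):(i + 1)])
  Sv <- S[(i - 1):(i + 1)]
  den <- Sv[1] - 2 * Sv[2] + Sv[3]
  aHat <- if (den > 0) {
    exp(la[2] + 0.5 * (la[2] - la[1]) * (Sv[1] - Sv[3]) / den)
  } else alpha[i]
  thr <- level * sMin
  cross <- function(idx) {
    # idx: indices moving away from the minimum; first crossing of thr
    for (k in seq_along(idx)[-1]) {
      a2 <- idx[k]; a1 <- idx[k - 1]
      if (S[a2] >= thr && S[a1] < thr) {
        w <- (thr - S[a1]) / (S[a2] - S[a1])
        return(alpha[a1] + w * (alpha[a2] - alpha[a1]))
      }
    }
    NA_real_
  }
  lo <- cross(rev(seq_len(i)))
  hi <- cross(i:length(S))
  list(alphaLo = lo, alphaHi = hi, bounded = !is.na(lo) && !is.na(hi),
       sMin = sMin, alphaHat = aHat)
}

#' Fit a fluorescence titration to the stochastic model
#'
#' Maximally constrained least-squares fit: all circuit parameters are fixed
#' except the per-condition induction rate `alpha_k` and one global
#' intensity-per-molecule factor X.  For a given X, each condition's
#' `alpha_k` minimises the mean squared difference between the empirical
#' CDF and the model CDF of `X * n`, evaluated without any density binning.
#' X is then chosen to minimise the sum of the per-condition
#' minima, by an outer search over `XGrid` refined by golden-section on log X.
#'
#' Two conventions for the CDF evaluation points are available.  The default
#' `"lattice"` evaluates at the midpoints `X (n + 1/2)` of the model's
#' intensity lattice across the sample range: the model CDF is exact there,
#' and a zero-molecule atom smeared by sub-molecule background noise is
#' counted in full, keeping the objective unbiased for background widths
#' below X/2.  The alternative `"deciles"` evaluates at the nine empirical
#' deciles; it is unbiased only when intensities sit exactly on the lattice,
#' and with continuous background noise it systematically inflates the
#' fitted induction rates of atom-heavy (low-induction) conditions.
#'
#' @param samples List of background-corrected [FluorescenceSample-class]
#'   objects (see [subtractBackground()]); the zero-induction condition should
#'   be excluded or kept as its own condition.
#' @param spec A [CircuitSpec-class] providing all fixed parameters.
#' @param alphaGrid Induction-rate grid over which model marginals are
#'   computed (log-spaced; the fit is restricted to this grid).
#' @param XGrid Candidate conversion factors (log-spaced).
#' @param probs CDF evaluation probabilities for `evalPoints = "deciles"`.
#' @param backgroundMode Background level to record in the result.
#' @param refine Golden-section refinement steps for X (0 disables).
#' @param evalPoints `"lattice"` (default) or `"deciles"`; see Details.
#' @param marginalCache Optional precomputed list of cumulative ComK marginals
#'   (one per `alphaGrid` point, each `cumsum(comKMarginal(...))`): steady
#'   states are the expensive step, and the same grid can be reused across
#'   fits.
#' @return A [TitrationFit-class].
#' @export
fitTitration <- function(samples, spec, alphaGrid, XGrid,
                         probs = seq(0.1, 0.9, by = 0.1),
                         backgroundMode = NA_real_, refine = 25L,
                         evalPoints = c("lattice", "deciles"),
                         marginalCache = NULL) {
  evalPoints <- match.arg(evalPoints)
  stopifnot(length(alphaGrid) > 2, length(XGrid) >= 1)
  marginals <- marginalCache %||% lapply(alphaGrid, function(a)
    cumsum(comKMarginal(steadyStateDistribution(setAlphaK(spec, a)))))
  stopifnot(length(marginals) == length(alphaGrid))
  intens <- lapply(samples, function(s) s@intensities)
  sumSmin <- function(X) {
    tot <- 0
    for (v in intens) {
      Sa <- vapply(marginals, function(cp)
        .cdfObjective(v, cp, X, probs, evalPoints), numeric(1))
      tot <- tot + min(Sa)
    }
    tot
  }
  scores <- vapply(XGrid, sumSmin, numeric(1))
  iBest <- which.min(scores)
  Xhat <- XGrid[iBest]
  if (refine > 0 && length(XGrid) >= 3 && iBest > 1 && iBest < length(XGrid)) {
    phi <- (sqrt(5) - 1) / 2
    loX <- log(XGrid[iBest - 1]); hiX <- log(XGrid[iBest + 1])
    x1 <- hiX - phi * (hiX - loX); x2 <- loX + phi * (hiX - loX)
    f1 <- sumSmin(exp(x1)); f2 <- sumSmin(exp(x2))
    for (it in seq_len(refine)) {
      if (f1 < f2) {
        hiX <- x2; x2 <- x1; f2 <- f1
        x1 <- hiX - phi * (hiX - loX); f1 <- sumSmin(exp(x1))
      } else {
        loX <- x1; x1 <- x2; f1 <- f2
        x2 <- loX + phi * (hiX - loX); f2 <- sumSmin(exp(x2))
      }
    }
    Xhat <- exp((loX + hiX) / 2)
  }
  rows <- list(); profiles <- list()
  for (k in seq_along(samples)) {
    v <- intens[[k]]
    Sa <- vapply(marginals, function(cp)
      .cdfObjective(v, cp, Xhat, probs, evalPoints), numeric(1))
    eb <- tryCatch(errorBars(alphaGrid, Sa),
                   error = function(e) list(alphaLo = NA_real_,
                                            alphaHi = NA_real_,
                                            bounded = FALSE, sMin = min(Sa),
                                            alphaHat = alphaGrid[which.min(Sa)]))
    rows[[k]] <- data.frame(label = samples[[k]]@conditionLabel,
                            alphaHat = eb$alphaHat, sMin = eb$sMin,
                            alphaLo = eb$alphaLo, alphaHi = eb$alphaHi,
                            bounded = eb$bounded, stringsAsFactors = FALSE)
    profiles[[k]] <- cbind(alpha = alphaGrid, S = Sa)
  }
  new("TitrationFit", X = Xhat, fits = do.call(rbind, rows),
      backgroundMode = backgroundMode, profiles = profiles)
}

#' @rdname TitrationFit-class
#' @param object A `TitrationFit`.
#' @export
setMethod("show", "TitrationFit", function(object) {
  cat(sprintf("TitrationFit: X = %.4g a.u./molecule, %d conditions\n",
              object@X, nrow(object@fits)))
  print(object@fits, row.names = FALSE)
})
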