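## The responsive fraction f: probability mass of the ComK steady-state
## marginal in the high-expression (competent) mode, computed by the two
## methods used for population-level analysis (inflection-point split and
## two-Poisson mixture fit), plus the f(alpha_k) curve and the viable-range
## expansion factors.

.binomialSmooth <- function(p) {
  # 3-point binomial kernel (1/4, 1/2, 1/4) with mass-preserving edges
  L <- length(p)
  w <- c(p[1] * 0.75 + p[2] * 0.25,
         0.25 * p[-c(L - 1, L)] + 0.5 * p[-c(1, L)] + 0.25 * p[-c(1, 2)],
         p[L] * 0.75 + p[L - 1] * 0.25)
  w / sum(w)
}

## Sign-change positions and types of the second finite difference.
## d2[i] is centred on 0-based count i; a change between d2[i] and d2[i+1]
## is located at i + 0.5 (0-based).
.inflections <- function(w) {
  d2 <- diff(w, differences = 2)
  sg <- sign(d2)
  nz <- which(sg[-length(sg)] * sg[-1] < 0)
  if (!length(nz))
    return(data.frame(pos = numeric(0), type = character(0)))
  data.frame(pos = nz - 0.5,  # 0-based count coordinate
             type = ifelse(sg[nz] > 0, "pm", "mp"),
             stringsAsFactors = FALSE)
}

#' Responsive fraction by the inflection-point method
#'
#' Splits the ComK marginal at the average `n* = (n1 + n2)/2` of the two
#' inflection points flanking the putative inter-mode minimum (located as sign
#' changes of the second finite difference), and returns the tail mass
#' `f = sum_{n >= n*} p_n`.  The distribution need not be fully bimodal: a
#' high-expression shoulder produces the same curvature signature as a true
#' second mode.  When the low mode sits at `n = 0` its concave flank is not
#' observable and the left inflection is taken at 0.  If no inter-mode
#' curvature structure exists the distribution is unimodal and `f` is 0 or 1
#' according to whether the mode lies below or above `hiAnchor`.
#'
#' A 3-point binomial smoothing kernel is applied first only if the raw second
#' differences show more than `smoothTrigger` sign changes (discrete-grid
#' noise produces spurious inflections).
#'
#' @param pn Normalised ComK marginal (length >= 5).
#' @param hiAnchor Count separating "low" from "high" modes for the unimodal
#'   fallback; default `length(pn)/2`.  [fractionCurve()] passes the geometric
#'   mean of the deterministic low- and high-branch ComK levels.
#' @param smoothTrigger See description.
#' @return List with `f`, `method = "inflection"`, `nStar` (the split point,
#'   or NA for unimodal input), `unimodal`.
#' @examples
#' pn <- 0.5 * dpois(0:120, 2) + 0.5 * dpois(0:120, 60)
#' fInflection(pn / sum(pn))$f
#' @export
fInflection <- function(pn, hiAnchor = NULL, smoothTrigger = 4L) {
  if (length(pn) < 5) stop("distribution must have length >= 5")
  pn <- pn / sum(pn)
  w <- pn
  infl <- .inflections(w)
  if (nrow(infl) > smoothTrigger) {
    w <- .binomialSmooth(w)
    infl <- .inflections(w)
  }
  nStar <- NA_real_
  if (nrow(infl) >= 2) {
    # valley flanked by a -to+ change (left) followed by a +to- change (right)
    for (i in seq_len(nrow(infl) - 1)) {
      if (infl$type[i] == "mp" && infl$type[i + 1] == "pm") {
        nStar <- (infl$pos[i] + infl$pos[i + 1]) / 2
        break
      }
    }
  }
  if (is.na(nStar) && nrow(infl) >= 1 && infl$type[1] == "pm" && which.max(w) == 1L) {
    # low mode at n = 0: its concave flank is hidden; left inflection ~ 0
    nStar <- infl$pos[1] / 2
  }
  if (!is.na(nStar)) {
    nStar <- max(1L, as.integer(round(nStar)))
    return(list(f = sum(pn[(nStar + 1L):length(pn)]), method = "inflection",
                nStar = nStar, unimodal = FALSE))
  }
  if (is.null(hiAnchor)) hiAnchor <- length(pn) / 2
  mode0 <- which.max(w) - 1L
  list(f = if (mode0 >= hiAnchor) 1 else 0, method = "inflection",
       nStar = NA_integer_, unimodal = TRUE)
}

.klDivergence <- function(p, q) {
  i <- p > 0
  sum(p[i] * log(p[i] / pmax(q[i], 1e-300)))
}

#' Responsive fraction by the two-Poisson mixture fit
#'
#' Fits the ComK marginal to `w Pois(mu1) + (1 - w) Pois(mu2)` with
#' `mu1 < mu2` enforced by parameterisation, minimising the Kullback-Leibler
#' divergence `D(p_n || mixture)` over the three parameters with multi-start
#' Nelder-Mead.  The responsive fraction is the weight `1 - w` of the
#' high-mean component.  When the input is effectively a single Poisson the
#' fit degenerates to two similar means with `f ~ 0.5`; this is flagged via
#' `degenerate` (`|mu2 - mu1| < 2 sqrt(mu2)`), and such fits should not be
#' read as fractions.
#'
#' @param pn Normalised ComK marginal.
#' @param nStarts Number of optimiser starts (moment-based; >= 5).
#' @return List with `f`, `method = "two_poisson"`, `w` (low-component
#'   weight), `muLow`, `muHigh`, `kl` (achieved divergence), `degenerate`,
#'   `converged`.
#' @examples
#' pn <- 0.3 * dpois(0:120, 3) + 0.7 * dpois(0:120, 40)
#' fTwoPoisson(pn / sum(pn))$f
#' @export
fTwoPoisson <- function(pn, nStarts = 9L) {
  pn <- pn / sum(pn)
  n <- seq_along(pn) - 1
  mbar <- sum(n * pn)
  unpack <- function(th) {
    w <- 1 / (1 + exp(-th[1]))
    mu1 <- exp(th[2])
    list(w = w, mu1 = mu1, mu2 = mu1 + exp(th[3]))
  }
  cost <- function(th) {
    z <- unpack(th)
    .klDivergence(pn, z$w * dpois(n, z$mu1) + (1 - z$w) * dpois(n, z$mu2))
  }
  starts <- list()
  for (w0 in c(0.2, 0.5, 0.8))
    for (sep in c(0.25, 0.5, 0.75))
      starts[[length(starts) + 1L]] <-
        c(log(w0 / (1 - w0)),
          log(max(mbar * sep * 0.3, 0.02)),
          log(max(mbar * (1 + sep) - max(mbar * sep * 0.3, 0.02), 0.5)))
  starts <- starts[seq_len(min(length(starts), max(nStarts, 5L)))]
  best <- NULL
  for (s0 in starts) {
    res <- tryCatch(
      optim(s0, cost, method = "Nelder-Mead",
            control = list(maxit = 3000, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best))
    stop("two-Poisson fit failed to converge from any start")
  z <- unpack(best$par)
  list(f = 1 - z$w, method = "two_poisson", w = z$w,
       muLow = z$mu1, muHigh = z$mu2, kl = best$value,
       degenerate = (z$mu2 - z$mu1) < 2 * sqrt(z$mu2),
       converged = best$convergence == 0)
}

#' Responsive fraction as a function of the induction rate
#'
#' For each `alpha_k` on the grid: solve the master equation, take the ComK
#' marginal, and compute `f`.  Following the population-analysis protocol, the
#' inflection-point method is used below the deterministic saddle-node
#' boundary `alpha_k_1` and again from the `f = 1` onset upward (the mixture
#' fit cannot represent `f = 1`); the two-Poisson method is used in between.
#' The `f = 1` onset is the first grid point at which the inflection method
#' reports `f >= 1 - 1e-2` while the mixture fit has degenerated to two
#' similar means.  A 3-point moving average over log-spaced neighbours is
#' applied at each method-concatenation point.
#'
#' @param spec A [CircuitSpec-class] (its own `alpha_k` is ignored).
#' @param alphaGrid Strictly increasing induction rates; log-spaced with >= 12
#'   points per decade recommended.
#' @param bounds Optional precomputed [regimeBoundaries()] result.
#' @param smooth Apply the concatenation smoothing (default TRUE).
#' @param verbose Print progress.
#' @return A [FractionCurve-class]; `@smoothing` records the concatenation
#'   indices, the `f = 1` onset alpha (`onsetAlpha`, NA if not reached) and
#'   the unimodal anchor used.
#' @export
fractionCurve <- function(spec, alphaGrid, bounds = NULL, smooth = TRUE,
                          verbose = FALSE) {
  stopifnot(all(diff(alphaGrid) > 0))
  if (is.null(bounds)) bounds <- regimeBoundaries(spec)
  fpLow <- findFixedPoints(setAlphaK(spec, alphaGrid[1]))
  fpHigh <- findFixedPoints(setAlphaK(spec, alphaGrid[length(alphaGrid)]))
  hiAnchor <- sqrt(max(min(fpLow$n), 1) * max(fpHigh$n))
  fvals <- numeric(length(alphaGrid))
  meth <- character(length(alphaGrid))
  onsetAlpha <- NA_real_
  pastOnset <- FALSE
  for (i in seq_along(alphaGrid)) {
    a <- alphaGrid[i]
    jd <- tryCatch(steadyStateDistribution(setAlphaK(spec, a)),
                   error = function(e)
                     stop("steady-state solve failed at alpha_k = ", a, ": ",
                          conditionMessage(e)))
    pn <- comKMarginal(jd)
    fi <- fInflection(pn, hiAnchor = hiAnchor)
    if (a < bounds$alpha_k_1) {
      fvals[i] <- fi$f; meth[i] <- "inflection"
    } else if (pastOnset) {
      fvals[i] <- fi$f; meth[i] <- "inflection"
    } else {
      f2 <- fTwoPoisson(pn)
      if (fi$f >= 1 - 1e-2 && f2$degenerate) {
        pastOnset <- TRUE
        onsetAlpha <- a
        fvals[i] <- fi$f; meth[i] <- "inflection"
      } else {
        fvals[i] <- f2$f; meth[i] <- "two_poisson"
      }
    }
    if (verbose)
      message(sprintf("alpha_k = %-10.4g f = %-8.4f (%s)", a, fvals[i], meth[i]))
  }
  smoothing <- list(applied = smooth, window = 3L, onsetAlpha = onsetAlpha,
                    hiAnchor = hiAnchor, concatIndices = integer(0))
  if (smooth) {
    joins <- which(meth[-1] != meth[-length(meth)])
    smoothing$concatIndices <- joins
    fs <- fvals
    for (j in joins) {
      for (k in intersect(c(j, j + 1L), 2:(length(fvals) - 1L)))
        fs[k] <- mean(fvals[(k - 1L):(k + 1L)])
    }
    fvals <- fs
  }
  new("FractionCurve", alphaGrid = alphaGrid, f = pmin(pmax(fvals, 0), 1),
      method = meth, smoothing = smoothing)
}

#' @rdname FractionCurve-class
#' @param object A `FractionCurve`.
#' @export
setMethod("show", "FractionCurve", function(object) {
  cat(sprintf("FractionCurve: %d points, alpha_k in [%.3g, %.3g], f in [%.3g, %.3g]\n",
              length(object@f), min(object@alphaGrid), max(object@alphaGrid),
              min(object@f), max(object@f)))
})

#' Viable-response-range expansion factors
#'
#' Quantifies how far the stochastic viable range `0 < f < 1` extends beyond
#' the deterministic oscillatory window.  The low-side edge `alpha_min` is the
#' smallest induction rate with `f > epsilon` (log-linear interpolation of the
#' first crossing); the high-side edge is the `f = 1` onset determined by the
#' inflection method (see [fractionCurve()]).  Factors:
#' `low = alpha_k_1 / alpha_min`, `high = alpha_max / alpha_k_2`,
#' `total = low x high`.
#'
#' @param curve A [FractionCurve-class] spanning well beyond both boundaries.
#' @param bounds A [regimeBoundaries()] result.
#' @param epsilon Threshold defining the low-side edge (default 1e-2).
#' @return List with `lowFactor`, `highFactor`, `totalFactor`, `alphaMin`,
#'   `alphaMax`, `epsilon`.
#' @export
expansionReport <- function(curve, bounds, epsilon = 1e-2) {
  a <- curve@alphaGrid; f <- curve@f
  above <- which(f > epsilon)
  if (!length(above))
    stop("f never exceeds epsilon = ", epsilon, " in the scanned range")
  i <- above[1]
  alphaMin <- if (i == 1L) a[1] else {
    # log-linear interpolation of the epsilon crossing
    la <- log(a[i - 1]) + (epsilon - f[i - 1]) / (f[i] - f[i - 1]) *
      (log(a[i]) - log(a[i - 1]))
    exp(la)
  }
  onset <- curve@smoothing$onsetAlpha
  if (is.null(onset) || is.na(onset)) {
    hi <- which(f >= 1 - 1e-2 & curve@method == "inflection" &
                  a > bounds$alpha_k_1)
    if (!length(hi))
      stop("f never reaches 1 (inflection method) in the scanned range")
    onset <- a[hi[1]]
  }
  lowFactor <- bounds$alpha_k_1 / alphaMin
  highFactor <- onset / bounds$alpha_k_2
  list(lowFactor = lowFactor, highFactor = highFactor,
       totalFactor = lowFactor * highFactor,
       alphaMin = alphaMin, alphaMax = onset, epsilon = epsilon)
}

#' Log-spaced induction-rate grid
#'
#' @param from,to Range (1/hour).
#' @param perDecade Points per decade (>= 12 recommended).
#' @return Strictly increasing numeric vector.
#' @export
alphaGridLog <- function(from, to, perDecade = 12) {
  n <- max(2L, ceiling(log10(to / from) * perDecade) + 1L)
  exp(seq(log(from), log(to), length.out = n))
}
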