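## Power-spectrum diagnostic: oscillatory stochastic dynamics produce a
## spectral peak at nonzero frequency; excitable or mono-stable fluctuations
## produce a monotone (Lorentzian-like) spectrum.

#' Segment-averaged power spectrum of a ComK time series
#'
#' The trajectory is resampled onto a uniform grid (zero-order hold), split
#' into `nSegments` equal segments, each segment is mean-subtracted, and the
#' periodograms are averaged to suppress estimator variance.  Normalisation:
#' the one-sided power sums to the series variance (Parseval).
#'
#' @param traj A [Trajectory-class].
#' @param dt Resampling interval (hours); must resolve the expected period.
#' @param nSegments Number of segments (>= 4 recommended).
#' @return A [PowerSpectrum-class]; frequencies are ordinary (1/hour).
#' @examples
#' tr <- new("Trajectory", times = seq(0, 500, by = 0.1),
#'           n = sin(2 * pi * seq(0, 500, by = 0.1) / 10), m = numeric(5001),
#'           kind = "deterministic", seed = NA_real_, absorbed = FALSE)
#' ps <- powerSpectrum(tr, dt = 0.5, nSegments = 4)
#' @export
powerSpectrum <- function(traj, dt, nSegments = 8L) {
  u <- resampleUniform(traj, dt)
  L <- length(u@n)
  segLen <- floor(L / nSegments)
  if (segLen < 16)
    stop("trajectory span too short for ", nSegments, " segments of >= 16 samples")
  nf <- floor(segLen / 2)
  acc <- numeric(nf + 1)
  for (k in seq_len(nSegments)) {
    x <- u@n[((k - 1) * segLen + 1):(k * segLen)]
    x <- x - mean(x)
    X <- fft(x)
    pg <- Mod(X)^2 / segLen^2          # sums to var(x) over all bins
    one <- pg[1:(nf + 1)]
    dbl <- rep(2, nf + 1)
    dbl[1] <- 1
    if (segLen %% 2 == 0) dbl[nf + 1] <- 1   # Nyquist bin unpaired
    acc <- acc + one * dbl
  }
  freqs <- (0:nf) / (segLen * dt)
  new("PowerSpectrum", freqs = freqs, power = acc / nSegments,
      detrended = TRUE, peak = NULL)
}

#' @rdname PowerSpectrum-class
#' @param object A `PowerSpectrum`.
#' @export
setMethod("show", "PowerSpectrum", function(object) {
  cat(sprintf("PowerSpectrum: %d bins up to %.3g /hour%s\n",
              length(object@freqs), max(object@freqs),
              if (is.null(object@peak)) ""
              else sprintf("; peak at %.3g /hour", object@peak$freq)))
})

#' Classify a spectrum as peaked or non-peaked
#'
#' Fits a Gaussian bump plus constant floor,
#' `P(f) = floor + height exp(-(f - center)^2 / (2 width^2))`, to the
#' positive-frequency spectrum by least squares.  The spectrum is called
#' peaked when the fitted height exceeds `heightFactor` times the floor and
#' the fitted center lies beyond `minCenterBins` frequency bins (the
#' zero-frequency bin is excluded throughout).  A failed fit classifies as
#' non-peaked with `fitOK = FALSE`.
#'
#' @param ps A [PowerSpectrum-class].
#' @param heightFactor Peak-to-floor ratio required (default 3; the published
#'   analysis classifies spectra visually, so this threshold is configurable).
#' @param minCenterBins Minimum fitted center, in bins.
#' @return List with `peaked` (logical), `peak` (list `freq`, `height`,
#'   `width`, `floor`), `fitOK`.
#' @export
classifyPeaked <- function(ps, heightFactor = 3, minCenterBins = 2) {
  f <- ps@freqs[-1]
  y <- ps@power[-1]
  df <- f[2] - f[1]
  fmax <- max(f)
  # bounded reparameterisation keeps the fitted center inside (df/2, fmax)
  # and the width inside (df/4, fmax); floor and height are log-positive
  ctr <- function(t) df / 2 + (fmax - df / 2) / (1 + exp(-t))
  wid <- function(t) df / 4 + (fmax - df / 4) / (1 + exp(-t))
  ss <- function(th) {
    mdl <- exp(th[1]) + exp(th[2]) * exp(-(f - ctr(th[3]))^2 / (2 * wid(th[4])^2))
    sum((y - mdl)^2)
  }
  i0 <- which.max(y)
  fl0 <- max(median(y), 1e-9 * max(y))
  h0 <- max(max(y) - fl0, fl0 * 0.1)
  logit <- function(p) log(p / (1 - p))
  t3 <- logit(min(max((f[i0] - df / 2) / (fmax - df / 2), 1e-3), 1 - 1e-3))
  fit <- tryCatch({
    best <- NULL
    for (w0 in c(2 * df, 8 * df)) {
      t4 <- logit(min(max((w0 - df / 4) / (fmax - df / 4), 1e-3), 1 - 1e-3))
      res <- optim(c(log(fl0), log(h0), t3, t4), ss, method = "Nelder-Mead",
                   control = list(maxit = 4000, reltol = 1e-12))
      if (is.null(best) || res$value < best$value) best <- res
    }
    # a fit no better than a flat spectrum is not a peak fit
    if (best$value > sum((y - mean(y))^2)) stop("no improvement over flat")
    list(floor = exp(best$par[1]), height = exp(best$par[2]),
         center = ctr(best$par[3]), width = wid(best$par[4]), ok = TRUE)
  }, error = function(e) list(ok = FALSE))
  if (!isTRUE(fit$ok)) {
    # moment fallback: compare the maximum bin against the spectral floor
    peaked <- y[i0] > heightFactor * fl0 && f[i0] > minCenterBins * df
    return(list(peaked = peaked,
                peak = list(freq = f[i0], height = y[i0] - fl0,
                            width = df, floor = fl0),
                fitOK = FALSE))
  }
  peaked <- fit$height > heightFactor * fit$floor &&
    fit$center > minCenterBins * df && fit$center < 0.95 * fmax
  list(peaked = peaked,
       peak = list(freq = fit$center, height = fit$height,
                   width = fit$width, floor = fit$floor),
       fitOK = TRUE)
}
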