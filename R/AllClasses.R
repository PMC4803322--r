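#' @import methods
#' @importFrom stats dpois fft optim quantile rgamma setNames uniroot median IQR
NULL

setClassUnion("listOrNULL", c("list", "NULL"))

#' CircuitSpec: a competence circuit and its rate-law parameters
#'
#' Container for one of the two circuit models: the native ComK/ComS circuit,
#' in which ComK represses its own protector ComS, or the synthetic SynEx
#' circuit, in which ComK activates its own repressor MecA.  The object is the
#' single source of truth for the four state-dependent reaction rates
#' (see [circuitRates()]): every consumer (master equation, Gillespie
#' simulation, mean-field ODEs) evaluates the same rate functions.
#'
#' @slot circuit `"native"` or `"synex"`.
#' @slot params Named numeric vector of rate parameters; the names depend on
#'   the circuit (see [nativeParams()] and [synexParams()]).
#' @slot species Character vector of length 2 naming the species counted by
#'   `n` and `m` (`c("ComK","ComS")` for native, `c("ComK","MecA")` for SynEx).
#'
#' @seealso [circuitSpec()], [circuitRates()]
#' @export
setClass("CircuitSpec",
  representation(circuit = "character", params = "numeric", species = "character"))

.native_fields <- c("alpha_k", "beta_k", "k_k", "h", "alpha_s", "beta_s",
                    "k_s", "p", "delta_k", "delta_s", "Gamma_k", "Gamma_s",
                    "lambda_k", "lambda_s")
.synex_fields  <- c("alpha_k", "beta_k", "k_k", "h", "alpha_m", "beta_m",
                    "k_m", "p", "delta", "lambda_k", "lambda_m")

setValidity("CircuitSpec", function(object) {
  msgs <- character()
  if (!object@circuit %in% c("native", "synex"))
    msgs <- c(msgs, "circuit must be 'native' or 'synex'")
  want <- if (identical(object@circuit, "native")) .native_fields else .synex_fields
  miss <- setdiff(want, names(object@params))
  if (length(miss))
    msgs <- c(msgs, paste("missing parameters:", paste(miss, collapse = ", ")))
  extra <- setdiff(names(object@params), want)
  if (length(extra))
    msgs <- c(msgs, paste("unknown parameters:", paste(extra, collapse = ", ")))
  if (!length(msgs)) {
    p <- object@params
    if (any(!is.finite(p)) || any(p < 0))
      msgs <- c(msgs, "all parameters must be finite and >= 0")
    else {
      if (p[["h"]] < 1 || p[["p"]] < 1)
        msgs <- c(msgs, "Hill coefficients h and p must be >= 1")
      pos <- intersect(c("k_k", "k_s", "k_m", "Gamma_k", "Gamma_s"), names(p))
      if (any(p[pos] <= 0))
        msgs <- c(msgs, "half-points and Michaelis constants must be > 0")
    }
  }
  if (length(object@species) != 2L)
    msgs <- c(msgs, "species must have length 2")
  if (length(msgs)) msgs else TRUE
})

#' JointDistribution: steady-state probability table over (n, m)
#'
#' Normalised joint probability of observing `n` copies of ComK and `m` copies
#' of the partner species (ComS or MecA), on the truncated grid
#' `0..nMax` by `0..mMax`.  Row `i` corresponds to `n = i - 1`, column `j` to
#' `m = j - 1`.  `boundaryMass` records the probability held in the outermost
#' row plus column and serves as the truncation-adequacy diagnostic.
#'
#' @slot p Nonnegative matrix summing to 1, dim `(nMax+1) x (mMax+1)`.
#' @slot nMax,mMax Integer truncation bounds.
#' @slot boundaryMass Probability in the last row plus last column.
#' @slot alphaK Induction rate at which the distribution was computed.
#' @seealso [steadyStateDistribution()], [comKMarginal()]
#' @export
setClass("JointDistribution",
  representation(p = "matrix", nMax = "integer", mMax = "integer",
                 boundaryMass = "numeric", alphaK = "numeric"))

setValidity("JointDistribution", function(object) {
  msgs <- character()
  if (!all(dim(object@p) == c(object@nMax + 1L, object@mMax + 1L)))
    msgs <- c(msgs, "dim(p) must be (nMax+1, mMax+1)")
  if (any(object@p < 0)) msgs <- c(msgs, "probabilities must be >= 0")
  if (abs(sum(object@p) - 1) > 1e-10) msgs <- c(msgs, "p must sum to 1 within 1e-10")
  if (length(msgs)) msgs else TRUE
})

#' Trajectory: a stochastic or deterministic time series of (n, m)
#'
#' Stochastic trajectories are piecewise constant between reaction events and
#' carry integer copy numbers; deterministic trajectories are densely sampled
#' solutions of the mean-field ODEs.
#'
#' @slot times Strictly increasing times in hours.
#' @slot n,m Copy-number series (integers for stochastic trajectories).
#' @slot kind `"stochastic"` or `"deterministic"`.
#' @slot seed RNG seed used (NA for deterministic trajectories).
#' @slot absorbed TRUE if a stochastic run halted in an absorbing state.
#' @export
setClass("Trajectory",
  representation(times = "numeric", n = "numeric", m = "numeric",
                 kind = "character", seed = "numeric", absorbed = "logical"))

setValidity("Trajectory", function(object) {
  msgs <- character()
  if (length(object@times) != length(object@n) ||
      length(object@times) != length(object@m))
    msgs <- c(msgs, "times, n, m must have equal length")
  if (length(object@times) > 1 && any(diff(object@times) <= 0))
    msgs <- c(msgs, "times must be strictly increasing")
  if (!object@kind %in% c("stochastic", "deterministic"))
    msgs <- c(msgs, "kind must be 'stochastic' or 'deterministic'")
  if (identical(object@kind, "stochastic") && any(object@n < 0 | object@m < 0))
    msgs <- c(msgs, "stochastic counts must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' FractionCurve: responsive fraction f as a function of induction rate
#'
#' @slot alphaGrid Strictly increasing induction rates (1/hour).
#' @slot f Responsive fraction in `[0, 1]` at each grid point.
#' @slot method Per-point provenance: `"inflection"` or `"two_poisson"`.
#' @slot smoothing List describing the smoothing applied near the
#'   method-concatenation point.
#' @seealso [fractionCurve()], [expansionReport()]
#' @export
setClass("FractionCurve",
  representation(alphaGrid = "numeric", f = "numeric", method = "character",
                 smoothing = "listOrNULL"))

setValidity("FractionCurve", function(object) {
  msgs <- character()
  if (length(object@alphaGrid) != length(object@f) ||
      length(object@alphaGrid) != length(object@method))
    msgs <- c(msgs, "alphaGrid, f, method must have equal length")
  if (any(diff(object@alphaGrid) <= 0))
    msgs <- c(msgs, "alphaGrid must be strictly increasing")
  if (any(object@f < -1e-9 | object@f > 1 + 1e-9))
    msgs <- c(msgs, "f must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' PowerSpectrum: segment-averaged periodogram of a ComK time series
#'
#' @slot freqs Ordinary frequencies (1/hour), nonnegative.
#' @slot power Nonnegative spectral power; with the normalisation used here
#'   `sum(power)` over positive frequencies equals the series variance.
#' @slot detrended TRUE (the mean is always removed per segment).
#' @slot peak NULL, or a list with elements `freq`, `height`, `width`, `floor`
#'   from the Gaussian-bump fit.
#' @seealso [powerSpectrum()], [classifyPeaked()]
#' @export
setClass("PowerSpectrum",
  representation(freqs = "numeric", power = "numeric", detrended = "logical",
                 peak = "listOrNULL"))

setValidity("PowerSpectrum", function(object) {
  msgs <- character()
  if (length(object@freqs) != length(object@power))
    msgs <- c(msgs, "freqs and power must have equal length")
  if (any(object@power < 0)) msgs <- c(msgs, "power must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' FluorescenceSample: per-cell intensities for one titration condition
#'
#' @slot intensities Nonnegative intensities, arbitrary units, one per cell.
#' @slot conditionLabel Condition label, typically the IPTG concentration in uM
#'   (the label `"0"` marks the background condition).
#' @slot circuitLabel Which circuit the strain carries.
#' @export
setClass("FluorescenceSample",
  representation(intensities = "numeric", conditionLabel = "character",
                 circuitLabel = "character"))

setValidity("FluorescenceSample", function(object) {
  msgs <- character()
  if (!length(object@intensities)) msgs <- c(msgs, "intensities must be nonempty")
  if (any(!is.finite(object@intensities))) msgs <- c(msgs, "intensities must be finite")
  if (length(msgs)) msgs else TRUE
})

#' TitrationFit: joint fit of induction rates and the intensity scale
#'
#' Result of fitting model steady-state ComK distributions to a set of
#' fluorescence intensity distributions: one induction rate `alpha_k` per
#' condition plus a single global intensity-per-molecule conversion factor X.
#'
#' @slot X Fitted intensity per molecule (a.u./molecule).
#' @slot fits Data frame with one row per condition: `label`, `alphaHat`,
#'   `sMin` (minimised sum of squared CDF errors), `alphaLo`, `alphaHi`
#'   (profile error bars at 1.25 x sMin), `bounded` (FALSE if an error bar hit
#'   the grid edge).
#' @slot backgroundMode Background intensity subtracted before fitting.
#' @slot profiles List (one per condition) of matrices with columns
#'   `alpha`, `S`: the per-condition objective profile at the fitted X.
#' @seealso [fitTitration()]
#' @export
setClass("TitrationFit",
  representation(X = "numeric", fits = "data.frame",
                 backgroundMode = "numeric", profiles = "list"))

setValidity("TitrationFit", function(object) {
  if (object@X <= 0) return("X must be > 0")
  TRUE
})
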