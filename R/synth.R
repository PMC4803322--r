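## Synthetic fluorescence-titration generator: draws per-cell ComK copy
## numbers from the model's steady-state marginal, converts them to arbitrary
## intensity units with a known factor X, and adds a nonnegative right-skewed
## camera background.  Stands in for microscopy data so the whole fitting
## pipeline (background subtraction, CDF fit, error bars) is testable with
## known ground truth.

#' Configuration for the synthetic titration generator
#'
#' @param spec A [CircuitSpec-class].
#' @param conditions Data frame with columns `label` (condition labels, e.g.
#'   IPTG concentrations `0, 0.75, 1.5, 3`; the `0` label marks the background
#'   condition and should carry the lowest `alpha_k`) and `alpha_k` (ground
#'   truth induction rates, 1/hour).
#' @param XTrue Intensity per molecule (a.u./molecule, > 0).
#' @param backgroundMode Mode of the additive background distribution (a.u.).
#' @param backgroundSpread Scale of the background's right tail (a.u.); 0
#'   gives a constant background.  The background is a shifted gamma (shape
#'   4) whose mode equals `backgroundMode`: nonnegative and right-skewed, as
#'   camera backgrounds are.
#' @param cellsPerCondition Cells drawn per condition (>= 100).
#' @param seed Integer RNG seed; generation is deterministic given the seed.
#' @return Validated list of class `"synthConfig"`.
#' @export
synthConfig <- function(spec, conditions, XTrue = 20, backgroundMode = 100,
                        backgroundSpread = 10, cellsPerCondition = 2000L,
                        seed = 1L) {
  stopifnot(is.data.frame(conditions),
            all(c("label", "alpha_k") %in% names(conditions)),
            cellsPerCondition >= 100, XTrue > 0, backgroundMode >= 0,
            backgroundSpread >= 0, all(conditions$alpha_k > 0))
  zero <- which(suppressWarnings(as.numeric(conditions$label)) == 0)
  if (length(zero) && any(conditions$alpha_k[zero] > min(conditions$alpha_k)))
    stop("the zero-labelled condition must carry the lowest alpha_k, ",
         "since its intensity mode estimates the background")
  structure(list(spec = spec, conditions = conditions, XTrue = XTrue,
                 backgroundMode = backgroundMode,
                 backgroundSpread = backgroundSpread,
                 cellsPerCondition = as.integer(cellsPerCondition),
                 seed = as.integer(seed)),
            class = "synthConfig")
}

.drawBackground <- function(nCells, mode, spread) {
  if (spread <= 0) return(rep(mode, nCells))
  shape <- 4
  shift <- max(mode - (shape - 1) * spread, 0)
  shift + rgamma(nCells, shape = shape, scale = spread)
}

#' Generate a synthetic fluorescence titration
#'
#' For each condition, per-cell ComK counts are drawn from the model
#' steady-state marginal at that condition's `alpha_k` (inverse-CDF sampling),
#' scaled by `XTrue` and summed with a background draw.
#'
#' @param config A [synthConfig()] object.
#' @return List with `samples` (list of [FluorescenceSample-class]) and
#'   `truth` (the configuration's ground-truth record: `conditions`, `XTrue`,
#'   `backgroundMode`, `seed`).
#' @export
generateTitration <- function(config) {
  stopifnot(inherits(config, "synthConfig"))
  set.seed(config$seed)
  samples <- vector("list", nrow(config$conditions))
  for (i in seq_len(nrow(config$conditions))) {
    a <- config$conditions$alpha_k[i]
    pn <- comKMarginal(steadyStateDistribution(setAlphaK(config$spec, a)))
    counts <- sample.int(length(pn), config$cellsPerCondition,
                         replace = TRUE, prob = pn) - 1L
    bg <- .drawBackground(config$cellsPerCondition, config$backgroundMode,
                          config$backgroundSpread)
    samples[[i]] <- fluorescenceSample(config$XTrue * counts + bg,
                                       config$conditions$label[i],
                                       circuitKind(config$spec))
  }
  list(samples = samples,
       truth = list(conditions = config$conditions, XTrue = config$XTrue,
                    backgroundMode = config$backgroundMode,
                    seed = config$seed))
}

#' Round-trip parameter recovery on synthetic data
#'
#' Generates a synthetic titration, runs the full fitting pipeline
#' (background subtraction then [fitTitration()]), and compares the recovered
#' per-condition induction rates and conversion factor to the ground truth.
#'
#' @param config A [synthConfig()] object.
#' @param alphaGrid,XGrid Grids for [fitTitration()]; defaults bracket the
#'   ground truth by a factor of ~5 on each side.
#' @param marginalCache Optional precomputed marginals for `alphaGrid` (see
#'   [fitTitration()]).
#' @return List with `fit` (a [TitrationFit-class]), `truth`, and `recovery`
#'   (data frame: per-condition true and estimated `alpha_k`, whether the
#'   truth lies inside the 1.25 S_min error bar) plus `XRelErr`.
#' @export
roundtripRecovery <- function(config, alphaGrid = NULL, XGrid = NULL,
                              marginalCache = NULL) {
  gen <- generateTitration(config)
  if (is.null(alphaGrid)) {
    r <- range(config$conditions$alpha_k)
    alphaGrid <- alphaGridLog(r[1] / 5, r[2] * 5, perDecade = 16)
  }
  if (is.null(XGrid))
    XGrid <- exp(seq(log(config$XTrue / 4), log(config$XTrue * 4),
                     length.out = 13))
  bg <- subtractBackground(gen$samples)
  fit <- fitTitration(bg$samples, config$spec, alphaGrid, XGrid,
                      backgroundMode = bg$backgroundMode,
                      marginalCache = marginalCache)
  truthA <- config$conditions$alpha_k
  est <- fit@fits
  covered <- !is.na(est$alphaLo) & !is.na(est$alphaHi) &
    truthA >= est$alphaLo & truthA <= est$alphaHi
  list(fit = fit, truth = gen$truth,
       recovery = data.frame(label = est$label, alphaTrue = truthA,
                             alphaHat = est$alphaHat, covered = covered,
                             stringsAsFactors = FALSE),
       XRelErr = abs(fit@X - config$XTrue) / config$XTrue)
}
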