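## Mean-field (deterministic) analysis: ODE integration, fixed points,
## linear stability, and the two regime-boundary induction rates.

## Right-hand side of the mean-field system
##   dn/dt = g(n) - r(n, m) n,   dm/dt = q(n) - s(n, m) m
.meanFieldRHS <- function(spec) {
  fn <- .rateFunctions(spec)
  function(n, m) c(fn$g(n) - fn$r(n, m) * n, fn$q(n) - fn$s(n, m) * m)
}

#' Integrate the mean-field ODEs
#'
#' Solves the deterministic limit of the circuit dynamics with a stiff-capable
#' integrator (`deSolve::lsoda`).
#'
#' @param spec A [CircuitSpec-class].
#' @param n0,m0 Initial mean copy numbers (real-valued, >= 0).
#' @param tEnd End time in hours.
#' @param dtOut Output sampling interval in hours.
#' @param rtol,atol Integrator tolerances.
#' @return A [Trajectory-class] with `kind = "deterministic"`.
#' @examples
#' spec <- circuitSpec("native", alpha_k = 0.072)
#' tr <- integrateCircuit(spec, n0 = 3, m0 = 15, tEnd = 100)
#' @export
integrateCircuit <- function(spec, n0, m0, tEnd, dtOut = tEnd / 2000,
                             rtol = 1e-8, atol = 1e-10) {
  stopifnot(n0 >= 0, m0 >= 0, tEnd > 0, dtOut > 0)
  rhs <- .meanFieldRHS(spec)
  times <- seq(0, tEnd, by = dtOut)
  out <- deSolve::lsoda(
    y = c(n = n0, m = m0), times = times,
    func = function(t, y, parms) list(rhs(max(y[1], 0), max(y[2], 0))),
    rtol = rtol, atol = atol)
  if (nrow(out) < length(times)) {
    last <- out[nrow(out), ]
    stop(sprintf("integrator failed at t = %.4g (last state n = %.4g, m = %.4g)",
                 last[1], last[2], last[3]))
  }
  new("Trajectory", times = out[, 1], n = pmax(out[, 2], -1e-9),
      m = pmax(out[, 3], -1e-9), kind = "deterministic", seed = NA_real_,
      absorbed = FALSE)
}

## m on the partner-species nullcline q(n) = s(n, m) m, solved per n.
## Native: with den = c + m/Gamma_s, c = 1 + n/Gamma_k, the nullcline is the
## positive root of the quadratic
##   (lambda_s/Gamma_s) m^2 + (delta_s + lambda_s c - q/Gamma_s) m - q c = 0.
## SynEx: m = q(n)/lambda_m explicitly.
.mNullcline <- function(spec) {
  p <- as.list(spec@params)
  fn <- .rateFunctions(spec)
  if (spec@circuit == "synex") {
    function(n) fn$q(n) / p$lambda_m
  } else if (p$lambda_s > 0) {
    function(n) {
      q <- fn$q(n)
      cc <- 1 + n / p$Gamma_k
      A <- p$lambda_s / p$Gamma_s
      B <- p$delta_s + p$lambda_s * cc - q / p$Gamma_s
      (-B + sqrt(B * B + 4 * A * q * cc)) / (2 * A)
    }
  } else {
    function(n) {
      q <- fn$q(n)
      cc <- 1 + n / p$Gamma_k
      # delta_s m / (cc + m/Gamma_s) = q  =>  m (delta_s - q/Gamma_s) = q cc
      d <- p$delta_s - q / p$Gamma_s
      ifelse(d > 0, q * cc / d, Inf)
    }
  }
}

#' Analytic Jacobian of the mean-field system
#'
#' @param spec A [CircuitSpec-class].
#' @param n,m Evaluation point.
#' @return 2x2 numeric matrix `J[i,j] = dF_i/dx_j` with `x = (n, m)`.
#' @export
circuitJacobian <- function(spec, n, m) {
  p <- as.list(spec@params)
  fn <- .rateFunctions(spec)
  gp <- p$beta_k * p$h * p$k_k^p$h * n^(p$h - 1) / (p$k_k^p$h + n^p$h)^2
  if (spec@circuit == "native") {
    u <- (n / p$k_s)^p$p
    qp <- -p$beta_s * p$p * (n / p$k_s)^(p$p - 1) / p$k_s / (1 + u)^2
    den <- 1 + n / p$Gamma_k + m / p$Gamma_s
    r <- fn$r(n, m); s <- fn$s(n, m)
    drdn <- -p$delta_k / (den^2 * p$Gamma_k); drdm <- -p$delta_k / (den^2 * p$Gamma_s)
    dsdn <- -p$delta_s / (den^2 * p$Gamma_k); dsdm <- -p$delta_s / (den^2 * p$Gamma_s)
    matrix(c(gp - r - n * drdn, qp - m * dsdn,
             -n * drdm,          -s - m * dsdm), 2, 2)
  } else {
    qp <- p$beta_m * p$p * p$k_m^p$p * n^(p$p - 1) / (p$k_m^p$p + n^p$p)^2
    r <- fn$r(n, m)
    matrix(c(gp - r, qp,
             -p$delta * n, -p$lambda_m), 2, 2)
  }
}

#' Find the mean-field fixed points of a circuit
#'
#' Scans the ComK nullcline residual `g(n) - r(n, m*(n)) n` along the
#' closed-form partner nullcline `m*(n)` over a bounded grid, polishes each
#' sign change with `uniroot`, and classifies every root by the eigenvalues of
#' the analytic Jacobian.
#'
#' @param spec A [CircuitSpec-class].
#' @param nMaxBox Upper end of the search box for `n`; default
#'   `20 * max(k_k, Gamma_k or k_m)` so that all Hill terms are resolved.
#' @param nGrid Number of scan points (split between a dense low-`n` region
#'   and the remainder of the box).
#' @return Data frame with one row per fixed point: `n`, `m`, `re1`, `im1`,
#'   `re2`, `im2` (eigenvalues), `stable`, `oscillatory`.
#' @examples
#' findFixedPoints(circuitSpec("native", alpha_k = 0.072))
#' @export
findFixedPoints <- function(spec, nMaxBox = NULL, nGrid = 6000L) {
  p <- as.list(spec@params)
  if (is.null(nMaxBox)) {
    scaleRef <- if (spec@circuit == "native") max(p$k_k, p$Gamma_k) else max(p$k_k, p$k_m)
    nMaxBox <- 20 * scaleRef
  }
  mfun <- .mNullcline(spec)
  fn <- .rateFunctions(spec)
  phi <- function(n) fn$g(n) - fn$r(n, mfun(n)) * n
  lowEdge <- min(4 * p$k_k, nMaxBox / 2)
  ns <- c(seq(1e-9, lowEdge, length.out = ceiling(nGrid * 0.6)),
          seq(lowEdge, nMaxBox, length.out = ceiling(nGrid * 0.4))[-1])
  ph <- phi(ns)
  idx <- which(ph[-length(ph)] * ph[-1] <= 0 & is.finite(ph[-length(ph)]) &
               is.finite(ph[-1]))
  if (!length(idx))
    stop("no fixed point found in [0, ", signif(nMaxBox, 4),
         "]; enlarge the search box (nMaxBox)")
  roots <- vapply(idx, function(i) {
    if (ph[i] == 0) return(ns[i])
    uniroot(phi, c(ns[i], ns[i + 1]), tol = 1e-12)$root
  }, numeric(1))
  # drop duplicates from grid-edge double hits
  roots <- roots[!duplicated(round(roots, 9))]
  if (length(roots) > 1)
    roots <- roots[c(TRUE, diff(roots) > 1e-7 * (1 + roots[-1]))]
  rows <- lapply(roots, function(nstar) {
    mstar <- mfun(nstar)
    ev <- eigen(circuitJacobian(spec, nstar, mstar), only.values = TRUE)$values
    ev <- ev[order(-Re(ev))]
    data.frame(n = nstar, m = mstar,
               re1 = Re(ev[1]), im1 = Im(ev[1]),
               re2 = Re(ev[2]), im2 = Im(ev[2]),
               stable = max(Re(ev)) < 0,
               oscillatory = max(abs(Im(ev))) > 1e-9)
  })
  do.call(rbind, rows)
}

#' Classify the dynamical regime at one induction rate
#'
#' Excitable: several fixed points, at least one stable.  Oscillatory: a single
#' unstable fixed point.  Mono-stable: a single stable fixed point.
#'
#' @param spec A [CircuitSpec-class].
#' @param alpha_k Optional induction rate; defaults to the one in `spec`.
#' @param ... Passed to [findFixedPoints()].
#' @return List with elements `alphaK`, `fixedPoints` (data frame), `regime`.
#' @examples
#' classifyRegime(circuitSpec("native"), alpha_k = 1.15)$regime
#' @export
classifyRegime <- function(spec, alpha_k = NULL, ...) {
  if (!is.null(alpha_k)) spec <- setAlphaK(spec, alpha_k)
  fp <- findFixedPoints(spec, ...)
  regime <- if (nrow(fp) >= 2) {
    if (any(fp$stable)) "excitable" else "oscillatory"
  } else if (fp$stable[1]) "mono_stable" else "oscillatory"
  list(alphaK = spec@params[["alpha_k"]], fixedPoints = fp, regime = regime)
}

#' Locate the two deterministic regime boundaries
#'
#' `alpha_k_1` (excitable to oscillatory) is found by bisection on the
#' fixed-point count (3 to 1; a saddle-node annihilation), `alpha_k_2`
#' (oscillatory to mono-stable) by bisection on the sign of the largest
#' eigenvalue real part of the single remaining fixed point (a Hopf-type
#' stabilisation).  Bisection is performed in log alpha; each boundary is the
#' midpoint of the final bracket.
#'
#' @param spec A [CircuitSpec-class].
#' @param alphaRange Length-2 interval bracketing both transitions.
#' @param rtol Relative tolerance on each boundary.
#' @param ... Passed to [findFixedPoints()].
#' @return List with `alpha_k_1` and `alpha_k_2` (1/hour).
#' @examples
#' \donttest{regimeBoundaries(circuitSpec("native"))}
#' @export
regimeBoundaries <- function(spec, alphaRange = c(1e-3, 40), rtol = 1e-4, ...) {
  stopifnot(length(alphaRange) == 2, alphaRange[1] > 0,
            alphaRange[1] < alphaRange[2])
  nfix <- function(a) nrow(findFixedPoints(setAlphaK(spec, a), ...))
  maxre <- function(a) {
    fp <- findFixedPoints(setAlphaK(spec, a), ...)
    if (nrow(fp) != 1) return(NA_real_)
    max(fp$re1, fp$re2)
  }
  lo <- alphaRange[1]; hi <- alphaRange[2]
  if (nfix(lo) < 3)
    stop("saddle-node boundary not bracketed: only ", nfix(lo),
         " fixed point(s) at alpha = ", lo)
  if (nfix(hi) != 1)
    stop("upper end of alphaRange still has multiple fixed points")
  a <- lo; b <- hi
  while (b / a > 1 + rtol) {
    mid <- sqrt(a * b)
    if (nfix(mid) >= 3) a <- mid else b <- mid
  }
  alpha1 <- sqrt(a * b)
  a <- b  # just above the saddle-node: single fixed point
  r0 <- maxre(a)
  if (is.na(r0) || r0 < 0)
    stop("Hopf boundary not bracketed: fixed point already stable just above ",
         "the saddle-node (no oscillatory window)")
  if (maxre(hi) >= 0)
    stop("Hopf boundary not bracketed: fixed point still unstable at alpha = ", hi)
  b <- hi
  while (b / a > 1 + rtol) {
    mid <- sqrt(a * b)
    rm_ <- maxre(mid)
    if (is.na(rm_)) stop("fixed-point count changed unexpectedly during Hopf bisection")
    # near-zero real parts are resolved by continuing the bisection, not by an
    # arbitrary sign call: the bracket keeps shrinking around the crossing
    if (rm_ > 0) a <- mid else b <- mid
  }
  alpha2 <- sqrt(a * b)
  list(alpha_k_1 = alpha1, alpha_k_2 = alpha2)
}
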