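## Exact stochastic simulation (Gillespie direct method) of the four-channel
## jump process: n birth at g(n), n death at r(n,m) n, m birth at q(n),
## m death at s(n,m) m.  The heavy lifting is in compiled code; R's RNG is
## used throughout, so set.seed()/the seed argument governs reproducibility.

#' @useDynLib CompetenceCircuits, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.kindCode <- function(spec) if (spec@circuit == "native") 1L else 2L

.parVector <- function(spec) {
  fields <- if (spec@circuit == "native") .native_fields else .synex_fields
  unname(spec@params[fields])
}

#' Simulate an exact stochastic trajectory
#'
#' Statistically exact sample path of the circuit's jump process by the
#' Gillespie direct method (two uniform variates per event).
#'
#' @param spec A [CircuitSpec-class].
#' @param n0,m0 Nonnegative integer initial copy numbers.
#' @param tEnd End time (hours).
#' @param seed Integer RNG seed (mandatory for reproducibility).
#' @param maxEvents Safety cap on the number of reaction events.
#' @return A [Trajectory-class] with `kind = "stochastic"`.  If all
#'   propensities vanish (absorbing state with no production) the trajectory
#'   terminates early and `@absorbed` is TRUE.
#' @examples
#' spec <- circuitSpec("native", alpha_k = 1.15)
#' tr <- simulateSSA(spec, 0, 50, tEnd = 100, seed = 1)
#' @export
simulateSSA <- function(spec, n0, m0, tEnd, seed, maxEvents = 2e7) {
  stopifnot(n0 >= 0, m0 >= 0, n0 == floor(n0), m0 == floor(m0), tEnd > 0)
  set.seed(seed)
  res <- ssa_events(.kindCode(spec), .parVector(spec), n0, m0, tEnd, maxEvents)
  if (isTRUE(res$truncated))
    warning("event cap reached at t = ", signif(res$t_final, 6),
            " h; trajectory truncated")
  new("Trajectory", times = res$times, n = res$n, m = res$m,
      kind = "stochastic", seed = as.numeric(seed),
      absorbed = isTRUE(res$absorbed))
}

#' @rdname Trajectory-class
#' @param object A `Trajectory`.
#' @export
setMethod("show", "Trajectory", function(object) {
  cat(sprintf("%s Trajectory: %d points over %.4g h%s\n", object@kind,
              length(object@times), diff(range(object@times)),
              if (isTRUE(object@absorbed)) " (absorbed)" else ""))
})

#' Resample a trajectory onto a uniform time grid
#'
#' Zero-order-hold resampling: the value at each grid time is the value the
#' trajectory held at that instant (piecewise-constant interpretation for
#' stochastic paths).
#'
#' @param traj A [Trajectory-class].
#' @param dt Grid spacing (hours); must be smaller than the trajectory span.
#' @return A [Trajectory-class] on the uniform grid.
#' @export
resampleUniform <- function(traj, dt) {
  stopifnot(dt > 0)
  t0 <- traj@times[1]
  span <- traj@times[length(traj@times)] - t0
  if (dt >= span)
    stop("dt (", dt, ") must be smaller than the trajectory span (", span, ")")
  grid <- seq(t0, t0 + span, by = dt)
  idx <- findInterval(grid, traj@times)
  new("Trajectory", times = grid, n = traj@n[idx], m = traj@m[idx],
      kind = traj@kind, seed = traj@seed, absorbed = traj@absorbed)
}

#' Time-averaged occupancy distribution from a long stochastic run
#'
#' Runs the Gillespie process for `tEnd` hours and accumulates the
#' time-weighted occupancy of each state (n, m) after a burn-in, without
#' storing the path.  With ergodicity this converges to the master-equation
#' steady state.
#'
#' @param spec A [CircuitSpec-class].
#' @param n0,m0 Initial copy numbers.
#' @param tEnd Total simulated time (hours).
#' @param burnin Initial time span excluded from the average.
#' @param nMax,mMax Histogram bounds (states beyond are clamped into the edge
#'   bin); default sized like the master-equation truncation.
#' @param seed Integer RNG seed.
#' @return Normalised matrix `p[n+1, m+1]`.
#' @export
occupancyDistribution <- function(spec, n0, m0, tEnd, burnin = tEnd * 0.05,
                                  nMax = NULL, mMax = NULL, seed) {
  if (is.null(nMax) || is.null(mMax)) {
    fp <- findFixedPoints(spec)
    kk <- spec@params[["k_k"]]
    if (is.null(nMax)) nMax <- ceiling(4 * max(max(fp$n), kk) + 25)
    if (is.null(mMax)) mMax <- ceiling(max(fp$m) + 8 * sqrt(max(fp$m) + 1) + 25)
  }
  set.seed(seed)
  ssa_occupancy(.kindCode(spec), .parVector(spec), n0, m0, tEnd, burnin,
                as.integer(nMax), as.integer(mMax))
}

#' Ensemble mean of stochastic paths on a time grid
#'
#' Averages `nPaths` independent Gillespie paths sampled at `times`
#' (zero-order hold).  Used to check that the stochastic model tracks the
#' mean-field ODEs in the high-copy-number regime.
#'
#' @param spec A [CircuitSpec-class].
#' @param n0,m0 Initial copy numbers.
#' @param times Sample times (hours), increasing.
#' @param nPaths Number of independent paths.
#' @param seed Integer RNG seed.
#' @return Matrix with columns `n`, `m`: ensemble means at `times`.
#' @export
ssaEnsembleMean <- function(spec, n0, m0, times, nPaths, seed) {
  stopifnot(all(diff(times) > 0), nPaths >= 1)
  set.seed(seed)
  acc <- matrix(0, length(times), 2)
  for (i in seq_len(nPaths))
    acc <- acc + ssa_sample(.kindCode(spec), .parVector(spec), n0, m0, times)
  acc <- acc / nPaths
  colnames(acc) <- c("n", "m")
  acc
}
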