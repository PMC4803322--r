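## Truncated chemical master equation: sparse generator and steady state.

#' Build the truncated master-equation generator
#'
#' Returns the sparse rate operator `A` of the two-species birth-death process
#' on the grid `0..nMax` by `0..mMax` (states ordered n-fastest, i.e. column
#' index `k = n + 1 + (nMax + 1) m`), such that `dp/dt = A p`.  The truncation
#' boundary is reflecting: birth propensities out of the last row/column are
#' set to zero, so every column of `A` sums to zero and total probability is
#' conserved (the null-space problem stays well posed).
#'
#' @param spec A [CircuitSpec-class].
#' @param nMax,mMax Truncation bounds (>= 1).
#' @return A `dgCMatrix` of dimension `(nMax+1)(mMax+1)` squared.
#' @examples
#' A <- buildGenerator(circuitSpec("native"), 10, 10)
#' max(abs(Matrix::colSums(A)))  # 0: probability conservation
#' @export
buildGenerator <- function(spec, nMax, mMax) {
  stopifnot(nMax >= 1, mMax >= 1)
  nMax <- as.integer(nMax); mMax <- as.integer(mMax)
  fn <- .rateFunctions(spec)
  nv <- 0:nMax
  mv <- 0:mMax
  N1 <- nMax + 1L; M1 <- mMax + 1L
  nn <- rep(nv, times = M1)
  mm <- rep(mv, each = N1)
  g <- fn$g(nn); q <- fn$q(nn)
  r <- fn$r(nn, mm); s <- fn$s(nn, mm)
  g[nn == nMax] <- 0     # reflecting boundary
  q[mm == mMax] <- 0
  state <- seq_len(N1 * M1)
  # off-diagonal inflow entries A[dst, src] = propensity(src -> dst)
  iN <- nn < nMax
  iD <- nn > 0
  jN <- mm < mMax
  jD <- mm > 0
  ii <- c(state,               # diagonal
          state[iN] + 1L,      # n birth
          state[iD] - 1L,      # n death
          state[jN] + N1,      # m birth
          state[jD] - N1)      # m death
  jj <- c(state, state[iN], state[iD], state[jN], state[jD])
  xx <- c(-(g + r * nn + q + s * mm),
          g[iN], (r * nn)[iD], q[jN], (s * mm)[jD])
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(N1 * M1, N1 * M1))
}

## One bordered solve: replace the first equation by the normalisation
## constraint sum(p) = 1 and solve the (nonsingular) sparse system.
.solveSteady <- function(A) {
  S <- nrow(A)
  B <- A
  B[1, ] <- 1
  b <- c(1, rep(0, S - 1))
  p <- as.numeric(Matrix::solve(B, b))
  p <- pmax(p, 0)
  p / sum(p)
}

#' Steady-state joint distribution of the master equation
#'
#' Computes the normalised null vector of the truncated generator by a sparse
#' bordered solve (one generator row replaced by the normalisation
#' constraint).  If the probability held at the truncation boundary exceeds
#' `boundaryTol`, the truncation is enlarged geometrically (factor 1.5 on the
#' offending axis) and the solve repeated, up to `cap` states per axis.
#'
#' The default initial truncation is sized from the mean-field fixed points:
#' `nMax ~ 4 max(n*, k_k) + 25` and `mMax ~ max(m*) + 8 sqrt(max(m*)) + 25`,
#' which covers the excursion range of the low-copy regimes; the boundary-mass
#' check guarantees adequacy regardless of the initial guess.
#'
#' @param spec A [CircuitSpec-class].
#' @param nMax,mMax Optional initial truncation bounds.
#' @param boundaryTol Maximum tolerated boundary mass (default 1e-6).
#' @param cap Per-axis truncation cap.
#' @return A [JointDistribution-class].
#' @examples
#' jd <- steadyStateDistribution(circuitSpec("native", alpha_k = 1.15))
#' sum(prob(jd))
#' @export
steadyStateDistribution <- function(spec, nMax = NULL, mMax = NULL,
                                    boundaryTol = 1e-6, cap = 3000L) {
  if (is.null(nMax) || is.null(mMax)) {
    fp <- tryCatch(findFixedPoints(spec), error = function(e) NULL)
    kk <- spec@params[["k_k"]]
    nstar <- if (is.null(fp)) kk else max(fp$n)
    mstar <- if (is.null(fp)) kk else max(fp$m)
    if (is.null(nMax)) nMax <- ceiling(4 * max(nstar, kk) + 25)
    if (is.null(mMax)) mMax <- ceiling(mstar + 8 * sqrt(mstar + 1) + 25)
  }
  repeat {
    A <- buildGenerator(spec, nMax, mMax)
    p <- .solveSteady(A)
    res <- max(abs(A %*% p))
    pm <- matrix(p, nrow = nMax + 1L)
    bmN <- sum(pm[nMax + 1L, ])
    bmM <- sum(pm[, mMax + 1L])
    if (bmN + bmM < boundaryTol || (nMax >= cap && mMax >= cap)) {
      if (bmN + bmM >= boundaryTol)
        stop(sprintf(paste0("boundary mass %.3g still exceeds %.1g at the ",
                            "truncation cap (%d, %d)"),
                     bmN + bmM, boundaryTol, nMax, mMax))
      if (res > 1e-10)
        warning(sprintf("steady-state residual %.3g exceeds 1e-10", res))
      return(new("JointDistribution", p = pm, nMax = as.integer(nMax),
                 mMax = as.integer(mMax), boundaryMass = bmN + bmM,
                 alphaK = spec@params[["alpha_k"]]))
    }
    if (bmN >= boundaryTol / 2) nMax <- min(ceiling(nMax * 1.5), cap)
    if (bmM >= boundaryTol / 2) mMax <- min(ceiling(mMax * 1.5), cap)
  }
}

#' @rdname JointDistribution-class
#' @param object A `JointDistribution`.
#' @export
setMethod("show", "JointDistribution", function(object) {
  cat(sprintf(paste0("JointDistribution on [0,%d] x [0,%d] (alpha_k = %.4g)\n",
                     "boundary mass %.3g; ComK mean %.3g\n"),
              object@nMax, object@mMax, object@alphaK, object@boundaryMass,
              sum((0:object@nMax) * rowSums(object@p))))
})

#' Probability table of a JointDistribution
#' @param jd A [JointDistribution-class].
#' @return Numeric matrix `p[n+1, m+1]`.
#' @export
prob <- function(jd) jd@p

#' Boundary mass of a JointDistribution
#' @param jd A [JointDistribution-class].
#' @export
boundaryMass <- function(jd) jd@boundaryMass

#' ComK marginal of a joint distribution
#'
#' Sums the joint table over the partner species, `p_n = sum_m p_nm`, and
#' renormalises defensively.
#'
#' @param jd A [JointDistribution-class], or a matrix `p[n+1, m+1]`.
#' @return Numeric vector `p_n` over `n = 0..nMax`, summing to 1.
#' @export
comKMarginal <- function(jd) {
  p <- if (is(jd, "JointDistribution")) jd@p else jd
  pn <- rowSums(p)
  pn / sum(pn)
}
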