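# Generator construction and steady-state solves.

test_that("generator columns sum to zero (probability conservation)", {
  for (spec in list(nativeDefault(0.5), synexDefault(0.5))) {
    A <- buildGenerator(spec, 15, 12)
    expect_lt(max(abs(Matrix::colSums(A))), 1e-12)
  }
})

test_that("generator action on a delta state equals the propensity stencil", {
  spec <- nativeDefault(0.9)
  nMax <- 12L; mMax <- 10L
  A <- buildGenerator(spec, nMax, mMax)
  idx <- function(n, m) n + 1L + (nMax + 1L) * m
  set.seed(42)
  for (k in 1:12) {
    n <- sample(0:nMax, 1); m <- sample(0:mMax, 1)
    e <- numeric((nMax + 1L) * (mMax + 1L))
    e[idx(n, m)] <- 1
    out <- as.numeric(A %*% e)
    # independent stencil: transcribe the rate laws directly
    p <- as.list(circuitParams(spec))
    g <- p$alpha_k + p$beta_k * n^p$h / (p$k_k^p$h + n^p$h)
    q <- p$alpha_s + p$beta_s / (1 + (n / p$k_s)^p$p)
    den <- 1 + n / p$Gamma_k + m / p$Gamma_s
    r <- p$delta_k / den + p$lambda_k
    s <- p$delta_s / den + p$lambda_s
    if (n == nMax) g <- 0         # reflecting boundary
    if (m == mMax) q <- 0
    ref <- numeric(length(e))
    ref[idx(n, m)] <- -(g + r * n + q + s * m)
    if (n < nMax) ref[idx(n + 1, m)] <- g
    if (n > 0)    ref[idx(n - 1, m)] <- r * n
    if (m < mMax) ref[idx(n, m + 1)] <- q
    if (m > 0)    ref[idx(n, m - 1)] <- s * m
    expect_equal(out, ref, tolerance = 1e-13)
  }
})

test_that("with all production off the steady state is a delta at the origin", {
  spec <- circuitSpec("native", alpha_k = 0, beta_k = 0, alpha_s = 0,
                      beta_s = 0, delta_k = 0, delta_s = 0,
                      lambda_k = 1, lambda_s = 1)
  jd <- steadyStateDistribution(spec, nMax = 8, mMax = 8)
  expect_equal(prob(jd)[1, 1], 1, tolerance = 1e-12)
})

test_that("unregulated pair has a product-Poisson steady state (TV < 1e-8)", {
  spec <- linearNativeSpec(alpha_k = 6, alpha_s = 10, lambda_k = 1,
                           lambda_s = 0.8)
  jd <- steadyStateDistribution(spec)
  pois <- outer(dpois(0:jd@nMax, 6), dpois(0:jd@mMax, 10 / 0.8))
  expect_lt(tvDist(as.numeric(prob(jd)), as.numeric(pois)), 1e-8)
  # marginal of a product distribution equals its n-factor
  expect_lt(tvDist(comKMarginal(jd), dpois(0:jd@nMax, 6)), 1e-8)
})

test_that("steady state solves the master equation to residual 1e-10", {
  for (spec in list(nativeDefault(1.15), synexDefault(1.8))) {
    jd <- steadyStateDistribution(spec)
    A <- buildGenerator(spec, jd@nMax, jd@mMax)
    expect_lt(max(abs(A %*% as.numeric(prob(jd)))), 1e-10)
    expect_equal(sum(prob(jd)), 1, tolerance = 1e-10)
    expect_lt(boundaryMass(jd), 1e-6)
  }
})

test_that("the marginal is stable under enlarging the truncation", {
  spec <- nativeDefault(1.15)
  jd1 <- steadyStateDistribution(spec)
  jd2 <- steadyStateDistribution(spec, nMax = ceiling(jd1@nMax * 1.5),
                                 mMax = ceiling(jd1@mMax * 1.5))
  p1 <- comKMarginal(jd1)
  p2 <- comKMarginal(jd2)[seq_along(comKMarginal(jd1))]
  expect_lt(0.5 * sum(abs(p1 - p2)) + 0.5 * (1 - sum(p2)), 1e-6)
  # and f is unchanged to 1e-4
  f1 <- fInflection(comKMarginal(jd1), hiAnchor = 5)$f
  f2 <- fInflection(comKMarginal(jd2), hiAnchor = 5)$f
  expect_lt(abs(f1 - f2), 1e-4)
})
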