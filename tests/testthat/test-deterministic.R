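# Mean-field integration, fixed points, stability, regime boundaries.

test_that("decoupled linear system relaxes to (alpha/lambda) with rates lambda", {
  spec <- linearNativeSpec(alpha_k = 6, alpha_s = 10, lambda_k = 1, lambda_s = 0.8)
  tr <- integrateCircuit(spec, n0 = 0, m0 = 0, tEnd = 30, dtOut = 0.1)
  expect_equal(tail(tr@n, 1), 6, tolerance = 1e-6)
  expect_equal(tail(tr@m, 1), 10 / 0.8, tolerance = 1e-6)
  # mono-exponential relaxation: log residual decays linearly at rate lambda
  mid <- tr@times > 2 & tr@times < 8
  slope <- coef(lm(log(6 - tr@n[mid]) ~ tr@times[mid]))[2]
  expect_equal(unname(slope), -1, tolerance = 1e-3)
  fp <- findFixedPoints(spec)
  expect_equal(nrow(fp), 1)
  expect_true(fp$stable)
  expect_false(fp$oscillatory)
  expect_equal(sort(c(fp$re1, fp$re2)), c(-1, -0.8), tolerance = 1e-8)
})

test_that("integrating from a fixed point yields a constant trajectory", {
  for (spec in list(nativeDefault(1.15), synexDefault(1.8))) {
    fp <- findFixedPoints(spec)
    i <- which.max(fp$n)
    tr <- integrateCircuit(spec, fp$n[i], fp$m[i], tEnd = 50, dtOut = 0.5)
    expect_lt(max(abs(tr@n - fp$n[i])), 1e-5 * (1 + fp$n[i]))
    expect_lt(max(abs(tr@m - fp$m[i])), 1e-5 * (1 + fp$m[i]))
  }
})

test_that("excitable regime shows a single transient excursion then rest", {
  tr <- integrateCircuit(circuitSpec("native", alpha_k = 0.072),
                         n0 = 3, m0 = 85, tEnd = 150, dtOut = 0.05)
  expect_gt(max(tr@n), 10)            # a genuine high-ComK excursion
  late <- tr@times > 100
  expect_lt(max(tr@n[late]), 0.5)     # returned to the low-ComK rest state
  up <- which(diff(tr@n > 5) == 1)    # upcrossings of a mid-level threshold
  expect_equal(length(up), 1)
})

test_that("fixed-point residuals vanish and match a brute-force scan", {
  for (spec in list(nativeDefault(0.072), nativeDefault(5),
                    synexDefault(0.036), synexDefault(20))) {
    fp <- findFixedPoints(spec)
    # residual of both steady-state equations
    for (i in seq_len(nrow(fp))) {
      rt <- circuitRates(spec, round(fp$n[i]), round(fp$m[i]))  # integer guard only
      fn <- CompetenceCircuits:::.rateFunctions(spec)
      res <- c(fn$g(fp$n[i]) - fn$r(fp$n[i], fp$m[i]) * fp$n[i],
               fn$q(fp$n[i]) - fn$s(fp$n[i], fp$m[i]) * fp$m[i])
      expect_lt(max(abs(res)), 1e-8)
    }
    # independent oracle: dense sign-change scan of the ComK residual along an
    # m-nullcline solved by bisection (no shared code path)
    p <- as.list(circuitParams(spec))
    F2 <- function(n, m) {
      if (circuitKind(spec) == "native")
        p$alpha_s + p$beta_s / (1 + (n / p$k_s)^p$p) -
          m * (p$delta_s / (1 + n / p$Gamma_k + m / p$Gamma_s) + p$lambda_s)
      else p$alpha_m + p$beta_m * n^p$p / (p$k_m^p$p + n^p$p) - p$lambda_m * m
    }
    F1 <- function(n, m) {
      g <- p$alpha_k + p$beta_k * n^p$h / (p$k_k^p$h + n^p$h)
      r <- if (circuitKind(spec) == "native")
        p$delta_k / (1 + n / p$Gamma_k + m / p$Gamma_s) + p$lambda_k
      else p$delta * m + p$lambda_k
      g - r * n
    }
    mOf <- function(n) uniroot(function(m) F2(n, m), c(0, 1e6), tol = 1e-12)$root
    ns <- seq(1e-8, 30, length.out = 2000)
    ph <- vapply(ns, function(n) F1(n, mOf(n)), numeric(1))
    sc <- which(ph[-1] * ph[-length(ph)] <= 0)
    bruteRoots <- (ns[sc] + ns[sc + 1]) / 2
    inScan <- fp$n[fp$n <= 30]
    expect_equal(length(inScan), length(bruteRoots))
    expect_lt(max(abs(sort(inScan) - sort(bruteRoots))), diff(ns[1:2]) * 1.01)
  }
})

test_that("analytic Jacobian matches central finite differences", {
  pts <- list(c(0.5, 80), c(5, 20), c(30, 1), c(2, 0.3))
  for (spec in list(nativeDefault(0.7), synexDefault(2))) {
    fn <- CompetenceCircuits:::.rateFunctions(spec)
    F <- function(x) c(fn$g(x[1]) - fn$r(x[1], x[2]) * x[1],
                       fn$q(x[1]) - fn$s(x[1], x[2]) * x[2])
    for (x in pts) {
      J <- circuitJacobian(spec, x[1], x[2])
      Jfd <- matrix(0, 2, 2)
      for (j in 1:2) {
        h <- 1e-6 * max(1, abs(x[j]))
        xp <- x; xm <- x
        xp[j] <- xp[j] + h; xm[j] <- xm[j] - h
        Jfd[, j] <- (F(xp) - F(xm)) / (2 * h)
      }
      expect_lt(max(abs(J - Jfd)) / max(abs(Jfd)), 1e-6)
    }
  }
})

test_that("regime boundaries converge and order the regimes correctly", {
  spec <- circuitSpec("native")
  b1 <- regimeBoundaries(spec, rtol = 1e-3)
  b2 <- regimeBoundaries(spec, rtol = 5e-4)
  expect_lt(abs(b1$alpha_k_1 - b2$alpha_k_1), 1e-3 * b1$alpha_k_1 * 1.5)
  expect_lt(abs(b1$alpha_k_2 - b2$alpha_k_2), 1e-3 * b1$alpha_k_2 * 1.5)
  expect_true(0 < b1$alpha_k_1 && b1$alpha_k_1 < b1$alpha_k_2)
  # regime label is a step function of alpha with exactly two switches
  alphas <- exp(seq(log(0.02), log(30), length.out = 15))
  labs <- vapply(alphas, function(a) classifyRegime(spec, a)$regime, character(1))
  expect_equal(sum(labs[-1] != labs[-length(labs)]), 2)
  expect_equal(unique(labs), c("excitable", "oscillatory", "mono_stable"))
})

test_that("just above the Hopf boundary the fixed point is a damped spiral", {
  fp <- findFixedPoints(circuitSpec("native", alpha_k = 2.0))
  expect_equal(nrow(fp), 1)
  expect_true(fp$stable && fp$oscillatory)
  fx <- findFixedPoints(circuitSpec("synex", alpha_k = 11.5))
  expect_equal(nrow(fx), 1)
  expect_true(fx$stable && fx$oscillatory)
})
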