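# Rate-law evaluation and parameter handling.

test_that("rates match a direct transcription of the rate laws on a 50x50 grid", {
  grid <- expand.grid(n = 0:49, m = 0:49)
  for (kind in c("native", "synex")) {
    spec <- circuitSpec(kind, alpha_k = 0.7)
    p <- as.list(circuitParams(spec))
    got <- circuitRates(spec, grid$n, grid$m)
    n <- grid$n; m <- grid$m
    g <- p$alpha_k + p$beta_k * n^p$h / (p$k_k^p$h + n^p$h)
    if (kind == "native") {
      q <- p$alpha_s + p$beta_s / (1 + (n / p$k_s)^p$p)
      den <- 1 + n / p$Gamma_k + m / p$Gamma_s
      r <- p$delta_k / den + p$lambda_k
      s <- p$delta_s / den + p$lambda_s
    } else {
      q <- p$alpha_m + p$beta_m * n^p$p / (p$k_m^p$p + n^p$p)
      r <- p$delta * m + p$lambda_k
      s <- rep(p$lambda_m, length(n))
    }
    for (pair in list(c("g", "g"), c("q", "q"), c("r", "r"), c("s", "s"))) {
      ref <- get(pair[2])
      expect_lt(max(abs(got[[pair[1]]] - ref) / pmax(abs(ref), 1e-300)), 1e-12)
    }
    expect_true(all(unlist(got) >= 0) && all(is.finite(unlist(got))))
  }
})

test_that("limiting values of the regulation functions are exact", {
  spec <- nativeDefault(alpha_k = 0.4)
  p <- as.list(circuitParams(spec))
  at0 <- circuitRates(spec, 0, 7)
  expect_equal(unname(at0$g), p$alpha_k)                      # Hill term vanishes
  expect_equal(unname(at0$q), p$alpha_s + p$beta_s)           # repression off
  r00 <- circuitRates(spec, 0, 0)
  expect_equal(unname(r00$r), p$delta_k + p$lambda_k)         # denominator = 1
  expect_equal(unname(r00$s), p$delta_s + p$lambda_s)
  athalf <- circuitRates(spec, p$k_k, 0)                      # k_k is integer
  expect_equal(unname(athalf$g), p$alpha_k + p$beta_k / 2)
  sx <- synexDefault()
  px <- as.list(circuitParams(sx))
  expect_equal(unname(circuitRates(sx, 5, 0)$r), px$lambda_k) # no MecA present
  expect_equal(unname(circuitRates(sx, 17, 31)$s), px$lambda_m)
})

test_that("regulation functions are monotone in the documented directions", {
  n <- 0:200
  spec <- nativeDefault()
  rw <- circuitRates(spec, n, rep(5, length(n)))
  expect_true(all(diff(rw$g) >= 0))
  expect_true(all(diff(rw$q) <= 0))
  expect_true(all(diff(rw$r) <= 0))
  expect_true(all(diff(rw$s) <= 0))
  cm <- circuitRates(spec, rep(5, 101), 0:100)
  expect_true(all(diff(cm$r) <= 0))
  expect_true(all(diff(cm$s) <= 0))
  sx <- synexDefault()
  rx <- circuitRates(sx, n, rep(5, length(n)))
  expect_true(all(diff(rx$g) >= 0))
  expect_true(all(diff(rx$q) >= 0))
})

test_that("invalid states and parameters are rejected", {
  spec <- nativeDefault()
  expect_error(circuitRates(spec, -1, 0), "nonnegative")
  expect_error(circuitRates(spec, 0, 2.5), "nonnegative")
  expect_error(circuitSpec("native", params = synexParams()), "missing")
  expect_error(nativeParams(nonsense = 3), "unknown")
  expect_error(circuitSpec("native", h = -2))
})

test_that("parameter files round-trip and support overrides", {
  p <- nativeParams()
  tmp <- tempfile(fileext = ".txt")
  writeLines(paste(names(p), p), tmp)
  expect_identical(loadParamFile(tmp)[names(p)], p)
  expect_equal(nativeParams(alpha_k = 2.5)[["alpha_k"]], 2.5)
  expect_equal(synexParams(file = system.file("extdata", "params_synex.txt",
                                              package = "CompetenceCircuits")),
               synexParams())
})

test_that("count rescaling multiplies mean-field fixed points by omega", {
  for (kind in c("native", "synex")) {
    spec <- circuitSpec(kind, alpha_k = 5)
    fp <- findFixedPoints(spec)
    omega <- 40
    fpS <- findFixedPoints(scaleCounts(spec, omega))
    expect_equal(nrow(fpS), nrow(fp))
    expect_equal(fpS$n, omega * fp$n, tolerance = 1e-6)
    expect_equal(fpS$m, omega * fp$m, tolerance = 1e-6)
  }
})
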