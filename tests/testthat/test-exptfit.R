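# Background subtraction, CDF objective, error bars, titration fit.

test_that("background mode is recovered and subtraction is shift-invariant", {
  set.seed(4)
  b <- 130
  # discrete signal on an intensity lattice plus a known constant background:
  # the histogram mode of the zero condition sits at b
  X <- 25
  counts <- sample.int(6, 20000, replace = TRUE,
                       prob = c(0.55, 0.2, 0.1, 0.07, 0.05, 0.03)) - 1L
  bg <- X * counts + b + rnorm(20000, sd = 1.5)
  s0 <- fluorescenceSample(bg, "0")
  s1 <- fluorescenceSample(bg + 400, "1.5")
  res <- subtractBackground(list(s0, s1))
  iqr <- IQR(bg); binw <- 2 * iqr / 20000^(1 / 3)
  expect_lt(abs(res$backgroundMode - b), binw)
  # the zero condition's post-subtraction mode sits at ~0
  m0 <- CompetenceCircuits:::.histogramMode(res$samples[[1]]@intensities)
  expect_lt(abs(m0), 2 * binw)
  # shifting every intensity by +c leaves the output unchanged
  shift <- lapply(list(s0, s1), function(s)
    initialize(s, intensities = s@intensities + 57))
  res2 <- subtractBackground(shift)
  expect_equal(res2$samples[[2]]@intensities, res$samples[[2]]@intensities,
               tolerance = 1e-8)
  expect_error(subtractBackground(list(s1)), "zero")
})

test_that("error bars invert a quadratic profile exactly", {
  alphaHat <- 2; w <- 0.8; sMin <- 0.04
  alpha <- seq(0.5, 4, by = 0.01)
  S <- sMin * (1 + ((alpha - alphaHat) / w)^2)
  eb <- errorBars(alpha, S, level = 1.25)
  expect_equal(eb$alphaLo, alphaHat - 0.5 * w, tolerance = 1e-3)
  expect_equal(eb$alphaHi, alphaHat + 0.5 * w, tolerance = 1e-3)
  expect_true(eb$bounded)
  # noisy profile: bars within one grid step of a dense-scan oracle
  set.seed(2)
  Sn <- S * exp(rnorm(length(S), sd = 0.01))
  ebN <- errorBars(alpha, Sn)
  thr <- 1.25 * min(Sn); i0 <- which.min(Sn)
  lo <- max(which(Sn[1:i0] >= thr)); hi <- i0 - 1 + min(which(Sn[i0:length(Sn)] >= thr))
  expect_lt(abs(ebN$alphaLo - alpha[lo]), 2 * 0.01)
  expect_lt(abs(ebN$alphaHi - alpha[hi]), 2 * 0.01)
  expect_error(errorBars(alpha, rev(sort(S)), level = 1.25), "edge")
})

test_that("self-fit of model-generated data recovers (alpha, X) with S ~ 0", {
  spec <- circuitSpec("synex")
  aTrue <- 3; X0 <- 12
  pn <- comKMarginal(steadyStateDistribution(setAlphaK(spec, aTrue)))
  set.seed(8)
  counts <- sample.int(length(pn), 6000, replace = TRUE, prob = pn) - 1L
  smp <- fluorescenceSample(X0 * counts, "1.5", "synex")
  alphaGrid <- alphaGridLog(0.5, 15, perDecade = 10)
  XGrid <- exp(seq(log(3), log(48), length.out = 9))
  fit <- fitTitration(list(smp), spec, alphaGrid, XGrid)
  expect_lt(abs(fit@X - X0) / X0, 0.1)
  gridStep <- alphaGrid[2] / alphaGrid[1]
  expect_lt(abs(log(fit@fits$alphaHat / aTrue)), 1.5 * log(gridStep))
  expect_lt(fit@fits$sMin, 5e-3)
  # intensity rescaling scales X and leaves alpha estimates unchanged
  smp2 <- fluorescenceSample(3 * smp@intensities, "1.5", "synex")
  fit2 <- fitTitration(list(smp2), spec, alphaGrid, 3 * XGrid)
  expect_lt(abs(fit2@X / fit@X - 3) / 3, 0.05)
  expect_equal(fit2@fits$alphaHat, fit@fits$alphaHat, tolerance = 0.3)
})
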