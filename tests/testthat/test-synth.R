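# Synthetic titration generator and round-trip recovery.

test_that("with X = 1 and no background, intensities are the raw counts", {
  spec <- circuitSpec("synex")
  cfg <- synthConfig(spec, data.frame(label = c("0", "3"),
                                      alpha_k = c(0.2, 5)),
                     XTrue = 1, backgroundMode = 0, backgroundSpread = 0,
                     cellsPerCondition = 200, seed = 2)
  gen <- generateTitration(cfg)
  v <- gen$samples[[2]]@intensities
  expect_true(all(v == floor(v)) && all(v >= 0))
  # deterministic given the seed
  gen2 <- generateTitration(cfg)
  expect_identical(gen$samples[[1]]@intensities, gen2$samples[[1]]@intensities)
})

test_that("large samples reproduce the model marginal and its moments", {
  spec <- circuitSpec("synex")
  a <- 3
  cfg <- synthConfig(spec, data.frame(label = c("0", "x"), alpha_k = c(0.2, a)),
                     XTrue = 1, backgroundMode = 0, backgroundSpread = 0,
                     cellsPerCondition = 1e5, seed = 3)
  gen <- generateTitration(cfg)
  pn <- comKMarginal(steadyStateDistribution(setAlphaK(spec, a)))
  v <- gen$samples[[2]]@intensities
  emp <- tabulate(v + 1, nbins = length(pn)) / length(v)
  expect_lt(tvDist(emp, pn), 0.02)
  mu <- sum((seq_along(pn) - 1) * pn)
  s2 <- sum(((seq_along(pn) - 1) - mu)^2 * pn)
  seMean <- sqrt(s2 / length(v))
  expect_lt(abs(mean(v) - mu), 3 * seMean)
  seVar <- sqrt(2 / (length(v) - 1)) * s2   # normal-approx SE of the variance
  expect_lt(abs(var(v) - s2), 5 * seVar)
})

test_that("titration conditions spanning the regimes change histogram shape", {
  spec <- circuitSpec("synex")
  cfg <- synthConfig(spec,
                     data.frame(label = c("0", "0.75", "3"),
                                alpha_k = c(0.05, 2, 60)),
                     XTrue = 1, backgroundMode = 0, backgroundSpread = 0,
                     cellsPerCondition = 5000, seed = 5)
  gen <- generateTitration(cfg)
  v <- lapply(gen$samples, function(s) s@intensities)
  cut <- 1   # between the rest state (~0) and the competent state (~7)
  fracHigh <- vapply(v, function(x) mean(x > cut), numeric(1))
  expect_lt(fracHigh[1], 0.05)                       # unimodal low
  expect_true(fracHigh[2] > 0.1 && fracHigh[2] < 0.9) # mixed
  expect_gt(fracHigh[3], 0.95)                       # unimodal high
})

test_that("round-trip recovery finds X and covers alpha_k with its error bars", {
  spec <- circuitSpec("synex")
  cfg <- synthConfig(spec,
                     data.frame(label = c("0", "0.75", "1.5", "3"),
                                alpha_k = c(0.3, 1.5, 5, 14)),
                     XTrue = 15, backgroundMode = 60, backgroundSpread = 1.5,
                     cellsPerCondition = 4000, seed = 7)
  rec <- roundtripRecovery(cfg,
                           alphaGrid = alphaGridLog(0.05, 60, perDecade = 8),
                           XGrid = exp(seq(log(5), log(45), length.out = 9)))
  expect_lt(rec$XRelErr, 0.1)
  # fitted induction rates are ordered like the truth (monotone titration)
  expect_true(all(diff(rec$recovery$alphaHat) > 0))
  # each induction rate is recovered to better than the titration spacing
  expect_true(all(abs(log(rec$recovery$alphaHat / rec$recovery$alphaTrue)) <
                    log(1.8)))
  cfgBad <- data.frame(label = c("0", "1"), alpha_k = c(5, 0.3))
  expect_error(synthConfig(spec, cfgBad), "lowest")
})
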