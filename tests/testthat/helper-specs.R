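# Shared fixtures: parameter sets built in code.

# Unregulated native pair: constant births (alpha_k, alpha_s), linear deaths
# (lambda_k, lambda_s).  Steady state is a product of Poissons with means
# alpha_k/lambda_k and alpha_s/lambda_s.
linearNativeSpec <- function(alpha_k = 6, alpha_s = 10,
                             lambda_k = 1, lambda_s = 0.8) {
  circuitSpec("native", alpha_k = alpha_k, beta_k = 0, alpha_s = alpha_s,
              beta_s = 0, delta_k = 0, delta_s = 0,
              lambda_k = lambda_k, lambda_s = lambda_s)
}

# Pure linear death process for ComK only.
pureDeathSpec <- function(lambda = 1) {
  circuitSpec("native", alpha_k = 0, beta_k = 0, alpha_s = 0, beta_s = 0,
              delta_k = 0, delta_s = 0, lambda_k = lambda, lambda_s = lambda)
}

nativeDefault <- function(alpha_k = 0.1) circuitSpec("native", alpha_k = alpha_k)
synexDefault  <- function(alpha_k = 0.1) circuitSpec("synex", alpha_k = alpha_k)

# Frozen deterministic regime boundaries of the packaged parameter sets,
# cross-checked against an independent nullcline/bisection implementation.
# Recomputed from scratch in the deterministic tests and in the acceptance
# script; kept here so downstream tests need not repeat the bisection.
NATIVE_BOUNDS <- list(alpha_k_1 = 0.6383, alpha_k_2 = 1.8638)
SYNEX_BOUNDS  <- list(alpha_k_1 = 0.5424, alpha_k_2 = 10.9155)

# Total-variation distance between two distributions on the same support.
tvDist <- function(p, q) 0.5 * sum(abs(p / sum(p) - q / sum(q)))
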