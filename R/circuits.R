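#' Native circuit parameters
#'
#' Build the parameter vector for the native competence circuit, in which ComK
#' auto-activates and represses ComS, and both species compete for degradation
#' by the MecA complex (Michaelis-Menten denominator `1 + n/Gamma_k + m/Gamma_s`).
#' All rates are per hour, all count-like quantities are molecule numbers.
#' Called with no arguments this returns the packaged default set
#' (`inst/extdata/params_native.txt`); individual values can be overridden.
#'
#' @param ... Named overrides of individual parameters.
#' @param file Optional path to a key-value parameter file replacing the
#'   packaged defaults.
#' @return Named numeric vector with fields `alpha_k, beta_k, k_k, h, alpha_s,
#'   beta_s, k_s, p, delta_k, delta_s, Gamma_k, Gamma_s, lambda_k, lambda_s`.
#' @examples
#' p <- nativeParams(alpha_k = 1.15)
#' @export
nativeParams <- function(..., file = NULL) {
  defaults <- loadParamFile(file %||% system.file("extdata", "params_native.txt",
                                                  package = "CompetenceCircuits"))
  .applyOverrides(defaults, .native_fields, list(...))
}

#' SynEx circuit parameters
#'
#' Build the parameter vector for the synthetic SynEx circuit, in which ComK
#' auto-activates and also activates MecA, and MecA degrades ComK enzymatically
#' at rate `delta` per MecA molecule.
#'
#' @inheritParams nativeParams
#' @return Named numeric vector with fields `alpha_k, beta_k, k_k, h, alpha_m,
#'   beta_m, k_m, p, delta, lambda_k, lambda_m`.
#' @export
synexParams <- function(..., file = NULL) {
  defaults <- loadParamFile(file %||% system.file("extdata", "params_synex.txt",
                                                  package = "CompetenceCircuits"))
  .applyOverrides(defaults, .synex_fields, list(...))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.applyOverrides <- function(defaults, fields, overrides) {
  if (length(overrides)) {
    bad <- setdiff(names(overrides), fields)
    if (length(bad))
      stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    defaults[names(overrides)] <- vapply(overrides, as.numeric, numeric(1))
  }
  defaults[fields]
}

#' Read a flat key-value parameter file
#'
#' One `key value` pair per line; `#` starts a comment.  Keys must be the field
#' names used by [nativeParams()] / [synexParams()].
#'
#' @param path File path.
#' @return Named numeric vector.
#' @export
loadParamFile <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  toks <- strsplit(lines, "[[:space:]]+")
  keys <- vapply(toks, `[[`, character(1), 1L)
  vals <- suppressWarnings(as.numeric(vapply(toks, `[[`, character(1), 2L)))
  if (any(is.na(vals)))
    stop("non-numeric value for key(s): ", paste(keys[is.na(vals)], collapse = ", "))
  setNames(vals, keys)
}

#' Construct a CircuitSpec
#'
#' @param circuit `"native"` or `"synex"`.
#' @param params Named numeric parameter vector; defaults to the packaged set
#'   for the chosen circuit.
#' @param ... Passed to [nativeParams()] or [synexParams()] when `params` is
#'   not supplied (e.g. `alpha_k = 1.15`).
#' @return A validated [CircuitSpec-class] object.
#' @examples
#' spec <- circuitSpec("native", alpha_k = 1.15)
#' circuitRates(spec, n = 0, m = 0)
#' @export
circuitSpec <- function(circuit = c("native", "synex"), params = NULL, ...) {
  circuit <- match.arg(circuit)
  if (is.null(params))
    params <- if (circuit == "native") nativeParams(...) else synexParams(...)
  species <- if (circuit == "native") c("ComK", "ComS") else c("ComK", "MecA")
  new("CircuitSpec", circuit = circuit, params = params, species = species)
}

#' @describeIn circuitSpec Replace the induction rate, returning a new spec.
#' @param spec A [CircuitSpec-class].
#' @param alpha_k New induction rate (1/hour).
#' @export
setAlphaK <- function(spec, alpha_k) {
  spec@params[["alpha_k"]] <- alpha_k
  validObject(spec)
  spec
}

#' @rdname CircuitSpec-class
#' @param object A `CircuitSpec`.
#' @export
setMethod("show", "CircuitSpec", function(object) {
  cat(sprintf("CircuitSpec: %s circuit (n = %s, m = %s)\n", object@circuit,
              object@species[1], object@species[2]))
  cat("parameters (per hour / molecules):\n")
  print(object@params)
})

#' Accessors for CircuitSpec
#'
#' `circuitKind` returns `"native"` or `"synex"`; `circuitParams` the named
#' parameter vector; `speciesNames` the two species labels.
#'
#' @param spec A [CircuitSpec-class].
#' @return See description.
#' @export
circuitKind <- function(spec) spec@circuit

#' @rdname circuitKind
#' @export
circuitParams <- function(spec) spec@params

#' @rdname circuitKind
#' @export
speciesNames <- function(spec) spec@species

## Internal: the four rate functions as closures over the parameter set.
## Every consumer (master-equation generator, Gillespie propensities, mean-field
## ODEs) evaluates these same closures, so the per-molecule convention for the
## death rates cannot diverge between solvers: r and s are PER-MOLECULE rates,
## and total death propensities are r(n,m)*n and s(n,m)*m.
.rateFunctions <- function(spec) {
  p <- as.list(spec@params)
  g <- function(n) p$alpha_k + p$beta_k * n^p$h / (p$k_k^p$h + n^p$h)
  if (spec@circuit == "native") {
    q <- function(n) p$alpha_s + p$beta_s / (1 + (n / p$k_s)^p$p)
    r <- function(n, m) p$delta_k / (1 + n / p$Gamma_k + m / p$Gamma_s) + p$lambda_k
    s <- function(n, m) p$delta_s / (1 + n / p$Gamma_k + m / p$Gamma_s) + p$lambda_s
  } else {
    q <- function(n) p$alpha_m + p$beta_m * n^p$p / (p$k_m^p$p + n^p$p)
    r <- function(n, m) p$delta * m + p$lambda_k + 0 * n
    s <- function(n, m) p$lambda_m + 0 * n + 0 * m
  }
  list(g = g, q = q, r = r, s = s)
}

#' Evaluate the four reaction rates of a circuit
#'
#' Returns the production propensities `g` (of ComK, depends only on `n`) and
#' `q` (of the partner species, depends only on `n`), and the per-molecule
#' death rates `r` and `s`.  Total death propensities are `r*n` and `s*m`.
#'
#' For the native circuit:
#' \deqn{g = \alpha_k + \beta_k n^h/(k_k^h + n^h), \quad
#'       q = \alpha_s + \beta_s/(1 + (n/k_s)^p),}
#' \deqn{r = \delta_k/(1 + n/\Gamma_k + m/\Gamma_s) + \lambda_k, \quad
#'       s = \delta_s/(1 + n/\Gamma_k + m/\Gamma_s) + \lambda_s.}
#' For the SynEx circuit `g` is as above and
#' \deqn{q = \alpha_m + \beta_m n^p/(k_m^p + n^p), \quad
#'       r = \delta m + \lambda_k, \quad s = \lambda_m.}
#'
#' @param spec A [CircuitSpec-class].
#' @param n,m Nonnegative integer copy numbers (vectors are recycled).
#' @return List with numeric components `g`, `q`, `r`, `s`.
#' @export
circuitRates <- function(spec, n, m) {
  if (any(n < 0) || any(m < 0) || any(n != floor(n)) || any(m != floor(m)))
    stop("n and m must be nonnegative integers")
  fn <- .rateFunctions(spec)
  nm <- cbind(n = as.numeric(n), m = as.numeric(m))  # recycle
  list(g = fn$g(nm[, 1]), q = fn$q(nm[, 1]),
       r = fn$r(nm[, 1], nm[, 2]), s = fn$s(nm[, 1], nm[, 2]))
}

#' Rescale a circuit to higher molecule numbers
#'
#' Multiplies every count-like parameter (production rates, Hill half-points,
#' Michaelis constants) by `omega` while leaving per-molecule rates unchanged;
#' for SynEx the per-molecule enzymatic rate `delta` is divided by `omega` so
#' that the mean-field dynamics of the scaled concentrations are unchanged.
#' Used to probe the high-copy-number regime, where the stochastic model is
#' expected to track the deterministic one.
#'
#' @param spec A [CircuitSpec-class].
#' @param omega Scale factor (> 0).
#' @return A new `CircuitSpec`.
#' @export
scaleCounts <- function(spec, omega) {
  stopifnot(omega > 0)
  p <- spec@params
  count_like <- intersect(c("alpha_k", "beta_k", "k_k", "alpha_s", "beta_s",
                            "k_s", "alpha_m", "beta_m", "k_m",
                            "Gamma_k", "Gamma_s"), names(p))
  p[count_like] <- p[count_like] * omega
  if (spec@circuit == "synex") p[["delta"]] <- p[["delta"]] / omega
  spec@params <- p
  validObject(spec)
  spec
}
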