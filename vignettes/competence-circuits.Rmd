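---
title: "Modelling noise in the B. subtilis competence circuits"
author: "CompetenceCircuits package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling noise in the B. subtilis competence circuits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(CompetenceCircuits)
```

## The biological question

Under stress, *Bacillus subtilis* cells can transiently differentiate into a
*competent* state in which they take up exogenous DNA.  Competence is switched
on by high levels of the master regulator ComK.  In the native circuit ComK
activates its own expression and represses ComS; ComS in turn protects ComK
from degradation by the MecA complex, for which both proteins compete.  In the
synthetic analog circuit (SynEx) the repressive arm is rewired: ComK activates
MecA directly, and MecA degrades ComK enzymatically.  Both architectures are
relaxation oscillators, but they place their molecular noise differently: in
the native circuit the competent state coexists with very low ComS numbers,
while in SynEx the competent state holds both species at high copy number.

This package implements the two-species stochastic model of each circuit, its
deterministic (mean-field) limit, and the population-level statistics that
quantify how molecular noise changes the circuits' response to induction: the
responsive fraction *f*, the viable-response-range expansion factors, spectral
diagnostics of noise-induced oscillations, and a cumulative-distribution fit
that maps fluorescence titration data onto the model's induction-rate axis.

## The stochastic model

The state is the pair of copy numbers (n, m): ComK and its partner species
(ComS for native, MecA for SynEx).  The joint distribution `p_nm(t)` obeys a
birth-death master equation with four reaction channels: production of n at
rate `g(n)`, death of n at per-molecule rate `r(n, m)` (total propensity
`r n`), production of m at `q(n)`, death of m at `s(n, m) m`.  The regulation
functions are

* native: `g = alpha_k + beta_k n^h/(k_k^h + n^h)`,
  `q = alpha_s + beta_s/(1 + (n/k_s)^p)`,
  `r = delta_k/(1 + n/Gamma_k + m/Gamma_s) + lambda_k`,
  `s = delta_s/(1 + n/Gamma_k + m/Gamma_s) + lambda_s`;
* SynEx: `g` as above, `q = alpha_m + beta_m n^p/(k_m^p + n^p)`,
  `r = delta m + lambda_k`, `s = lambda_m`.

The shared Michaelis-Menten denominator in the native death rates encodes the
competition of ComK and ComS for MecA: abundant ComS protects ComK (positive
feedback), while ComK's repression of ComS closes a delayed negative loop.
All solvers — the sparse master-equation generator, the Gillespie simulator
and the mean-field ODEs — evaluate one shared implementation of these four
functions, so the per-molecule convention cannot diverge between them.

Steady states are computed on a truncated (n, m) grid with a reflecting
boundary (births out of the last row/column are dropped), which conserves
probability and keeps the null-space problem well posed.  The normalised null
vector is obtained by a bordered sparse solve: one generator row is replaced
by the normalisation constraint.  The truncation is sized from the mean-field
fixed points (`nMax ~ 4 max(n*, k_k) + 25`,
`mMax ~ max(m*) + 8 sqrt(max(m*)) + 25`) and grown geometrically whenever the
probability in the outermost row/column exceeds `1e-6`, so the initial guess
only affects run time, never correctness.  A square truncation proportional
to the largest fixed-point coordinate would also work but wastes an order of
magnitude of states when the two species occupy very different ranges (rest
ComS sits near 85 molecules while ComK rarely exceeds a few dozen).

Exact trajectories use the Gillespie direct method (two uniform variates per
event) in compiled code, driven by R's RNG so that `set.seed()` governs
reproducibility exactly.  Long-run statistics accumulate time-weighted
occupancy histograms on the fly instead of storing events.

## Parameter values

The packaged parameter files (`inst/extdata/params_*.txt`) are a
*reconstruction*, documented value by value in the files themselves.  The
molecule-number scale is fixed by the high-copy-number variants quoted for
these circuits (`Gamma_k = 25000`, `Gamma_s = 20`; `k_k = 5000`,
`k_m = 2500`, a thousandfold above the low-copy regime), giving
`Gamma_k = 25`, `Gamma_s = 20`, `k_k = 5`, `k_m = 2.5` at working copy
numbers; Hill exponents (`h = 2`, `p = 5`) and the ComS repression half-point
(`k_s = 0.222 Gamma_k`) follow the classical two-component reduction of the
ComK/ComS/MecA module.  The remaining rates were designed once, before any
stochastic quantity was computed, to reproduce the published deterministic
anatomy of the circuits: regime boundaries near
`alpha_k^(1) ~ 0.64 /h`, `alpha_k^(2) ~ 1.86 /h` (native) and
`0.54 /h`, `10.9 /h` (SynEx); an excitable rest state with ComK below one
molecule; a competent state at tens of ComK molecules with ComS nearly absent
(native) or MecA abundant (SynEx).  Two deliberate departures from a naive
transcription were necessary for that anatomy: the ComK activation half-point
of the native circuit sits at `k_k = 8` so that the intermediate fixed point
lies on the rising flank of the Hill function (otherwise no oscillatory
window exists), and ComS turns over more slowly than ComK
(`delta_s = delta_k/5`) so that the negative-feedback arm lags enough to
destabilise the spiral point.

Because the exact original rate values are not public, quantities that depend
on the *noise magnitude* at the rest state — most visibly the low-induction
expansion factor — should be read as properties of this reconstructed set
rather than of the original one.  The deterministic regime structure, the
qualitative noise effects, and the architecture contrast between the two
circuits are robust to this caveat; the package's tests quantify each of
these.

## Deterministic analysis

The mean-field limit replaces copy numbers by their means:
`dn/dt = g(n) - r(n, m) n`, `dm/dt = q(n) - s(n, m) m`.  Fixed points are
found by scanning the ComK residual along the partner species' nullcline
(available in closed form: a quadratic for the native circuit, explicit for
SynEx) and polishing each sign change with `uniroot`; each root is classified
by the eigenvalues of the analytic Jacobian.  Three regimes appear as the
induction rate `alpha_k` grows: *excitable* (three fixed points, one stable;
perturbations trigger a single large ComK excursion), *oscillatory* (a single
unstable spiral; a limit cycle), and *mono-stable* (a single stable point:
permanent competence).  The two boundaries are located by bisection in log
`alpha_k` — on the fixed-point count for the saddle-node at `alpha_k^(1)`,
and on the sign of the largest eigenvalue real part for the Hopf-type
transition at `alpha_k^(2)` — to relative tolerance `1e-4` by default; each
boundary is reported as the midpoint of the final bracket, which also
resolves eigenvalues straddling zero without an arbitrary sign call.

```{r}
spec <- circuitSpec("native")
regimeBoundaries(spec)
classifyRegime(spec, alpha_k = 1.15)$regime
```

## The responsive fraction f

`f` is the probability mass of the steady-state ComK marginal
`p_n = sum_m p_nm` in the high-expression mode — equivalently the fraction of
an isogenic population found competent at any instant.  Two estimators are
implemented.

The **inflection-point method** locates the two curvature sign changes of the
(lightly smoothed) marginal that flank the putative inter-mode minimum, and
splits at their midpoint `n*`; `f` is the tail mass from `n*` upward.  The
curvature signature exists even when the high mode is only a shoulder, which
is the common case in the excitable regime.  When the low mode sits at
`n = 0` its concave flank is unobservable and the left inflection is taken at
0.  For unimodal distributions `f` is 0 or 1 according to whether the mode
lies below or above an anchor count (the geometric mean of the deterministic
low- and high-branch ComK levels, floored at one molecule).  Smoothing (a
3-point binomial kernel) is applied only if the raw second differences show
more than four sign changes, since discrete-grid noise produces spurious
inflections.

The **two-Poisson method** fits `w Pois(mu1) + (1-w) Pois(mu2)` by minimising
the Kullback-Leibler divergence from the marginal, with `mu1 < mu2` enforced
by parameterisation and nine moment-based multi-starts; `f = 1 - w`.  It is
smoother in `alpha_k` but cannot represent `f = 1`: a balanced mixture of two
similar means always beats a single Poisson, so at high induction the fit
degenerates (flagged when `|mu2 - mu1| < 2 sqrt(mu2)`).

The `f(alpha_k)` curve therefore concatenates the methods: inflection below
`alpha_k^(1)`, two-Poisson in between, and inflection again from the `f = 1`
onset — defined as the first grid point where the inflection method reports
`f >= 0.99` *and* the mixture fit has degenerated — with a 3-point moving
average applied at the joins.  The viable range is where `0 < f < 1`.  Its
expansion beyond the deterministic window is quantified by
`low = alpha_k^(1)/alpha_min` with `alpha_min` the (log-interpolated) first
crossing of `f = epsilon = 1e-2`, `high = alpha_max/alpha_k^(2)` with
`alpha_max` the `f = 1` onset, and their product.  The default grid is
log-spaced at 12 points per decade from `alpha_k^(1)/40` to
`30 alpha_k^(2)`; halving epsilon or the grid spacing moves the factors by a
few percent only.

```{r}
b <- regimeBoundaries(spec)
curve <- fractionCurve(spec, alphaGridLog(b$alpha_k_1 / 40,
                                          b$alpha_k_2 * 30), bounds = b)
expansionReport(curve, b)
```

With the packaged parameters the native circuit's total expansion factor is
about three times the SynEx circuit's — the architecture contrast carried by
the high-induction side, where the native circuit's low-copy ComS keeps
injecting noise while SynEx's abundant MecA averages it away.

## Noise-induced oscillations and spectra

Outside the deterministic oscillatory window the stochastic dynamics can stay
oscillatory: repeated noise-triggered excitations below `alpha_k^(1)`, and
noise-prevented damping above `alpha_k^(2)`.  The diagnostic is the power
spectrum of the ComK series: segment-averaged periodograms (mean removed per
segment; one-sided power normalised so it sums to the series variance), with
a Gaussian-bump-plus-floor fit.  A spectrum counts as peaked when the fitted
bump height exceeds three times the floor at a center beyond two frequency
bins — a quantitative stand-in for a judgement the eye makes easily.  With
the packaged parameters the persistence of peaked spectra beyond the Hopf
boundary extends to about 1.5x `alpha_k^(2)` but has faded by 15x, where the
fixed point has become a heavily damped node; how far persistence reaches is
exactly the kind of quantity that is sensitive to the reconstructed rates.

## Fitting fluorescence titrations

To compare the model to fluorescence snapshots at increasing inducer
concentrations, each condition's intensity distribution is mapped to an
induction rate.  The background is estimated as the histogram mode of the
zero-inducer condition (Freedman-Diaconis bins, parabolic refinement) and
subtracted everywhere, with negatives clipped.  The fit is maximally
constrained: every circuit parameter is fixed except one `alpha_k` per
condition and a single global intensity-per-molecule factor X.  For each
candidate X, each condition's objective `S(alpha)` is the mean squared
difference between the empirical CDF and the model CDF of `X n`; X is chosen
by an outer log-grid search with golden-section refinement on the summed
minima, and per-condition error bars are read off where `S` crosses
`1.25 S_min` (linear interpolation, parabolic refinement of the minimum).

The CDF comparison is evaluated, by default, at the midpoints `X (n + 1/2)`
of the model's intensity lattice across the sample range.  The model CDF is
exact at those points, and — crucially — a zero-molecule atom smeared by
sub-molecule camera noise is counted in full, so the objective stays unbiased
for background widths below X/2.  Evaluating at the nine empirical deciles
(available as `evalPoints = "deciles"`) is attractive for being fully
sample-driven, but with any continuous background noise the low-condition
deciles land inside the first lattice bin where a step CDF cannot match, and
the fitted induction rates inflate severalfold; the lattice convention fixes
this while remaining free of density binning.

On synthetic titrations the conversion factor X is recovered to a few
percent and the fitted `alpha_k` reproduce the ordering and magnitude of the
truth.  The `1.25 S_min` bars themselves under-cover on synthetic data: the
model matches the generator almost perfectly, so `S_min` is dominated by
sampling noise and the bars are a few percent wide, while the estimate's
seed-to-seed scatter (which includes the coupling to the fitted X that the
per-condition profile ignores) is two to three times larger.  On real pixel
data the model-misfit floor in `S_min` widens the bars substantially; that
floor is absent here by construction.

## The synthetic-data generator

`generateTitration()` draws per-cell ComK counts from the model's steady-state
marginal at each condition's ground-truth `alpha_k`, scales them by a known
`XTrue`, and adds a nonnegative right-skewed background (shifted gamma, shape
4, mode `backgroundMode`, scale `backgroundSpread`) — the shape of a typical
camera/autofluorescence background.  The zero-labelled condition carries the
lowest induction rate so that its intensity mode estimates the background,
exactly as the fitting stage assumes.  Generation is per cell; real pixel
histograms additionally carry within-cell correlations between neighbouring
pixels that neither the model nor the generator describes, so passing
recovery tests here demonstrates the fitting machinery, not the imaging
model.  Defaults: four conditions labelled like an IPTG series (0, 0.75,
1.5, 3 uM), at least a few thousand cells per condition, background spread
well below one molecule of intensity.

## Problem sizes and numerical settings

The shipped tests and the acceptance script run at the following sizes,
chosen to keep every quantity's estimator error well inside its assertion
tolerance: master-equation truncations of roughly 60-250 ComK states by
120-250 partner states (boundary mass below `1e-6` enforced adaptively);
f curves at 12 grid points per decade; Gillespie statistics over `1e5` hours
(about `1e7` events) for distribution comparisons and 4000 hours for
spectra; ensembles of 200 paths at a hundredfold copy-number scaling for the
mean-field comparison; ten seeds of four-condition titrations with 4000
cells each for recovery statistics.

## Known limitations

* The parameter files are a documented reconstruction (see above); rest-state
  noise levels, and with them the low-induction expansion factor and the
  reach of noise-prevented damping, are the quantities most affected.
* Only the adiabatic two-species models are implemented; explicit mRNA or
  enzymatic-complex dynamics and three-species variants are out of scope.
* The master-equation path computes steady states only; time-dependent
  distribution propagation is not implemented (trajectory statistics come
  from the Gillespie side).
* The titration fit assumes a single global X and background; spectral
  bleed-through, segmentation artefacts and pixel-level correlation are not
  modelled.
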