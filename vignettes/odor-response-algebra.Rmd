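---
title: "Modelling OSN responses to odor mixtures: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling OSN responses to odor mixtures: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odormix)
```

## The model

Olfactory sensory neurons (OSNs) respond to odorant concentration with, in
most recorded cases, a sigmoidal dose-response curve. `odormix` models the
response of one OSN type to a single odorant $U$ at concentration $X$ as

$$F(X; n, \eta, s) \;=\; \frac{F_{\max}}{1 + \left(\dfrac{1 + sX}{\eta\, s X}\right)^{n}},
\qquad s = 1/K,$$

with three odor-specific parameters:

* $n$ — the Hill coefficient. Crucially it is treated as a property of the
  *odor-receptor pair*, not of the neuron: the same OSN can respond to two
  structurally similar odorants with very different steepness. This is what
  distinguishes the model from its predecessors and what lets mixtures
  produce synergy and inhibition (see below).
* $\eta$ — the efficacy. All odors share one physiological ceiling
  $F_{\max}$ (default 1, i.e. normalized responses), and $\eta$ sets the
  per-odor asymptote $F_{\max}\,\eta^n/(1+\eta^n) < F_{\max}$.
* $K$ — the concentration scale ($s = 1/K$ its inverse). For this family
  $K$ is only approximately the half-maximum point; the exact midpoint is
  available in closed form through `curve_summary()`.

The functional form is the classical two-state receptor-activation sigmoid;
the package treats it as an empirical description, not as derived from a
kinetic scheme.

The response to a mixture of $N$ odorants at concentrations $c_i$ is built
from three aggregates of the dimensionless inputs $z_i = s_i c_i$:

$$S = \sum_i z_i, \quad H = \sum_i \eta_i z_i, \quad N^\* = \sum_i n_i \eta_i z_i,
\qquad F_{\text{mix}} = \frac{F_{\max}}{1 + \left(\frac{1+S}{H}\right)^{N^\*/H}}.$$

This is the unique formulation within the family that simultaneously

1. satisfies the self-mixture consistency $F_{U+U}(c, c) = F_U(2c)$ (a
   mixture of an odor with itself is just more of that odor),
2. reduces to the earlier shared-coefficient efficacy model when all $n_i$
   coincide, and
3. becomes *linear* under the embedding described below, which is what
   gives the odor response space its vector-space structure.

Both legacy baselines are implemented in `legacy_response()`: the
competitive syntopic form with per-odor asymptotes $F_{M_i}$, and the
shared-ceiling efficacy form. For both, the mixture asymptote along any
fixed-ratio ray is a weighted mean of the component asymptotes, so neither
can exhibit synergy or inhibition near the maximal response — the package's
property tests assert this over random parameter draws, and assert that the
odor-specific-$n$ model *does* exhibit both for the corresponding
demonstration parameter sets.

### Fixed-ratio mixtures

Holding the components at a fixed concentration ratio ($U = rV$) collapses
the mixture to another member of the same sigmoid family
(`effective_fixed_ratio()`), with

$$s_{\mathrm{eff}} = r s_U + s_V, \qquad
\eta_{\mathrm{eff}} = \frac{r \eta_U s_U + \eta_V s_V}{s_{\mathrm{eff}}}, \qquad
n_{\mathrm{eff}} = \frac{r n_U \eta_U s_U + n_V \eta_V s_V}{r \eta_U s_U + \eta_V s_V}.$$

The effective curve agrees with direct mixture evaluation along its ray to
relative $10^{-9}$ on a 200-point log grid (tested); all quantities are
closed-form, so this tolerance is purely a floating-point allowance.

## Behavior classification

A mixture curve is compared with its two component curves and labelled with
one of five empirical behaviors: *suppression* (between the components),
*hypoadditivity* (similar to the more effective component), *synergy*
(above both), *inhibition* (below both), *overshadowing* (similar to one
component). Design choices, all configurable:

* **Comparison axis.** Single-odor curves are evaluated on the common
  concentration axis; the mixture is parameterized by total concentration,
  with components $r/(1+r)$ and $1/(1+r)$ of the total. Output tables state
  the convention.
* **Similarity band.** "Similar" means within 5% of $F_{\max}$
  (`tol = 0.05`). Equality-type labels take precedence over the strict
  inequalities, otherwise every near-tie would oscillate between synergy
  and suppression.
* **Hypoadditivity vs overshadowing.** The two prose definitions overlap:
  similarity to the *most effective* component is a special case of
  similarity to *one* component. The classifier returns the refined label —
  hypoadditivity when the matched component dominates the other everywhere
  on the analysed grid, overshadowing otherwise — and downstream checks
  treat hypoadditivity as implying overshadowing. This resolves the
  composite labels ("overshadowing/hypoadditivity") that arise when a
  mixture tracks a component which is dominant at saturation but not at low
  concentration.
* **Asymptotic region.** "Close to the asymptote" is taken as the
  concentrations where all three curves exceed 95% of their own analytic
  asymptotes; if the grid does not reach that region the top grid point is
  used.
* **Default grid.** 200 log-spaced points spanning 1.5 decades beyond the
  smallest and largest of the three midpoints — wide enough to contain
  every behavior transition exhibited by the demonstration sets.
* **Phase maps.** `phase_map()` classifies each cell from the analytic
  asymptotes with *tolerance zero* by default. A published-style efficacy
  sweep uses only three colors (suppression, synergy, inhibition), which
  implies strict ordering; with the 5% band the narrow synergy sliver near
  $\eta_V \approx 1$ would be absorbed into the similarity classes. The
  efficacy sweep in the tests runs $\eta_U, \eta_V \in [0.1, 2]$ in steps
  of 0.1 around the fixed set $n_U = 1$, $n_V = 12$, $K_U = 0.5\times
  10^{-4}$, $K_V = 10^{-3}$, $r = 1$; suppression is the modal label with
  synergy and inhibition as minority fractions.

### Synergy feasibility bound

Under the same-dilution paradigm the mixture cannot exceed both components
at axis concentrations below the *midpoint* (half-asymptote concentration,
not $K$) of the component with the lower Hill coefficient. The distinction
matters: with "midpoint" read as $K$ the bound admits rare counterexamples
in random sampling, while with the true half-asymptote midpoint no
violation was found in 8000 random draws. `synergy_feasible()` implements
the bound analytically and the property tests check it against brute-force
classification.

## Experimental-protocol adapters

Two measurement protocols are supported for predicting a mixture from
single-odor parameters alone (no mixture data enter the prediction):

* `predict_same_dilution()` — both odorants delivered at a shared dilution
  $d$ of their saturated vapor, so $c_U = d \cdot \mathrm{svp}_U$,
  $c_V = d \cdot \mathrm{svp}_V$: a fixed-ratio mixture with
  $r = \mathrm{svp}_U/\mathrm{svp}_V$.
* `predict_fixed_background()` — one odorant swept with the second held at
  a fixed background concentration.

When the delivered mixture concentration may differ from the nominal one
(vapor-phase calculation error), `apply_log_shift()` displaces a curve
along $\log_{10}$ concentration, and `fit_shift()` estimates the
displacement that best aligns a prediction with observed mixture points.

## The odor response space

A response is identified by the triple $(n, \eta, s)$. Two operations give
the set its structure: scaling $\alpha \otimes (n, \eta, s) = (n, \eta,
\alpha s)$, the same odor at $\alpha$-fold concentration, and composition
$(n,\eta,s) \bullet (n',\eta',s')$, the equal-concentration binary mixture.
The embedding

$$(n, \eta, s) \;\mapsto\; (n\eta s, \;\eta s,\; s)$$

is a bijection onto the positive octant under which scaling is scalar
multiplication and composition is vector addition — so the space is exactly
three-dimensional, and familiar linear algebra applies:

* three responses form a **basis** iff the determinant of their embedded
  images is nonzero (`is_valid_basis()`, with a scale-relative tolerance of
  $10^{-12}$ against near-degenerate vertex choices);
* a target is **decomposed** over a basis by Cramer's rule
  (`decompose_odor()`); only positive coefficients are physically
  realizable, since coefficients are (scaled) concentrations. Coefficients
  within $-10^{-12}$ (relative) of zero are clamped to zero and flagged
  `on_boundary`; genuinely negative ones raise a not-representable error;
* representability depends only on $(n, \eta)$ — scaling the target's $s$
  scales all coefficients by the same positive factor — and corresponds to
  membership of $(n\eta, \eta)$ in the convex hull of the basis images
  under $(n,\eta) \mapsto (n\eta, \eta)$ (`hull_coverage()`). Shared-`s`
  reasoning defaults to $s = 10^6$.

### Canonical corner bases

Experimentally observed responses occupy a bounded rectangle in the
$(n, \eta)$ plane (the package default spans $n \in [0.5, 20]$,
$\eta \in [0.3, 16]$, covering the printed parameter sets). The rectangle's
image under $(n,\eta) \mapsto (n\eta, \eta)$ is a convex quadrilateral
whose vertices are the four corner responses. Any triple of corners is a
valid basis (nonzero determinant), but no single triple covers the whole
rectangle; a diagonal split yields two bases whose coverage regions are the
two triangles and whose union is the full quadrilateral.
`canonical_bases()` returns the split along the
$(n_{\min},\eta_{\min})$–$(n_{\max},\eta_{\max})$ diagonal:

$$E_1 = \{(n_{\min},\eta_{\min}), (n_{\max},\eta_{\min}), (n_{\max},\eta_{\max})\}, \quad
E_2 = \{(n_{\min},\eta_{\min}), (n_{\min},\eta_{\max}), (n_{\max},\eta_{\max})\}.$$

The choice of diagonal is a genuine design freedom (the other diagonal
works equally); this one keeps the shared low-$n$, low-$\eta$ corner — the
weakest, flattest response — in both bases. Tests verify on a 50×50 grid
that the union of the two coverage regions contains the whole rectangle
while each basis alone leaves points uncovered.

### Target synthesis

`synthesize_target()` addresses the design question: given the response
triples a set of available odorants elicits in each OSN type, find one
vector of positive mixture coefficients reproducing a target triple in
*every* OSN type simultaneously. Stacking the embedded images gives a
linear system (3 equations per OSN type) solved by least squares, then
checked for coefficient positivity and per-OSN relative residual (default
$10^{-8}$); infeasibility reports the offending OSN.

## Fitting and metrics

`fit_single_odor()` estimates $(n, \eta, K)$ by plain (unweighted)
nonlinear least squares with $F_{\max}$ held fixed — the ceiling is a
shared physiological constant, not a per-curve parameter, and whether the
original analyses weighted points is unstated, so unweighted is the
default. The objective is multimodal in $n$, hence a multistart: 20 starts
drawn deterministically (seeded jitter) from a coarse log-grid over the
bounds $n \in [0.1, 30]$, $\eta \in [10^{-3}, 10^3]$,
$K \in [\min c / 100, \max c \times 100]$, each refined with bounded
Levenberg-Marquardt; the best converged solution is kept. Goodness of fit
is reported as MSE and MAPE (in percent; zero-response observations are
excluded from MAPE with a warning and kept in MSE).

Closed-loop behavior, verified in the tests: noiseless 12-point data
recover the generating parameters to $10^{-6}$ relative; with 5%
multiplicative noise on a 12-point, 3-decade design the median relative
parameter error over 100 seeds is below 10%. $K$ is the weakly identified
parameter in this family ($\eta$ moves the midpoint too), so per-seed
worst-parameter errors run higher; the optimizer itself is exact in the
sense that it never returns a worse sum of squares than the generating
parameters.

## Synthetic data

`generate_curve()` produces the fixtures every test is built from: model
responses on a log-spaced grid (default 12 points over 4 decades centered
on $K$, resembling typical published sampling density) with multiplicative
Gaussian noise of configurable coefficient of variation (default
conditions use 5%), truncated to $[0, F_{\max}]$, bit-reproducible under a
fixed seed. Multiplicative noise reflects that firing-rate variability
scales with response magnitude; no noise model is prescribed by the source
analyses, so this is the package's choice.

What the generator deliberately does **not** emulate: temporal/sniff-cycle
dynamics, adaptation, trial-to-trial baseline drift, heteroscedasticity
beyond the multiplicative form, and censoring at the recording floor.
Passing closed-loop tests therefore demonstrate correctness of the
estimation machinery under the stated noise model, not robustness to every
feature of real recordings.

`builtin_parameter_sets()` carries the printed demonstration sets: six
behavior examples (default mixing ratio $r = 0.2$ where none is stated),
the control set for sensitivity sweeps, and the fixed parameters of the
efficacy sweep.

## Numerical choices

* All sigmoid evaluations run in log space
  (`exp(n * (log1p(z) - log(eta) - log(z)))`), so Hill coefficients of 20
  and dimensionless inputs spanning 12 decades neither overflow nor lose
  the asymptote; the legacy competitive form rescales by the largest
  exponent for the same reason. Zero concentration returns exactly zero by
  continuity, including $n < 1$ where the naive power is singular.
* Dense-grid agreement assertions on noiseless curves use relative
  $10^{-9}$; everything compared is closed-form, so this is a pure
  floating-point allowance.
* The decomposition positivity tolerance ($-10^{-12}$, relative to the
  largest coefficient) exists for targets on the hull boundary, e.g. a
  basis vertex itself.
* Problem sizes in the test suite — 200 to 1000 random draws per property,
  100 fitting seeds, 50×50 coverage grids, 20×20 phase maps — were chosen
  as the smallest sizes that still exercise every code path and keep the
  full suite under a minute on a laptop-class machine.

## Known limitations

* The model is empirical: no biophysical kinetic scheme is claimed to
  generate it, and none is fitted.
* Only responses that are sigmoidal in concentration are representable;
  non-monotone (e.g. biphasic) dose-response curves fall outside the
  family.
* Temporal response features are out of scope; the model describes peak
  activity as a function of concentration.
* Behavior classification applies to model curves and fitted curves, not
  directly to noisy point sets; fit first, then classify.
* The decomposition coefficients are algebraic statements about response
  triples; no claim about perceptual equivalence of the corresponding
  mixtures is made.
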