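---
title: "Quantifying the segmental distribution of lumbar lordosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the segmental distribution of lumbar lordosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lordist)
```

## The measurement model

`lordist` quantifies how lumbar lordosis is distributed along the spine,
starting from manually digitized vertebral corner landmarks on a midsagittal
MRI. The data model is deliberately minimal: per reading, the four corners of
T12 and of each lumbar vertebra L1–L5 plus the two superior corners of S1
(26 points), in pixel coordinates. No pixels are processed; landmark picking
happens upstream in whatever viewer the operator uses. Because image viewers
draw y downward while the geometry below assumes y upward, readers normalize
orientation on input (`y_axis = "image_down"` is the default).

Each vertebral centroid is the arithmetic mean of its four corners, and the
sacral point is the midpoint of S1's superior corners, giving seven points
P₀…P₆. A *rigid* similarity transform — translation, rotation, and if needed
a reflection, but never a scaling — places P₀ (T12) at the origin and P₆
(sacrum) on the positive x-axis with the lumbar centroids above the axis. We
deliberately exclude scaling: every parameter below is an angle or a
percentage and therefore scale-free, and keeping the pixel scale intact means
that landmark-level measurement-error statistics (repeatability in pixels)
stay interpretable. If the aligned centroids are not strictly increasing in
x, the reading is rejected as outside the model's domain (such a spine cannot
be the graph of a function of x).

The lordosis curve is the unique interpolating polynomial of degree ≤ 6
through the seven aligned points. Two representations are kept:

* **barycentric** form for evaluation — numerically stable and exact at the
  nodes by construction;
* **monomial** coefficients on the rescaled abscissa u = (x − x₀)/(x₆ − x₀)
  for calculus. Seven nodes on [0, 1] give a Vandermonde system that is well
  conditioned enough for this conversion, and exact differentiation and
  integration of the monomial form beat numerical quadrature both in speed
  and accuracy.

## Parameters

With S = (x_S, y_S) the global maximum of p on [x₀, x₆]:

| parameter | definition | units | interpretation |
|---|---|---|---|
| Cobb angle | angle between L1 superior and L5 inferior endplate lines | degrees | overall lordosis magnitude |
| Rho angle ρ | atan(y_S / x_S) | degrees | maximum deflection from the T12–sacrum axis |
| digression K% | 100 · x_S / x₆ | percent | where along the span the lordosis peaks |
| expansion A₁…A₆ | 100 · Tᵢ / T, Tᵢ = ∫ p dx between adjacent centroids | percent | per-segment share of the total lordosis area |

The apex is found from the real roots of p′ (degree ≤ 5) inside the open
span, computed via `polyroot()` (a companion-matrix method) and polished with
two Newton steps, compared against both endpoints. Numerical conventions,
chosen where the method definition is silent:

* roots with |imaginary part| < 10⁻⁹ are treated as real;
* if two candidate maxima tie, the smallest abscissa wins (the method
  presumes a unique interior maximum; ties essentially only arise in
  synthetic edge cases);
* an argmax at an endpoint is *flagged* (`degenerate_apex`) rather than
  raised, so cohort pipelines can log and skip such readings — ρ and K% are
  not meaningful for a curve that never turns;
* segment areas are kept *signed*. A curve dipping below the axis between
  two centroids produces a negative share with a warning, and in exchange
  ΣAᵢ = 100 holds exactly for every valid curve — conservation is the
  invariant the rest of the package leans on.

The Cobb angle uses the lines through the marked corner pairs directly (no
re-fitting) and is reported as the acute, unsigned intersection angle in
[0, 90]°, matching the magnitude-only convention of clinical tables; a signed
variant (oriented difference of endplate inclinations) is available behind
the `signed` flag for users who need a lordosis/kyphosis sign.

All five parameter families are invariant to rotation, translation, uniform
scaling and reflection of the input landmarks; the test suite asserts this to
10⁻⁹.

## Reliability statistics

Landmark-based methods stand or fall on observer reliability, so the package
implements the standard battery:

* **ICC(2,1)** — two-way random-effects ANOVA (subjects and raters random),
  single measurement, absolute agreement:
  ICC = (MSR − MSE) / (MSR + (k−1)MSE + k(MSC − MSE)/n). Confidence
  intervals use the F-based construction with Satterthwaite degrees of
  freedom. ICCs are computed *per landmark coordinate* (each vertebra ×
  corner × axis is one measured quantity), since pooling heterogeneous
  coordinates into one grid would mix scales; a cross-coordinate summary
  (mean, min) is emitted alongside. Bands follow Winer (≥ 0.90 excellent).
* **Repeatability** — 2.77 × s_w, where s_w² is the one-way ANOVA
  within-subject mean square; the 95% bound on the absolute difference
  between two repeat measurements. Reported in pixels.
* **Interobserver consistency** — Pearson r between the two observers'
  session-averaged values, per coordinate, with Evans bands.
* **Paired ordinal gradings** (5-level Pfirrmann disc-degeneration scores) —
  agreement percentage, Cohen's κ = (P₀ − Pₑ)/(1 − Pₑ) with the simple
  asymptotic SE √(P₀(1−P₀)/(n(1−Pₑ)²)) and a normal-approximation CI
  (multiplier 1.96 at the default 95% level), and weighted kappa.

Two deliberate choices in the kappa module: the **default weighting is
linear** (w = 1 − |i−j|/(k−1)); quadratic weights (1 − (i−j)²/(k−1)²) are
available but produce systematically higher values on the same table —
on the bundled reference cross-tabulation the linear scheme gives 0.896
where the quadratic gives ≈ 0.944 — so the scheme must always be stated when
reporting. The **simple asymptotic SE** is the default because it is the
form used in the clinical literature this method comes from; the
Fleiss–Cohen–Everitt large-sample variance is available via `se = "fleiss"`.

Correlation analysis (`correlation_matrix()`, `cmd_correlate()`) defaults to
Spearman — most of the morphological parameters are not normally
distributed — reports the lower triangle with two-sided p values, and flags
significance at α = 0.05. Constant columns yield NA correlations, reported
rather than raised. For parameter-versus-grade runs, an observer-1-only mode
restricts both tables to the first observer, the usual convention when one
observer is the more experienced reader.

## The synthetic cohort generator

Every statistical claim in the package is exercised on synthetic cohorts
with analytic ground truth, so the generator is first-class, tested code.

**Midline family.** The generated midline must (a) lie in the method's own
model class (degree ≤ 6), (b) vanish at both ends, (c) be positive between
them, and (d) have its unique interior maximum at an *exactly* prescribed
apex fraction f, so that recovery tests can assert K% = 100f to 10⁻⁶ rather
than "approximately". A beta-like family x^a(L−x)^b resampled through the
interpolant meets (a)–(c) but shifts the apex for non-integer exponents, so
we instead construct the derivative directly: p′(x) ∝ (x_S − x)(x² + q) with
q > 0 chosen so that p(L) = 0. This integrates to a quartic that is positive
on (0, L), increases up to x_S = fL and decreases after it — properties
(a)–(d) all hold by construction, for f ∈ (0.25, 0.75) (f = 0.5 is the
parabola limit and is handled as such). The lumbar apex fraction in practice
sits near 0.6, well inside this range.

**Geometry.** Vertebral centers sit at slightly *unequal* span fractions
(cumulative 0.150, 0.158, 0.165, 0.170, 0.175, 0.182 — roughly proportional
to lumbar body heights), so no test can silently rely on uniform node
spacing. Each body is a rectangle centered on the midline, its corners offset
by half the body depth along the local tangent and half the body height
along the normal; the corner centroid therefore inverts the construction
exactly, and the full generator → pipeline loop is an identity on noiseless
data (asserted to 10⁻⁶). Each subject's frame is randomly rotated and
translated so that generated files exercise the alignment step.

**Default study conditions.** Cohorts default to 60 subjects read by 2
observers in 2 sessions; apex fraction ~ N(0.6268, 0.0436) and Rho angle ~
N(7.80°, 2.97°), the published clinical cohort means and SDs for these
parameters; T12–sacrum span ~ N(352, 25) px, a typical midsagittal lumbar
field of view at 0.5 mm/px; landmark jitter SD 0.5 px, a sub-millimetre
manual-picking error, with an optional constant per-observer bias. Paired
gradings use latent marginals (0.02, 0.31, 0.32, 0.245, 0.105) — the averaged
observer marginals of the bundled reference table — and an adjacent-misread
probability of 0.06 per observer, which analytically yields ≈ 89% expected
agreement (`analytic_agreement()` gives the closed form). A Gaussian-copula
generator produces grades with a prescribed Spearman correlation against any
continuous covariate (latent correlation 2 sin(πρ/6); 5-level discretization
attenuates the realized value slightly, which is why recovery tests use a
±0.1 band at n = 500). One global seed fans out to named substreams (spine,
observer, grades) so each stage is independently reproducible.

**What the generator does *not* emulate** — and hence what passing tests do
not show about real data: true vertebral shape variation (bodies are
rectangles), anatomically structured observer error (jitter is isotropic
Gaussian, real picking errors correlate with edge contrast), pathological
morphology outside the unimodal model class (severe deformity, transitional
vertebrae), and any image-level effect. Reliability figures from synthetic
cohorts validate the *statistical machinery*, not the clinical difficulty of
landmark picking.

## Problem sizes and numerical tolerances

The default test and acceptance runs use 60-subject cohorts (2 × 2 readings,
52 coordinates), 300-disc grading simulations with 200 replicates for the
Monte-Carlo band, 10⁶-point grid searches as the apex oracle, and n = 500
copula cohorts for correlation recovery — sizes chosen to keep every
sampling error an order of magnitude below the tolerance it is checked
against while the full suite runs in well under a minute per file.
Interpolation identities and invariances are asserted at 10⁻⁹, exact
integrals against adaptive quadrature at 10⁻⁸ relative, apex location
against the grid oracle at 2·10⁻⁶ of the span, and the ICC against an
independently coded `aov()` mean-squares oracle at 10⁻¹⁰.

## Known limitations

* The degree-6 interpolant can oscillate (Runge phenomenon) for extreme
  landmark configurations; the package flags rather than repairs such
  curves (negative-share warning, degenerate-apex flag). Spline or arc
  alternatives are out of scope.
* K% and ρ are undefined for curves whose maximum sits at an endpoint;
  such readings are flagged and should be excluded from cohort statistics.
* Averaging of repeated readings is done at the landmark-coordinate level
  before parameter computation (the stabler policy); averaging computed
  parameters instead is possible by summarizing `compute_lordosis()` output,
  and the two differ slightly for nonlinear parameters. Both policies are
  exposed; neither is asserted as canonical.
* Supine MRI geometry differs from standing radiographs; parameters from the
  two should not be mixed.
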