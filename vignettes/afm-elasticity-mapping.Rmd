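---
title: "AFM elasticity mapping: models, pipeline and synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{AFM elasticity mapping: models, pipeline and synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(forcemap)
```

forcemap turns raw AFM force-distance records acquired with large spherical
probes on soft tissue into spatial elasticity maps and the summary
statistics built on them: per-compartment medians, the gray-to-white
stiffness ratio, postmortem time courses and temperature regressions. This
vignette is the package's own account of the models it fits, the numerical
choices it makes, and what its synthetic-data tests do and do not
demonstrate.

## The contact models

A rigid sphere of radius $R$ pressed a depth $\delta$ into an elastic
half-space exerts, in the Hertz (paraboloid) approximation,

$$F = \tfrac{4}{3} K \sqrt{R}\, \delta^{3/2},$$

where $K = E/(1-\nu^2)$ is the reduced apparent elastic modulus. Reporting
$K$ rather than the Young's modulus $E$ avoids committing to a Poisson's
ratio for tissue, where $\nu$ is not well constrained; the package never
computes $E$ or $\nu$.

The paraboloid approximation degrades as $\delta/R$ grows. The exact
rigid-sphere solution parametrises contact by the contact radius $a$:

$$\delta = \frac{a}{2}\ln\frac{R+a}{R-a}, \qquad
  F = K\left[\frac{a^2+R^2}{2}\ln\frac{R+a}{R-a} - aR\right].$$

`sneddon_contact_radius()` inverts the first relation by bracketed root
finding on $a \in [0, (1-10^{-9})R]$; the guard keeps the bracket clear of
the logarithmic singularity at $a = R$, and the left-hand side is strictly
increasing so the root is unique and bisection-safe. Depths at or beyond
$R$ are rejected as a domain error rather than extrapolated — deep
indentations of real tissue with this probe stay below $R$, and the
half-space model has no meaning past it. The two models agree to well
under 2% for $\delta/R \lesssim 0.05$ and drift apart beyond
$\delta/R \approx 1/3$; the conventional rule of thumb is that Hertz is
adequate below $1/3$, and every fit records `delta_max_over_R` and a
`hertz_regime` flag so the caller can judge. The package never switches
models silently; requesting Hertz outside its regime warns.

Both models are linear in $K$, so `fit_modulus()` solves the
one-parameter least squares in closed form,
$K = \sum F g(\delta) / \sum g(\delta)^2$, with $g$ the model's depth
shape. For Sneddon fits $g$ is evaluated through a dense monotone-spline
interpolant (512 exact solver nodes, square-root node spacing to resolve
the shallow-contact curvature), avoiding one root solve per sample; the
interpolation error is orders of magnitude below measurement noise.

Adhesion is deliberately absent from both forward models and from the
simulator: the analysis fits purely repulsive elastic contact, and retract
segments never enter any fit.

## From raw record to fitted curve

Units are SI (m, N, Pa) everywhere inside the package; the curve-file
dialect carries instrument-convention headers (nN, um) that are converted
exactly once, on read and write. Silent unit mixing is the dominant bug
class in this kind of pipeline, which is why the boundary is explicit.

The per-curve pipeline (`process_curve()`) is:

1. **Calibration** — force is deflection times the cantilever spring
   constant, $F = k_c d$ (`calibrate()`).
2. **Baseline** — a least-squares line (offset + tilt) over the early
   extend segment, first pass over the first 30% of the full z span, then
   refitted over the first half of the actual pre-contact span once a
   provisional contact point is known, so near-contact curvature never
   contaminates the baseline (`fit_baseline()`).
3. **Contact point** — grid search over candidate contact points on the
   sampled heights. Each candidate is scored by the residual sum of
   squares *per fitted point* of the contact-model fit to the samples
   beyond it; per-point normalisation prevents bias toward late candidates
   that leave few samples. Candidates are only drawn where the corrected
   force is below 30% of the maximum exerted force: a contact point sits
   near zero force by definition, and without that restriction a candidate
   deep in the contact region, fitting only the last handful of samples,
   can beat the true contact point's score by chance under noise. The
   search is coarse-to-fine (160 coarse candidates, then every sample
   around the coarse minimum) and ends with parabolic interpolation of the
   log-RSS profile, so the recovered $z_c$ is not quantised to the
   sampling pitch (`find_contact_point()`).
4. **Indentation** — $\delta = (z - z_c) - (d - d_c)$: piezo travel past
   contact minus the additional cantilever deflection
   (`compute_indentation()`).
5. **Modulus and stiffness** — $K$ by the closed-form fit above over all
   extend samples past contact; the model-free stiffness $k$ as the OLS
   slope of force versus indentation over the top 90--100% force window
   (`fit_modulus()`, `fit_stiffness()`).
6. **QC** — a curve is kept only if achieved maximum force and achieved
   speed are within 10% of their setpoints and the fit succeeded. The
   achieved speed is the median finite-difference $dz/dt$ over the
   in-contact extend samples, robust to turnaround transients (the
   protocol does not pin down this estimator; the median is our choice).
   Failed fits are verdicts, not exceptions, so batch runs always complete
   with a per-curve report (`qc_setpoints()`).

## Maps, ratios, bins

Compartment labels (gray / white / excluded) are *inputs*, supplied as a
manifest, because segmentation of real maps is manual; the pipeline never
infers them. Repeated measurements at one position are combined by the
arithmetic mean of $K$ over QC-passing results (a geometric mean was
considered and rejected for transparency — medians downstream are robust
to the difference). Per map, `summarize_map()` reports the median $K$ per
compartment and their ratio $K_g/K_w$; the ratio is always a ratio of
medians, never a median of pointwise ratios, which would require an
arbitrary pairing of gray with white positions. Each map also carries the
median postmortem time (and temperature) per compartment; ratio records
are placed in time at the mean of the two compartment medians.

Time courses are binned into half-open one-hour bins starting at 1.5 h
postmortem, reporting mean, SD ($n-1$) and count per bin; records earlier
than the first edge land in a flagged underflow bin so counts are
conserved. Grid construction (`build_grid()`) uses a cell-centre lattice
(points at `min + (i - 1/2) * pitch`) clipped to the outline with boundary
points counted as interior — cell centring makes counts deterministic for
round outline/pitch combinations (a 1 mm square at 200 um pitch is exactly
5 × 5) and keeps points away from the outline where half the contact area
would hang over the edge. Positions across remeasured maps must match
exactly; mismatches are surfaced as errors rather than fuzzily matched.

## The regression layer

Temperature (or time) effects on per-map medians are tested by comparing
ordinary least squares of $K = a x + b$ against the horizontal line
$K = c$ with an extra-sum-of-squares F-test,
$F = (RSS_0 - RSS_1) / (RSS_1 / (n-2))$, $p$ from $F_{1,n-2}$, at
$\alpha = 0.05$ (configurable). The adjusted $r^2$ uses the alternative
model's $n-2$ residual degrees of freedom. Slopes are made comparable
across compartments as *relative* slopes, $100\,a / \hat K(T_{\rm ref})$
in %/°C with $T_{\rm ref} = 38$°C (rat body temperature). The regression
consumes per-map medians — one point per map per animal — never raw
curves, so each point carries comparable weight.

Two deliberately simple estimators place AFM settings on a strain axis:
the nominal strain $\varepsilon = \delta/h$ (indentation over section
height) and the strain rate $\dot\varepsilon = 1/(2 t_\delta)$, which
treats one indentation of duration $t_\delta$ as half an oscillation
period. The factor 2 is a convention, not a derivation, and is implemented
verbatim; display rounding (0.39 Hz printed as "~0.4 Hz") is left to the
caller.

## What the synthetic generator emulates

`simulate_curve()` integrates the closed-loop kinematics of a
constant-speed ramp: the piezo advances at the setpoint speed, and at
height $z$ past contact, $z - z_c = \delta + F(\delta)/k_c$, with $F$ the
chosen forward model; the ramp ends when force reaches the setpoint (or a
finite piezo range is exhausted, producing the flagged under-force curves
used to exercise QC). Sampling honours the protocol floor of 2500 extend
points. Gaussian deflection noise (default 1% of the setpoint force,
expressed through $k_c$) and a linear baseline (offset + tilt, tilt up to
$10^{-5}$ N/m) are applied on top. The response is quasi-static within a
curve: rate dependence enters only through the condition dependence of the
true modulus, because the analysis pipeline fits elastic models — a
simulator with intra-curve viscoelasticity would test a model the pipeline
does not fit.

`make_phantom()` builds two-compartment cross-sections (an outer ellipse
of white matter with one or two interior gray-matter ellipses, a
simplified butterfly) with base moduli $K_{g0} = 230$ Pa,
$K_{w0} = 47$ Pa — values in the range AFM reports for fresh CNS tissue,
chosen to give low-force transverse ratios of a few. The per-compartment
response surface is a product of four factors:

* **Force and speed stiffening**: saturating exponentials
  $(1 + A(1 - e^{-x/x_c}))$ with white-matter amplitudes larger than gray
  ($A_F$: 2.5 vs 0.4; $A_s$: 1.0 vs 0.25; $F_c = 300$ nN,
  $s_c = 400$ um/s), so effects are strongest at the low end of the
  protocol range and the gray-to-white ratio falls monotonically toward 1
  along the force axis. A saturating form was chosen over a power law
  because it captures "large effect at the low end, flattening above"
  with two parameters per axis.
* **Postmortem softening**: a smooth logistic plateau–decline–plateau,
  gray holding until ~3 h then settling at 2/3 of its starting value by
  ~6 h, white declining from the start to 1/2 by ~6 h (logistic width
  one-eighth of the decline window, which keeps the curve flat outside
  it).
* **Temperature**: linear with relative slope anchored at 38 °C,
  $-3.9$ %/°C (gray) and $-3.7$ %/°C (white), so both compartments soften
  on warming at nearly the same relative rate and the ratio is
  temperature-invariant by construction.

`simulate_experiment()` crosses a phantom with a protocol factorial,
spawns one reproducible sub-seed per curve from a single master seed, and
emits curve files, a manifest with true labels, and a ground-truth table.
`simulate_temperature_study()` adds the experiment-level structure of a
temperature study: six phantom replicates ("animals") with log-normal
(SD 0.2) animal-to-animal variation of the base moduli and log-normal
(SD 0.15) point-to-point heterogeneity within maps — scatter levels chosen
so per-animal medians disperse visibly around the regression line while
five temperature levels across 20–38 °C remain clearly resolvable, the
regime the real study operates in.

**What passing synthetic tests shows** — that the implementation inverts
its own forward physics correctly at realistic noise levels: contact
points recovered to sub-pitch accuracy, $K$ to <1% noise-free and <5% in
median at 2% noise, type-I error of the model comparison calibrated, the
generator's relative temperature slope recovered inside the fitted CI, and
QC excluding exactly the curves built to miss their setpoints.
**What it does not show** — anything about real tissue: no adhesion, no
drift, no viscoelastic creep inside a curve, no surface tilt, isotropic
and piecewise-homogeneous phantoms, and noise that is Gaussian and white.
Absolute agreement with published tissue values is outside what synthetic
data can certify.

## Numerical choices and degenerate inputs

* Root finding: bisection-based `uniroot` on guarded brackets everywhere;
  no derivatives, guaranteed convergence; relative tolerance $10^{-12} R$.
* Contact-point search: interior-minimum requirement — a best candidate at
  either end of the admissible range raises contact-not-found instead of
  returning a boundary value; pure-baseline curves fail fast because no
  candidate admits a positive modulus.
* Non-positive modulus estimates and under-populated fits produce
  fit-failure verdicts (`ok = FALSE`), not exceptions.
* Ties and order: map summaries are invariant to entry order and
  duplication; binning conserves counts including the underflow bin.
* Problem sizes in the shipped tests are chosen to keep the full suite in
  the minutes range on one core: 60–200 seeded replicates for noise
  robustness, 2000 null replicates for type-I calibration, five seeded
  temperature studies of 6 animals × 5 temperatures on ~600 um grids.

## Known limitations

Bottom-effect corrections for finite section thickness are not applied
(sections are ~20× deeper than the deepest default indentations);
conical/pyramidal tips are out of scope; the simulator's compartment
geometry is a stylised stand-in, not an anatomical atlas; and the
half-comparison (`compare_halves()`) reports effect sizes only — the
inferential test on those changes is left to general-purpose statistics.
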