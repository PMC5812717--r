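---
title: "Methods: passive mechanics, elastography and stiffness determinants of diaphragm muscle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: passive mechanics, elastography and stiffness determinants of diaphragm muscle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myomech)
```

`myomech` implements the quantitative core of a diaphragm-stiffness study in
dystrophic mice: how stiff is the tissue, what drives that stiffness, and
what are the respiratory consequences. Every analysis stage is paired with a
seeded synthetic-data generator whose ground truth is recorded, so the whole
pipeline is testable end to end without any lab recording. This vignette
explains the models, the defaults and why they were chosen, and what the
synthetic data can and cannot establish.

## Passive mechanics: the Veronda-Westman model

A muscle strip stretched beyond its optimal length \(L_0\) resists with a
passive stress that rises roughly exponentially with strain. We model the
loading ramp as an incompressible Veronda-Westman material under uniaxial
tension:

\[
\sigma(\lambda) \;=\; \frac{2E}{3}\left(\lambda^2 - \frac{1}{\lambda}\right)
\left(e^{\gamma\left(\lambda^2 + 2/\lambda - 3\right)} - \frac{1}{2\lambda}\right),
\qquad \lambda = 1 + \varepsilon,
\]

with two parameters: \(E\) (Pa), the Young's modulus at zero strain, and
\(\gamma\) (dimensionless), the exponential rate at which the tangent
modulus grows with strain. Two analytic facts anchor the interpretation and
are enforced by property tests: \(\sigma(1) = 0\) for every admissible
parameter pair, and \(d\sigma/d\lambda|_{\lambda=1} = E\), which is what
makes \(E\) a genuine *zero-strain* modulus.

The printed rendering of this constitutive law is typographically ambiguous
(flat text collapses exponents); the form above is the standard
incompressible uniaxial Veronda-Westman stress and is the only reading that
satisfies both anchor identities, so it is the one implemented.

Measured force is converted to engineering stress through the mass-based
cross-sectional area \(CSA = m /(L_0\,\rho_m)\) with muscle density
\(\rho_m = 1.06\) g/cm³, the same normalization used for specific force
(N/cm²). The fit is unweighted nonlinear least squares of \(\sigma(\lambda)\)
against the measured stress — engineering stress directly, with no Cauchy
conversion, matching how such data are reported.

Numerical choices:

* **Initialization.** \(E_0\) is the secant slope of stress over the first
  2 % of strain — the model-consistent small-strain estimate — and
  \(\gamma_0 = 1\).
* **Bounds.** \(E > 0\), \(\gamma \in [0, 50]\); the upper bound exists only
  to prevent exponential overflow, and \(\gamma\) estimates pin cleanly at 0
  when the truth is linear without destabilizing \(\hat E\).
* **Convergence.** Levenberg-Marquardt with `ftol = ptol = 1e-15`; noiseless
  synthetic ramps are recovered to relative \(10^{-6}\) or better.
* **"First stretch".** Only the longest initial monotone non-decreasing
  segment of \(\lambda\) is fitted; later cycles show hysteresis the model
  does not describe.

The default protocol matches the study conditions: a ramp to 120 % of
\(L_0\) at 1 \(L_0\)/s, i.e. 20 % strain over 0.2 s, sampled at 1 kHz.
Force noise in the generator is **multiplicative** with 2 % SD: passive
stress spans two orders of magnitude over the ramp, and proportional noise
keeps the signal-to-noise ratio uniform, which is how load-cell error
typically behaves. Under those conditions the median recovery error across
50 simulated strips is well under 5 % for \(E\) and 10 % for \(\gamma\).

## Optical coherence elastography

OCE estimates stiffness by launching a gentle elastic wave (a ~1 ms,
<10 Pa focused air puff) and imaging its propagation with phase-sensitive
OCT: the temporal phase of the interferometric signal reports axial tissue
displacement at the nanometer scale. The processing chain is:

1. **Phase to displacement.** Each (depth, lateral) pixel's phase time
   series is unwrapped *temporally* and scaled by the two-pass factor
   \(u = \phi\,\lambda_0/(4\pi n)\). The instrument constants —
   center wavelength \(\lambda_0\) (default 840 nm) and tissue refractive
   index \(n\) (default 1.38) — are not part of the wave physics, only of
   the phase scale, so they are configuration fields echoed into every
   field's metadata. Traces whose frame-to-frame step still exceeds
   \(\pi\) after unwrapping (fringe washout) are flagged and excluded.
2. **Arrival delays.** The wave's arrival delay at each lateral position,
   relative to a reference position (by default the position of maximal
   pulse energy, i.e. nearest the source), is the argmax of the normalized
   zero-padded cross-correlation of displacement traces, refined to
   sub-frame precision by 3-point parabolic interpolation. No DC removal is
   applied: the traces are zero-baseline pulses, and subtracting a mean
   imposes a triangular envelope on the padded correlation that biases the
   peak toward zero lag (this bias is large — tens of percent on broad
   pulses — and is the reason the implementation correlates raw traces).
   Parabolic refinement is accurate to well under 0.1 frame on smooth
   pulses, verified against a brute-force dense-lag oracle.
3. **Speed.** Ordinary least squares of delay against propagation distance;
   speed is the reciprocal slope. Positions with correlation peaks below
   0.5, or peaks at the lag-window edge, are excluded; a non-positive slope
   is rejected as non-physical.
4. **Depth averaging.** Per-row speeds are averaged (unweighted) over the
   rows lying 0–100 µm below the detected tissue surface — the superficial
   layer in which the surface-wave model is meaningful. The surface is the
   first row whose maximal temporal displacement SD exceeds 3× the 11 nm
   noise floor. Both the threshold multiple and the correlation floor are
   configurable because they are instrument- and preparation-dependent.
5. **Modulus.** The Rayleigh surface-wave closed form
   \(E = 2\rho(1+\nu)^3 C^2/(0.87 + 1.12\nu)^2\) with tissue density
   \(\rho = 1060\) kg/m³ and Poisson's ratio \(\nu = 0.5\) (soft tissue is
   nearly incompressible). The \((1+\nu)^3\) factor is cubic — the only
   reading consistent with the Rayleigh approximation
   \(c_R = c_T(0.87+1.12\nu)/(1+\nu)\), \(c_T = \sqrt{E/(2\rho(1+\nu))}\).
   The identity holds *exactly* in every estimate the package emits, and
   \(E \propto C^2\).

The synthetic field is a laterally propagating, depth-attenuating Gaussian
pulse, \(u(z,x,t) = A\,e^{-z/d}\,g(t-(x-x_0)/C)\), sampled at the
instrument's 16 µs frame interval with additive 11 nm Gaussian displacement
noise, emitted either as displacement or as wrapped phase. The pulse shape
is Gaussian because only the ~1 ms duration of the air puff is known; the
exponential depth profile (default decay length 150 µm) is likewise a
modeling choice, as the physical amplitude-depth profile is not specified.
Default geometry: 40 depth × 64 lateral × 320 time samples at 5 µm axial
and 10 µm lateral pitch. Anisotropy lives in the data: transverse and
longitudinal acquisitions run through byte-identical code paths, and tests
assert the direction label cannot change any number.

At these settings the end-to-end recovery (wrapped phase in, modulus out)
is within 0.5 % of the true speed noiseless and well within 3 % at 11 nm
noise, median over 20 seeds.

## Plethysmography filtering

Whole-body plethysmography of unrestrained mice logs one averaged row per
minute for 60 minutes (breath frequency f, tidal volume Tv, minute
ventilation Mv, peak flows, breath timings). Minutes where the animal held
its breath, buried its head, or hyperventilated are removed by the breath
frequency rule: compute the mean and SD of f **once** over all minutes and
exclude minutes falling strictly outside mean ± 1 SD.

Three readings of that rule were fixed deliberately:

* **Single pass.** Re-trimming on the kept subset would exclude further
  minutes on every iteration without bound; one mean/SD computation is the
  plain reading and is what the package does (and documents).
* **Sample SD** (divisor \(n-1\)) is the conventional default; population
  SD is available and the choice is echoed in the output.
* **Boundary minutes are kept** ("outside" read strictly).

One statistical subtlety is worth recording: with a lone aberrant minute,
the deviation of that minute is always ≈ \(\sqrt{n-1}\,(1-1/n)\) sample
SDs — about 7.6 at \(n = 60\) — *regardless of how small the aberration
is*, so a single odd minute is always excluded. The filter's correctness is
therefore asserted against an independent two-line mean/SD oracle on
thousands of random logs rather than against intuitions about magnitude.
The generator plants outliers displaced 20 nominal SDs by default
(breath-hold-scale excursions of hundreds of breaths/min against a ~2 %
minute-to-minute jitter), which is what makes exact planted-set recovery
the typical outcome; at small displacements the filter still agrees exactly
with the oracle, it just (correctly) excludes additional jittery minutes.

Whole minutes are dropped: exclusion applies row-wise to all variables, and
summaries report mean ± SEM of each variable over kept minutes. A
consistency check flags minutes where \(|Mv - f\,Tv|/Mv > 5\%\); the
generator builds \(Mv = f\,Tv(1+\text{jitter})\) with jitter ≤ 2 %, so a
flag indicates corruption, not noise.

## Variance partitioning of stiffness determinants

Fibrosis (collagen accumulation) and microtubule alterations (α-, β-,
de-tyrosinated tubulin, and the DT/α ratio) are candidate drivers of
dystrophic stiffening. The determinant analysis regresses each response
(transverse stiffness, longitudinal stiffness, peak specific force) on each
candidate alone, then on fibrosis *plus* a tubulin measure, and compares
adjusted R²:

\[
\bar R^2 = 1 - (1 - R^2)\,\frac{n-1}{n-p-1}
\]

(the Wherry/Ezekiel form — the standard "Adj R²"). If tubulin carries no
variance beyond its correlation with fibrosis, the multiple regression's
adjusted R² does not exceed fibrosis alone; that contrast
(`variance_gain()`) is the package's variance-partition statistic.
Significance stars use the overall-regression F-test at the a priori
p ≤ 0.05 threshold; per-coefficient t-tests are also reported. Regressions
pool animals across genotypes with no group indicators, as the printed
tables do. Group-level ANOVA/Tukey testing is out of scope — the focus is
the regression logic behind the determinant tables.

The cohort generator encodes exactly the hypothesis the analysis is
designed to detect: a latent fibrosis variable (three groups of eight
animals — healthy, dystrophic and rescued-dystrophic means of 5 %, 22 %,
12 % fibrosis with 3.5 % within-group SD) drives stiffness and force
linearly, with residual noise calibrated **analytically** so the population
R² of fibrosis equals the design targets (0.70 transverse, 0.45
longitudinal, 0.57 force — the magnitudes of the published variance
pattern). Tubulin columns are generated at fixed population correlation
with fibrosis (~0.7) and contribute nothing else. Because the pooled
fibrosis variance of the mixture is known in closed form, the design
targets are recoverable: across 200 simulated cohorts of n = 24 the
fibrosis-alone adjusted R² brackets the design value and adding DT-tubulin
yields no expected gain — the published qualitative pattern.

## Microtubule density

Fluorescence stacks of single fibers (10 intra-myofibrillar planes) are
summed pixelwise (double-precision accumulator — no saturation), binarized,
and the density is the fraction of above-threshold pixels. The thresholding
method in the original workflow is an interactive ImageJ step and is not
specified, so Otsu's method is the default — it is scale-invariant and
parameter-free — with a fixed-threshold escape hatch; both the method and
the threshold used are recorded in the result. Background subtraction is
not applied by default (in the original workflow it was cosmetic only).
Density is reported as a pixel fraction and labeled as such, since no
physical unit is defined for it. The directionality/organization score
sometimes reported alongside density comes from third-party software whose
algorithm is not public, and is deliberately not implemented.

The synthetic stack scatters randomly oriented bright line segments across
frames until the union mask reaches the requested coverage within ±0.5 %
absolute; the mask is stored as ground truth. Noiseless recovery is exact
to within 0.01 absolute across coverages 0.05–0.4 with unit slope against
truth.

## Determinism and problem sizes

Every generator takes a mandatory integer seed, draws from a local RNG
state, and restores the caller's state — identical inputs give
bit-identical outputs, and a composite `run_pipeline()` run writes a
manifest (seed, package version, md5 of every artifact) sufficient to
replay it. The test suite and the reproduction script use deliberately
modest problem sizes — 200-point stretch ramps, 40×64×320 wave fields,
50-seed fit studies, 200-cohort Monte Carlo, 256² image stacks — chosen so
the full suite completes in a couple of minutes on one core while keeping
Monte-Carlo envelopes tight enough for the stated tolerances.

## What the synthetic data does not show

The generators emulate the *structure* of the real recordings, not their
biology. Passing tests demonstrate that the estimators recover known
parameters under the stated noise models; they cannot validate the
constitutive model against real dystrophic tissue (real muscle is
viscoelastic and history-dependent; only the first loading ramp is
modeled), nor the surface-wave assumption on thin samples (no guided-wave
or dispersion corrections), nor Otsu's behavior on real immunofluorescence
backgrounds, nor the plethysmography chamber physics (minute-level rows
are taken as given). The cohort generator builds linear,
normally-distributed relationships; real fibrosis-stiffness relationships
need not be linear, and the regression stage inherits all the usual
caveats of observational correlation.
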