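# myomech

Quantitative analysis of diaphragm muscle stiffness and its consequences,
for muscle physiologists studying dystrophic (e.g. mdx mouse) diaphragm:

* **Passive mechanics** — fit the Veronda-Westman hyperelastic model to
  passive-stretch recordings and estimate the zero-strain Young's modulus
  *E* and stiffening rate *γ*.
* **Optical coherence elastography (OCE)** — estimate elastic wave speed
  from phase-sensitive OCT spatiotemporal fields by cross-correlation
  time-of-flight, and convert to Young's modulus with the Rayleigh
  surface-wave model.
* **Respiration** — apply the 1-SD breath-frequency exclusion rule to
  whole-body plethysmography logs and summarize respiratory variables.
* **Stiffness determinants** — partition variance in stiffness/force across
  fibrosis and tubulin measures with adjusted-R² simple and multiple
  regressions.
* **Microtubule density** — sum-binarize-fraction quantification of
  fluorescence image stacks.
* **Synthetic data** — seeded generators for every input, with ground truth
  recorded, so the whole pipeline is testable without lab data.

## The models

Passive stress on the loading ramp (incompressible Veronda-Westman,
uniaxial tension; λ = 1 + ε is the stretch ratio):

    σ(λ) = (2E/3) (λ² − 1/λ) (exp[γ(λ² + 2/λ − 3)] − 1/(2λ))

with σ(1) = 0 and dσ/dλ|₁ = E, so E is the Young's modulus at zero strain.
Force is normalized by the mass-based cross-section CSA = m/(L₀·ρ_m),
ρ_m = 1.06 g/cm³.

Surface-wave elasticity from wave speed C:

    E = 2ρ (1+ν)³ C² / (0.87 + 1.12ν)²

with tissue density ρ = 1060 kg/m³ and Poisson's ratio ν = 0.5. Wave speed
is the reciprocal slope of an OLS fit of cross-correlation arrival delay
against propagation distance, averaged over depth rows 0–100 µm below the
detected tissue surface.

Adjusted R² (Wherry/Ezekiel) drives the determinant tables:

    adj R² = 1 − (1 − R²)(n − 1)/(n − p − 1)

See `vignettes/diaphragm-stiffness-methods.Rmd` for assumptions, defaults
and numerical choices.

## Worked example

```r
library(myomech)

# simulate a passive-stretch ramp to 120% L0 at 1 L0/s, 2% force noise
rec <- generate_stretch_recording(E_pa = 30000, gamma = 4,
                                  mass_mg = 10, L0_mm = 10,
                                  noise_rel = 0.02, seed = 20260919)
fit <- fit_veronda_westman(to_stress_strain(rec))
print(fit)
#> Veronda-Westman fit (n = 201)
#>   E     = 2.989e+04 Pa  (SE 128)
#>   gamma = 4.059     (SE 0.0379)
#>   R^2   = 0.999246, RSS = 2.186e+06
```

The true modulus (30 kPa) is recovered within 0.4% and the stiffening rate
within 1.5% at this noise level.

```r
# elastography: wrapped-phase field at 16 us frames, 11 nm noise
field <- generate_oce_field(wave_scene(wave_speed_m_s = 2.5),
                            acquisition_config(), mode = "phase",
                            seed = 20260920)
est <- depth_average_speed(phase_to_displacement(field))
surface_wave_modulus(est)
#> Young's modulus: 2.181e+04 Pa (C = 2.497 m/s, rho = 1060 kg/m^3, nu = 0.5)
```

The 2.5 m/s wave planted in the field is recovered to 0.13%, and the
modulus (21.8 kPa) satisfies the surface-wave relation exactly.

## Analysis workflow

The numbered scripts under `analysis/` run the full simulate-then-analyze
study from `analysis/config.yaml`, writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R                    # all synthetic inputs + ground truth
Rscript analysis/02_fit_passive_stretch.R         # VW fit: E, gamma
Rscript analysis/03_estimate_elastography.R       # wave speed + Young's modulus
Rscript analysis/04_filter_respiration.R          # 1-SD filter + summary table
Rscript analysis/05_partition_stiffness_variance.R# adj R^2 determinant table
Rscript analysis/06_quantify_mt_density.R         # microtubule density
```

With the default config, script 04 excludes exactly the two planted
outlier minutes {5, 17}, and script 05 reports fibrosis-alone adjusted R²
of 0.747 (transverse) and 0.546 (longitudinal) on a cohort designed at
population R² 0.70/0.45, with adding DT-tubulin changing adjusted R² by
−0.010 — no independent tubulin signal, the qualitative determinant
pattern.

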