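# Shared configuration for the analysis workflow (scripts 01-06).
# Every dataset is synthetic, generated by 01_simulate.R with the ground
# truth recorded, so each downstream script can report recovered vs true.
seed: 20260919
out_dir: results/data

stretch:
  E_pa: 30000        # zero-strain Young's modulus (Pa)
  gamma: 4           # exponential stiffening rate
  mass_mg: 10
  L0_mm: 10
  noise_rel: 0.02    # 2% multiplicative force noise
  max_strain: 0.20   # stretch to 120% of L0
  strain_rate: 1.0   # L0/s

oce:
  wave_speed_m_s: 2.5
  direction: transverse
  rho: 1060          # tissue density (kg/m^3)
  nu: 0.5            # Poisson's ratio (incompressible)
  depth_max_um: 100  # average speeds over 0-0.1 mm below the surface
  displacement_noise_nm: 11

breath:
  n_minutes: 60
  outlier_minutes: [5, 17]   # planted breath-hold / burrowing minutes

cohort:
  n_per_group: 8
  r2_transverse: 0.70
  r2_longitudinal: 0.45
  r2_force: 0.57

mt:
  coverage: 0.20
  size: 256
  n_frames: 10
  method: otsu
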