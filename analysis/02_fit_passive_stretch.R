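#!/usr/bin/env Rscript
# Fit the Veronda-Westman hyperelastic model to the simulated
# passive-stretch recording: convert force/length to engineering
# stress/stretch using the mass-based CSA, keep the first loading ramp,
# and estimate the zero-strain Young's modulus E and stiffening rate gamma.

suppressPackageStartupMessages(library(myomech))

data_dir <- file.path("results", "data")
rec <- read_stretch_csv(file.path(data_dir, "stretch_recording.csv"))
truth <- jsonlite::read_json(file.path(data_dir, "ground_truth.json"),
                             simplifyVector = TRUE)$stretch

curve <- to_stress_strain(rec)
fit <- fit_veronda_westman(curve)
print(fit)

cat(sprintf("true E = %g Pa -> recovered %.1f Pa (%.2f%% error)\n",
            truth$E_pa, fit$E_pa, 100 * abs(fit$E_pa - truth$E_pa) / truth$E_pa))
cat(sprintf("true gamma = %g -> recovered %.4f (%.2f%% error)\n",
            truth$gamma, fit$gamma,
            100 * abs(fit$gamma - truth$gamma) / truth$gamma))

out_dir <- file.path("results", "passive_mechanics")
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
write_result_json(fit, file.path(out_dir, "vw_fit.json"))
write_table_csv(
  data.frame(lambda = curve$lambda, strain = curve$strain,
             sigma_n_cm2 = curve$sigma_n_cm2,
             sigma_fit_n_cm2 = vw_stress(curve$lambda, fit$E_pa, fit$gamma) / 1e4),
  file.path(out_dir, "fitted_curve.csv"))
cat("fit and fitted curve written under", out_dir, "\n")
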