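#!/usr/bin/env Rscript
# Estimate the elastic wave speed from the simulated wrapped-phase
# elastography field (temporal unwrap -> displacement -> cross-correlation
# delays -> delay-vs-distance slope, averaged over the 0-0.1 mm layer) and
# convert it to Young's modulus with the Rayleigh surface-wave model.

suppressPackageStartupMessages(library(myomech))

cfg <- read_pipeline_config(file.path("analysis", "config.yaml"))$oce
data_dir <- file.path("results", "data")
field <- read_oce_tiff(file.path(data_dir, "oce_field.tif"))
truth <- jsonlite::read_json(file.path(data_dir, "ground_truth.json"),
                             simplifyVector = TRUE)$oce

u <- phase_to_displacement(field)
est <- depth_average_speed(u, z_max_um = cfg$depth_max_um)
print(est)
mod <- surface_wave_modulus(est, rho = cfg$rho, nu = cfg$nu)
print(mod)

cat(sprintf("true C = %g m/s -> recovered %.4f m/s (%.2f%% error)\n",
            truth$wave_speed_m_s, est$C_m_s,
            100 * abs(est$C_m_s - truth$wave_speed_m_s) / truth$wave_speed_m_s))
cat(sprintf("Young's modulus %.2f kPa at rho = %g kg/m^3, nu = %g\n",
            mod$E_pa / 1000, cfg$rho, cfg$nu))

out_dir <- file.path("results", "elastography")
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
write_result_json(list(wave_speed = est[c("C_m_s", "se_m_s", "r_squared",
                                          "n_rows", "surface_row")],
                       modulus = unclass(mod)),
                  file.path(out_dir, "elasticity_estimate.json"))
write_table_csv(est$per_row, file.path(out_dir, "per_depth_speeds.csv"))
cat("estimates written under", out_dir, "\n")
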