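#!/usr/bin/env Rscript
# Simulate every input dataset for the workflow: a passive-stretch
# recording, a wrapped-phase elastography field, a 60-minute breath log
# with planted outliers, a 24-animal cohort table in which fibrosis drives
# stiffness and force, and a filament-texture image stack of known
# coverage. Ground truth is written alongside each artifact so scripts
# 02-06 can report recovered vs true.

suppressPackageStartupMessages(library(myomech))

cfg <- read_pipeline_config(file.path("analysis", "config.yaml"))
seed <- as.integer(cfg$seed)
out <- cfg$out_dir
dir.create(out, showWarnings = FALSE, recursive = TRUE)
truth <- list(seed = seed)

s <- cfg$stretch
rec <- generate_stretch_recording(
  E_pa = s$E_pa, gamma = s$gamma,
  protocol = stretch_protocol(max_strain = s$max_strain,
                              strain_rate = s$strain_rate),
  mass_mg = s$mass_mg, L0_mm = s$L0_mm, noise_rel = s$noise_rel, seed = seed)
write_stretch_csv(rec, file.path(out, "stretch_recording.csv"))
truth$stretch <- list(E_pa = s$E_pa, gamma = s$gamma)
cat(sprintf("stretch: %d samples to %.0f%% strain, true E = %g Pa, gamma = %g\n",
            length(rec$time_s), 100 * s$max_strain, s$E_pa, s$gamma))

o <- cfg$oce
field <- generate_oce_field(
  wave_scene(wave_speed_m_s = o$wave_speed_m_s, direction = o$direction),
  acquisition_config(displacement_noise_nm = o$displacement_noise_nm),
  mode = "phase", seed = seed + 1L)
write_oce_tiff(field, file.path(out, "oce_field.tif"))
truth$oce <- list(wave_speed_m_s = o$wave_speed_m_s)
cat(sprintf("oce: %s wrapped-phase field, true C = %g m/s, %g nm noise\n",
            paste(dim(field$data), collapse = "x"), o$wave_speed_m_s,
            o$displacement_noise_nm))

b <- cfg$breath
log <- generate_breath_log(n_minutes = b$n_minutes,
                           outlier_minutes = unlist(b$outlier_minutes),
                           seed = seed + 2L)
write_table_csv(log, file.path(out, "breath_log.csv"))
truth$breath <- list(outlier_minutes = unlist(b$outlier_minutes))
cat(sprintf("breath: %d minutes, planted outliers at {%s}\n", b$n_minutes,
            paste(unlist(b$outlier_minutes), collapse = ", ")))

co <- cfg$cohort
design <- cohort_design(n_per_group = co$n_per_group,
                        r2_transverse = co$r2_transverse,
                        r2_longitudinal = co$r2_longitudinal,
                        r2_force = co$r2_force)
tab <- generate_cohort(design, seed = seed + 3L)
write_table_csv(tab, file.path(out, "cohort.csv"))
truth$cohort <- design[c("r2_transverse", "r2_longitudinal", "r2_force")]
cat(sprintf("cohort: %d animals in %d groups, fibrosis population R^2 = %.2f (trans) / %.2f (long)\n",
            nrow(tab), length(design$groups), co$r2_transverse,
            co$r2_longitudinal))

m <- cfg$mt
stack <- generate_filament_image(coverage = m$coverage, n_frames = m$n_frames,
                                 size = m$size, seed = seed + 4L)
write_stack_tiff(stack, file.path(out, "mt_stack.tif"))
truth$mt <- list(coverage = stack$ground_truth$coverage)
cat(sprintf("mt: %dx%dx%d stack, union-mask coverage %.4f (target %.2f)\n",
            m$size, m$size, m$n_frames, stack$ground_truth$coverage,
            m$coverage))

write_result_json(truth, file.path(out, "ground_truth.json"))
cat("ground truth recorded in", file.path(out, "ground_truth.json"), "\n")
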