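#' Read and validate a pipeline configuration
#'
#' YAML configuration with one block per stage. Unknown top-level or
#' per-stage keys are rejected so that typos never silently fall back to
#' defaults.
#'
#' @param path Path to a YAML file, or a named list already in memory.
#' @return A validated `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  if (!is.list(cfg) || !length(cfg)) {
    stop("empty config; required blocks: seed, out_dir and at least one of ",
         "stretch, oce, breath, cohort, mt.", call. = FALSE)
  }
  allowed <- list(
    seed = character(),
    out_dir = character(),
    stretch = c("E_pa", "gamma", "mass_mg", "L0_mm", "noise_rel",
                "max_strain", "strain_rate", "sample_rate", "density_g_cm3"),
    oce = c("wave_speed_m_s", "direction", "rho", "nu", "depth_max_um",
            "n_frames", "n_lateral", "n_depth", "displacement_noise_nm",
            "min_corr"),
    breath = c("n_minutes", "outlier_minutes", "rel_sd"),
    cohort = c("n_per_group", "r2_transverse", "r2_longitudinal", "r2_force"),
    mt = c("coverage", "size", "n_frames", "method"))
  unknown <- setdiff(names(cfg), names(allowed))
  if (length(unknown)) {
    stop("unknown config block(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (blk in intersect(names(cfg), c("stretch", "oce", "breath", "cohort", "mt"))) {
    bad <- setdiff(names(cfg[[blk]]), allowed[[blk]])
    if (length(bad)) {
      stop(sprintf("unknown key(s) in `%s` block: %s", blk,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  if (is.null(cfg$seed)) stop("config requires a `seed`.", call. = FALSE)
  if (is.null(cfg$out_dir)) stop("config requires an `out_dir`.", call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the simulate-then-analyze pipeline
#'
#' Executes every stage present in the configuration: simulate the input
#' with the stage's ground truth, run the corresponding analysis, and write
#' both artifacts and a per-stage recovered-versus-true report. A resolved
#' configuration snapshot and a machine-readable run manifest (package
#' version, seed, output digests) are written next to the outputs, so a
#' run is replayable from the manifest alone.
#'
#' @param config A `pipeline_config`, or a path/list accepted by
#'   [read_pipeline_config()].
#' @return The run report (named list per stage), invisibly; artifacts
#'   under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config else
    read_pipeline_config(config)
  out_dir <- cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed)
  report <- list()
  failed <- NULL

  run_stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      failed <<- c(failed, name)
      writeLines(sprintf("stage %s FAILED: %s", name, conditionMessage(res)),
                 file.path(out_dir, paste0(name, ".FAILED")))
      NULL
    } else res
  }

  if (!is.null(cfg$stretch)) {
    report$stretch <- run_stage("stretch", function() {
      s <- cfg$stretch
      rec <- generate_stretch_recording(
        E_pa = s$E_pa %||% 30000, gamma = s$gamma %||% 4,
        protocol = stretch_protocol(max_strain = s$max_strain %||% 0.20,
                                    strain_rate = s$strain_rate %||% 1,
                                    sample_rate = s$sample_rate %||% 1000),
        mass_mg = s$mass_mg %||% 10, L0_mm = s$L0_mm %||% 10,
        noise_rel = s$noise_rel %||% 0.02, seed = seed)
      write_stretch_csv(rec, file.path(out_dir, "stretch_recording.csv"))
      fit <- fit_veronda_westman(to_stress_strain(rec, s$density_g_cm3 %||% 1.06))
      write_result_json(fit, file.path(out_dir, "vw_fit.json"))
      list(true_E_pa = rec$ground_truth$E_pa, fitted_E_pa = fit$E_pa,
           true_gamma = rec$ground_truth$gamma, fitted_gamma = fit$gamma,
           converged = fit$converged)
    })
  }

  if (!is.null(cfg$oce)) {
    report$oce <- run_stage("oce", function() {
      o <- cfg$oce
      acq <- acquisition_config(
        n_frames = o$n_frames %||% 320, n_lateral = o$n_lateral %||% 64,
        n_depth = o$n_depth %||% 40,
        displacement_noise_nm = o$displacement_noise_nm %||% 11)
      field <- generate_oce_field(
        wave_scene(wave_speed_m_s = o$wave_speed_m_s %||% 2.5,
                   direction = o$direction %||% "transverse"),
        acq, mode = "phase", seed = seed + 1L)
      write_oce_tiff(field, file.path(out_dir, "oce_field.tif"))
      u <- phase_to_displacement(field)
      est <- depth_average_speed(u, z_max_um = o$depth_max_um %||% 100,
                                 min_corr = o$min_corr %||% 0.5)
      mod <- surface_wave_modulus(est, rho = o$rho %||% 1060, nu = o$nu %||% 0.5)
      write_result_json(list(wave_speed = est[c("C_m_s", "se_m_s", "r_squared",
                                                "n_rows")],
                             modulus = unclass(mod)),
                        file.path(out_dir, "oce_estimate.json"))
      list(true_C_m_s = field$ground_truth$wave_speed_m_s,
           estimated_C_m_s = est$C_m_s, E_pa = mod$E_pa)
    })
  }

  if (!is.null(cfg$breath)) {
    report$breath <- run_stage("breath", function() {
      b <- cfg$breath
      log <- generate_breath_log(
        n_minutes = b$n_minutes %||% 60,
        outlier_minutes = unlist(b$outlier_minutes) %||% integer(),
        rel_sd = b$rel_sd %||% 0.02, seed = seed + 2L)
      write_table_csv(log, file.path(out_dir, "breath_log.csv"))
      filt <- filter_breath_frequency(log)
      summ <- summarize_respiration(log, filt)
      write_table_csv(summ, file.path(out_dir, "respiration_summary.csv"))
      write_result_json(filt[c("mean_f", "sd_f", "n_excluded",
                               "excluded_minutes", "sd_type")],
                        file.path(out_dir, "breath_filter.json"))
      list(planted_outliers = attr(log, "ground_truth")$outlier_minutes,
           excluded_minutes = filt$excluded_minutes)
    })
  }

  if (!is.null(cfg$cohort)) {
    report$cohort <- run_stage("cohort", function() {
      co <- cfg$cohort
      design <- cohort_design(
        n_per_group = co$n_per_group %||% 8,
        r2_transverse = co$r2_transverse %||% 0.70,
        r2_longitudinal = co$r2_longitudinal %||% 0.45,
        r2_force = co$r2_force %||% 0.57)
      tab <- generate_cohort(design, seed = seed + 3L)
      write_table_csv(tab, file.path(out_dir, "cohort.csv"))
      dt <- determinant_table(tab)
      write_table_csv(dt, file.path(out_dir, "determinant_table.csv"))
      list(design_r2_transverse = design$r2_transverse,
           fitted_adj_r2_transverse = dt$adj_r2[
             dt$response == "transverse_stiffness" & dt$predictors == "fibrosis"])
    })
  }

  if (!is.null(cfg$mt)) {
    report$mt <- run_stage("mt", function() {
      m <- cfg$mt
      stack <- generate_filament_image(coverage = m$coverage %||% 0.2,
                                       n_frames = m$n_frames %||% 10,
                                       size = m$size %||% 256, seed = seed + 4L)
      write_stack_tiff(stack, file.path(out_dir, "mt_stack.tif"))
      dens <- mt_density(stack, method = m$method %||% "otsu")
      write_result_json(dens, file.path(out_dir, "mt_density.json"))
      list(true_coverage = stack$ground_truth$coverage,
           measured_density = dens$density)
    })
  }

  # resolved config snapshot + manifest
  yaml::write_yaml(unclass(cfg), file.path(out_dir, "config_resolved.yaml"))
  files <- setdiff(list.files(out_dir, full.names = TRUE),
                   file.path(out_dir, "manifest.json"))
  manifest <- list(
    package = "myomech",
    version = as.character(utils::packageVersion("myomech")),
    seed = seed,
    stages = names(report),
    failed_stages = failed,
    outputs = data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  if (length(failed)) {
    stop("pipeline stage(s) failed: ", paste(failed, collapse = ", "),
         "; partial outputs retained with FAILED markers in ", out_dir,
         call. = FALSE)
  }
  invisible(report)
}
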