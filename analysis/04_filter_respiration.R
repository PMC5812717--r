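#!/usr/bin/env Rscript
# Apply the one-standard-deviation breath-frequency exclusion rule to the
# simulated plethysmography log, verify minute-ventilation consistency
# (Mv ~ f x Tv), and summarize the respiratory variables over kept minutes.

suppressPackageStartupMessages(library(myomech))

data_dir <- file.path("results", "data")
log <- read_table_csv(file.path(data_dir, "breath_log.csv"))
truth <- jsonlite::read_json(file.path(data_dir, "ground_truth.json"),
                             simplifyVector = TRUE)$breath

filt <- filter_breath_frequency(log)
cat(sprintf("mean f = %.1f, SD = %.1f (%s); excluded %d of %d minutes: {%s}\n",
            filt$mean_f, filt$sd_f, filt$sd_type, filt$n_excluded, nrow(log),
            paste(filt$excluded_minutes, collapse = ", ")))
cat(sprintf("planted outlier minutes: {%s}\n",
            paste(truth$outlier_minutes, collapse = ", ")))

bad_mv <- which(check_mv_consistency(log))
cat(if (length(bad_mv)) sprintf("Mv inconsistent in minutes {%s}\n",
                                paste(bad_mv, collapse = ", "))
    else "Mv consistent with f x Tv in every minute (5% tolerance)\n")

summ <- summarize_respiration(log, filt)
print(summ, digits = 4)

out_dir <- file.path("results", "respiration")
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
write_table_csv(summ, file.path(out_dir, "respiration_summary.csv"))
write_result_json(filt[c("mean_f", "sd_f", "n_excluded", "excluded_minutes",
                         "sd_type")],
                  file.path(out_dir, "exclusion_report.json"))
cat("summary and exclusion report written under", out_dir, "\n")
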