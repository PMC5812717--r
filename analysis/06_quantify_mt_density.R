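#!/usr/bin/env Rscript
# Microtubule density from the simulated fluorescence stack: sum the
# frames, Otsu-binarize, and report the foreground pixel fraction against
# the generator's ground-truth union-mask coverage.

suppressPackageStartupMessages(library(myomech))

cfg <- read_pipeline_config(file.path("analysis", "config.yaml"))$mt
data_dir <- file.path("results", "data")
stack <- read_stack_tiff(file.path(data_dir, "mt_stack.tif"))
truth <- jsonlite::read_json(file.path(data_dir, "ground_truth.json"),
                             simplifyVector = TRUE)$mt

dens <- mt_density(stack, method = cfg$method)
print(dens)
cat(sprintf("true coverage %.4f -> measured density %.4f (abs error %.4f)\n",
            truth$coverage, dens$density, abs(dens$density - truth$coverage)))

out_dir <- file.path("results", "mt_density")
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
write_result_json(c(unclass(dens), list(true_coverage = truth$coverage)),
                  file.path(out_dir, "mt_density.json"))
cat("density result written under", out_dir, "\n")
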