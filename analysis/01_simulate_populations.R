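#!/usr/bin/env Rscript
# Simulate the three-colour reporter populations across the acid-stress
# time course (pH 7.6 t0 -> pH 5.8 + lysine t150 -> pH 4.4 t300) using the
# packaged demo configuration, and run the full quantification pipeline.
# Outputs: results/pipeline/{cells,population_summary,correlations}.csv

suppressMessages(library(acidhet))

cfg <- yaml::read_yaml(demo_config_path())
cfg$out_dir <- "results/pipeline"
log <- run_pipeline(cfg)

cat("Simulated and quantified", sum(sapply(log$stages, `[[`, "n_cells")),
    "cells across", length(log$stages), "conditions.\n\n")
cat("Per-condition summaries (noise = sd/mean of log(x+1) intensities):\n")
print(log$summary, digits = 3)
cat("\nThe Cad channel is right-skewed (lognormal ON mixture) while Gad and",
    "Adi are Gaussian-like, mirroring the reporter families.\n")
cat("Wrote:", paste(log$files, collapse = ", "), "\n")
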