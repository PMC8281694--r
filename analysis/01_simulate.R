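#!/usr/bin/env Rscript
# Simulate the synthetic tomato trial: three replicate plots, five rows of
# 14 hills each (210 plants), ten acquisition dates from late May to late
# July. Writes the plant table, the yield table and the ground truth to
# results/, and the (large) raster scene to scratch/scene/ for the later
# steps. Rerunning with the same seed reproduces every file bit-for-bit.

library(phenoyield)

seed <- 1L
dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

layout <- field_layout()
sim <- generate_field(layout, growth_params(), synthetic_truth(),
                      seed = stage_seed(seed, "simulate"))

cat(sprintf("simulated %d plants over %d dates; raster %d x %d at %.0f mm\n",
            nrow(sim$plants), length(sim$scene$dates),
            nrow(sim$terrain$values), ncol(sim$terrain$values),
            1000 * layout$gsd_m))
cat(sprintf("mean yields: SM %.2f kg, FW %.2f kg, FN %.1f fruit per plant\n",
            mean(sim$yields$SM), mean(sim$yields$FW), mean(sim$yields$FN)))
cat("causal features:", paste(sim$truth$causal_features, collapse = ", "), "\n")

write.csv(sim$plants, "results/plants.csv", row.names = FALSE)
write.csv(sim$yields, "results/yields.csv", row.names = FALSE)
jsonlite::write_json(
  list(causal_features = sim$truth$causal_features,
       coefficients = as.data.frame(sim$truth$coefficients),
       intercepts = as.list(sim$truth$intercepts),
       noise_sd = as.list(sim$truth$noise_sd),
       seed = sim$seed),
  "results/truth.json", auto_unbox = TRUE, digits = NA)

write_scene(sim$scene, "scratch/scene")
cat("wrote results/plants.csv, results/yields.csv, results/truth.json and scratch/scene/\n")
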