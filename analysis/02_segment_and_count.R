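#!/usr/bin/env Rscript
# Segment the 15 clean control cells and check how well the per-cell
# EEA1-vesicle count and vesicle measurements recover the generator truth.
# Expects results/scenes_control from 01_simulate_scenes.R.

library(endoquant)

scenes <- endoquant:::load_scene_dir("results/scenes_control")
rec <- run_recovery(scenes)
write.csv(rec$per_cell, "results/count_recovery.csv", row.names = FALSE)

cat(sprintf("cells: %d\n", nrow(rec$per_cell)))
cat(sprintf("mean true count: %.1f  mean estimated: %.1f\n",
            mean(rec$per_cell$true_count), mean(rec$per_cell$est_count)))
cat(sprintf("exact-count recovery: %.0f%% of cells (bias %.2f)\n",
            100 * rec$count_exact_fraction, rec$count_bias))

res <- run_analyze(scenes, out_dir = "results/control_analysis")
fn <- five_number(res$summaries$n_vesicles[res$summaries$channel == "green"])
cat("green vesicle count five-number summary:\n")
print(round(fn, 1))
cat("tables written under results/control_analysis\n")
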