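#!/usr/bin/env Rscript
# Densitometry statistics: Ponceau-normalized fold changes relative to the
# unstimulated control, per-timepoint one-sample sign tests against 1, and
# Bonferroni-Holm correction across timepoints. Under the null generator the
# family can never reach significance: with n = 3 replicates the smallest
# attainable sign-test p is 0.25, and Holm over three timepoints lifts it to
# 0.75 at best.
# Expects results/densitometry_null.csv from 01_simulate_scenes.R.

library(endoquant)

dens <- read.csv("results/densitometry_null.csv")
fc <- densitometry_foldchange(dens, "0min")
write.csv(fc, "results/densitometry_foldchanges.csv", row.names = FALSE)

cat("fold changes per timepoint:\n")
print(aggregate(fold_change ~ timepoint, fc,
                function(v) round(c(mean = mean(v)), 3)), row.names = FALSE)

res <- membrane_marker_test(fc)
write.csv(res, "results/densitometry_sign_tests.csv", row.names = FALSE)
cat("\nsign tests vs control (Holm-adjusted):\n")
print(res, row.names = FALSE)
cat(sprintf("\nsignificant at 0.05: %s (Holm floor for n=3 x 3 timepoints is 0.75)\n",
            any(res$p_adjusted < 0.05, na.rm = TRUE)))
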