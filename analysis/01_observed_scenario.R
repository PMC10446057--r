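#!/usr/bin/env Rscript
# Observed powder-pouring shift: Monte-Carlo exposure distribution,
# per-task concentrations and 8-h TWA statistics.
#
# Writes results/observed/ (iteration table, summary, sensitivity
# tables, compliance verdicts, run log).

library(twozone)

report <- run_pipeline("observed", seed = 1, out_dir = "results/observed")
print(report)

cat("\nThe shift-average NF concentration distribution is narrow\n")
cat(sprintf("(GSD %.2f): the per-repetition resampling of the process\n",
            report$summary$gsd))
cat("determinants averages much of their variability out over the shift.\n")
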