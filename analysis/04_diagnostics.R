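#!/usr/bin/env Rscript
# Step 4: weighting diagnostics on the step-1 sample — propensity overlap
# (positivity), covariate balance before/after IPTW weighting, and the
# distribution of the combined analysis weights.

library(svypate)

samp <- read_survey_csv("results/sample.csv")

prop <- fit_propensity(samp)
cat("propensity score range: ",
    sprintf("[%.3f, %.3f]; %d values outside (0.001, 0.999)\n",
            min(prop$pi), max(prop$pi), prop$n_flagged))

cw <- compute_iptw_weights(prop, samp)
cat(sprintf("treatment weights: median %.2f, max %.2f\n",
            median(cw$t), max(cw$t)))
cat(sprintf("combined analysis weights: median %.1f, max %.1f\n",
            median(cw$w), max(cw$w)))

bal <- balance_smd(samp, weights = cw$t)
write.csv(bal, "results/balance.csv", row.names = FALSE)
print(format(bal, digits = 2), row.names = FALSE)
cat(sprintf("\nmax |SMD| before: %.3f, after IPTW weighting: %.3f ",
            max(abs(bal$smd_before), na.rm = TRUE),
            max(abs(bal$smd_after), na.rm = TRUE)))
cat("(conventional adequacy threshold 0.1)\n")
cat("Wrote results/balance.csv\n")
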