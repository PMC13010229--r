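#!/usr/bin/env Rscript
# Step 3: replicate simulation study. Repeatedly draws survey samples from
# one superpopulation and summarises each estimator's bias, empirical SE,
# mean CI width and 95% coverage of the true PATE. Bootstrap sizes are kept
# modest here (B = 150) because every replicate re-runs every bootstrap; the
# acceptance checks probe bias and coverage at larger replicate counts.

library(svypate)

gen <- generator_config(n = 5e4, seed = 2026)
out <- simulation_study(gen, n_replicates = 30,
                        config = analysis_config(B = 150,
                                                 gcomp_mode = "plug-in",
                                                 seed = 2026))

write.csv(out$summary, "results/simulation_summary.csv", row.names = FALSE)

cat(sprintf("true PATE = %.3f; %d replicate samples\n\n",
            out$truth$pate, out$n_replicates))
print(format(out$summary, digits = 3), row.names = FALSE)
cat("\nExpected pattern: weighted, adjusted estimators are unbiased with\n")
cat("coverage near 0.95; unweighted ones are biased upward (the oversampled\n")
cat("strata carry larger effects) with narrower intervals; IPTW has the\n")
cat("widest intervals of the three causal estimators.\n")
cat("Wrote results/simulation_summary.csv\n")
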