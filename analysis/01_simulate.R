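#!/usr/bin/env Rscript

# Stage 1 - simulate the study cohort.
#
# The study's participant-level data are not public, so the whole analysis
# runs on a synthetic cohort with known ground truth: 3,063 employees, 14
# indicators (3 psychological-problem scores, 11 stressful-life-event
# domain scores on the 0-5 intensity scale), a latent profile regressed on
# two latent stressor domains plus 12 fixed covariates, and a right-skewed
# structural error. Generating parameters are calibrated so the factor
# structure matches the study's printed percentages.

library(quantsem)

dir.create("results", showWarnings = FALSE)

n_design <- cochran_sample_size(p = 0.1, alpha = 0.05, d = 0.01,
                                round_to = 100)
cat(sprintf("design sample size (prevalence 0.1, alpha 0.05, d 0.01): %d\n",
            n_design))

truth <- synthetic_truth(seed = 20260921L)   # n = 3063, skewness 0.9
sim <- generate_dataset(truth)

cat(sprintf("simulated %d participants, %d indicators, %d covariates\n",
            nrow(sim$indicators), ncol(sim$indicators), ncol(sim$X)))
cat(sprintf("structural error skewness target 0.9, achieved %.3f\n",
            quantsem:::structural_error_moments(truth$error)$skewness))

write.csv(cbind(sim$indicators, sim$covariates),
          "results/cohort_scored.csv", row.names = FALSE)
write.csv(as.data.frame(sim$X), "results/cohort_design.csv",
          row.names = FALSE)
# ground truth kept separately; fitting stages never read it
write.csv(sim$latent, "results/cohort_latent_truth.csv", row.names = FALSE)
cat("wrote results/cohort_scored.csv, cohort_design.csv,",
    "cohort_latent_truth.csv\n")
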