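#!/usr/bin/env Rscript

# Stage 2 - measurement constructs.
#
# Extracts the one-factor psychological problems profile from distress,
# anxiety and depression, runs the exploratory two-factor analysis of the
# 11 stressor domains (varimax), and tabulates covariates across quartiles
# of the profile score.

library(quantsem)

ind <- read.csv("results/cohort_scored.csv")

profile <- extract_profile(ind[c("ghq12_distress", "hads_anxiety",
                                 "hads_depression")])
cat(sprintf("profile factor explains %.2f%% of indicator variance\n",
            profile$variance_explained))

domains <- c(stressor_domains()$socioeconomic, stressor_domains()$personal)
efa <- efa_stressors(ind[domains])
cat(sprintf("two stressor factors explain %.2f%% of total variance\n",
            efa$variance_explained))
cat("domain assignment (factor 1 = socioeconomic-type block):\n")
print(efa$assignment)

covars <- setdiff(names(ind), c(domains, "ghq12_distress", "hads_anxiety",
                                "hads_depression"))
desc <- quartile_descriptives(ind[covars], profile$factor_scores[, 1])

write.csv(as.data.frame(round(efa$loadings, 3)),
          "results/stressor_loadings.csv")
write.csv(efa$scree, "results/scree.csv", row.names = FALSE)
write.csv(desc$table, "results/quartile_descriptives.csv",
          row.names = FALSE)
write.csv(data.frame(profile_score = profile$factor_scores[, 1]),
          "results/profile_scores.csv", row.names = FALSE)
cat("wrote results/stressor_loadings.csv, scree.csv,",
    "quartile_descriptives.csv, profile_scores.csv\n")
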