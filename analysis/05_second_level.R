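#!/usr/bin/env Rscript

# Stage 5 — second-level brain-behavior model.
#
# Reduces MMSE, ACE-R and RAVLT to a first-principal-component composite,
# fits the robust interaction model (composite ~ brain score x group +
# covariates), reports within-group post hoc correlations, and tabulates
# the cohort summary with group tests.

suppressPackageStartupMessages(library(inflammetry))

cohort <- read_cohort("results/cohort")
scores <- read.csv("results/brain_scores.csv")
inc <- match(scores$subject_id, cohort$cohort$subject_id)

comp <- cognitive_pca(cohort$cohort[inc, c("MMSE", "ACER", "RAVLT")])
message("cognitive PC1 explains ",
        round(100 * comp$variance_explained), "% of variance ",
        "(loadings ", paste(round(comp$loadings, 2), collapse = ", "), ")")

covars <- with(cohort$cohort[inc, ],
               data.frame(age = age, sex = as.numeric(sex == "F"),
                          motion_rms = motion_rms, total_gm = total_gm))
model <- fit_interaction_model(comp$pc1_scores, scores$brain_score,
                               cohort$cohort$group[inc], covars)
it <- model$terms[model$terms$term == "brain_score:group", ]
message("brain-score x group interaction: t = ", round(it$t, 2),
        ", p = ", signif(it$p, 2))

wg <- within_group_correlations(comp$pc1_scores, scores$brain_score,
                                cohort$cohort$group[inc])
message("post hoc: patients r = ", round(wg$r[wg$group == "AD_MCI"], 2),
        " (p = ", signif(wg$p[wg$group == "AD_MCI"], 2), "); controls r = ",
        round(wg$r[wg$group == "HC"], 2),
        " (p = ", signif(wg$p[wg$group == "HC"], 2), ")")

write.csv(model$terms, "results/second_level_terms.csv", row.names = FALSE)
write.csv(wg, "results/within_group_correlations.csv", row.names = FALSE)
write.csv(cohort_summary(cohort$cohort), "results/cohort_summary.csv",
          row.names = FALSE)
message("wrote results/second_level_terms.csv, ",
        "results/within_group_correlations.csv, results/cohort_summary.csv")
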