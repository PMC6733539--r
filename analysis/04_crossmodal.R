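#!/usr/bin/env Rscript

# Stage 4 — first-level cross-modal regression.
#
# Regresses the selected component's subject loadings on whole-brain
# connectivity with Ledoit-Wolf shrinkage regularization (after screening
# the loadings for outliers), reports structure coefficients and brain
# scores, validates the fit by
# 5-fold cross-validation repeated 1,000 times (median R), and assesses
# model- and connection-level significance by label permutation.

suppressPackageStartupMessages(library(inflammetry))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L

cohort <- read_cohort("results/cohort")
fc <- as.matrix(read.csv("results/connectivity_matrix.csv",
                         check.names = FALSE)[, -1])
loadings <- read.csv("results/sbi_loadings.csv")[, -1]
tests <- read.csv("results/sbi_component_tests.csv")
sel <- tests$component[tests$selected]

# covariates of no interest enter at the second level; the first level is
# fitted on the connectivity and loadings directly
res <- crossmodal_analysis(fc, loadings[[sel]], covariates = NULL,
                           config = cv_config(n_repeats = 1000L,
                                              seed = substream_seed(seed,
                                                                    "cv")),
                           n_perm = 5000L,
                           seed = substream_seed(seed, "cv_perm"))

message("in-sample r = ", round(res$insample_r, 2),
        "; cross-validated median R = ", round(res$cv_r_median, 2),
        " (permutation p = ", signif(res$model_p, 2), ")")
message(length(res$significant_connections),
        " connections survive FDR at 0.05")

write.csv(data.frame(label = names(res$structure_coefficients),
                     coefficient = res$coefficients,
                     structure_coefficient = res$structure_coefficients,
                     p_perm = res$structure_p, p_fdr = res$structure_p_fdr),
          "results/crossmodal_connections.csv", row.names = FALSE)
write.csv(data.frame(subject_id = cohort$cohort$subject_id[res$included],
                     brain_score = res$brain_scores),
          "results/brain_scores.csv", row.names = FALSE)
jsonlite::write_json(list(insample_r = res$insample_r,
                          cv_r_median = res$cv_r_median,
                          model_p = res$model_p,
                          shrinkage_rho = res$rho),
                     "results/crossmodal_summary.json",
                     auto_unbox = TRUE, digits = NA)
message("wrote results/crossmodal_*.csv/json, results/brain_scores.csv")
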