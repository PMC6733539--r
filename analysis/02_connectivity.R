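#!/usr/bin/env Rscript

# Stage 2 — clean node time-series and compute pairwise connectivity.
#
# One GLM per subject regresses out a linear trend together with a
# discrete-cosine stop-band basis (bandpass 0.0078-0.1 Hz performed
# simultaneously with nuisance regression), then Pearson correlations are
# taken over all 78 node pairs. Univariate group statistics (Fisher-z
# pooled t, FDR) are reported per connection.

suppressPackageStartupMessages(library(inflammetry))

cohort <- read_cohort("results/cohort")
tr <- cohort$truth$tr_seconds
tt <- ncol(cohort$series[[1]]$values)
design <- suppressMessages(build_nuisance_design(tt, tr))
message("design columns: ", ncol(design$regressors),
        " (", sum(design$labels == "dct"), " stop-band DCT)")

vectors <- lapply(cohort$series, function(ts)
  connectivity_vector(clean_timeseries(ts, design)))
fc <- inflammetry:::connectivity_matrix(vectors)
stats_tab <- group_connectivity_stats(vectors, cohort$cohort$group)

write.csv(data.frame(subject_id = cohort$cohort$subject_id, fc,
                     check.names = FALSE),
          "results/connectivity_matrix.csv", row.names = FALSE)
write.csv(stats_tab, "results/connectivity_group_stats.csv",
          row.names = FALSE)

sig <- stats_tab[stats_tab$p_fdr < 0.05, ]
message(nrow(sig), " of ", nrow(stats_tab),
        " connections differ between groups after FDR")
message("wrote results/connectivity_matrix.csv, ",
        "results/connectivity_group_stats.csv")
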