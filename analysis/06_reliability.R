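#!/usr/bin/env Rscript
# Stage 6 — test-retest reliability of the selected measures.
#
# ICC(2,1), SEM and minimal detectable change for every pruning
# survivor, from the PD group's paired test/retest sessions.

source(file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(FALSE), value = TRUE))), "common.R"))

coh <- load_cohort()
built <- build_ensemble(coh)
selected <- filter_by_smd(effect_size_table(built$ensemble), 0.5)
corr <- spearman_matrix(built$ensemble, selected$measure_id)
audit <- prune_redundant(selected, corr, built$catalogue, 0.70)

# observed pairs only: imputed test values carry no retest information
observed <- drop_high_missing_tasks(coh$table,
                                    build_default_catalogue(), 0.20)$table
rel <- reliability_table(observed, coh$retest, audit$survivors)
rel <- rel[order(-rel$icc), ]
utils::write.csv(rel, file.path(RESULTS, "reliability.csv"),
                 row.names = FALSE)

message("Reliability of the ", nrow(rel), " survivors:")
print(utils::head(rel, 8), digits = 3)
message(sprintf("ICC range: %.2f - %.2f", min(rel$icc), max(rel$icc)))
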