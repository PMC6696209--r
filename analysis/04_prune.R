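#!/usr/bin/env Rscript
# Stage 4 — redundancy pruning.
#
# Spearman cross-correlations among the SMD-passing measures, pooled
# over the completed datasets; pairs with |rho| > 0.70 are thinned by
# dropping dual-task twins, otherwise the less sensitive member, using
# a minimum-removal resolution.

source(file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(FALSE), value = TRUE))), "common.R"))

coh <- load_cohort()
built <- build_ensemble(coh)
selected <- filter_by_smd(effect_size_table(built$ensemble), 0.5)

corr <- spearman_matrix(built$ensemble, selected$measure_id)
audit <- prune_redundant(selected, corr, built$catalogue, 0.70)

utils::write.csv(as.data.frame(corr$rho),
                 file.path(RESULTS, "correlation_matrix.csv"))
utils::write.csv(audit$removed, file.path(RESULTS, "pruning_removed.csv"),
                 row.names = FALSE)
utils::write.csv(data.frame(measure_id = audit$survivors),
                 file.path(RESULTS, "survivors.csv"), row.names = FALSE)

print(audit)
message("Survivors: ", length(audit$survivors), " of ", nrow(selected))
print(audit$removed)
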