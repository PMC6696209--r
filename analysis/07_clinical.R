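#!/usr/bin/env Rscript
# Stage 7 — clinical validity of the selected measures.
#
# Spearman correlations of the survivors with dynamic balance
# (Mini-BEST) and balance confidence (ABC) over the pooled cohort, and
# with quality of life (PDQ-39) and disease severity (MDS-UPDRS) in the
# PD group; Benjamini-Hochberg control per scale, significance at
# adjusted p < 0.01.

source(file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(FALSE), value = TRUE))), "common.R"))

coh <- load_cohort()
built <- build_ensemble(coh)
selected <- filter_by_smd(effect_size_table(built$ensemble), 0.5)
corr <- spearman_matrix(built$ensemble, selected$measure_id)
audit <- prune_redundant(selected, corr, built$catalogue, 0.70)

assoc <- associate_clinical(built$ensemble$datasets[[1]], coh$clinical,
                            audit$survivors, alpha = 0.01)
utils::write.csv(as.data.frame(assoc),
                 file.path(RESULTS, "clinical_associations.csv"),
                 row.names = FALSE)

df <- as.data.frame(assoc)
message("Significant associations per scale (of ",
        length(audit$survivors), " measures):")
print(tapply(df$significant, df$scale, sum))
strongest <- df[order(-abs(df$rho)), ][1:5, ]
message("Strongest correlations:")
print(strongest[, c("measure_id", "scale", "rho", "p_adjusted")],
      digits = 3)
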