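#!/usr/bin/env Rscript
# Stage 1 — simulate the study cohort.
#
# Generates the default synthetic cohort: 144 PD + 79 control subjects,
# 93 balance measures in five domains with planted group effects
# (Gait > APA > Sway > APR > LOS), domain-blocked correlations, 20
# planted redundant measure pairs, condition-specific missingness, a
# retest session for the PD group, and latent-factor clinical scales.

source(file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(FALSE), value = TRUE))), "common.R"))

cfg <- study_config()
coh <- generate_cohort(cfg)

dir.create(COHORT_DIR, recursive = TRUE, showWarnings = FALSE)
write_cohort_csv(coh, COHORT_DIR)
write_catalogue_csv(cfg$catalogue, file.path(COHORT_DIR, "catalogue.csv"))

mt <- missingness_by_task(coh$table, cfg$catalogue)
utils::write.csv(mt, file.path(RESULTS, "missingness_by_task.csv"),
                 row.names = FALSE)

message("Cohort: ", sum(coh$table$group == "PD"), " PD + ",
        sum(coh$table$group == "HC"), " HC, ",
        ncol(coh$table$values), " measures")
message("Planted: ", length(planted_sensitive(cfg)), " sensitive, ",
        length(planted_independent(cfg)), " independent")
message("Missing cells: ", sum(is.na(coh$table$values)))
print(mt[mt$frac_all > 0, ])
message("Wrote ", COHORT_DIR, "/")
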