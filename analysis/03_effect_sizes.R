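#!/usr/bin/env Rscript
# Stage 3 — standardized mean differences and the sensitivity filter.
#
# Computes per-measure SMDs between PD and controls, pooled over the 25
# completed datasets, and retains measures with |SMD| > 0.5 (at least a
# moderate group difference).

source(file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(FALSE), value = TRUE))), "common.R"))

coh <- load_cohort()
built <- build_ensemble(coh)

effects <- effect_size_table(built$ensemble)
effects$magnitude <- as.character(classify_smd(effects$smd))
selected <- filter_by_smd(effects, 0.5)

utils::write.csv(effects, file.path(RESULTS, "effect_sizes.csv"),
                 row.names = FALSE)
utils::write.csv(as.data.frame(selected),
                 file.path(RESULTS, "smd_selected.csv"), row.names = FALSE)

message(nrow(selected), " of ", nrow(effects),
        " measures pass |SMD| > 0.5")
print(utils::head(selected[, c("measure_id", "smd", "abs_smd")], 8))
dom <- table(sub("\\..*", "", selected$measure_id))
message("Selected measures by task: ",
        paste(names(dom), dom, sep = "=", collapse = ", "))
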