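# Shared plumbing for the numbered analysis scripts: fixed seeds, output
# locations, and reconstruction of the imputed ensemble from the saved
# cohort (imputation is fully seeded, so downstream scripts re-derive it
# instead of serializing 25 datasets).

library(balanceselect)

SEED <- 20260926L      # master analysis seed
RESULTS <- "results"
COHORT_DIR <- file.path(RESULTS, "cohort")

study_config <- function() default_study_config(seed = SEED + 101L)

load_cohort <- function() {
  stopifnot(file.exists(file.path(COHORT_DIR, "measures_test.csv")))
  list(
    table = read_measure_table(file.path(COHORT_DIR, "measures_test.csv")),
    retest = read_measure_table(file.path(COHORT_DIR,
                                          "measures_retest.csv")),
    clinical = utils::read.csv(file.path(COHORT_DIR, "clinical.csv"))
  )
}

# stages up to the completed ensemble (task removal -> worst-case
# imputation -> multiple imputation, m = 25)
build_ensemble <- function(cohort, cat = build_default_catalogue()) {
  d <- drop_high_missing_tasks(cohort$table, cat, 0.20)
  wc <- impute_worst_case(d$table, d$catalogue)
  list(ensemble = impute_multiple(wc, m = 25, seed = SEED + 202L),
       catalogue = d$catalogue, removed = d$removed_tasks)
}
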