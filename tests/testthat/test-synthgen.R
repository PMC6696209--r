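test_that("default study configuration carries the study conditions", {
  cfg <- default_study_config()
  expect_equal(cfg$n_pd, 144L)
  expect_equal(cfg$n_hc, 79L)
  ms <- cfg$missingness_spec
  expect_equal(ms$rate[ms$task == "ECFoam" & ms$group == "PD"], 0.389)
  expect_equal(ms$rate[ms$task == "ECFoam" & ms$group == "HC"], 0.114)
  expect_equal(ms$rate[ms$task == "EOFoam" & ms$group == "PD"], 0.139)
  expect_equal(sum(ms$rate[ms$task == "PushRelease" & ms$group == "PD"]),
               0.139)
  expect_equal(sum(ms$rate[ms$task == "APA_DT" & ms$group == "PD"]), 0.125)
  expect_equal(unname(cfg$retest_icc["Gait_ST.Turn_velocity"]), 0.95)
  expect_equal(unname(cfg$retest_icc["Gait_ST.Foot_strike_angle"]), 0.97)
  expect_equal(unname(cfg$retest_icc["Gait_ST.Arm_ROM"]), 0.96)
  expect_equal(unname(cfg$retest_icc["APA_ST.First_step_ROM"]), 0.82)
  # planted selection structure: 44 sensitive, 20 redundant, 24 independent
  expect_length(planted_sensitive(cfg), 44)
  expect_length(planted_independent(cfg), 24)
  expect_equal(nrow(cfg$redundancy), 20)
  expect_true(all(cfg$smd_profile[planted_sensitive(cfg)] >= 1.0))
  expect_true(all(cfg$smd_profile[cfg$catalogue$domain == "LOS"] < 0.3))
  # domain ordering of mean planted sensitivity
  sens <- planted_sensitive(cfg)
  dom <- as.character(cfg$catalogue$domain[match(sens,
                                                 cfg$catalogue$measure_id)])
  m <- tapply(cfg$smd_profile[sens], dom, mean)
  expect_true(m["Gait"] > m["APA"] && m["APA"] > m["Sway"] &&
                m["Sway"] > m["APR"])
})

test_that("invalid configurations are rejected before sampling", {
  expect_error(synth_config(cross_block_correlation = 0.5),
               "positive-definite")
  expect_error(synth_config(block_correlation = c(Sway = 1, APA = .2,
                                                  APR = .2, Gait = .2,
                                                  LOS = .2)),
               "\\[0, 1\\)")
  expect_error(synth_config(retest_icc_default = 0), "ICC")
  expect_error(synth_config(smd_profile = c(nonexistent = 1)),
               "nonexistent")
})

test_that("generation is bit-identical under a fixed seed", {
  cfg <- default_study_config(seed = 11)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$table$values, b$table$values)
  expect_identical(a$table$miss_code, b$table$miss_code)
  expect_identical(a$retest_table$values, b$retest_table$values)
  expect_identical(a$clinical, b$clinical)
  cfg2 <- default_study_config(seed = 12)
  expect_false(identical(generate_cohort(cfg2)$table$values,
                         a$table$values))
})

test_that("cohort shape, missingness rates and informative masking", {
  cfg <- default_study_config(seed = 21)
  coh <- generate_cohort(cfg)
  expect_equal(nrow(coh$table$values), 223)
  expect_equal(nrow(coh$retest_table$values), 144)
  mt <- missingness_by_task(coh$table, cfg$catalogue)
  expect_equal(mt$frac_pd[mt$task == "ECFoam"], 0.389, tolerance = 0.01)
  expect_equal(mt$frac_hc[mt$task == "ECFoam"], 0.114, tolerance = 0.01)
  expect_equal(mt$frac_pd[mt$task == "APA_DT"], 0.125, tolerance = 0.01)
  expect_equal(mt$frac_all[mt$task == "Gait_ST"], 0)
  # fall-category masking hits the most impaired subjects of the group
  pd <- coh$table$group == "PD"
  masked <- is.na(coh$table$values[, "ECFoam.RMS_ML"]) & pd
  expect_gt(mean(coh$truth$latent[masked]),
            mean(coh$truth$latent[pd & !masked]))
  # every missing cell is coded, every observed cell is 'Observed'
  expect_identical(unname(is.na(coh$table$values)),
                   unname(coh$table$miss_code != "Observed"))
})

test_that("a null configuration produces centred effect sizes", {
  cfg <- synth_config(seed = 31)   # all planted SMDs zero, no missingness
  coh <- generate_cohort(cfg)
  es <- effect_size_table(coh$table)
  expect_lt(abs(mean(es$smd)), 0.05)
  expect_lt(max(abs(es$smd)), 4 * sqrt(1 / 144 + 1 / 79))
})

test_that("planted group effects are recovered across replicate cohorts", {
  # Monte-Carlo over replicate cohorts of the study size: the mean
  # empirical SMD of a measure planted at 1.0 is within +/-0.05
  ids <- c("Gait_ST.Gait_speed", "EOFoam.RMS_ML")
  est <- matrix(NA_real_, 100, 2)
  for (r in 1:100) {
    cfg <- synth_config(smd_profile = stats::setNames(c(1, 1), ids),
                        seed = 4000 + r)
    coh <- generate_cohort(cfg)
    es <- effect_size_table(coh$table)
    est[r, ] <- es$abs_smd[match(ids, es$measure_id)]
  }
  expect_equal(mean(est[, 1]), 1.0, tolerance = 0.05)
  expect_equal(mean(est[, 2]), 1.0, tolerance = 0.05)
})

test_that("planted parameters are recovered at large n", {
  ids <- c("Gait_ST.Gait_speed", "Gait_ST.Stride_length",
           "EOFoam.RMS_ML", "EOFoam.RMS_AP",
           "APA_ST.First_step_ROM", "LOS.Forward_range")
  prof <- stats::setNames(c(1.0, 0.8, 0.6, 1.2, 0.9, 0.0), ids)
  cfg <- synth_config(n_pd = 10000, n_hc = 10000, smd_profile = prof,
                      redundancy = data.frame(
                        redundant_id = "EOFoam.Jerk_ML",
                        partner_id = "EOFoam.RMS_ML", rho = 0.85),
                      retest_icc = c(Gait_ST.Gait_speed = 0.9),
                      seed = 41)
  coh <- generate_cohort(cfg)
  es <- effect_size_table(coh$table)
  err <- es$abs_smd[match(ids, es$measure_id)] - abs(prof)
  expect_lt(mean(abs(err)), 0.02)
  expect_lt(max(abs(err)), 0.06)

  # within-domain and planted-pair Spearman correlations approach the
  # rank-scale image of the planted Pearson values (Greiner's relation
  # rho_s = 6/pi * asin(rho/2) for the Gaussian copula)
  pd <- coh$table$group == "PD"
  v <- coh$table$values[pd, c("EOFoam.RMS_ML", "EOFoam.RMS_AP",
                              "EOFoam.Jerk_ML", "Gait_ST.Gait_speed")]
  sp <- stats::cor(v, method = "spearman")
  expect_lt(abs(sp[1, 2] - 6 / pi * asin(0.25 / 2)), 0.02)
  expect_lt(abs(sp[1, 3] - 6 / pi * asin(0.85 / 2)), 0.02)
  expect_lt(abs(abs(sp[1, 4]) - 6 / pi * asin(0.15 / 2)), 0.02)

  # planted retest reliability
  m <- cbind(coh$table$values[pd, "Gait_ST.Gait_speed"],
             coh$retest_table$values[, "Gait_ST.Gait_speed"])
  expect_lt(abs(icc_two_way(m) - 0.9), 0.02)
})

test_that("planted retest ICC is recovered at the study size", {
  cfg <- synth_config(retest_icc = c(Gait_ST.Turn_velocity = 0.95),
                      seed = 51)
  coh <- generate_cohort(cfg)
  pd <- coh$table$group == "PD"
  m <- cbind(coh$table$values[pd, "Gait_ST.Turn_velocity"],
             coh$retest_table$values[, "Gait_ST.Turn_velocity"])
  expect_equal(icc_two_way(m), 0.95, tolerance = 0.05)
})

test_that("cohort CSV export round-trips the test table", {
  cfg <- default_study_config(seed = 61)
  coh <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort_csv(coh, dir)
  back <- read_measure_table(file.path(dir, "measures_test.csv"))
  expect_equal(back$values, coh$table$values)
  expect_equal(back$miss_code, coh$table$miss_code)
  expect_equal(as.character(back$group), as.character(coh$table$group))
})
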