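test_that("tasks exceeding the missingness threshold are removed", {
  cfg <- default_study_config(seed = 71)
  coh <- generate_cohort(cfg)
  res <- drop_high_missing_tasks(coh$table, cfg$catalogue, 0.20)
  expect_equal(res$removed_tasks$task, "ECFoam")
  expect_equal(nrow(res$catalogue), 86)
  expect_equal(ncol(res$table$values), 86)
  # a complete table is untouched
  tab <- make_toy_table(matrix(rnorm(40), 10, 4))
  cat4 <- make_toy_catalogue(paste0("t", 1:4))
  colnames(tab$values) <- colnames(tab$miss_code) <- cat4$measure_id
  res2 <- drop_high_missing_tasks(tab, cat4, 0.2)
  expect_equal(nrow(res2$removed_tasks), 0)
  expect_equal(ncol(res2$table$values), 4)
  # near-zero threshold removes any task with any missingness
  res3 <- drop_high_missing_tasks(coh$table, cfg$catalogue, 1e-9)
  expect_true(all(c("ECFoam", "EOFoam", "PushRelease", "APA_DT") %in%
                    res3$removed_tasks$task))
})

test_that("worst-case imputation lands 2 SD beyond the observed extreme", {
  # higher-is-worse measure, observed {1,2,3}: SD 1, anchor 3 + 2 = 5
  vals <- cbind(hi = c(1, 2, 3, NA), lo = c(10, 12, 14, NA))
  miss <- matrix("Observed", 4, 2, dimnames = dimnames(vals))
  miss[4, ] <- c("A_Fall", "D_NoAPA")
  vals2 <- vals
  tab <- measure_table(vals, rep(c("PD", "HC"), 2), miss_code = miss)
  cat2 <- new_catalogue(c("hi", "lo"), c("Gait", "Gait"),
                        c("Gait_ST", "Gait_ST"),
                        c("higher_is_worse", "lower_is_worse"))
  colnames(tab$values) <- colnames(tab$miss_code) <- cat2$measure_id
  out <- impute_worst_case(tab, cat2)
  expect_equal(unname(out$values[4, 1]), 3 + 2 * 1)
  expect_equal(unname(out$values[4, 2]), 10 - 2 * 2)
  expect_false(anyNA(out$values))
  # no A/D cells: identity
  tab0 <- make_toy_table(matrix(rnorm(20), 5, 4))
  cat0 <- make_toy_catalogue(paste0("t", 1:4))
  colnames(tab0$values) <- colnames(tab0$miss_code) <- cat0$measure_id
  expect_identical(impute_worst_case(tab0, cat0)$values, tab0$values)
})

test_that("worst-case cells sit exactly 2 observed SDs past the extreme", {
  cfg <- default_study_config(seed = 81)
  coh <- generate_cohort(cfg)
  d <- drop_high_missing_tasks(coh$table, cfg$catalogue, 0.2)
  out <- impute_worst_case(d$table, d$catalogue)
  dirs <- stats::setNames(d$catalogue$impairment_direction,
                          d$catalogue$measure_id)
  for (id in c("EOFoam.RMS_ML", "PushRelease.Step_latency")) {
    cells <- d$table$miss_code[, id] == "A_Fall"
    obs <- d$table$values[!is.na(d$table$values[, id]), id]
    expected <- if (dirs[id] == "higher_is_worse")
      max(obs) + 2 * sd(obs) else min(obs) - 2 * sd(obs)
    expect_true(all(out$values[cells, id] == expected))
    expect_gt(sum(cells), 0)
  }
})

test_that("multiple imputation is seeded, varied across draws, and
           degenerate without stochastic cells", {
  cfg <- default_study_config(seed = 91)
  coh <- generate_cohort(cfg)
  d <- drop_high_missing_tasks(coh$table, cfg$catalogue, 0.2)
  wc <- impute_worst_case(d$table, d$catalogue)
  ens <- impute_multiple(wc, m = 5, seed = 17)
  expect_length(ens$datasets, 5)
  expect_false(any(vapply(ens$datasets, function(t) anyNA(t$values), NA)))
  # reproducible from the seed
  ens2 <- impute_multiple(wc, m = 5, seed = 17)
  expect_identical(lapply(ens$datasets, `[[`, "values"),
                   lapply(ens2$datasets, `[[`, "values"))
  # imputed (track-2) cells vary across datasets
  mi_cells <- which(wc$miss_code != "Observed", arr.ind = TRUE)
  sds <- apply(mi_cells, 1, function(rc) {
    sd(vapply(ens$datasets, function(t) t$values[rc[1], rc[2]], 0))
  })
  expect_gt(mean(sds > 0), 0.99)
  # observed cells never change
  keep <- !is.na(wc$values)
  for (t in ens$datasets) expect_equal(t$values[keep], wc$values[keep])
  # without stochastic cells the ensemble is m identical copies
  tab0 <- make_toy_table(matrix(rnorm(40), 10, 4))
  ens0 <- impute_multiple(tab0, m = 3, seed = 1)
  expect_identical(ens0$datasets[[1]]$values, tab0$values)
  expect_identical(ens0$datasets[[2]]$values, tab0$values)
})

test_that("multiple imputation refuses unprocessed worst-case cells and
           empty measures", {
  vals <- matrix(rnorm(20), 5, 4,
                 dimnames = list(NULL, paste0("m", 1:4)))
  miss <- matrix("Observed", 5, 4, dimnames = dimnames(vals))
  vals[2, 1] <- NA; miss[2, 1] <- "A_Fall"
  tab <- measure_table(vals, rep(c("PD", "HC"), length.out = 5),
                       miss_code = miss)
  expect_error(impute_multiple(tab, m = 2), "worst-case")
  vals2 <- matrix(rnorm(20), 5, 4,
                  dimnames = list(NULL, paste0("m", 1:4)))
  miss2 <- matrix("Observed", 5, 4, dimnames = dimnames(vals2))
  vals2[, 2] <- NA; miss2[, 2] <- "B_Skip"
  tab2 <- measure_table(vals2, rep(c("PD", "HC"), length.out = 5),
                        miss_code = miss2)
  expect_error(impute_multiple(tab2, m = 2), "entirely missing")
})

test_that("pooling averages element-wise and flags shape mismatches", {
  # two toy datasets differing in one cell by 2: pooled per-measure mean
  # is offset by 1/n_subjects
  v1 <- matrix(1:12 * 1.0, 4, 3, dimnames = list(NULL, paste0("m", 1:3)))
  v2 <- v1; v2[1, 1] <- v2[1, 1] + 2
  g <- rep(c("PD", "HC"), 2)
  ens <- structure(list(datasets = list(make_toy_table(v1, g),
                                        make_toy_table(v2, g)),
                        provenance = NULL),
                   class = "imputed_ensemble")
  pooled <- pool_over_ensemble(function(t) colMeans(t$values), ens)
  expect_equal(unname(pooled$mean["m1"] - mean(v1[, "m1"])), 1 / 4 * 2 / 2)
  expect_equal(unname(pooled$mean["m2"]), mean(v1[, "m2"]))
  expect_equal(unname(pooled$sd["m2"]), 0)
  # identical datasets pool to the single-dataset statistic with SD 0
  ens_same <- structure(list(datasets = list(make_toy_table(v1, g),
                                             make_toy_table(v1, g))),
                        class = "imputed_ensemble")
  pooled_same <- pool_over_ensemble(function(t) colMeans(t$values), ens_same)
  expect_equal(pooled_same$mean, colMeans(v1))
  expect_true(all(pooled_same$sd == 0))
  # pooling is linear: pooled mean of a linear statistic equals the
  # statistic of the element-wise pooled data
  pooled_vals <- (v1 + v2) / 2
  expect_equal(pooled$mean, colMeans(pooled_vals))
  bad <- structure(list(datasets = list(make_toy_table(v1, g),
                                        make_toy_table(v1[, 1:2], g))),
                   class = "imputed_ensemble")
  expect_error(pool_over_ensemble(function(t) colMeans(t$values), bad),
               "shape")
})
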