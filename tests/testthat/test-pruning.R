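test_that("spearman_matrix is rank-based and matches the d^2 oracle", {
  set.seed(12)
  x <- rnorm(40)
  vals <- cbind(x = x, ex = exp(x), neg = -x, other = rnorm(40))
  tab <- make_toy_table(vals)
  sp <- spearman_matrix(tab)
  expect_equal(sp$rho["x", "ex"], 1)      # monotone transform
  expect_equal(sp$rho["x", "neg"], -1)    # order reversal
  expect_true(isSymmetric(sp$rho))
  expect_equal(unname(diag(sp$rho)), rep(1, 4))
  # the 5-point vector against the brute-force rank-difference formula
  x5 <- c(1, 2, 3, 4, 5); y5 <- c(3, 1, 2, 5, 4)
  tab5 <- make_toy_table(cbind(a = x5, b = y5))
  expect_equal(spearman_matrix(tab5)$rho["a", "b"],
               oracle_spearman(x5, y5), tolerance = 1e-12)
  expect_equal(oracle_spearman(x5, y5), 1 - 6 * 8 / (5 * 24))
  # constant column is refused by name
  tabc <- make_toy_table(cbind(ok = rnorm(10), flat = rep(1, 10)))
  expect_error(spearman_matrix(tabc), "flat")
})

test_that("spearman_matrix pools an ensemble element-wise", {
  set.seed(13)
  v1 <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  v2 <- v1; v2[, 3] <- rnorm(20)
  ens <- structure(list(datasets = list(make_toy_table(v1),
                                        make_toy_table(v2))),
                   class = "imputed_ensemble")
  pooled <- spearman_matrix(ens)
  m1 <- spearman_matrix(ens$datasets[[1]])$rho
  m2 <- spearman_matrix(ens$datasets[[2]])$rho
  expect_equal(pooled$rho, (m1 + m2) / 2)
})

test_that("a single violating pair drops the rule-designated member", {
  ids <- c("Gait_ST.b1", "Gait_ST.b2")
  rho <- matrix(c(1, .9, .9, 1), 2, dimnames = list(ids, ids))
  cat <- make_toy_catalogue(c("b1", "b2"))
  effects <- data.frame(measure_id = ids, abs_smd = c(1.0, 0.6))
  corr <- structure(list(measure_ids = ids, rho = rho),
                    class = "correlation_matrix")
  audit <- prune_redundant(effects, corr, cat, 0.7)
  expect_equal(audit$survivors, "Gait_ST.b1")
  expect_equal(audit$removed$removed_id, "Gait_ST.b2")
  expect_equal(audit$removed$rule_applied, "smaller_smd")
  expect_equal(audit$removed$rho, 0.9)
})

test_that("the dual-task twin is dropped even when it has the larger SMD", {
  cat <- make_toy_catalogue(c("b1", "b1"), c("Gait_ST", "Gait_DT"))
  ids <- cat$measure_id
  rho <- matrix(c(1, .8, .8, 1), 2, dimnames = list(ids, ids))
  effects <- data.frame(measure_id = ids,
                        abs_smd = ifelse(grepl("DT", ids), 1.2, 0.8))
  corr <- structure(list(measure_ids = ids, rho = rho),
                    class = "correlation_matrix")
  audit <- prune_redundant(effects, corr, cat, 0.7)
  expect_equal(audit$survivors, "Gait_ST.b1")
  expect_equal(audit$removed$rule_applied, "dual_task")
})

test_that("pruning takes the minimum-removal solution on chains", {
  # pairs (a,b) -> drop b and (b,c) -> drop c with rho(b,c) > rho(a,b):
  # removing b alone resolves both; a severity-ordered greedy pass would
  # remove both b and c
  ids <- c("Gait_ST.a", "Gait_ST.b", "Gait_ST.c")
  rho <- diag(3); dimnames(rho) <- list(ids, ids)
  rho["Gait_ST.a", "Gait_ST.b"] <- rho["Gait_ST.b", "Gait_ST.a"] <- 0.75
  rho["Gait_ST.b", "Gait_ST.c"] <- rho["Gait_ST.c", "Gait_ST.b"] <- 0.9
  cat <- make_toy_catalogue(c("a", "b", "c"))
  effects <- data.frame(measure_id = ids, abs_smd = c(1.0, 0.8, 0.6))
  corr <- structure(list(measure_ids = ids, rho = rho),
                    class = "correlation_matrix")
  audit <- prune_redundant(effects, corr, cat, 0.7)
  expect_equal(audit$survivors, c("Gait_ST.a", "Gait_ST.c"))
  expect_equal(audit$removed$removed_id, "Gait_ST.b")
})

test_that("pruning matches the exhaustive rule-respecting search on toys", {
  for (s in 1:40) {
    inst <- random_prune_instance(s)
    audit <- prune_redundant(inst$effects, inst$corr, inst$cat, 0.7)
    expect_equal(sort(audit$survivors),
                 oracle_prune_exhaustive(inst$ids, inst$rho, inst$cat,
                                         inst$smd, 0.7),
                 info = paste("instance seed", s))
  }
})

test_that("pruning output is deterministic and leaves no violation", {
  inst <- random_prune_instance(99)
  a1 <- prune_redundant(inst$effects, inst$corr, inst$cat, 0.7)
  a2 <- prune_redundant(inst$effects, inst$corr, inst$cat, 0.7)
  expect_identical(a1$survivors, a2$survivors)
  expect_identical(a1$removed, a2$removed)
  surv <- a1$survivors
  sub <- inst$rho[surv, surv, drop = FALSE]
  expect_true(all(abs(sub[upper.tri(sub)]) <= 0.7))
  # audit partitions the input set
  expect_setequal(c(a1$survivors, a1$removed$removed_id), inst$ids)
  # mismatched ids are refused
  expect_error(prune_redundant(inst$effects[-1, ], inst$corr, inst$cat),
               "different measure ids")
})
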