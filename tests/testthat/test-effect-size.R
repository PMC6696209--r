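test_that("smd matches the arithmetic oracles on frozen and random input", {
  # equal means: zero for either variant
  expect_equal(smd(3, 1, 20, 3, 2, 30), 0)
  expect_equal(smd(3, 1, 20, 3, 2, 30, variant = "cohen_pooled"), 0)
  # unit case: equal n and SD give S = 1
  expect_equal(smd(1, 1, 50, 0, 1, 50), 1.0)
  expect_equal(smd(1, 1, 50, 0, 1, 50, variant = "cohen_pooled"), 1.0)
  # the published cohort's dynamic-balance summary (control mean 24.0,
  # SD 2.6, n 79; PD mean 18.5, SD 4.8, n 144) against the longhand
  # pooled-SD oracle
  expect_equal(smd(24.0, 2.6, 79, 18.5, 4.8, 144, "cohen_pooled"),
               oracle_smd_cohen(24.0, 2.6, 79, 18.5, 4.8, 144),
               tolerance = 1e-12)
  set.seed(7)
  for (i in 1:50) {
    m1 <- rnorm(1); m2 <- rnorm(1)
    s1 <- runif(1, .1, 5); s2 <- runif(1, .1, 5)
    n1 <- sample(2:500, 1); n2 <- sample(2:500, 1)
    expect_equal(smd(m1, s1, n1, m2, s2, n2),
                 oracle_smd_paper(m1, s1, n1, m2, s2, n2),
                 tolerance = 1e-12)
    expect_equal(smd(m1, s1, n1, m2, s2, n2, "cohen_pooled"),
                 oracle_smd_cohen(m1, s1, n1, m2, s2, n2),
                 tolerance = 1e-12)
  }
  expect_error(smd(1, 0, 10, 2, 0, 10), "degenerate")
})

test_that("smd is antisymmetric, scale invariant, and variant-stable", {
  set.seed(8)
  for (i in 1:20) {
    m1 <- rnorm(1); m2 <- rnorm(1)
    s1 <- runif(1, .5, 3); s2 <- runif(1, .5, 3)
    n1 <- sample(10:300, 1); n2 <- sample(10:300, 1)
    # antisymmetry, exactly
    expect_identical(smd(m1, s1, n1, m2, s2, n2),
                     -smd(m2, s2, n2, m1, s1, n1))
    # scale invariance, exactly up to floating point
    c0 <- runif(1, 0.1, 10)
    expect_equal(smd(c0 * m1, c0 * s1, n1, c0 * m2, c0 * s2, n2),
                 smd(m1, s1, n1, m2, s2, n2), tolerance = 1e-12)
  }
  # variants coincide at equal n and SD
  expect_equal(smd(2, 1.3, 80, 1, 1.3, 80),
               smd(2, 1.3, 80, 1, 1.3, 80, "cohen_pooled"),
               tolerance = 1e-12)
  # at unequal group sizes the two denominators weight the group SDs
  # oppositely (S_paper^2 = (n2 SD1^2 + n1 SD2^2)/(n1+n2) versus Cohen's
  # own-n weighting), so agreement degrades with the SD ratio: a few
  # percent near SD1 = SD2, ~20% at SD ratio 2 for the 144/79 design
  set.seed(9)
  for (i in 1:20) {
    s1 <- runif(1, 1, 1.1); s2 <- 1
    a <- smd(1, s1, 144, 0, s2, 79)
    b <- smd(1, s1, 144, 0, s2, 79, "cohen_pooled")
    expect_lt(abs(a - b) / abs(b), 0.03)
  }
  expect_equal(smd(1, 2, 144, 0, 1, 79),
               oracle_smd_paper(1, 2, 144, 0, 1, 79))
  expect_lt(abs(smd(1, 2, 144, 0, 1, 79) /
                  smd(1, 2, 144, 0, 1, 79, "cohen_pooled") - 1), 0.25)
})

test_that("SMD magnitudes are classified with the conventional cuts", {
  expect_equal(as.character(classify_smd(c(0, 0.19, 0.20, 0.499, 0.50,
                                           0.799, 0.80, -0.95))),
               c("negligible", "negligible", "small", "small", "moderate",
                 "moderate", "large", "large"))
})

test_that("filter_by_smd thresholds absolute pooled effects", {
  vals <- cbind(strong = c(rnorm(60, 2), rnorm(40, 0)),
                null = rnorm(100))
  tab <- make_toy_table(vals, rep(c("PD", "HC"), c(60, 40)))
  sel <- filter_by_smd(tab, 0.5)
  expect_equal(sel$measure_id, "strong")
  expect_true(all(sel$passes_threshold))
  # threshold 0 retains everything, sorted by decreasing |SMD|
  all_sel <- filter_by_smd(tab, 0)
  expect_equal(nrow(all_sel), 2)
  expect_equal(all_sel$abs_smd, sort(all_sel$abs_smd, decreasing = TRUE))
  # a negatively oriented measure passes on magnitude
  vals2 <- cbind(neg = c(rnorm(60, -2), rnorm(40, 0)))
  tab2 <- make_toy_table(vals2, rep(c("PD", "HC"), c(60, 40)))
  sel2 <- filter_by_smd(tab2, 0.5)
  expect_equal(sel2$measure_id, "neg")
  expect_lt(sel2$smd, 0)
})

test_that("effect sizes pool over an imputed ensemble by averaging", {
  set.seed(10)
  vals <- matrix(rnorm(200), 50, 4,
                 dimnames = list(NULL, paste0("m", 1:4)))
  g <- rep(c("PD", "HC"), 25)
  shift <- vals; shift[, 1] <- shift[, 1] + 0.1
  ens <- structure(list(datasets = list(make_toy_table(vals, g),
                                        make_toy_table(shift, g))),
                   class = "imputed_ensemble")
  pooled <- effect_size_table(ens)
  e1 <- effect_size_table(ens$datasets[[1]])
  e2 <- effect_size_table(ens$datasets[[2]])
  expect_equal(pooled$smd, (e1$smd + e2$smd) / 2)
  expect_equal(pooled$mean_pd, (e1$mean_pd + e2$mean_pd) / 2)
})
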