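test_that("within-sex z-scores have per-sex mean 0 and SD 1", {
  set.seed(1)
  sex <- rep(c("M", "F"), c(40, 30))
  x <- rnorm(70, ifelse(sex == "M", 100, 80), 10)
  z <- sex_zscore(x, sex)
  for (s in c("M", "F")) {
    expect_equal(mean(z[sex == s]), 0, tolerance = 1e-12)
    expect_equal(sd(z[sex == s]), 1, tolerance = 1e-12)
  }
  # single-sex input reduces to a plain z-score
  xm <- x[sex == "M"]
  expect_equal(sex_zscore(xm, rep("M", 40)),
               as.numeric(scale(xm)), tolerance = 1e-12)
  expect_error(sex_zscore(rep(1, 10), rep(c("M", "F"), 5)), "zero")
})

test_that("standardisation removes the sex main effect", {
  set.seed(2)
  sex <- rep(c("M", "F"), each = 25)
  x <- rnorm(50, ifelse(sex == "M", 120, 90), 15)
  z <- sex_zscore(x, sex)
  tt <- t.test(z[sex == "M"], z[sex == "F"], var.equal = TRUE)
  expect_equal(unname(tt$statistic), 0, tolerance = 1e-10)
  expect_equal(tt$p.value, 1, tolerance = 1e-10)
  # a null genotype association on standardised values stays uniform
  set.seed(3)
  pvals <- replicate(300, {
    g <- rbinom(50, 2, 0.5)
    fit <- fit_diplotype_regression(sex_zscore(rnorm(50,
      ifelse(sex == "M", 120, 90), 15), sex), g, sex)
    fit$p_value[fit$term == "genotype"]
  })
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("regression: perfect fit, collinearity error, listwise deletion", {
  g <- c(0, 1, 2, 0, 1, 2, 1, 0)
  fit <- suppressWarnings(fit_diplotype_regression(g, g))
  expect_equal(fit$beta[fit$term == "genotype"], 1, tolerance = 1e-12)
  expect_lt(sum(residuals(attr(fit, "fit"))^2), 1e-20)

  expect_error(
    fit_diplotype_regression(rnorm(6), rep(1, 6), rep("F", 6)),
    "collinear|rank")

  y <- c(rnorm(7), NA)
  fit2 <- fit_diplotype_regression(y, g)
  expect_equal(attr(fit2, "n_used"), 7L)
})

test_that("OLS matches the normal-equations oracle to 1e-9", {
  set.seed(13)
  g <- rbinom(6 * 6, 2, 0.5)
  sex <- rep(c("M", "F"), 18)
  y <- 2 + 0.8 * g + 1.5 * (sex == "M") + rnorm(36)
  fit <- fit_diplotype_regression(y, g, sex)
  X <- cbind(1, g, sex == "M")
  orc <- oracle_ols(X, y)
  expect_equal(fit$beta, orc$beta[c(1, 2, 3)], tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(fit$se, unname(orc$se), tolerance = 1e-9)
  expect_equal(fit$t_stat, orc$t_stat, tolerance = 1e-9)
  expect_equal(fit$p_value, orc$p, tolerance = 1e-9)
})

test_that("carrier-coded regression reproduces the pooled two-sample t", {
  set.seed(23)
  copies <- rep(c(0, 1, 2), c(12, 8, 5))
  y <- rnorm(25, 50 + 5 * (copies > 0), 8)
  fit <- fit_diplotype_regression(y, copies, coding = "carrier")
  tt <- t.test(y[copies > 0], y[copies == 0], var.equal = TRUE)
  g <- fit[fit$term == "genotype", ]
  expect_equal(abs(g$t_stat), abs(unname(tt$statistic)),
               tolerance = 1e-9)
  expect_equal(g$p_value, tt$p.value, tolerance = 1e-9)
  # ANOVA F on the two-group factor equals t squared
  f_stat <- summary(aov(y ~ factor(copies > 0)))[[1]]$`F value`[1]
  expect_equal(f_stat, unname(tt$statistic)^2, tolerance = 1e-9)
})

test_that("groupwise t tests: identical groups, null calibration, power", {
  x <- rnorm(20)
  d <- data.frame(v = c(x, x), group = rep(c("aa", "b-carrier"), each = 20))
  res <- groupwise_tests(d, "v")
  expect_equal(res$t_stat, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1, tolerance = 1e-12)

  set.seed(31)
  null_p <- replicate(1000, {
    d <- data.frame(v = rnorm(24),
                    group = rep(c("aa", "b-carrier"), each = 12))
    groupwise_tests(d, "v")$p_value
  })
  expect_gt(ks.test(null_p, "punif")$p.value, 0.01)

  power_hits <- replicate(400, {
    d <- data.frame(v = c(rnorm(10), rnorm(10, 2)),
                    group = rep(c("aa", "b-carrier"), each = 10))
    groupwise_tests(d, "v")$p_value < 0.05
  })
  expect_gt(mean(power_hits), 0.95)
})

test_that("groupwise tests flag too-small strata instead of failing", {
  d <- data.frame(v = rnorm(6), sex = c("F", rep("M", 5)),
                  group = c("aa", "aa", "aa", rep("b-carrier", 3)))
  res <- groupwise_tests(d, "v", stratify_by_sex = TRUE)
  f_row <- res[res$stratum == "F", ]
  expect_true(is.na(f_row$t_stat))
  expect_equal(f_row$note, "sample too small")
})

test_that("threshold correlation is plain Pearson r", {
  expect_equal(threshold_correlation(1:8, 1:8), 1)
  expect_equal(threshold_correlation(1:8, 8:1), -1)
  thr <- c(2, 5, 3, 7, 1, 4, 6, 2)
  code <- c(0, 2, 1, 2, 0, 1, 2, 1)
  hand <- sum((thr - mean(thr)) * (code - mean(code))) /
    ((length(thr) - 1) * sd(thr) * sd(code))
  expect_equal(threshold_correlation(thr, code), hand,
               tolerance = 1e-12)
  expect_error(threshold_correlation(1:5, rep(2, 5)), "zero variance")
})

test_that("female-restricted effect shows in females, not males", {
  st <- generate_study(recovery_spec(seed = 47, n_per_sex = 120L,
                                     effect_rsp = -100))
  calls <- call_diplotypes(st$genotypes, default_blocks()$H2)
  geom <- derive_geometry(st$subjects$height_cm, st$subjects$weight_kg,
                          st$subjects$arm_circ_cm,
                          st$subjects$waist_circ_cm,
                          st$subjects$calf_circ_cm)
  d <- data.frame(
    v = specific_vector(st$subjects$R_ohm, st$subjects$Xc_ohm, geom)$rsp,
    sex = st$subjects$sex,
    group = group_diplotypes(calls$pair, "carrier_vs_aa"))
  res <- groupwise_tests(d, "v", stratify_by_sex = TRUE)
  expect_lt(res$p_value[res$stratum == "F"], 0.05)
  expect_gt(res$p_value[res$stratum == "M"], 0.05)
})

test_that("association table reports the four phenotypes with optional Bonferroni", {
  st <- generate_study(recovery_spec(seed = 53))
  calls <- call_diplotypes(st$genotypes, default_blocks()$H2)
  geom <- derive_geometry(st$subjects$height_cm, st$subjects$weight_kg,
                          st$subjects$arm_circ_cm,
                          st$subjects$waist_circ_cm,
                          st$subjects$calf_circ_cm)
  sv <- specific_vector(st$subjects$R_ohm, st$subjects$Xc_ohm, geom)
  dat <- cbind(sv, b_copies = haplotype_copies(calls$pair),
               sex = st$subjects$sex)
  tab <- association_table(dat, bonferroni = TRUE)
  expect_equal(tab$phenotype, c("rsp", "xcsp", "zsp", "pha"))
  expect_true(all(tab$p_bonferroni >= tab$p_value))
  # injected -100 per copy in half the cohort (females): strong Rsp hit
  expect_lt(tab$p_value[tab$phenotype == "rsp"], 0.05)
  expect_lt(tab$beta[tab$phenotype == "rsp"], 0)
})
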